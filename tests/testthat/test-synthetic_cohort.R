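test_that("zero-noise exact-quota implant gives a clean plateau", {
  imp <- implant_spec("8", 20e6, 40e6, "gain",
                      freq_stageI = 0.5, freq_stageII = 0.5)
  cfg <- cohort_config(n_samples = 48, n_stageI = 12, probe_count = 6000,
                       noise_sd = 0, implants = list(imp),
                       carrier_mode = "exact", seed = 3)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$truth$carriers), 24L)  # exactly half carry it
  inside <- as.character(sim$probes$chrom) == "8" &
    sim$probes$position >= 20e6 & sim$probes$position <= 40e6
  carr <- sim$truth$carriers[, 1] == 1L
  expect_true(all(sim$ratios[carr, inside] == 0.58))
  expect_true(all(sim$ratios[carr, !inside] == 0))
  expect_true(all(sim$ratios[!carr, ] == 0))
})

test_that("same seed reproduces the cohort exactly; seeds differ", {
  cfg <- cohort_config(n_samples = 6, n_stageI = 2, probe_count = 400,
                       seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ratios, b$ratios)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$carriers, b$truth$carriers)
  cfg2 <- cohort_config(n_samples = 6, n_stageI = 2, probe_count = 400,
                        seed = 12)
  expect_false(identical(simulate_cohort(cfg2)$ratios, a$ratios))
})

test_that("binomial carrier frequency concentrates near the target", {
  imp <- implant_spec("2", 10e6, 30e6, "gain",
                      freq_stageI = 0.5, freq_stageII = 0.5)
  freqs <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_samples = 48, n_stageI = 11, probe_count = 50,
                         implants = list(imp), seed = 1000 + s)
    mean(simulate_cohort(cfg)$truth$carriers[, 1])
  }, 0)
  # binomial SE at n=48 is 0.072, so +/-0.15 is ~2 SE: expect ~95% of
  # replicates inside, and the mean on target
  expect_gte(mean(abs(freqs - 0.5) <= 0.15), 0.90)
  expect_lt(abs(mean(freqs) - 0.5), 0.05)
})

test_that("per-stage carrier quotas are drawn within stage strata", {
  imp <- implant_spec("5", 10e6, 30e6, "gain",
                      freq_stageI = 0.2, freq_stageII = 0.8)
  cfg <- cohort_config(n_samples = 40, n_stageI = 20, probe_count = 50,
                       implants = list(imp), carrier_mode = "exact",
                       seed = 4)
  sim <- simulate_cohort(cfg)
  st <- sim$truth$stage
  expect_equal(sum(sim$truth$carriers[st == "I", 1]), 4L)
  expect_equal(sum(sim$truth$carriers[st == "II", 1]), 16L)
})

test_that("opposite-sign overlapping implants in one sample are refused", {
  g <- implant_spec("3", 10e6, 30e6, "gain", freq_stageI = 1,
                    freq_stageII = 1)
  l <- implant_spec("3", 20e6, 40e6, "loss", freq_stageI = 1,
                    freq_stageII = 1)
  cfg <- cohort_config(n_samples = 4, n_stageI = 2, probe_count = 50,
                       implants = list(g, l), carrier_mode = "exact",
                       seed = 1)
  expect_error(simulate_cohort(cfg), "opposite sign")
})

test_that("hazard multipliers scale the event rate of carriers", {
  imp <- implant_spec("1", 10e6, 30e6, "gain", freq_stageI = 0.5,
                      freq_stageII = 0.5, hazard_multiplier = 8)
  cfg <- cohort_config(n_samples = 200, n_stageI = 50, probe_count = 50,
                       implants = list(imp), carrier_mode = "exact",
                       seed = 21)
  sim <- simulate_cohort(cfg)
  carr <- sim$truth$carriers[, 1] == 1
  expect_equal(unique(sim$truth$rate[carr]), 0.025 * 8)
  expect_equal(unique(sim$truth$rate[!carr]), 0.025)
  expect_gt(mean(sim$clinical$event[carr]), mean(sim$clinical$event[!carr]))
})

test_that("qPCR simulation matches delta-delta-Ct arithmetic exactly", {
  imp <- implant_spec("16", 28e6, 31e6, "gain", freq_stageI = 0.5,
                      freq_stageII = 0.5)
  cfg <- cohort_config(n_samples = 8, n_stageI = 4, probe_count = 50,
                       implants = list(imp), carrier_mode = "exact",
                       seed = 2)
  sim <- simulate_cohort(cfg)
  ct <- simulate_qpcr(sim$truth, colnames(sim$truth$carriers)[1],
                      ct_noise_sd = 0, dosage = 4, locus = "NUPR1",
                      seed = 5)
  calls <- ddct_calls(ct, "control_13q32")
  carr <- sim$truth$carriers[calls$sample, 1] == 1
  expect_equal(calls$delta_delta_ct[carr], rep(-2, sum(carr)))
  expect_equal(calls$dosage_ratio[carr], rep(4, sum(carr)))
  expect_true(all(calls$gain[carr]))
  expect_equal(calls$dosage_ratio[!carr], rep(1, sum(!carr)))
  expect_false(any(calls$gain[!carr]))

  # seeded determinism
  ct2 <- simulate_qpcr(sim$truth, colnames(sim$truth$carriers)[1],
                       ct_noise_sd = 0.3, locus = "NUPR1", seed = 5)
  ct3 <- simulate_qpcr(sim$truth, colnames(sim$truth$carriers)[1],
                       ct_noise_sd = 0.3, locus = "NUPR1", seed = 5)
  expect_identical(ct2, ct3)
  expect_error(simulate_qpcr(sim$truth, colnames(sim$truth$carriers)[1],
                             ct_noise_sd = -1), "ct_noise_sd")
})
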