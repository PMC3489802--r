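make_call <- function(sample, chrom, start, end, state,
                      first_probe, last_probe) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             first_probe = first_probe, last_probe = last_probe,
             n_probes = last_probe - first_probe + 1L,
             mean_log2 = if (state == "gain") 0.6 else
               if (state == "loss") -0.6 else 0,
             flag = "", state = state,
             high_level = "none", stringsAsFactors = FALSE)
}

# 10-sample cohort on a 60-probe chromosome: one sample carries a gain
# over probes 21..40
tiny_cohort <- function() {
  pm <- dense_probe_map(60)
  calls <- do.call(rbind, lapply(1:10, function(i) {
    id <- sprintf("s%02d", i)
    if (i == 1) rbind(
      make_call(id, "1", pm$position[1], pm$position[20], "neutral", 1L, 20L),
      make_call(id, "1", pm$position[21], pm$position[40], "gain", 21L, 40L),
      make_call(id, "1", pm$position[41], pm$position[60], "neutral", 41L, 60L))
    else make_call(id, "1", pm$position[1], pm$position[60], "neutral",
                   1L, 60L)
  }))
  list(pm = pm, calls = calls)
}

test_that("probe frequencies count carriers per probe and per state", {
  tc <- tiny_cohort()
  f <- probe_frequency(tc$calls, tc$pm, "gain")
  expect_equal(f[21:40], rep(0.1, 20))
  expect_equal(f[c(1:20, 41:60)], rep(0, 40))
  expect_equal(probe_frequency(tc$calls, tc$pm, "loss"), rep(0, 60))
})

test_that("gain+loss frequencies are bounded by construction", {
  set.seed(17)
  pm <- dense_probe_map(40)
  for (rep in 1:5) {
    calls <- do.call(rbind, lapply(1:6, function(i) {
      brk <- sort(sample(5:35, 2))
      states <- sample(c("gain", "loss", "neutral"), 3, replace = TRUE)
      rbind(
        make_call(sprintf("s%d", i), "1", pm$position[1],
                  pm$position[brk[1]], states[1], 1L, brk[1]),
        make_call(sprintf("s%d", i), "1", pm$position[brk[1] + 1],
                  pm$position[brk[2]], states[2], brk[1] + 1L, brk[2]),
        make_call(sprintf("s%d", i), "1", pm$position[brk[2] + 1],
                  pm$position[40], states[3], brk[2] + 1L, 40L))
    }))
    fg <- probe_frequency(calls, pm, "gain")
    fl <- probe_frequency(calls, pm, "loss")
    expect_true(all(fg >= 0 & fg <= 1 & fl >= 0 & fl <= 1))
    expect_true(all(fg + fl <= 1 + 1e-12))
  }
})

test_that("event classification matches the published frequency table", {
  ref <- reference_rar_table()
  got <- classify_event(ref$freq_stageI_pct / 100,
                        ref$freq_stageII_pct / 100)
  map <- c(earlier = "Earlier", later = "Later", unclassified = "UC")
  expect_equal(unname(map[got]), ref$event)
  expect_equal(sum(got == "earlier"), 15L)
  expect_equal(sum(got == "later"), 2L)
  expect_equal(sum(got == "unclassified"), 6L)
})

test_that("event rule boundaries behave as specified", {
  # at-least-30% is inclusive for earlier
  expect_equal(classify_event(0.30, 0.30), "earlier")
  expect_equal(classify_event(0.29, 0.54), "unclassified")
  # later needs strictly <10% and >40%
  expect_equal(classify_event(0.09, 0.46), "later")
  expect_equal(classify_event(0.10, 0.46), "unclassified")
  expect_equal(classify_event(0.09, 0.40), "unclassified")
  expect_equal(classify_event(0.36, 0.54), "earlier")
  expect_equal(classify_event(0.27, 0.41), "unclassified")
})

test_that("the 30% frequency floor is inclusive at exactly 30%", {
  pm <- dense_probe_map(40)
  build <- function(n_carriers, n_total = 100) {
    do.call(rbind, lapply(1:n_total, function(i) {
      id <- sprintf("s%03d", i)
      if (i <= n_carriers) rbind(
        make_call(id, "1", pm$position[1], pm$position[10], "neutral",
                  1L, 10L),
        make_call(id, "1", pm$position[11], pm$position[30], "gain",
                  11L, 30L),
        make_call(id, "1", pm$position[31], pm$position[40], "neutral",
                  31L, 40L))
      else make_call(id, "1", pm$position[1], pm$position[40], "neutral",
                     1L, 40L)
    }))
  }
  # 29 carriers of 100: frequency 0.29 < 0.30, no candidate region
  expect_equal(nrow(detect_rars(build(29), pm, min_freq = 0.30,
                                n_perm = 99, seed = 1)), 0L)
  # 30 carriers of 100: exactly 30%, reported with exact probe bounds
  rars <- detect_rars(build(30), pm, min_freq = 0.30, n_perm = 199,
                      seed = 1)
  expect_equal(nrow(rars), 1L)
  expect_equal(rars$first_probe, 11L)
  expect_equal(rars$last_probe, 30L)
  expect_lt(rars$p_value, 0.05)
})

test_that("raising min_freq never adds RARs", {
  tc <- tiny_cohort()
  # 5 of 10 samples carry the gain
  calls <- do.call(rbind, lapply(1:10, function(i) {
    id <- sprintf("s%02d", i)
    if (i <= 5) rbind(
      make_call(id, "1", tc$pm$position[1], tc$pm$position[20], "neutral",
                1L, 20L),
      make_call(id, "1", tc$pm$position[21], tc$pm$position[40], "gain",
                21L, 40L),
      make_call(id, "1", tc$pm$position[41], tc$pm$position[60], "neutral",
                41L, 60L))
    else make_call(id, "1", tc$pm$position[1], tc$pm$position[60],
                   "neutral", 1L, 60L)
  }))
  lo <- detect_rars(calls, tc$pm, min_freq = 0.3, n_perm = 99, seed = 2)
  hi <- detect_rars(calls, tc$pm, min_freq = 0.6, n_perm = 99, seed = 2)
  expect_gte(nrow(lo), nrow(hi))
  expect_equal(nrow(hi), 0L)
})

test_that("reported RAR frequencies equal marker-matrix recounts", {
  imp <- implant_spec("8", 20e6, 40e6, "gain", freq_stageI = 0.5,
                      freq_stageII = 0.5)
  cfg <- cohort_config(n_samples = 16, n_stageI = 4, probe_count = 6000,
                       noise_sd = 0, implants = list(imp),
                       carrier_mode = "exact", seed = 5)
  sim <- simulate_cohort(cfg)
  segs <- segment_cohort(sim$ratios, sim$probes,
                         seg_params(seed = 2, max_permutations = 2000))
  calls <- call_segments(segs)
  rars <- detect_rars(calls, sim$probes, sim$clinical, n_perm = 199,
                      seed = 7)
  expect_equal(nrow(rars), 1L)
  mm <- marker_matrix(rars, calls)
  expect_equal(rars$freq_total, unname(colMeans(mm)))
  st <- collapse_stage(sim$clinical$stage[match(rownames(mm),
                                                sim$clinical$sample)])
  expect_equal(rars$freq_stageI, unname(colMeans(mm[st == "I", ,
                                                    drop = FALSE])))
})

test_that("high-level regions report half-up rounded carrier percents", {
  pm <- dense_probe_map(30)
  mk_hl <- function(sample, hl) {
    r <- make_call(sample, "1", pm$position[11], pm$position[20],
                   if (hl == "amplification") "gain" else "loss", 11L, 20L)
    r$high_level <- hl
    r$mean_log2 <- if (hl == "amplification") 1.8 else -1.8
    r
  }
  neutral_row <- function(sample)
    make_call(sample, "1", pm$position[1], pm$position[30], "neutral",
              1L, 30L)
  # 14 amplification carriers among 48 -> 29%
  calls <- rbind(
    do.call(rbind, lapply(sprintf("c%02d", 1:14), mk_hl,
                          hl = "amplification")),
    do.call(rbind, lapply(sprintf("n%02d", 1:34), neutral_row)))
  hl <- detect_high_level(calls, pm)
  expect_equal(nrow(hl), 1L)
  expect_equal(hl$carrier_count, 14)
  expect_equal(hl$carrier_percent, 29L)

  # 6 of 48 = 12.5% rounds half-up to 13%
  calls6 <- rbind(
    do.call(rbind, lapply(sprintf("c%02d", 1:6), mk_hl,
                          hl = "amplification")),
    do.call(rbind, lapply(sprintf("n%02d", 1:42), neutral_row)))
  expect_equal(detect_high_level(calls6, pm)$carrier_percent, 13L)

  # 4 of 48 (8.3%) is excluded at the 10% cutoff
  calls4 <- rbind(
    do.call(rbind, lapply(sprintf("c%02d", 1:4), mk_hl,
                          hl = "amplification")),
    do.call(rbind, lapply(sprintf("n%02d", 1:44), neutral_row)))
  expect_equal(nrow(detect_high_level(calls4, pm)), 0L)
})

test_that("marker membership requires half the RAR span", {
  pm <- dense_probe_map(60)
  rar <- data.frame(name = "RAR-G1", chrom = "1",
                    start = pm$position[21], end = pm$position[40],
                    type = "gain", stringsAsFactors = FALSE)
  span <- rar$end - rar$start + 1
  full <- make_call("full", "1", pm$position[21], pm$position[40],
                    "gain", 21L, 40L)
  none <- make_call("none", "1", pm$position[1], pm$position[60],
                    "neutral", 1L, 60L)
  # covers 30% of the span only
  part <- make_call("part", "1", pm$position[21],
                    pm$position[21] + round(0.3 * span) - 1, "gain",
                    21L, 26L)
  wrong <- make_call("wrong", "1", pm$position[21], pm$position[40],
                     "loss", 21L, 40L)
  mm <- marker_matrix(rar, rbind(full, none, part, wrong))
  expect_equal(mm["full", 1], 1L)
  expect_equal(mm["none", 1], 0L)
  expect_equal(mm["part", 1], 0L)
  expect_equal(mm["wrong", 1], 0L)
})
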