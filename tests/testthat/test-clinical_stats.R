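test_that("subtype classification covers all receptor combinations", {
  pn <- c("positive", "negative")
  grid <- expand.grid(er = pn, pr = pn, her2 = pn,
                      stringsAsFactors = FALSE)
  got <- classify_subtype(grid$er, grid$pr, grid$her2)
  want <- ifelse(grid$her2 == "positive",
                 ifelse(grid$er == "positive" | grid$pr == "positive",
                        "LuminalB", "HER2"),
                 ifelse(grid$er == "positive" | grid$pr == "positive",
                        "LuminalA", "TNBC"))
  expect_equal(got, want)
  expect_equal(classify_subtype("positive", "negative", "negative"),
               "LuminalA")
  expect_equal(classify_subtype("negative", "negative", "positive"),
               "HER2")
  expect_equal(classify_subtype("negative", "negative", "negative"),
               "TNBC")
})

test_that("Fisher test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  t2 <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(fisher_exact_2x2(t2), oracle_fisher_p(t2),
               tolerance = 1e-12)
  t3 <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact_2x2(t3), oracle_fisher_p(t3),
               tolerance = 1e-12)
  expect_lt(fisher_exact_2x2(t3), 0.001)
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "empty margin")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("FDR adjustment reproduces hand-applied Benjamini-Hochberg", {
  expect_equal(fdr_adjust(0.02), 0.02)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.04, 0.03, 0.8)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_equal(q[order(p)], cummax(q[order(p)]))
})

test_that("Kaplan-Meier estimate matches the hand product-limit values", {
  km <- km_estimate(1:5, c(1, 1, 0, 1, 0))
  expect_equal(km$survival[km$time %in% c(1, 2, 4)], c(0.8, 0.6, 0.3))
  ora <- oracle_km(1:5, c(1, 1, 0, 1, 0))
  expect_equal(km$survival[km$n_event > 0], ora$survival)

  # duplicating every subject leaves the curve unchanged
  km2 <- km_estimate(rep(1:5, 2), rep(c(1, 1, 0, 1, 0), 2))
  expect_equal(km2$survival[km2$n_event > 0], ora$survival)

  # no events: flat at 1
  km0 <- km_estimate(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # non-increasing from 1 by construction
  set.seed(2)
  km3 <- km_estimate(rexp(30), rbinom(30, 1, 0.6))
  expect_true(all(diff(km3$survival) <= 1e-12))
  expect_lte(km3$survival[1], 1)
})

test_that("log-rank matches first-principles computation and symmetry", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e0 <- c(1, 0, 1, 0, 1, 0, 1, 0)
  g0 <- rep(c("a", "b"), each = 4)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)

  # 6-subject example vs the observed-minus-expected oracle
  t1 <- c(1, 3, 4, 2, 5, 6); e1 <- c(1, 1, 0, 1, 1, 0)
  g1 <- rep(c("x", "y"), each = 3)
  lr1 <- logrank_test(t1, e1, g1)
  expect_equal(lr1$statistic, oracle_logrank(t1, e1, g1),
               tolerance = 1e-10)

  # invariant to label swap
  g1r <- ifelse(g1 == "x", "y", "x")
  expect_equal(logrank_test(t1, e1, g1r)$statistic, lr1$statistic)
})

test_that("log-rank trend orders survival across three marker groups", {
  set.seed(14)
  n <- 90
  g <- factor(rep(c("neither", "either", "both"), each = 30),
              levels = c("neither", "either", "both"), ordered = TRUE)
  rate <- c(neither = 0.03, either = 0.1, both = 0.4)[as.character(g)]
  t <- rexp(n, rate); e <- as.integer(t <= 10); t <- pmin(t, 10)
  tr <- logrank_trend(t, e, g)
  expect_equal(tr$df, 1)
  expect_lt(tr$p, 0.01)
  # trend on identical groups is null
  tr0 <- logrank_trend(rep(c(1, 2, 3, 4), 3), rep(c(1, 0, 1, 0), 3),
                       factor(rep(c("a", "b", "c"), each = 4)))
  expect_equal(tr0$statistic, 0, tolerance = 1e-12)
})

test_that("the event horizon censors late deaths at 10 years", {
  h <- apply_horizon(c(3, 10, 12, 15), c(1, 1, 1, 0), 10)
  expect_equal(h$time, c(3, 10, 10, 10))
  expect_equal(h$event, c(1L, 1L, 0L, 0L))
})

test_that("Cox fit matches golden-section partial-likelihood optimum", {
  set.seed(23)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(1.2 * x))
  e <- as.integer(t <= 10); tt <- pmin(t, 10)
  # keep times untied so Breslow = exact partial likelihood
  tt <- tt + seq_len(n) * 1e-6
  fit <- cox_fit(data.frame(x = x), tt, e, horizon = Inf)
  expect_equal(fit$coef, oracle_cox_beta(tt, e, x), tolerance = 1e-6)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_gt(fit$hr, 0)

  # 6-subject worked example
  t6 <- c(1, 2, 3, 4, 5, 6) + 0.1 * (1:6)
  e6 <- c(1, 1, 0, 1, 1, 0)
  x6 <- c(1, 1, 0, 0, 1, 0)
  f6 <- cox_fit(data.frame(x = x6), t6, e6, horizon = Inf)
  expect_equal(f6$coef, oracle_cox_beta(t6, e6, x6), tolerance = 1e-6)
})

test_that("Cox fit drops constant covariates and flags divergence", {
  set.seed(3)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.7)
  expect_warning(
    fit <- cox_fit(data.frame(x = x, z = rep(1, n)), t, e),
    "constant covariate")
  expect_equal(fit$term, "x")
  # perfectly separating covariate has a monotone likelihood
  xs <- as.integer(rank(t) <= n / 2)
  expect_error(
    suppressWarnings(cox_fit(data.frame(xs = xs), t, rep(1, n))),
    "monotone")
})

test_that("marker combination logic follows the conjunction truth table", {
  m <- matrix(c(1, 1, 0, 0,
                1, 0, 1, 0), 4, 2,
              dimnames = list(sprintf("s%d", 1:4), c("A", "B")))
  expect_equal(combined_marker(m, c("A", "B")), c(1L, 0L, 0L, 0L))
  g <- marker_groups(m, c("A", "B"))
  expect_equal(as.character(g), c("both", "either", "either", "neither"))
  expect_equal(sum(table(g)), 4L)
  expect_error(combined_marker(m, c("A", "Z")), "unknown marker")
})

test_that("marker-by-clinical association table uses Fisher plus BH", {
  set.seed(6)
  n <- 40
  cl <- toy_clinical(sprintf("s%02d", 1:n))
  m <- matrix(rbinom(n * 2, 1, 0.4), n, 2,
              dimnames = list(cl$sample, c("RAR-G1", "RAR-L1")))
  res <- rar_clinical_association(m, cl)
  expect_equal(nrow(res), 10L)  # 2 markers x 5 variables
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$p >= 0 & res$p <= 1))
  i <- 3
  tab <- matrix(c(res$n00[i], res$n01[i], res$n10[i], res$n11[i]), 2,
                byrow = TRUE)
  expect_equal(res$p[i], suppressWarnings(fisher_exact_2x2(tab)))
})
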