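# Independent oracles used to verify the package's implementations.
# Each is written from the textbook definition, not from package code.

# Exhaustive best binary split of a sequence by the standardized
# Wilcoxon rank-sum statistic (classical tie-corrected variance
# formula). Returns list(k = leftmost argmax left-block size, z = max).
oracle_best_split <- function(values, min_probes) {
  n <- length(values)
  ks <- seq.int(min_probes, n - min_probes)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  best_z <- -Inf; best_k <- NA_integer_
  for (k in ks) {
    W <- sum(r[1:k])
    mu <- k * (n + 1) / 2
    v <- k * (n - k) / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- if (v > 0) abs(W - mu) / sqrt(v) else 0
    if (z > best_z + 1e-12) { best_z <- z; best_k <- k }
  }
  list(k = best_k, z = best_z)
}

# Hand product-limit estimator: survival after each distinct event time.
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  s <- 1; out_t <- numeric(0); out_s <- numeric(0)
  for (t in sort(unique(times[events == 1]))) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  data.frame(time = out_t, survival = out_s)
}

# Log-rank statistic for two groups from first principles: sum of
# observed-minus-expected deaths in group 1 over event times, squared,
# over the summed hypergeometric variances.
oracle_logrank <- function(times, events, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == sort(unique(group))[1]
  u <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    u <- u + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# Breslow partial log-likelihood for a single covariate; beta maximized
# by golden-section search.
oracle_cox_beta <- function(times, events, x, interval = c(-10, 10)) {
  loglik <- function(beta) {
    ll <- 0
    for (t in sort(unique(times[events == 1]))) {
      d_idx <- which(times == t & events == 1)
      risk <- which(times >= t)
      ll <- ll + beta * sum(x[d_idx]) -
        length(d_idx) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Two-sided Fisher exact p by hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  prob <- function(a) stats::dhyper(a, r1, r2, c1)
  p_obs <- prob(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, prob, 0)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force best Laplace accuracy over antecedents of positive
# literals up to max_size, both classes.
oracle_best_laplace <- function(markers, class, max_size = 3, m = 2) {
  best <- 0
  for (sz in seq_len(min(max_size, ncol(markers)))) {
    for (cb in utils::combn(ncol(markers), sz, simplify = FALSE)) {
      sat <- rowSums(markers[, cb, drop = FALSE] == 1) == sz
      nt <- sum(sat)
      for (cl in unique(class))
        best <- max(best, (sum(sat & class == cl) + 1) / (nt + m))
    }
  }
  best
}

# Dense single/multi-chromosome probe map for unit tests: `spacing` bp
# between probes (default 100 kb, well inside the 1000 kb gap rule).
dense_probe_map <- function(n_per_chrom, chroms = "1", spacing = 1e5) {
  ids <- character(0); cc <- character(0); pos <- integer(0)
  for (ch in chroms) {
    ids <- c(ids, sprintf("p%s_%04d", ch, seq_len(n_per_chrom)))
    cc <- c(cc, rep(ch, n_per_chrom))
    pos <- c(pos, as.integer(seq_len(n_per_chrom) * spacing))
  }
  probe_map(ids, cc, pos)
}

# Four-reaction qPCR Ct fixture (target + control locus, tumor +
# reference template) with optional replicate jitter.
ct_fixture <- function(target_tumor = 26, target_ref = 26,
                       ctrl_tumor = 26, ctrl_ref = 26, sample = "s1",
                       reps = 3, jitter = 0) {
  mk <- function(locus, template, base)
    data.frame(sample = sample, locus = locus, template = template,
               replicate = seq_len(reps),
               ct = base + jitter * c(0, 1, -1)[seq_len(reps)],
               stringsAsFactors = FALSE)
  rbind(mk("NUPR1", "tumor", target_tumor),
        mk("NUPR1", "reference", target_ref),
        mk("ctrl", "tumor", ctrl_tumor),
        mk("ctrl", "reference", ctrl_ref))
}

# Minimal valid clinical table for n samples.
toy_clinical <- function(ids, stage = NULL, time = NULL, event = NULL) {
  n <- length(ids)
  data.frame(sample = ids,
             age_group = rep(c("<50", ">=50"), length.out = n),
             stage = stage %||% rep(c("I", "IIA", "IIB"), length.out = n),
             er = rep(c("positive", "negative"), length.out = n),
             pr = rep("positive", n),
             her2 = rep("negative", n),
             survival_time = time %||% rep(12, n),
             event = event %||% rep(0L, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
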