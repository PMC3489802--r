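# Synthetic cohorts with implanted copy-number alterations and
# proportional-hazards survival. The generator is the test bed for the
# whole pipeline: every implant is recorded in a truth table so parameter
# recovery can be checked end to end.

# Approximate autosome + X lengths (Mb) used to lay out the default
# evenly spaced probe grid.
.chrom_mb <- stats::setNames(
  c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135, 134, 132,
    114, 106, 100, 89, 79, 76, 64, 62, 47, 50, 155),
  c(as.character(1:22), "X"))

.default_mean_log2 <- c(gain = 0.58, loss = -1.0, amplification = 1.8,
                        homozygous_deletion = -1.8)

#' Specify an implanted copy-number alteration
#'
#' An implant is a genomic interval that carrier samples receive as a
#' shift of their per-probe log2 ratios, together with the stage-stratified
#' carrier frequencies and an optional multiplicative effect on the event
#' hazard of carriers.
#'
#' @param chrom chromosome label.
#' @param start,end interval in bp, 1-based inclusive, `start < end`.
#' @param type one of `gain`, `loss`, `amplification`, `homozygous_deletion`.
#' @param mean_log2 segment-level mean shift in log2 units; defaults are
#'   +0.58 (gain), -1.0 (loss), +1.8 (amplification), -1.8 (HD) and must
#'   agree in sign with `type`.
#' @param freq_stageI,freq_stageII carrier proportions in `[0, 1]` within
#'   the stage I and stage II strata.
#' @param hazard_multiplier multiplicative effect (>= 0) on the event hazard
#'   of carriers; 1 = no prognostic effect.
#' @param name optional implant label.
#' @return an `implant_spec` list.
#' @export
implant_spec <- function(chrom, start, end,
                         type = c("gain", "loss", "amplification",
                                  "homozygous_deletion"),
                         mean_log2 = NULL,
                         freq_stageI = 0.3, freq_stageII = 0.3,
                         hazard_multiplier = 1, name = NULL) {
  type <- match.arg(type)
  if (is.null(mean_log2)) mean_log2 <- .default_mean_log2[[type]]
  if (start >= end) stop("implant must have start < end", call. = FALSE)
  want_pos <- type %in% c("gain", "amplification")
  if ((want_pos && mean_log2 <= 0) || (!want_pos && mean_log2 >= 0))
    stop("mean_log2 sign inconsistent with implant type", call. = FALSE)
  for (f in c(freq_stageI, freq_stageII))
    if (f < 0 || f > 1) stop("carrier frequencies must be in [0, 1]",
                             call. = FALSE)
  if (hazard_multiplier < 0)
    stop("hazard_multiplier must be >= 0", call. = FALSE)
  structure(list(chrom = as.character(as_chrom(chrom)), start = start,
                 end = end, type = type, mean_log2 = mean_log2,
                 freq_stageI = freq_stageI, freq_stageII = freq_stageII,
                 hazard_multiplier = hazard_multiplier,
                 name = name %||% sprintf("%s_%s_%d", type, chrom, start)),
            class = "implant_spec")
}

#' Configure a synthetic cohort
#'
#' Defaults emulate a 48-sample early breast cancer discovery cohort on a
#' ~24,000-probe whole-genome oligoarray: 11 stage I samples, per-probe
#' Gaussian noise of 0.15 log2 units around segment-level means,
#' exponential survival with administrative censoring at 10 years.
#'
#' @param n_samples cohort size.
#' @param n_stageI number of stage I samples (the rest are stage II,
#'   split ~70/30 into IIA/IIB).
#' @param probe_count total probes laid out evenly over chromosomes
#'   1--22 and X proportionally to chromosome length.
#' @param noise_sd per-probe Gaussian noise SD, log2 units.
#' @param implants list of [implant_spec()] objects.
#' @param interactions optional list of `list(implants = c(i, j),
#'   hazard_multiplier = h)`: samples carrying *all* the named implants
#'   receive the extra hazard multiplier (models synergistic
#'   double-positive effects).
#' @param baseline_hazard events per year for a carrier-free sample.
#' @param censor_years administrative censoring horizon (years).
#' @param carrier_mode `"binomial"` draws each carrier flag independently;
#'   `"exact"` assigns round(freq * n) carriers per stage stratum, which
#'   makes frequency-threshold behavior deterministic.
#' @param p_er,p_pr,p_her2,p_age_lt50 marginal probabilities for the
#'   clinical covariates (defaults follow typical early-breast-cancer
#'   cohort composition).
#' @param seed integer; fixing it makes the whole cohort reproducible.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 48, n_stageI = 11, probe_count = 24107,
                          noise_sd = 0.15, implants = list(),
                          interactions = list(),
                          baseline_hazard = 0.025, censor_years = 10,
                          carrier_mode = c("binomial", "exact"),
                          p_er = 0.52, p_pr = 0.73, p_her2 = 0.23,
                          p_age_lt50 = 0.5, seed = 1L) {
  carrier_mode <- match.arg(carrier_mode)
  if (n_stageI > n_samples) stop("n_stageI must be <= n_samples", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (inherits(implants, "implant_spec")) implants <- list(implants)
  stopifnot(all(vapply(implants, inherits, TRUE, "implant_spec")))
  structure(list(n_samples = n_samples, n_stageI = n_stageI,
                 probe_count = probe_count, noise_sd = noise_sd,
                 implants = implants, interactions = interactions,
                 baseline_hazard = baseline_hazard,
                 censor_years = censor_years, carrier_mode = carrier_mode,
                 p_er = p_er, p_pr = p_pr, p_her2 = p_her2,
                 p_age_lt50 = p_age_lt50, seed = seed),
            class = "cohort_config")
}

# Evenly spaced probe grid proportional to chromosome lengths.
default_probe_layout <- function(probe_count) {
  n_per <- pmax(round(probe_count * .chrom_mb / sum(.chrom_mb)), 1L)
  # adjust the largest chromosome so counts sum exactly
  n_per[1] <- n_per[1] + probe_count - sum(n_per)
  ids <- character(0); chroms <- character(0); pos <- integer(0)
  for (chrom in chrom_levels()) {
    n <- n_per[[chrom]]
    len <- .chrom_mb[[chrom]] * 1e6
    p <- as.integer(round(seq_len(n) * len / (n + 1)))
    ids <- c(ids, sprintf("P_%s_%05d", chrom, seq_len(n)))
    chroms <- c(chroms, rep(chrom, n))
    pos <- c(pos, p)
  }
  probe_map(ids, chroms, pos)
}

#' Simulate a cohort of array-CGH profiles with clinical follow-up
#'
#' Each sample's log2 profile is the sum of implanted segment means over
#' implants the sample carries plus independent Gaussian noise. Survival
#' times are exponential with hazard `baseline_hazard` times the product of
#' hazard multipliers of carried implants (and of any satisfied
#' interactions); times past `censor_years` are administratively censored.
#'
#' @param config a [cohort_config()].
#' @return list with elements `probes` ([probe_map()]), `ratios`
#'   (samples x probes matrix), `clinical` (data frame), and `truth`
#'   (list: `carriers` samples x implants 0/1 matrix, `stage`, `rate`,
#'   and the implant list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  probes <- default_probe_layout(config$probe_count)

  stage1 <- sort(sample.int(n, config$n_stageI))
  stage_collapsed <- ifelse(seq_len(n) %in% stage1, "I", "II")
  stage <- stage_collapsed
  ii <- which(stage == "II")
  if (length(ii)) {
    n_iib <- round(0.3 * length(ii))
    iib <- if (n_iib > 0) sort(sample(ii, n_iib)) else integer(0)
    stage[ii] <- "IIA"; stage[iib] <- "IIB"
  }

  imps <- config$implants
  carriers <- matrix(0L, n, length(imps),
                     dimnames = list(ids, vapply(imps, `[[`, "", "name")))
  for (k in seq_along(imps)) {
    for (s in c("I", "II")) {
      idx <- which(stage_collapsed == s)
      if (!length(idx)) next
      f <- if (s == "I") imps[[k]]$freq_stageI else imps[[k]]$freq_stageII
      if (config$carrier_mode == "exact") {
        m <- as.integer(round_half_up(f * length(idx)))
        pick <- if (m > 0) sample(idx, m) else integer(0)
        carriers[pick, k] <- 1L
      } else {
        carriers[idx, k] <- stats::rbinom(length(idx), 1L, f)
      }
    }
  }
  check_ambiguous_overlaps(imps, carriers)

  ratios <- matrix(stats::rnorm(n * nrow(probes), 0, config$noise_sd),
                   nrow = n, dimnames = list(ids, probes$probe_id))
  for (k in seq_along(imps)) {
    sp <- imps[[k]]
    cols <- which(as.character(probes$chrom) == sp$chrom &
                  probes$position >= sp$start & probes$position <= sp$end)
    rows <- which(carriers[, k] == 1L)
    if (length(cols) && length(rows))
      ratios[rows, cols] <- ratios[rows, cols] + sp$mean_log2
  }

  mult <- rep(1, n)
  for (k in seq_along(imps))
    mult <- mult * ifelse(carriers[, k] == 1L, imps[[k]]$hazard_multiplier, 1)
  for (ia in config$interactions) {
    hit <- rowSums(carriers[, ia$implants, drop = FALSE] == 1L) ==
      length(ia$implants)
    mult <- mult * ifelse(hit, ia$hazard_multiplier, 1)
  }
  rate <- config$baseline_hazard * mult
  t_raw <- stats::rexp(n, rate = pmax(rate, 1e-12))
  t_raw[rate == 0] <- Inf
  event <- as.integer(t_raw <= config$censor_years)
  time <- pmin(t_raw, config$censor_years)

  clinical <- data.frame(
    sample = ids,
    age_group = ifelse(stats::runif(n) < config$p_age_lt50, "<50", ">=50"),
    stage = stage,
    er = ifelse(stats::runif(n) < config$p_er, "positive", "negative"),
    pr = ifelse(stats::runif(n) < config$p_pr, "positive", "negative"),
    her2 = ifelse(stats::runif(n) < config$p_her2, "positive", "negative"),
    survival_time = round(time, 6), event = event,
    stringsAsFactors = FALSE)
  clinical$subtype <- classify_subtype(clinical$er, clinical$pr,
                                       clinical$her2)

  list(probes = probes, ratios = ratios, clinical = clinical,
       truth = list(carriers = carriers, stage = stage_collapsed,
                    rate = rate, implants = imps))
}

# Overlapping implants of opposite sign carried by the same sample make
# the implanted truth ambiguous; refuse to simulate them.
check_ambiguous_overlaps <- function(imps, carriers) {
  if (length(imps) < 2) return(invisible())
  for (a in seq_along(imps)) for (b in seq_len(a - 1L)) {
    ia <- imps[[a]]; ib <- imps[[b]]
    if (ia$chrom != ib$chrom) next
    if (ia$start > ib$end || ib$start > ia$end) next
    if (sign(ia$mean_log2) == sign(ib$mean_log2)) next
    both <- carriers[, a] == 1L & carriers[, b] == 1L
    if (any(both))
      stop(sprintf(
        "implants '%s' and '%s' overlap with opposite sign in sample(s) %s",
        ia$name, ib$name,
        paste(utils::head(rownames(carriers)[both], 3), collapse = ", ")),
        call. = FALSE)
  }
  invisible()
}

#' Simulate a genomic qPCR Ct table for one implanted region
#'
#' Carriers of the implant get their tumor-template target Ct lowered by
#' `log2(dosage)` cycles relative to the diploid control locus; the
#' reference template and all control-locus reactions sit at the baseline
#' cycle number. Triplicate Cts are jittered with Gaussian noise of
#' `ct_noise_sd` cycles.
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param implant_name name of a gain/amplification implant in the truth.
#' @param ct_noise_sd replicate noise SD in cycles (>= 0).
#' @param dosage copy-dosage ratio of carriers (default 1.5, i.e. 3 copies
#'   over a diploid 2).
#' @param locus label for the target locus rows; the diploid control locus
#'   is written as `control_13q32`.
#' @param base_ct baseline threshold cycle.
#' @param n_replicates replicates per reaction.
#' @param seed RNG seed.
#' @return a Ct table data frame (see [read_ct_table()]).
#' @export
simulate_qpcr <- function(truth, implant_name, ct_noise_sd = 0.2,
                          dosage = 1.5, locus = implant_name,
                          base_ct = 26, n_replicates = 3, seed = 1L) {
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  k <- match(implant_name, colnames(truth$carriers))
  if (is.na(k)) stop("unknown implant: ", implant_name, call. = FALSE)
  type <- truth$implants[[k]]$type
  if (!type %in% c("gain", "amplification"))
    stop("qPCR simulation expects a gain/amplification implant", call. = FALSE)
  with_seed(seed, {
    ids <- rownames(truth$carriers)
    grid <- expand.grid(sample = ids,
                        locus = c(locus, "control_13q32"),
                        template = c("tumor", "reference"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$sample, grid$locus, grid$template,
                       grid$replicate), ]
    carrier <- truth$carriers[grid$sample, k] == 1L
    shift <- ifelse(grid$locus == locus & grid$template == "tumor" & carrier,
                    -log2(dosage), 0)
    grid$ct <- base_ct + shift +
      stats::rnorm(nrow(grid), 0, ct_noise_sd)
    rownames(grid) <- NULL
    grid
  })
}
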