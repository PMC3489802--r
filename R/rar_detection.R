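# Cohort-level recurrence analysis: per-probe alteration frequencies,
# recurrently altered regions (RARs) against a circular-shift permutation
# null, stage-based event timing, and high-level amplification/HD regions.

# samples x probes integer state matrix (-1 loss, 0 neutral, +1 gain)
# from a called segment table. Uses probe-index bookkeeping columns when
# present, else maps segments to probes by coordinates.
.state_matrix <- function(calls, probes, field = "state") {
  samples <- unique(calls$sample)
  P <- nrow(probes)
  codes <- if (field == "state") c(gain = 1L, loss = -1L, neutral = 0L)
           else c(amplification = 1L, homozygous_deletion = -1L, none = 0L)
  M <- matrix(0L, length(samples), P, dimnames = list(samples, NULL))
  has_idx <- all(c("first_probe", "last_probe") %in% names(calls))
  si <- match(calls$sample, samples)
  for (r in seq_len(nrow(calls))) {
    code <- codes[[calls[[field]][r]]]
    if (code == 0L) next
    if (has_idx) {
      cols <- calls$first_probe[r]:calls$last_probe[r]
    } else {
      cols <- which(probes$chrom == calls$chrom[r] &
                    probes$position >= calls$start[r] &
                    probes$position <= calls$end[r])
    }
    M[si[r], cols] <- code
  }
  M
}

#' Per-probe alteration frequency across a cohort
#'
#' @param calls a `cna_calls` table for the full cohort.
#' @param probes the [probe_map()].
#' @param type `"gain"` or `"loss"`; the two are computed independently.
#' @return numeric vector (length = probes) of carrier proportions.
#' @export
probe_frequency <- function(calls, probes, type = c("gain", "loss")) {
  type <- match.arg(type)
  S <- .state_matrix(calls, probes)
  colMeans(S == if (type == "gain") 1L else -1L)
}

#' Stage-stratified event-timing rule for RARs
#'
#' A RAR frequent in both stage strata is interpreted as an earlier event
#' in tumor progression; one rare in stage I but frequent in stage II as a
#' relatively later event; anything else is unclassified.
#'
#' @param earlier_min_freq both-stage minimum frequency for `earlier`
#'   (default 0.30, inclusive).
#' @param later_maxI stage I frequency strictly below this (default 0.10)
#'   and
#' @param later_minII stage II frequency strictly above this (default
#'   0.40) classify a RAR as `later`.
#' @return an `event_rule` list.
#' @export
event_rule <- function(earlier_min_freq = 0.30, later_maxI = 0.10,
                       later_minII = 0.40) {
  if (later_maxI >= earlier_min_freq)
    stop("later_maxI must be below earlier_min_freq", call. = FALSE)
  structure(list(earlier_min_freq = earlier_min_freq,
                 later_maxI = later_maxI, later_minII = later_minII),
            class = "event_rule")
}

#' Classify RARs as earlier/later events from stage-stratified frequencies
#'
#' @param freq_I,freq_II carrier proportions in stage I and stage II
#'   samples (vectors recycled to common length).
#' @param rule an [event_rule()].
#' @return character vector of `"earlier"`, `"later"`, `"unclassified"`.
#' @export
classify_event <- function(freq_I, freq_II, rule = event_rule()) {
  stopifnot(all(freq_I >= 0 & freq_I <= 1), all(freq_II >= 0 & freq_II <= 1))
  eps <- 1e-9
  later <- freq_I < rule$later_maxI & freq_II > rule$later_minII
  earlier <- freq_I >= rule$earlier_min_freq - eps &
    freq_II >= rule$earlier_min_freq - eps
  ifelse(later, "later", ifelse(earlier, "earlier", "unclassified"))
}

# maximal runs (within one chromosome's column range) where `keep` is TRUE
.maximal_runs <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect recurrently altered regions (RARs)
#'
#' Candidate regions are maximal probe runs whose gain (or loss) frequency
#' is at least `min_freq`; gains and losses are delineated in independent
#' passes. Each candidate is tested against a permutation null in which
#' every sample's per-probe state vector is circularly shifted within the
#' chromosome (preserving that sample's segment-length spectrum and
#' alteration burden); the p-value is the fraction of permutations whose
#' maximum frequency over the candidate's span reaches the observed
#' maximum. Regions with `p < alpha` are reported as RAR-G1, RAR-G2, ...
#' / RAR-L1, ... in genomic order.
#'
#' @param calls cohort `cna_calls` table (>= 2 samples).
#' @param probes the [probe_map()].
#' @param clinical optional clinical table; when given, stage-stratified
#'   frequencies and the earlier/later event class are reported.
#' @param min_freq minimum carrier frequency (default 0.30, inclusive).
#' @param alpha significance level on the permutation p (default 0.05,
#'   strict).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the shifts.
#' @param rule an [event_rule()].
#' @return a `rar_table` data frame: `name`, `chrom`, `start`, `end` (bp),
#'   `size_mb`, `type`, `p_value`, `freq_total`, `freq_stageI`,
#'   `freq_stageII`, `event`, plus probe-index bounds.
#' @export
detect_rars <- function(calls, probes, clinical = NULL, min_freq = 0.30,
                        alpha = 0.05, n_perm = 1000, seed = 1L,
                        rule = event_rule()) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  samples <- unique(calls$sample)
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  S <- .state_matrix(calls, probes)
  n <- length(samples)
  eps <- 1e-9

  regions <- with_seed(seed, {
    out <- list()
    for (type in c("gain", "loss")) {
      code <- if (type == "gain") 1L else -1L
      ind <- S == code
      freq <- colMeans(ind)
      for (chrom in levels(probes$chrom)) {
        cols <- which(probes$chrom == chrom)
        if (!length(cols)) next
        runs <- .maximal_runs(freq[cols] >= min_freq - eps)
        if (!nrow(runs)) next
        L <- length(cols)
        indc <- ind[, cols, drop = FALSE]
        obs_max <- vapply(seq_len(nrow(runs)), function(r)
          max(freq[cols[runs[r, 1]:runs[r, 2]]]), 0)
        exceed <- integer(nrow(runs))
        for (b in seq_len(n_perm)) {
          counts <- numeric(L)
          offs <- sample.int(L, n, replace = TRUE) - 1L
          for (s in seq_len(n)) {
            o <- offs[s]
            row <- if (o == 0L) indc[s, ] else
              indc[s, c((L - o + 1L):L, 1L:(L - o))]
            counts <- counts + row
          }
          pmaxs <- vapply(seq_len(nrow(runs)), function(r)
            max(counts[runs[r, 1]:runs[r, 2]]), 0) / n
          exceed <- exceed + (pmaxs >= obs_max - eps)
        }
        pv <- (exceed + 1) / (n_perm + 1)
        for (r in seq_len(nrow(runs))) {
          fp <- cols[runs[r, 1]]; lp <- cols[runs[r, 2]]
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = probes$position[fp],
            end = probes$position[lp], first_probe = fp, last_probe = lp,
            type = type, p_value = pv[r], stringsAsFactors = FALSE)
        }
      }
    }
    out
  })

  empty <- data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      first_probe = integer(), last_probe = integer(),
                      size_mb = numeric(), type = character(),
                      p_value = numeric(), freq_total = numeric(),
                      freq_stageI = numeric(), freq_stageII = numeric(),
                      event = character(), stringsAsFactors = FALSE)
  if (!length(regions)) {
    class(empty) <- c("rar_table", "data.frame"); return(empty)
  }
  reg <- do.call(rbind, regions)
  reg <- reg[reg$p_value < alpha, , drop = FALSE]
  if (!nrow(reg)) {
    class(empty) <- c("rar_table", "data.frame"); return(empty)
  }
  reg$chrom_f <- factor(reg$chrom, levels = chrom_levels())
  reg <- reg[order(reg$type, reg$chrom_f, reg$start), , drop = FALSE]
  reg$name <- ""
  for (type in c("gain", "loss")) {
    i <- which(reg$type == type)
    reg$name[i] <- sprintf("RAR-%s%d", if (type == "gain") "G" else "L",
                           seq_along(i))
  }
  reg$size_mb <- round_half_up((reg$end - reg$start + 1) / 1e6, 2)
  reg$chrom_f <- NULL

  mm <- marker_matrix(reg, calls)
  reg$freq_total <- colMeans(mm)
  if (!is.null(clinical)) {
    st <- collapse_stage(clinical$stage[match(rownames(mm),
                                              clinical$sample)])
    fI <- colMeans(mm[st == "I", , drop = FALSE])
    fII <- colMeans(mm[st == "II", , drop = FALSE])
    reg$freq_stageI <- fI
    reg$freq_stageII <- fII
    reg$event <- classify_event(fI, fII, rule)
  } else {
    reg$freq_stageI <- NA_real_; reg$freq_stageII <- NA_real_
    reg$event <- NA_character_
  }
  reg <- reg[, names(empty)]
  rownames(reg) <- NULL
  class(reg) <- c("rar_table", "data.frame")
  reg
}

#' Detect recurrent high-level amplification / homozygous-deletion regions
#'
#' Maximal probe runs where at least one sample carries the high-level
#' flag; regions whose carrier fraction exceeds `min_carrier_frac`
#' (strict) are reported with the carrier count and a half-up rounded
#' percentage.
#'
#' @param calls cohort `cna_calls` table.
#' @param probes the [probe_map()].
#' @param min_carrier_frac reporting cutoff on the carrier fraction
#'   (default 0.10, exclusive).
#' @return data frame: `name` (AMP1../HD1..), `chrom`, `start`, `end`,
#'   `size_mb`, `type`, `carrier_count`, `carrier_percent`.
#' @export
detect_high_level <- function(calls, probes, min_carrier_frac = 0.10) {
  stopifnot_cols(calls, "high_level", "call table")
  samples <- unique(calls$sample)
  n <- length(samples)
  H <- .state_matrix(calls, probes, field = "high_level")
  out <- list()
  for (type in c("amplification", "homozygous_deletion")) {
    code <- if (type == "amplification") 1L else -1L
    ind <- H == code
    count <- colSums(ind)
    for (chrom in levels(probes$chrom)) {
      cols <- which(probes$chrom == chrom)
      if (!length(cols)) next
      runs <- .maximal_runs(count[cols] >= 1)
      for (r in seq_len(nrow(runs))) {
        rc <- cols[runs[r, 1]:runs[r, 2]]
        carriers <- sum(rowSums(ind[, rc, drop = FALSE]) > 0)
        if (carriers / n <= min_carrier_frac) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = probes$position[rc[1]],
          end = probes$position[rc[length(rc)]], type = type,
          carrier_count = carriers, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      size_mb = numeric(), type = character(),
                      carrier_count = integer(),
                      carrier_percent = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$chrom_f <- factor(res$chrom, levels = chrom_levels())
  res <- res[order(res$type, res$chrom_f, res$start), , drop = FALSE]
  res$name <- ""
  for (type in c("amplification", "homozygous_deletion")) {
    i <- which(res$type == type)
    res$name[i] <- sprintf("%s%d", if (type == "amplification") "AMP"
                           else "HD", seq_along(i))
  }
  res$size_mb <- round_half_up((res$end - res$start + 1) / 1e6, 2)
  res$carrier_percent <- as.integer(round_half_up(100 * res$carrier_count / n))
  res$chrom_f <- NULL
  res <- res[, c("name", "chrom", "start", "end", "size_mb", "type",
                 "carrier_count", "carrier_percent")]
  rownames(res) <- NULL
  res
}

#' Binary RAR marker matrix
#'
#' A sample scores 1 for a RAR when its same-direction non-neutral calls
#' cover at least half of the RAR span (in bp), 0 otherwise.
#'
#' @param rars a `rar_table` from [detect_rars()].
#' @param calls the cohort `cna_calls` table.
#' @param min_overlap minimum covered fraction of the RAR span
#'   (default 0.5).
#' @return integer matrix, samples x RARs (named by RAR).
#' @export
marker_matrix <- function(rars, calls, min_overlap = 0.5) {
  samples <- unique(calls$sample)
  M <- matrix(0L, length(samples), nrow(rars),
              dimnames = list(samples, rars$name))
  if (!nrow(rars)) return(M)
  cstate <- calls$state
  cchrom <- as.character(calls$chrom)
  for (j in seq_len(nrow(rars))) {
    span <- as.numeric(rars$end[j] - rars$start[j] + 1)
    sel <- which(cstate == rars$type[j] & cchrom == rars$chrom[j] &
                 calls$start <= rars$end[j] & calls$end >= rars$start[j])
    if (!length(sel)) next
    ov <- pmin(calls$end[sel], rars$end[j]) -
      pmax(calls$start[sel], rars$start[j]) + 1
    cov <- tapply(as.numeric(ov), calls$sample[sel], sum)
    hit <- names(cov)[cov >= min_overlap * span]
    M[hit, j] <- 1L
  }
  M
}
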