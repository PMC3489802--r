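# Rank-statistic recursive segmentation of probe-ordered log2 ratios.
#
# Within each gap-free probe run, the best binary split is the position
# maximizing the standardized Wilcoxon rank-sum statistic between the left
# and right halves (midranks for ties). A split is accepted when its
# permutation p-value (labels permuted within the run) clears the
# significance threshold and both children keep at least `min_probes`
# probes; accepted splits recurse into both children.

#' Segmentation parameters
#'
#' @param significance_threshold permutation p-value a split must beat
#'   (default 5.0e-4).
#' @param max_probe_spacing maximum contiguous probe spacing in kbp
#'   (default 1000); larger gaps break a chromosome into separate runs.
#' @param min_probes minimum probes per segment (default 5); runs shorter
#'   than this are emitted as single segments flagged `"short"`.
#' @param max_permutations permutation budget per tested split
#'   (default 10000). Permutations stop early once the p-value provably
#'   cannot beat the threshold, which does not change any accept/reject
#'   decision.
#' @param seed RNG seed for the permutation stream.
#' @return a `seg_params` list.
#' @export
seg_params <- function(significance_threshold = 5e-4,
                       max_probe_spacing = 1000,
                       min_probes = 5,
                       max_permutations = 10000,
                       seed = 1L) {
  if (significance_threshold <= 0 || significance_threshold >= 1)
    stop("significance_threshold must be in (0, 1)", call. = FALSE)
  if (min_probes < 2) stop("min_probes must be >= 2", call. = FALSE)
  if (max_permutations < 1) stop("max_permutations must be >= 1", call. = FALSE)
  structure(list(significance_threshold = significance_threshold,
                 max_probe_spacing = max_probe_spacing,
                 min_probes = min_probes,
                 max_permutations = max_permutations,
                 seed = seed),
            class = "seg_params")
}

#' Split a probe map into contiguous runs
#'
#' Runs break at chromosome boundaries and wherever adjacent probes lie
#' more than `max_probe_spacing` kbp apart. Every probe belongs to exactly
#' one run.
#'
#' @param probes a [probe_map()].
#' @param params a [seg_params()].
#' @return list of integer vectors of probe-map row indices.
#' @export
split_runs <- function(probes, params = seg_params()) {
  stopifnot(inherits(probes, "probe_map"))
  gap_bp <- params$max_probe_spacing * 1000
  runs <- list()
  for (chrom in levels(probes$chrom)) {
    idx <- which(probes$chrom == chrom)
    if (!length(idx)) next
    pos <- probes$position[idx]
    brk <- which(diff(pos) > gap_bp)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(idx))
    for (r in seq_along(starts))
      runs[[length(runs) + 1L]] <- idx[starts[r]:ends[r]]
  }
  runs
}

# Standardized rank-sum statistic |Z_k| for every candidate split k of a
# rank vector (left block = first k values). Var uses the empirical rank
# variance, which is the exact permutation variance including ties.
# Returns numeric(0) when no candidate split exists.
.split_stats <- function(ranks, k_range) {
  n <- length(ranks)
  cs <- cumsum(ranks)[k_range]
  rbar <- (n + 1) / 2
  s2 <- sum((ranks - rbar)^2)
  vr <- k_range * (n - k_range) * s2 / (n * (n - 1))
  z <- abs(cs - k_range * rbar) / sqrt(vr)
  z[vr <= 0] <- 0
  z
}

# Deterministic per-node RNG seed. Seeding each tested split from its own
# (salt, offset, length) identity makes every node's permutation stream
# independent of how many draws earlier nodes consumed, so early stopping
# and threshold changes never perturb decisions at unrelated nodes.
.node_seed <- function(seed, salt, offset, n) {
  as.integer((abs(seed) * 48271 + salt * 16807 + offset * 69621 + n) %%
               2147483563)
}

# Permutation test of the maximal split statistic within one run.
# Returns list(p, k) with k the leftmost argmax split (left size), or
# NULL when no candidate split exists. Early stopping: once the
# exceedance count guarantees p >= threshold, remaining permutations
# cannot flip the decision and are skipped.
.test_split <- function(values, params, node_seed) {
  n <- length(values)
  if (n < 2 * params$min_probes) return(NULL)
  k_range <- seq.int(params$min_probes, n - params$min_probes)
  ranks <- rank(values)
  z <- .split_stats(ranks, k_range)
  obs <- max(z)
  k_best <- k_range[which.max(z)]
  if (obs <= 0) return(list(p = 1, k = k_best))

  B <- params$max_permutations
  thr <- params$significance_threshold
  # exceedances b making p = (b+1)/(B+1) >= thr regardless of further draws
  b_stop <- ceiling(thr * (B + 1) - 1)
  set.seed(node_seed)
  # precomputed permutation-invariant pieces of the split statistic
  rbar <- (n + 1) / 2
  ew <- k_range * rbar
  s2 <- sum((ranks - rbar)^2)
  sdv <- sqrt(k_range * (n - k_range) * s2 / (n * (n - 1)))
  lim <- (obs - 1e-12) * sdv
  b <- 0L; done <- 0L; block <- 128L
  while (done < B) {
    m <- min(block, B - done)
    for (i in seq_len(m)) {
      cs <- cumsum(ranks[sample.int(n)])[k_range]
      if (any(abs(cs - ew) >= lim)) b <- b + 1L
    }
    done <- done + m
    if (b >= b_stop) break
  }
  list(p = (b + 1) / (done + 1), k = k_best)
}

# Recursive segmentation of one gap-free vector of values (no NAs).
# `offset` locates the node within the sample for seed derivation.
# Returns integer matrix with columns first,last (local 1-based indices).
.segment_run <- function(values, params, salt = 0L, offset = 0L) {
  n <- length(values)
  res <- .test_split(values, params,
                     .node_seed(params$seed %||% 0L, salt, offset, n))
  if (is.null(res) || res$p >= params$significance_threshold)
    return(matrix(c(1L, n), 1L, dimnames = list(NULL, c("first", "last"))))
  k <- res$k
  left <- .segment_run(values[1:k], params, salt, offset)
  right <- .segment_run(values[(k + 1):n], params, salt, offset + k)
  right <- right + k
  rbind(left, right)
}

#' Segment one sample's log2 ratio profile
#'
#' @param values numeric vector of per-probe log2 ratios aligned to
#'   `probes`; `NA`s are excluded from the statistics and inherit the
#'   enclosing segment on report.
#' @param probes a [probe_map()].
#' @param params a [seg_params()].
#' @param sample_id label written into the output rows.
#' @return a `seg_table` data frame: `sample`, `chrom`, `start`, `end`
#'   (bp), `first_probe`, `last_probe` (probe-map indices), `n_probes`
#'   (non-missing probes used), `mean_log2`, `flag` (`""` or `"short"`
#'   for runs below `min_probes`).
#' @export
segment_sample <- function(values, probes, params = seg_params(),
                           sample_id = "sample") {
  stopifnot(inherits(probes, "probe_map"), length(values) == nrow(probes))
  with_seed(params$seed %||% 0L,
            segment_sample_impl(values, probes, params, sample_id))
}

segment_sample_impl <- function(values, probes, params, sample_id,
                                salt = 0L) {
  runs <- split_runs(probes, params)
  out <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    idx <- runs[[r]]
    obs <- idx[!is.na(values[idx])]
    if (!length(obs)) next
    v <- values[obs]
    flag <- if (length(v) < params$min_probes) "short" else ""
    segs <- if (length(v) < 2 * params$min_probes)
      matrix(c(1L, length(v)), 1L, dimnames = list(NULL, c("first", "last")))
    else .segment_run(v, params, salt = salt, offset = idx[1])
    # extend segment bounds over missing probes: each missing probe joins
    # the segment of the nearest preceding non-missing probe (leading
    # missings join the first segment)
    first_idx <- obs[segs[, "first"]]
    last_idx <- obs[segs[, "last"]]
    first_idx[1] <- idx[1]
    if (nrow(segs) > 1) first_idx[-1] <- last_idx[-nrow(segs)] + 1L
    last_idx[nrow(segs)] <- idx[length(idx)]
    means <- vapply(seq_len(nrow(segs)), function(s)
      mean(v[segs[s, "first"]:segs[s, "last"]]), 0)
    out[[r]] <- data.frame(
      sample = sample_id,
      chrom = probes$chrom[first_idx],
      start = probes$position[first_idx],
      end = probes$position[last_idx],
      first_probe = first_idx, last_probe = last_idx,
      n_probes = segs[, "last"] - segs[, "first"] + 1L,
      mean_log2 = means, flag = flag,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(sample = character(), chrom = factor(character(),
                      levels = chrom_levels()), start = integer(),
                      end = integer(), first_probe = integer(),
                      last_probe = integer(), n_probes = integer(),
                      mean_log2 = numeric(), flag = character())
  rownames(res) <- NULL
  class(res) <- c("seg_table", "data.frame")
  res
}

#' Segment every sample of a ratio matrix
#'
#' Samples are processed in row order under a single seeded permutation
#' stream, so a fixed `params$seed` makes the whole table reproducible.
#'
#' @param ratios samples x probes matrix (see [read_ratio_matrix()]).
#' @inheritParams segment_sample
#' @return a `seg_table` covering all samples.
#' @export
segment_cohort <- function(ratios, probes, params = seg_params()) {
  stopifnot(is.matrix(ratios), ncol(ratios) == nrow(probes))
  with_seed(params$seed %||% 0L, {
    parts <- lapply(seq_len(nrow(ratios)), function(i)
      segment_sample_impl(ratios[i, ], probes, params,
                          rownames(ratios)[i], salt = i))
    res <- do.call(rbind, parts)
    class(res) <- c("seg_table", "data.frame")
    res
  })
}
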