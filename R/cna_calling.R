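#' Copy-number call thresholds
#'
#' Segment means above `gain_min` (strict) are gains, below `loss_max`
#' (strict) losses; means at or beyond `amp_min` / `hd_max` additionally
#' carry the high-level amplification / homozygous-deletion flag
#' (inclusive thresholds).
#'
#' @param gain_min exclusive lower bound for gains (log2, default +0.2).
#' @param loss_max exclusive upper bound for losses (log2, default -0.3).
#' @param amp_min inclusive amplification threshold (log2, default +1.5).
#' @param hd_max inclusive homozygous-deletion threshold (log2,
#'   default -1.5).
#' @return a `call_thresholds` list.
#' @export
call_thresholds <- function(gain_min = 0.2, loss_max = -0.3,
                            amp_min = 1.5, hd_max = -1.5) {
  if (!(hd_max < loss_max && loss_max < 0 && 0 < gain_min &&
        gain_min < amp_min))
    stop("thresholds must satisfy hd_max < loss_max < 0 < gain_min < amp_min",
         call. = FALSE)
  structure(list(gain_min = gain_min, loss_max = loss_max,
                 amp_min = amp_min, hd_max = hd_max),
            class = "call_thresholds")
}

#' Call copy-number states on a segment table
#'
#' @param segs a `seg_table` (see [segment_cohort()]).
#' @param thresholds a [call_thresholds()].
#' @return the input table with `state` (`gain`/`loss`/`neutral`) and
#'   `high_level` (`none`/`amplification`/`homozygous_deletion`) columns
#'   appended; class `cna_calls`.
#' @export
call_segments <- function(segs, thresholds = call_thresholds()) {
  stopifnot_cols(segs, "mean_log2", "segment table")
  m <- segs$mean_log2
  if (any(!is.finite(m)))
    stop("non-finite segment mean; cannot call state", call. = FALSE)
  state <- ifelse(m > thresholds$gain_min, "gain",
                  ifelse(m < thresholds$loss_max, "loss", "neutral"))
  high <- ifelse(m >= thresholds$amp_min, "amplification",
                 ifelse(m <= thresholds$hd_max, "homozygous_deletion",
                        "none"))
  out <- segs
  out$state <- state
  out$high_level <- high
  class(out) <- c("cna_calls", class(segs)[!(class(segs) %in% "cna_calls")])
  out
}

#' Per-sample alteration summary
#'
#' @param calls `cna_calls` rows for a single sample.
#' @param probes the [probe_map()] the calls were made on; its covered
#'   span is the denominator of `altered_fraction`.
#' @return list with `n_cna` (non-neutral segment count), `altered_mb`
#'   (megabases in non-neutral segments) and `altered_fraction`.
#' @export
sample_summary <- function(calls, probes) {
  stopifnot_cols(calls, c("state", "start", "end"), "call table")
  alt <- calls$state != "neutral"
  altered_bp <- sum(as.numeric(calls$end[alt] - calls$start[alt] + 1))
  total_bp <- sum(vapply(split(probes$position, probes$chrom), function(p)
    if (length(p)) as.numeric(max(p) - min(p) + 1) else 0, 0))
  list(n_cna = sum(alt), altered_mb = altered_bp / 1e6,
       altered_fraction = if (total_bp > 0) altered_bp / total_bp else 0)
}

#' Cohort-level CNA burden statistics
#'
#' @param calls a `cna_calls` table covering >= 1 sample.
#' @param probes the [probe_map()].
#' @return list with `median_n_cna`, `range_n_cna` (length-2),
#'   `mean_altered_mb`, `mean_altered_fraction` and the per-sample table.
#' @export
cohort_cna_stats <- function(calls, probes) {
  samples <- unique(calls$sample)
  if (!length(samples)) stop("empty cohort", call. = FALSE)
  per <- lapply(samples, function(id)
    sample_summary(calls[calls$sample == id, , drop = FALSE], probes))
  n_cna <- vapply(per, `[[`, 0, "n_cna")
  mb <- vapply(per, `[[`, 0, "altered_mb")
  fr <- vapply(per, `[[`, 0, "altered_fraction")
  list(median_n_cna = stats::median(n_cna), range_n_cna = range(n_cna),
       mean_altered_mb = mean(mb), mean_altered_fraction = mean(fr),
       per_sample = data.frame(sample = samples, n_cna = n_cna,
                               altered_mb = mb, altered_fraction = fr,
                               stringsAsFactors = FALSE))
}
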