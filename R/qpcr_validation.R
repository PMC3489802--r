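# Relative copy-number quantification from genomic qPCR by the
# delta-delta-Ct method, and survival replication on the resulting
# binary gain calls.

#' Delta-delta-Ct dosage call for one sample and locus
#'
#' Replicate Cts are averaged first (mean-Ct convention); then
#' `ddCt = (Ct_target,tumor - Ct_control,tumor) -
#' (Ct_target,ref - Ct_control,ref)` and the dosage ratio is
#' `efficiency^-ddCt`. The region is called a gain when the ratio is
#' strictly above `gain_cutoff`.
#'
#' @param ct a Ct table (see [read_ct_table()]).
#' @param sample,locus the reaction to quantify.
#' @param control_locus diploid internal-control locus name.
#' @param gain_cutoff dosage ratio a gain must exceed (default 2, strict).
#' @param efficiency per-cycle amplification factor (default 2, pure
#'   delta-delta-Ct).
#' @param sd_limit replicate Ct SD above which the call is flagged (not
#'   dropped); default 0.5 cycles.
#' @return one-row data frame: `sample`, `locus`, `delta_delta_ct`,
#'   `dosage_ratio`, `gain`, `flagged`.
#' @export
ddct_call <- function(ct, sample, locus, control_locus,
                      gain_cutoff = 2, efficiency = 2, sd_limit = 0.5) {
  pick <- function(loc, tmpl) {
    v <- ct$ct[ct$sample == sample & ct$locus == loc & ct$template == tmpl]
    if (!length(v))
      stop(sprintf("no Ct for sample '%s', locus '%s', template '%s'",
                   sample, loc, tmpl), call. = FALSE)
    v
  }
  if (!any(ct$sample == sample & ct$locus == control_locus))
    stop(sprintf("control locus '%s' missing for sample '%s'",
                 control_locus, sample), call. = FALSE)
  tt <- pick(locus, "tumor"); tc <- pick(control_locus, "tumor")
  rt <- pick(locus, "reference"); rc <- pick(control_locus, "reference")
  spread <- max(vapply(list(tt, tc, rt, rc), function(v)
    if (length(v) > 1) stats::sd(v) else 0, 0))
  ddct <- (mean(tt) - mean(tc)) - (mean(rt) - mean(rc))
  ratio <- efficiency^(-ddct)
  data.frame(sample = sample, locus = locus, delta_delta_ct = ddct,
             dosage_ratio = ratio, gain = ratio > gain_cutoff,
             flagged = spread > sd_limit, stringsAsFactors = FALSE)
}

#' Delta-delta-Ct calls for every sample and target locus in a Ct table
#'
#' @inheritParams ddct_call
#' @return data frame of calls, one row per sample x target locus.
#' @export
ddct_calls <- function(ct, control_locus, gain_cutoff = 2, efficiency = 2,
                       sd_limit = 0.5) {
  loci <- setdiff(unique(ct$locus), control_locus)
  samples <- unique(ct$sample)
  out <- do.call(rbind, lapply(samples, function(s)
    do.call(rbind, lapply(loci, function(l)
      ddct_call(ct, s, l, control_locus, gain_cutoff, efficiency,
                sd_limit)))))
  rownames(out) <- NULL
  out
}

#' Survival replication on qPCR-derived marker calls
#'
#' Converts dosage calls for two target loci into a binary marker matrix
#' and runs the full single-marker, double-positive and three-level
#' (neither/either/both) survival battery: Kaplan-Meier curves, log-rank
#' tests, a trend test, and Cox regression of the combined marker
#' adjusted for age, stage, ER, PR and HER2.
#'
#' @param calls output of [ddct_calls()] for two loci.
#' @param clinical clinical table for the same samples.
#' @param loci the two locus names (default: the loci present).
#' @param horizon event horizon in years (default 10).
#' @return list with `markers`, `km`, `logrank` (per grouping; groupings
#'   with a single level are skipped with a message), `trend`, `cox`.
#' @export
replicate_survival <- function(calls, clinical, loci = NULL, horizon = 10) {
  if (is.null(loci)) loci <- unique(calls$locus)
  samples <- unique(calls$sample)
  markers <- matrix(0L, length(samples), length(loci),
                    dimnames = list(samples, loci))
  for (i in seq_len(nrow(calls)))
    markers[calls$sample[i], calls$locus[i]] <-
      as.integer(calls$gain[i])
  cl <- clinical[match(samples, clinical$sample), ]
  h <- apply_horizon(cl$survival_time, cl$event, horizon)

  groupings <- list()
  for (l in loci) groupings[[l]] <- factor(markers[, l], levels = 0:1)
  both <- combined_marker(markers, loci)
  groupings[["double_positive"]] <- factor(both, levels = 0:1)
  three <- marker_groups(markers, loci)
  groupings[["three_level"]] <- three

  km <- lapply(groupings, function(g)
    km_estimate(h$time, h$event, droplevels(g)))
  logrank <- lapply(names(groupings), function(nm) {
    g <- droplevels(groupings[[nm]])
    if (nlevels(g) < 2) {
      message("grouping '", nm, "' has a single level; log-rank skipped")
      return(NULL)
    }
    logrank_test(h$time, h$event, g)
  })
  names(logrank) <- names(groupings)
  trend <- if (nlevels(droplevels(three)) >= 2)
    logrank_trend(h$time, h$event, droplevels(three)) else NULL

  covs <- data.frame(age = as.integer(cl$age_group == ">=50"),
                     stage = as.integer(collapse_stage(cl$stage) == "II"),
                     er = as.integer(cl$er == "positive"),
                     pr = as.integer(cl$pr == "positive"),
                     her2 = as.integer(cl$her2 == "positive"))
  covs$double_positive <- both
  cox <- tryCatch(cox_fit(covs, cl$survival_time, cl$event, horizon),
                  error = function(e) {
                    message("Cox fit skipped: ", conditionMessage(e))
                    NULL
                  })
  list(markers = markers, km = km, logrank = logrank, trend = trend,
       cox = cox)
}
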