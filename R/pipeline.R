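# End-to-end orchestration: discovery (segment -> call -> RARs -> rule
# mining -> survival) and replication (qPCR -> survival). Reports are
# plain lists of data frames so every number is recomputable from the
# inputs, the parameters and the seed recorded in the provenance block.

#' Run the discovery-arm pipeline
#'
#' Segments every sample, calls copy-number states, delineates RARs and
#' high-level regions, codes the binary RAR marker matrix, mines
#' death-predicting association rules, and evaluates single and combined
#' markers against survival (log-rank and covariate-adjusted Cox).
#'
#' @param probes a [probe_map()].
#' @param ratios samples x probes log2 ratio matrix.
#' @param clinical clinical table (see [read_clinical()]).
#' @param seg a [seg_params()].
#' @param thresholds a [call_thresholds()].
#' @param min_freq,alpha,n_perm RAR detection settings (see
#'   [detect_rars()]).
#' @param mining a [cpar_params()].
#' @param combine optional character vector of two RAR names for the
#'   combined-marker Cox model; defaults to the two most frequent markers
#'   of the top reported death rule when one exists.
#' @param horizon event horizon in years (default 10).
#' @param seed seed for RAR permutations (segmentation uses `seg$seed`).
#' @param verbose log per-stage record counts via `message()`.
#' @return a `run_report` list: `segments`, `calls`, `cna_stats`, `rars`,
#'   `high_level`, `markers`, `rules`, `death_rules`, `survival`
#'   (per-marker log-rank p), `cox_single`, `cox_combined`, `provenance`.
#' @export
run_discovery <- function(probes, ratios, clinical,
                          seg = seg_params(),
                          thresholds = call_thresholds(),
                          min_freq = 0.30, alpha = 0.05, n_perm = 1000,
                          mining = cpar_params(), combine = NULL,
                          horizon = 10, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message("[rarseek] ", sprintf(...))
  clinical <- validate_clinical(clinical)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("segmenting %d samples x %d probes", nrow(ratios), ncol(ratios))
  segs <- stage("segmentation", segment_cohort(ratios, probes, seg))
  say("%d segments", nrow(segs))

  calls <- stage("cna_calling", call_segments(segs, thresholds))
  stats <- stage("cna_calling", cohort_cna_stats(calls, probes))
  say("median CNAs/sample %s, mean altered %.1f Mb",
      format(stats$median_n_cna), stats$mean_altered_mb)

  rars <- stage("rar_detection",
                detect_rars(calls, probes, clinical, min_freq = min_freq,
                            alpha = alpha, n_perm = n_perm, seed = seed))
  high <- stage("rar_detection", detect_high_level(calls, probes))
  say("%d RARs, %d high-level regions", nrow(rars), nrow(high))

  markers <- stage("rar_detection", marker_matrix(rars, calls))
  h <- apply_horizon(clinical$survival_time[match(rownames(markers),
                                                  clinical$sample)],
                     clinical$event[match(rownames(markers),
                                          clinical$sample)], horizon)
  cls <- 1L - h$event  # 0 dead within horizon, 1 alive

  rules <- death_rules <- NULL
  if (ncol(markers) >= 1 && length(unique(cls)) == 2) {
    rules <- stage("rule_mining", mine_rules(markers, cls, mining))
    death_rules <- report_death_rules(rules, mining)
    say("%d rules mined, %d death rules reported", nrow(rules),
        nrow(death_rules))
  } else {
    say("rule mining skipped (no markers or single outcome class)")
  }

  surv <- stage("clinical_stats", {
    res <- lapply(colnames(markers), function(mk) {
      g <- factor(markers[, mk], levels = 0:1)
      if (nlevels(droplevels(g)) < 2) return(NA_real_)
      logrank_test(h$time, h$event, g)$p
    })
    data.frame(marker = colnames(markers),
               logrank_p = unlist(res) %||% numeric(0),
               stringsAsFactors = FALSE)
  })

  base_covs <- data.frame(
    age = as.integer(clinical$age_group == ">=50"),
    stage = as.integer(collapse_stage(clinical$stage) == "II"),
    er = as.integer(clinical$er == "positive"),
    pr = as.integer(clinical$pr == "positive"),
    her2 = as.integer(clinical$her2 == "positive"))
  base_covs <- base_covs[match(rownames(markers), clinical$sample), ,
                         drop = FALSE]

  if (is.null(combine) && !is.null(death_rules) && nrow(death_rules)) {
    top <- strsplit(death_rules$antecedent[1], " & ", fixed = TRUE)[[1]]
    top <- sub("=.*$", "", top)
    if (length(top) >= 2) combine <- top[1:2]
  }

  fit_or_null <- function(covs) {
    tryCatch(suppressWarnings(
      cox_fit(covs, clinical$survival_time[match(rownames(markers),
                                                 clinical$sample)],
              clinical$event[match(rownames(markers), clinical$sample)],
              horizon)),
      error = function(e) { say("Cox fit skipped: %s",
                                conditionMessage(e)); NULL })
  }
  sig <- surv$marker[!is.na(surv$logrank_p) & surv$logrank_p < 0.05]
  cox_single <- if (length(sig))
    fit_or_null(cbind(base_covs,
                      as.data.frame(markers[, sig, drop = FALSE])))
  else fit_or_null(base_covs)
  cox_combined <- NULL
  if (!is.null(combine) && length(combine) >= 2) {
    cc <- combined_marker(markers, combine)
    covs <- base_covs
    covs[[paste(combine, collapse = "*")]] <- cc
    cox_combined <- fit_or_null(covs)
  }

  list(segments = segs, calls = calls, cna_stats = stats, rars = rars,
       high_level = high, markers = markers, rules = rules,
       death_rules = death_rules, survival = surv,
       cox_single = cox_single, cox_combined = cox_combined,
       provenance = list(seed = seed, seg = seg, thresholds = thresholds,
                         min_freq = min_freq, alpha = alpha,
                         n_perm = n_perm, mining = mining,
                         horizon = horizon, combine = combine,
                         version = as.character(
                           utils::packageVersion("rarseek"))))
}

#' Run the replication-arm pipeline
#'
#' Quantifies target-locus dosage from a qPCR Ct table by delta-delta-Ct,
#' calls gains, and runs the replication survival battery.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param clinical clinical table for the replication cohort.
#' @param control_locus diploid internal-control locus name.
#' @param gain_cutoff dosage-ratio cutoff (default 2, strict).
#' @param horizon event horizon in years.
#' @param verbose log stage progress.
#' @return a `run_report` list: `dosage_calls`, `survival` (see
#'   [replicate_survival()]), `provenance`.
#' @export
run_replication <- function(ct, clinical, control_locus,
                            gain_cutoff = 2, horizon = 10,
                            verbose = TRUE) {
  say <- function(...) if (verbose) message("[rarseek] ", sprintf(...))
  clinical <- validate_clinical(clinical)
  calls <- tryCatch(ddct_calls(ct, control_locus, gain_cutoff),
                    error = function(e)
                      stop("stage 'qpcr_validation' failed: ",
                           conditionMessage(e), call. = FALSE))
  say("%d dosage calls, %d gains", nrow(calls), sum(calls$gain))
  surv <- tryCatch(replicate_survival(calls, clinical, horizon = horizon),
                   error = function(e)
                     stop("stage 'clinical_stats' failed: ",
                          conditionMessage(e), call. = FALSE))
  list(dosage_calls = calls, survival = surv,
       provenance = list(control_locus = control_locus,
                         gain_cutoff = gain_cutoff, horizon = horizon,
                         version = as.character(
                           utils::packageVersion("rarseek"))))
}
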