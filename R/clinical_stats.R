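# Clinicopathologic association and survival analysis of RAR markers.
# Standard models are delegated to stats:: and survival::; this module
# fixes the conventions used throughout the pipeline (two-sided Fisher,
# Benjamini-Hochberg FDR, Breslow ties, 10-year event horizon).

#' Molecular subtype from receptor status
#'
#' Luminal A: hormone-receptor positive (ER and/or PR), HER2 negative;
#' Luminal B: hormone-receptor positive, HER2 positive; HER2: both
#' hormone receptors negative, HER2 positive; TNBC: all three negative.
#'
#' @param er,pr,her2 `"positive"`/`"negative"` vectors.
#' @return character vector of `LuminalA`, `LuminalB`, `HER2`, `TNBC`.
#' @export
classify_subtype <- function(er, pr, her2) {
  stopifnot(all(c(er, pr, her2) %in% c("positive", "negative")))
  hr_pos <- er == "positive" | pr == "positive"
  ifelse(her2 == "positive",
         ifelse(hr_pos, "LuminalB", "HER2"),
         ifelse(hr_pos, "LuminalA", "TNBC"))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities of tables (with
#' the observed margins) no more probable than the observed one. A table
#' with an empty margin carries no information: p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in 2x2 table; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values.
#' @return q-values (monotone step-up adjustment).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Kaplan-Meier survival curves
#'
#' @param times follow-up times (years).
#' @param events 0 = censored, 1 = event.
#' @param groups optional group labels; one curve per group.
#' @return data frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival` (the product-limit estimate after each event time).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (is.null(fit$strata)) {
    grp <- rep(levels(groups)[1], length(fit$time))
  } else {
    grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank test for equality of survival curves
#'
#' @inheritParams km_estimate
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2)
    stop("log-rank test needs >= 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Log-rank test for trend across ordered groups
#'
#' Collapses the vector of observed-minus-expected event counts with
#' ordered scores (default equally spaced), giving a 1-df chi-square
#' trend statistic; used for the neither/either/both marker grouping.
#'
#' @inheritParams logrank_test
#' @param groups ordered factor (or labels coerced in level order).
#' @param scores numeric scores per group level.
#' @return list with `statistic`, `df` (1), `p`.
#' @export
logrank_trend <- function(times, events, groups,
                          scores = seq_len(nlevels(as.factor(groups)))) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2)
    stop("trend test needs >= 2 groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  u <- scores - mean(scores)
  omE <- sd$obs - sd$exp
  num <- sum(u * omE)^2
  den <- drop(t(u) %*% sd$var %*% u)
  stat <- if (den > 0) num / den else 0
  list(statistic = stat, df = 1,
       p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Apply the 10-year event horizon
#'
#' The event is death within `horizon` years of diagnosis; survivors and
#' later deaths are censored at `min(followup, horizon)`.
#'
#' @param times follow-up times in years.
#' @param events 0/1 death indicator at end of follow-up.
#' @param horizon horizon in years (default 10).
#' @return list with `time` and `event` vectors.
#' @export
apply_horizon <- function(times, events, horizon = 10) {
  list(time = pmin(times, horizon),
       event = as.integer(events == 1 & times <= horizon))
}

#' Cox proportional-hazards fit with Wald confidence intervals
#'
#' Fits `coxph` with Breslow tie handling on the horizon-censored data.
#' Constant covariates are dropped with a warning; a monotone likelihood
#' (diverging coefficient) is an error naming the covariate.
#'
#' @param covariates data frame of numeric (0/1 for binary) covariates,
#'   one row per sample.
#' @param times,events survival outcome (years; 0/1).
#' @param horizon event horizon in years (default 10); `Inf` disables it.
#' @return data frame per covariate: `term`, `coef`, `hr`, `ci_low`,
#'   `ci_high` (Wald 95%), `p`, plus attributes `n` and `n_event`.
#' @export
cox_fit <- function(covariates, times, events, horizon = 10) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times))
  keep <- vapply(covariates, function(x) length(unique(x)) > 1, TRUE)
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  if (!ncol(covariates)) stop("no usable covariates", call. = FALSE)
  h <- apply_horizon(times, events, horizon)
  dat <- cbind(data.frame(.time = h$time, .event = h$event), covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = dat, ties = "breslow")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  diverged <- !is.finite(beta) | abs(beta) > 15
  if (any(diverged))
    stop("Cox partial likelihood is monotone for covariate(s): ",
         paste(names(beta)[diverged], collapse = ", "), call. = FALSE)
  z <- beta / se
  out <- data.frame(term = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta - 1.96 * se)),
                    ci_high = exp(unname(beta + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- fit$n
  attr(out, "n_event") <- fit$nevent
  out
}

#' Combine binary markers by conjunction
#'
#' @param markers samples x markers 0/1 matrix.
#' @param which_markers column names to combine.
#' @return 0/1 vector: 1 iff the sample is positive for every named
#'   marker.
#' @export
combined_marker <- function(markers, which_markers) {
  miss <- setdiff(which_markers, colnames(markers))
  if (length(miss)) stop("unknown marker(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  as.integer(rowSums(markers[, which_markers, drop = FALSE] == 1) ==
               length(which_markers))
}

#' Three-level grouping for a marker pair
#'
#' @inheritParams combined_marker
#' @return ordered factor `neither < either < both`.
#' @export
marker_groups <- function(markers, which_markers) {
  k <- rowSums(markers[, which_markers, drop = FALSE] == 1)
  factor(c("neither", "either", "both")[pmin(k, 2) + 1],
         levels = c("neither", "either", "both"), ordered = TRUE)
}

#' Association of RAR markers with clinicopathologic variables
#'
#' Each marker is cross-tabulated against each binary clinical variable
#' (age <50 vs >=50, stage I vs II, ER, PR, HER2 status) and tested with
#' the two-sided Fisher exact test; q-values are Benjamini-Hochberg
#' adjusted across all marker x variable tests.
#'
#' @param markers samples x markers 0/1 matrix (rownames = sample ids).
#' @param clinical clinical table (see [read_clinical()]).
#' @return data frame: `marker`, `variable`, `p`, `q` and the 2x2 counts.
#' @export
rar_clinical_association <- function(markers, clinical) {
  cl <- clinical[match(rownames(markers), clinical$sample), ]
  vars <- list(age_group = cl$age_group == "<50",
               stage = collapse_stage(cl$stage) == "II",
               er = cl$er == "positive",
               pr = cl$pr == "positive",
               her2 = cl$her2 == "positive")
  rows <- list()
  for (mk in colnames(markers)) for (v in names(vars)) {
    tab <- table(factor(markers[, mk], levels = 0:1),
                 factor(vars[[v]], levels = c(FALSE, TRUE)))
    p <- suppressWarnings(fisher_exact_2x2(tab))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = mk, variable = v,
      n00 = tab[1, 1], n01 = tab[1, 2], n10 = tab[2, 1], n11 = tab[2, 2],
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}
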