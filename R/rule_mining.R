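# Predictive association-rule mining over binary RAR markers vs a binary
# outcome class, in the CPAR family: greedy FOIL-gain literal selection on
# decaying example weights, branching on near-best literals, with rule
# quality reported as Laplace accuracy recomputed on the raw data.

#' Laplace accuracy of a classification rule
#'
#' `(N_c + 1) / (N_total + m)`: the smoothed precision of a rule whose
#' body is satisfied by `n_total` examples of which `n_c` are in the
#' predicted class, with `m` classes.
#'
#' @param n_c examples satisfying the body that belong to the predicted
#'   class.
#' @param n_total examples satisfying the body.
#' @param m number of classes (>= 2).
#' @return numeric in (0, 1).
#' @export
laplace_accuracy <- function(n_c, n_total, m = 2) {
  if (any(m < 2)) stop("m must be >= 2", call. = FALSE)
  if (any(n_c > n_total)) stop("n_c cannot exceed n_total", call. = FALSE)
  if (any(n_c < 0) || any(n_total < 0))
    stop("counts must be non-negative", call. = FALSE)
  (n_c + 1) / (n_total + m)
}

#' CPAR mining parameters
#'
#' Search hyperparameters follow the published CPAR defaults; the
#' reporting cutoff keeps rules whose Laplace accuracy is strictly above
#' `min_laplace_report`.
#'
#' @param min_gain minimum FOIL gain to extend a rule (default 0.7).
#' @param decay multiplicative weight decay of covered positive examples
#'   (default 2/3).
#' @param gain_similarity branch on every literal whose gain is within
#'   this factor of the best (default 0.99).
#' @param best_k number of best rules retained per class for prediction
#'   contexts (default 5; rule generation itself reports all rules).
#' @param min_laplace_report strict lower bound on reported Laplace
#'   accuracy (default 0.75).
#' @param weight_threshold stop once the remaining total positive weight
#'   falls to this fraction of its initial value (default 0.05).
#' @param negative_literals allow `marker = 0` literals in rule bodies
#'   (default `FALSE`: only the presence of an alteration predicts).
#' @return a `cpar_params` list.
#' @export
cpar_params <- function(min_gain = 0.7, decay = 2 / 3,
                        gain_similarity = 0.99, best_k = 5,
                        min_laplace_report = 0.75,
                        weight_threshold = 0.05,
                        negative_literals = FALSE) {
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)", call. = FALSE)
  if (gain_similarity <= 0 || gain_similarity > 1)
    stop("gain_similarity must be in (0, 1]", call. = FALSE)
  structure(list(min_gain = min_gain, decay = decay,
                 gain_similarity = gain_similarity, best_k = best_k,
                 min_laplace_report = min_laplace_report,
                 weight_threshold = weight_threshold,
                 negative_literals = negative_literals),
            class = "cpar_params")
}

#' Mine predictive association rules between markers and a binary class
#'
#' For each class in turn, rules are grown greedily: the literal with the
#' highest FOIL gain (computed on weighted examples) is appended, with
#' branches for every literal whose gain is within `gain_similarity` of
#' the best, until no literal clears `min_gain` or no negative example
#' remains. After each rule, the weights of the positive examples it
#' covers decay by `decay`; mining stops when the remaining positive
#' weight drops below `weight_threshold` of its initial total. Weighting
#' drives the search only: each reported rule carries exact support
#' counts recounted on the unweighted data, and rules are ranked by
#' Laplace accuracy (ties: smaller antecedent, then lexicographic).
#'
#' @param markers samples x markers matrix or data frame of 0/1 values
#'   with column names.
#' @param class vector of 0/1 outcomes (0 = dead, 1 = alive), one per
#'   sample; both classes must be present.
#' @param params a [cpar_params()].
#' @return data frame with `antecedent` (e.g. `"RAR-G12=1 & RAR-G13=1"`),
#'   `class`, `n_total`, `n_c`, `laplace`, sorted best-first.
#' @export
mine_rules <- function(markers, class, params = cpar_params()) {
  markers <- as.matrix(markers)
  if (is.null(colnames(markers)))
    colnames(markers) <- sprintf("M%d", seq_len(ncol(markers)))
  if (any(is.na(markers)) || any(is.na(class)))
    stop("mining input must have no missing entries", call. = FALSE)
  if (!all(markers %in% c(0, 1)))
    stop("markers must be coded 0/1", call. = FALSE)
  if (length(class) != nrow(markers))
    stop("class length must match marker rows", call. = FALSE)
  if (length(unique(class)) < 2)
    stop("both classes must be present in the input", call. = FALSE)
  m_classes <- 2L

  # literal table: one row per (marker column, value)
  vals <- if (params$negative_literals) c(1L, 0L) else 1L
  lits <- expand.grid(col = seq_len(ncol(markers)), val = vals)
  lit_label <- sprintf("%s=%d", colnames(markers)[lits$col], lits$val)
  satisfies <- function(lit_ids) {
    ok <- rep(TRUE, nrow(markers))
    for (l in lit_ids)
      ok <- ok & markers[, lits$col[l]] == lits$val[l]
    ok
  }

  seen <- new.env(parent = emptyenv())
  rules <- list()
  emit <- function(lit_ids, cls) {
    key <- paste(cls, paste(sort(lit_ids), collapse = ","))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      rules[[length(rules) + 1L]] <<- list(lits = sort(lit_ids),
                                           class = cls)
    }
  }

  for (cls in sort(unique(class))) {
    pos <- which(class == cls)
    neg <- which(class != cls)
    w <- rep(1, length(pos))
    total0 <- sum(w)
    max_rounds <- 200L

    # one growth pass; returns the literal sets found (duplicates of
    # earlier rounds included, so their covered weights keep decaying)
    grow <- function(body, avail, pos_ok, neg_ok) {
      p0 <- sum(w[pos_ok])
      n0 <- sum(neg_ok)
      if (n0 == 0 || !length(avail)) {
        if (length(body)) return(list(body))
        return(list())
      }
      gains <- vapply(avail, function(l) {
        sat <- markers[, lits$col[l]] == lits$val[l]
        p1 <- sum(w[pos_ok & sat[pos]])
        if (p1 <= 0) return(-Inf)
        n1 <- sum(neg_ok & sat[neg])
        p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
      }, 0)
      best <- max(gains)
      if (!is.finite(best) || best < params$min_gain) {
        if (length(body)) return(list(body))
        return(list())
      }
      sel <- avail[gains >= params$gain_similarity * best &
                   gains >= params$min_gain]
      sel <- sel[order(-gains[match(sel, avail)], sel)]
      found <- list()
      for (l in sel) {
        sat <- markers[, lits$col[l]] == lits$val[l]
        found <- c(found, grow(
          c(body, l), setdiff(avail, which(lits$col == lits$col[l])),
          pos_ok & sat[pos], neg_ok & sat[neg]))
      }
      found
    }

    for (round in seq_len(max_rounds)) {
      pass <- grow(integer(0), seq_len(nrow(lits)),
                   rep(TRUE, length(pos)), rep(TRUE, length(neg)))
      if (!length(pass)) break
      for (body in pass) {
        emit(body, cls)
        cov <- satisfies(body)[pos]
        w[cov] <- w[cov] * params$decay
      }
      if (sum(w) <= params$weight_threshold * total0) break
    }
  }

  if (!length(rules))
    return(data.frame(antecedent = character(), class = integer(),
                      n_total = integer(), n_c = integer(),
                      laplace = numeric(), stringsAsFactors = FALSE))
  ant <- vapply(rules, function(r)
    paste(lit_label[r$lits][order(lit_label[r$lits])], collapse = " & "), "")
  n_total <- vapply(rules, function(r) sum(satisfies(r$lits)), 0L)
  n_c <- vapply(rules, function(r)
    sum(satisfies(r$lits) & class == r$class), 0L)
  size <- lengths(lapply(rules, `[[`, "lits"))
  out <- data.frame(antecedent = ant,
                    class = vapply(rules, `[[`, class[1], "class"),
                    n_total = n_total, n_c = n_c,
                    laplace = laplace_accuracy(n_c, n_total, m_classes),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$laplace, size, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter mined rules to reported death-associated combinations
#'
#' Keeps rules that predict the death class (0) with Laplace accuracy
#' strictly above the reporting cutoff.
#'
#' @param rules output of [mine_rules()].
#' @param params a [cpar_params()] (uses `min_laplace_report`).
#' @return filtered rule data frame.
#' @export
report_death_rules <- function(rules, params = cpar_params()) {
  rules[rules$class == 0 & rules$laplace > params$min_laplace_report, ,
        drop = FALSE]
}
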