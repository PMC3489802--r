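#' Construct a probe map
#'
#' A probe map is the genomic backbone of the pipeline: an ordered table of
#' array probes with one representative coordinate each. All segmentation,
#' calling and recurrence analysis is expressed in probe-map order
#' (chromosome 1..22 then X, position ascending within chromosome).
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom chromosome labels (`1`--`22`, `X`; a `chr` prefix is accepted).
#' @param position 1-based probe coordinate in base pairs.
#'
#' @return A `probe_map` data frame with columns `probe_id`, `chrom`,
#'   `position`, sorted by (chromosome, position).
#' @export
probe_map <- function(probe_id, chrom, position) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) {
    dup <- unique(probe_id[duplicated(probe_id)])
    stop("duplicated probe_id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  chrom <- as_chrom(chrom)
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1))
    stop("probe positions must be positive integers", call. = FALSE)
  pm <- data.frame(probe_id = probe_id, chrom = chrom, position = position,
                   stringsAsFactors = FALSE)
  ord <- order(pm$chrom, pm$position)
  pm <- pm[ord, , drop = FALSE]
  rownames(pm) <- NULL
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Read a probe map from a tab-separated file
#'
#' Expects a header line `probe_id  chrom  position`. Rows out of genomic
#' order are sorted silently (with a message); duplicate probe ids are an
#' error because every downstream matrix is keyed by them.
#'
#' @param path path to a TSV file.
#' @return A [probe_map()].
#' @export
read_probe_map <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "chrom", "position"), "probe map")
  pos <- suppressWarnings(as.numeric(df$position))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("probe map %s: malformed position at data line %d ('%s')",
                 path, bad, df$position[bad]), call. = FALSE)
  }
  pm0 <- data.frame(probe_id = as.character(df$probe_id),
                    chrom = as_chrom(df$chrom),
                    position = as.integer(pos))
  if (is.unsorted(order(pm0$chrom, pm0$position), strictly = FALSE) ||
      any(diff(order(pm0$chrom, pm0$position)) < 0))
    message("probe map not in genomic order; sorting")
  probe_map(pm0$probe_id, pm0$chrom, pm0$position)
}

#' @export
write_probe_map <- function(probes, path) {
  stopifnot(inherits(probes, "probe_map"))
  out <- data.frame(probe_id = probes$probe_id,
                    chrom = as.character(probes$chrom),
                    position = probes$position)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 ratio matrix keyed to a probe map
#'
#' The file layout is one row per sample: first column `sample`, remaining
#' columns named by probe id. Columns are re-aligned to probe-map order;
#' probes unknown to the map and non-numeric cells are errors. Missing
#' values (`NA` cells) are allowed and are skipped probe-wise by
#' segmentation.
#'
#' @param path path to a TSV file.
#' @param probes a [probe_map()].
#' @return Numeric matrix, samples x probes, dimnames = (sample ids, probe ids).
#' @export
read_ratio_matrix <- function(path, probes) {
  stopifnot(inherits(probes, "probe_map"))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (names(df)[1] != "sample")
    stop("ratio matrix must have 'sample' as its first column", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  alien <- setdiff(names(vals), probes$probe_id)
  if (length(alien))
    stop("ratio matrix contains probe(s) absent from the probe map: ",
         paste(utils::head(alien, 5), collapse = ", "), call. = FALSE)
  miss <- setdiff(probes$probe_id, names(vals))
  if (length(miss))
    stop("ratio matrix lacks probe column(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(v) & !is.na(vals[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric ratio at sample '%s', probe '%s'",
                     ids[bad[1]], names(vals)[j]), call. = FALSE)
      vals[[j]] <- v
    }
  }
  m <- as.matrix(vals)[, probes$probe_id, drop = FALSE]
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (any(is.infinite(m)))
    stop("ratio matrix contains non-finite values", call. = FALSE)
  m
}

#' @rdname read_ratio_matrix
#' @param ratios samples x probes numeric matrix with dimnames.
#' @export
write_ratio_matrix <- function(ratios, path) {
  stopifnot(is.matrix(ratios), !is.null(rownames(ratios)),
            !is.null(colnames(ratios)))
  df <- data.frame(sample = rownames(ratios), ratios, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read copy-number segments (SEG-style table)
#'
#' Columns: `sample`, `chrom`, `start`, `end` (bp, 1-based inclusive),
#' `n_probes`, `mean_log2`, plus bookkeeping columns `first_probe`,
#' `last_probe` (probe-map indices) and `flag` when present. Values
#' round-trip at full double precision.
#'
#' @param segs a segment table as returned by [segment_cohort()].
#' @param path path to a TSV file.
#' @export
write_segments <- function(segs, path) {
  stopifnot_cols(segs, c("sample", "chrom", "start", "end", "n_probes",
                         "mean_log2"), "segment table")
  out <- as.data.frame(segs)
  out$chrom <- as.character(out$chrom)
  out$mean_log2 <- sprintf("%.17g", out$mean_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample", "chrom", "start", "end", "n_probes",
                       "mean_log2"), "segment file")
  if (nrow(df) == 0) {
    df$chrom <- factor(character(), levels = chrom_levels())
    class(df) <- c("seg_table", "data.frame")
    return(df)
  }
  df$chrom <- as_chrom(df$chrom)
  df$mean_log2 <- as.numeric(df$mean_log2)
  if (any(df$start > df$end)) stop("segment with start > end", call. = FALSE)
  if (any(df$n_probes < 1)) stop("segment with n_probes < 1", call. = FALSE)
  sp <- split(df, list(df$sample, df$chrom), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      stop(sprintf("overlapping segments for sample '%s' chromosome %s",
                   g$sample[1], as.character(g$chrom[1])), call. = FALSE)
  }
  ord <- order(df$sample, df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seg_table", "data.frame")
  df
}

#' Read / write a clinical table
#'
#' Required columns: `sample`, `age_group` (`<50` / `>=50`), `stage`
#' (`I`/`IIA`/`IIB`), `er`, `pr`, `her2` (`positive`/`negative`),
#' `survival_time` (years, >= 0), `event` (0 censored / 1 dead). A derived
#' `subtype` column is added on read when absent.
#'
#' @param path TSV path.
#' @return data frame, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param clinical clinical data frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_clinical <- function(df) {
  stopifnot_cols(df, c("sample", "age_group", "stage", "er", "pr", "her2",
                       "survival_time", "event"), "clinical table")
  if (!all(df$age_group %in% c("<50", ">=50")))
    stop("age_group must be '<50' or '>=50'", call. = FALSE)
  if (!all(df$stage %in% c("I", "IIA", "IIB")))
    stop("stage must be I, IIA or IIB", call. = FALSE)
  for (v in c("er", "pr", "her2"))
    if (!all(df[[v]] %in% c("positive", "negative")))
      stop(v, " status must be 'positive' or 'negative'", call. = FALSE)
  if (any(df$survival_time < 0)) stop("survival_time must be >= 0", call. = FALSE)
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1", call. = FALSE)
  if (is.null(df$subtype))
    df$subtype <- classify_subtype(df$er, df$pr, df$her2)
  df
}

#' Collapse tumor stage to I vs II
#'
#' Stage IIA and IIB are pooled for all stratified frequency and
#' association analyses.
#'
#' @param stage character vector of `I`, `IIA`, `IIB`.
#' @return character vector of `I` / `II`.
#' @export
collapse_stage <- function(stage) ifelse(stage == "I", "I", "II")

#' Read / write a qPCR Ct table
#'
#' Long format: `sample`, `locus`, `template` (`tumor`/`reference`),
#' `replicate`, `ct` (cycles, > 0). The diploid-control locus rows use the
#' same layout as the target loci.
#'
#' @param path TSV path.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample", "locus", "template", "replicate", "ct"),
                 "Ct table")
  if (!all(df$template %in% c("tumor", "reference")))
    stop("template must be 'tumor' or 'reference'", call. = FALSE)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  df
}

#' @rdname read_ct_table
#' @param ct Ct data frame.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared strict TSV reader: checks header and reports 1-based data line
# numbers for rows with the wrong field count.
read_tsv_checked <- function(path, cols, what) {
  lines <- readLines(path)
  if (!length(lines)) stop(what, " file is empty: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(cols, header)
  if (length(miss))
    stop(what, " header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("%s %s: malformed row at data line %d (%d fields, expected %d)",
                 what, path, bad, nf[bad], length(header)), call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Format base-pair bounds as a megabase map-position string
#'
#' Report tables print intervals such as `148.12-150.25` (megabases,
#' two decimals).
#'
#' @param start,end 1-based inclusive bp coordinates.
#' @return character vector.
#' @export
format_mb <- function(start, end) {
  sprintf("%.2f-%.2f", start / 1e6, end / 1e6)
}
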