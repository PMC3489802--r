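# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL runs expr untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (reports print 12.5% as 13, not R's banker's 12).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical chromosome ordering: 1..22 then X.
chrom_levels <- function() c(as.character(1:22), "X")

as_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  bad <- !(x %in% chrom_levels())
  if (any(bad))
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  factor(x, levels = chrom_levels())
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
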