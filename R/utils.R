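#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, so `round_half_away(1203.5)`
#' is 1204 (base R's [round()] uses banker's rounding and would give 1204 or
#' 1203 depending on floating point representation).
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Size of each extreme set
#'
#' Number of items taken on each side (enriched and deficient) of the trend
#' line when classifying the `fraction` extremes of a universe of `n` items.
#'
#' @param n number of items in the universe.
#' @param fraction fraction taken on each side, in (0, 0.5]. Default 0.05.
#' @return integer count per side, `round_half_away(fraction * n)`.
#' @export
#' @examples
#' extreme_set_size(24070)  # 1204
#' extreme_set_size(3095)   # 155
extreme_set_size <- function(n, fraction = 0.05) {
  stopifnot(is.numeric(n), n >= 0)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 0.5) {
    stop("'fraction' must be a single number in (0, 0.5]")
  }
  as.integer(round_half_away(fraction * n))
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# TSV writers/readers used for all tabular artifacts: tab-separated, header
# line, no quoting, no row names, no scientific notation.
write_tsv <- function(df, path) {
  old <- options(scipen = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
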