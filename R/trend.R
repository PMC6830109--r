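## The central estimator: a zero-intercept least-squares trend of the
## relative score (NGRE or NPII) on the absolute score (GRE or PII), and
## the classification of the items farthest above and below that line.
##
## The model is y = beta * x + e with the intercept constrained to zero:
## a gene whose RE-linked fraction is exactly proportional to its absolute
## RE-linked signal sits on the line.  Items are ranked by the signed
## vertical residual y - beta * x; the top `fraction` are called
## RRE-enriched (more relative RE-linked regulation than their absolute
## signal predicts) and the bottom `fraction` RRE-deficient.  Vertical
## rather than perpendicular distance is used because the relative score
## is modelled as a function of the absolute one.

#' Zero-intercept least-squares slope
#'
#' Fits y = beta * x through the origin: beta = sum(x*y) / sum(x^2).
#'
#' @param x,y numeric vectors of equal length >= 2, no NA.
#' @return the slope beta.
#' @export
#' @examples
#' fit_zero_intercept(c(1, 2), c(1, 3))  # 7/5
fit_zero_intercept <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L,
            !anyNA(x), !anyNA(y))
  if (sum(x^2) == 0) stop("degenerate fit: all x are zero")
  unname(stats::lm.fit(matrix(x, ncol = 1L), y)$coefficients)
}

#' Fit the RE-regulation trend model and classify extremes
#'
#' Fits the zero-intercept trend of a relative score on an absolute score
#' and labels each item `enriched`, `deficient` or `intermediate`. The
#' `m = round_half_away(fraction * N)` items with the largest residuals
#' form the enriched set and the `m` with the smallest (most negative)
#' residuals the deficient set; residual ties are broken by item id in
#' lexicographic order, so the classification is deterministic. Items
#' with an undefined (NA) relative score are excluded before fitting and
#' counted in `n_excluded`.
#'
#' @param formula a two-sided formula, relative score on the left and
#'   absolute score on the right, e.g. `ngre ~ gre` or `npii ~ pii`.
#' @param data a data frame containing the formula variables and the id
#'   column.
#' @param fraction fraction of items taken on each side, in (0, 0.5].
#' @param id name of the id column in `data`; defaults to the first of
#'   `"gene_id"`, `"pathway_id"`, `"item_id"` found, else row names.
#' @return an object of class `"rre_fit"`: a list with elements `slope`,
#'   `ids`, `x`, `y`, `residuals`, `labels` (factor with levels
#'   `enriched`, `intermediate`, `deficient`), `m`, `fraction`,
#'   `n_excluded`, `xname`, `yname` and `call`.
#' @seealso [classify_extremes()], [extremes()], [extreme_set_size()]
#' @export
#' @examples
#' d <- data.frame(gene_id = sprintf("g%02d", 1:40),
#'                 gre = rep(1:10, 4),
#'                 ngre = 0.05 * rep(1:10, 4) + rnorm(40, sd = 0.01))
#' fit <- rre_fit(ngre ~ gre, d, fraction = 0.1)
#' coef(fit)
#' table(fit$labels)
rre_fit <- function(formula, data, fraction = 0.05, id = NULL) {
  if (!inherits(formula, "formula") || length(formula) != 3L) {
    stop("'formula' must be two-sided, e.g. ngre ~ gre")
  }
  if (fraction <= 0 || fraction > 0.5) {
    stop("'fraction' must be in (0, 0.5]")
  }
  yname <- deparse(formula[[2L]])
  xname <- deparse(formula[[3L]])
  if (is.null(id)) {
    id <- intersect(c("gene_id", "pathway_id", "item_id"), names(data))[1L]
  }
  ids <- if (!is.null(id) && !is.na(id)) as.character(data[[id]])
         else rownames(data)
  x <- data[[xname]]
  y <- data[[yname]]
  if (is.null(x) || is.null(y)) {
    stop("columns '", xname, "' and '", yname, "' must exist in 'data'")
  }
  keep <- !is.na(x) & !is.na(y)
  n_excluded <- sum(!keep)
  ids <- ids[keep]; x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < ceiling(2 / fraction)) {
    stop("too few items with defined scores (", n, ") for fraction ",
         fraction)
  }
  if (anyDuplicated(ids)) stop("item ids must be unique")
  slope <- fit_zero_intercept(x, y)
  res <- y - slope * x
  m <- extreme_set_size(n, fraction)
  ord_hi <- order(-res, ids)       # largest residuals first, ties by id
  ord_lo <- order(res, ids)        # smallest residuals first
  labels <- rep("intermediate", n)
  labels[ord_hi[seq_len(m)]] <- "enriched"
  labels[ord_lo[seq_len(m)]] <- "deficient"
  structure(list(slope = slope,
                 ids = ids, x = x, y = y,
                 residuals = stats::setNames(res, ids),
                 labels = factor(labels,
                                 levels = c("enriched", "intermediate",
                                            "deficient")),
                 m = m, fraction = fraction, n_excluded = n_excluded,
                 xname = xname, yname = yname,
                 call = match.call()),
            class = "rre_fit")
}

#' Classify score-table extremes along the trend line
#'
#' Convenience wrapper around [rre_fit()] for the standard score tables:
#' uses `ngre ~ gre` for gene tables and `npii ~ pii` for pathway tables
#' (detected from the columns present).
#'
#' @param scores a score table from [aggregate_cell_lines()] or
#'   [compute_pathway_scores()].
#' @param fraction fraction per side, default 0.05.
#' @return an `"rre_fit"` object.
#' @export
classify_extremes <- function(scores, fraction = 0.05) {
  if (all(c("gre", "ngre") %in% names(scores))) {
    rre_fit(ngre ~ gre, scores, fraction = fraction)
  } else if (all(c("pii", "npii") %in% names(scores))) {
    rre_fit(npii ~ pii, scores, fraction = fraction)
  } else {
    stop("'scores' must have columns gre/ngre or pii/npii")
  }
}

#' Extract the extreme sets from a trend fit
#'
#' @param fit an `"rre_fit"` object.
#' @return list with character vectors `enriched` and `deficient`.
#' @export
extremes <- function(fit) {
  stopifnot(inherits(fit, "rre_fit"))
  list(enriched = fit$ids[fit$labels == "enriched"],
       deficient = fit$ids[fit$labels == "deficient"])
}

#' @export
print.rre_fit <- function(x, ...) {
  cat("Zero-intercept RE-regulation trend fit\n")
  cat(sprintf("  model: %s = %.6g * %s\n", x$yname, x$slope, x$xname))
  cat(sprintf("  items: %d scored (%d excluded, undefined %s)\n",
              length(x$ids), x$n_excluded, x$yname))
  cat(sprintf("  extremes: %d enriched / %d deficient (fraction %.3g per side)\n",
              sum(x$labels == "enriched"), sum(x$labels == "deficient"),
              x$fraction))
  invisible(x)
}

#' @export
#' @method summary rre_fit
summary.rre_fit <- function(object, ...) {
  s <- list(slope = object$slope,
            n = length(object$ids),
            n_excluded = object$n_excluded,
            m = object$m,
            fraction = object$fraction,
            label_counts = table(object$labels),
            residual_quantiles = stats::quantile(
              object$residuals, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)),
            xname = object$xname, yname = object$yname)
  class(s) <- "summary.rre_fit"
  s
}

#' @export
print.summary.rre_fit <- function(x, ...) {
  cat(sprintf("Trend: %s = %.6g * %s over %d items (%d excluded)\n",
              x$yname, x$slope, x$xname, x$n, x$n_excluded))
  cat("Labels:\n")
  print(x$label_counts)
  cat("Residual quantiles:\n")
  print(signif(x$residual_quantiles, 4))
  invisible(x)
}

#' @export
#' @method coef rre_fit
coef.rre_fit <- function(object, ...) {
  stats::setNames(object$slope, object$xname)
}

#' @export
#' @method residuals rre_fit
residuals.rre_fit <- function(object, ...) object$residuals

#' @export
fitted.rre_fit <- function(object, ...) {
  stats::setNames(object$slope * object$x, object$ids)
}

#' @export
predict.rre_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  x <- if (is.data.frame(newdata)) newdata[[object$xname]] else newdata
  object$slope * x
}

#' Scatter plot of the trend fit
#'
#' Absolute score on the abscissa, relative score on the ordinate, the
#' fitted through-origin trend line, with the enriched and deficient
#' extremes highlighted.
#'
#' @param x an `"rre_fit"` object.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot rre_fit
plot.rre_fit <- function(x, ...) {
  cols <- c(enriched = "firebrick", intermediate = "grey60",
            deficient = "dodgerblue3")
  graphics::plot(x$x, x$y, col = cols[as.character(x$labels)],
                 pch = 20, cex = 0.6,
                 xlab = toupper(x$xname), ylab = toupper(x$yname), ...)
  graphics::abline(0, x$slope, lwd = 2)
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = 20, bty = "n")
  invisible(x)
}

#' Labelled score table from a trend fit
#'
#' @param x an `"rre_fit"` object.
#' @param ... ignored.
#' @return data frame `item_id`, absolute score, relative score,
#'   `residual`, `label`.
#' @export
#' @method as.data.frame rre_fit
as.data.frame.rre_fit <- function(x, ...) {
  out <- data.frame(item_id = x$ids, x = x$x, y = x$y,
                    residual = unname(x$residuals),
                    label = as.character(x$labels),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- c(x$xname, x$yname)
  out
}
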