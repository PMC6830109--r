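## Permutation control for the functional annotation of the extreme gene
## sets.  Gene names are randomly rearranged over the (GRE, NGRE) score
## pairs B times (default 500); each permutation is re-classified and its
## extreme sets re-annotated against the term collection, keeping the
## `top_terms` smallest term p-values.  The test statistic per group is
## the minimum term p-value; the empirical q-value is (r + 1) / (B + 1)
## where r counts permutations whose minimum p is at least as small as
## the real one.

#' Permute gene labels over score pairs
#'
#' Randomly rearranges the `gene_id` column of a score table, leaving the
#' multiset of (gre, ngre) rows unchanged. Deterministic for a given
#' seed.
#'
#' @param scores an aggregate gene score table.
#' @param seed integer seed.
#' @return the table with `gene_id` permuted.
#' @export
permute_gene_labels <- function(scores, seed) {
  stopifnot(nrow(scores) >= 1L)
  out <- scores
  out$gene_id <- with_seed(seed, sample(scores$gene_id))
  out
}

#' Permutation null for term annotation of the extreme sets
#'
#' For each of `B` permutations of gene names over score pairs, re-runs
#' [classify_extremes()] and [term_enrichment()] and records the
#' `top_terms` smallest term p-values for the enriched and deficient
#' sets (padded with p = 1 when fewer terms exist). Per group, `r`
#' counts permutations whose minimum term p-value is at least as small
#' as the real one, and `q = (r + 1) / (B + 1)`. Per-permutation seeds
#' are derived from `seed` by counter, so results are reproducible and
#' independent of iteration order.
#'
#' @param scores aggregate gene score table ([aggregate_cell_lines()]).
#' @param terms named list of term member vectors ([read_gmt()]).
#' @param fraction extreme fraction per side, default 0.05.
#' @param B number of permutations, default 500.
#' @param top_terms p-values kept per permutation and group, default 100.
#' @param seed master integer seed.
#' @param variant term-test variant, see [term_enrichment()].
#' @param bins histogram bins for the mode comparison, default 30.
#' @return an object of class `"permutation_summary"`: per group
#'   (`enriched`, `deficient`) a list with `real_p` (top real p-values),
#'   `real_min_p`, `null_min_p` (length B), `null_p` (B x top_terms
#'   matrix), `r`, `q`, `mode_real`, `mode_null`; plus `B`, `top_terms`,
#'   `fraction`, `seed`.
#' @export
permutation_null <- function(scores, terms, fraction = 0.05, B = 500,
                             top_terms = 100, seed = 1,
                             variant = "standard", bins = 30) {
  stopifnot(B >= 1, top_terms >= 1, length(terms) >= 1L)
  fit <- classify_extremes(scores, fraction = fraction)
  universe <- fit$ids
  groups <- c("enriched", "deficient")

  top_p <- function(selected) {
    te <- term_enrichment(selected, universe, terms, variant = variant)
    p <- sort(te$p_value)
    out <- rep(1, top_terms)
    nkeep <- min(top_terms, length(p))
    out[seq_len(nkeep)] <- p[seq_len(nkeep)]
    out
  }

  real_ext <- extremes(fit)
  real_p <- lapply(real_ext[groups], top_p)
  real_min <- vapply(real_p, min, numeric(1L))

  null_p <- lapply(groups, function(g) matrix(1, nrow = B, ncol = top_terms))
  names(null_p) <- groups
  for (b in seq_len(B)) {
    perm <- permute_gene_labels(scores, seed = seed + b)
    pfit <- classify_extremes(perm, fraction = fraction)
    pext <- extremes(pfit)
    for (g in groups) null_p[[g]][b, ] <- top_p(pext[[g]])
  }

  per_group <- lapply(groups, function(g) {
    null_min <- apply(null_p[[g]], 1L, min)
    r <- sum(null_min <= real_min[[g]])
    pooled <- c(real_p[[g]], as.vector(null_p[[g]]))
    rng <- range(-log10(pooled))
    list(real_p = real_p[[g]],
         real_min_p = real_min[[g]],
         null_p = null_p[[g]],
         null_min_p = null_min,
         r = r,
         q = (r + 1) / (B + 1),
         mode_real = distribution_mode(real_p[[g]], bins = bins,
                                       range = rng),
         mode_null = distribution_mode(as.vector(null_p[[g]]),
                                       bins = bins, range = rng))
  })
  names(per_group) <- groups
  structure(c(per_group,
              list(B = B, top_terms = top_terms, fraction = fraction,
                   seed = seed)),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation control: B = %d, top %d terms per set\n",
              x$B, x$top_terms))
  for (g in c("enriched", "deficient")) {
    s <- x[[g]]
    cat(sprintf("  %-9s real min p = %.3g, r = %d, q = %.4g; mode real/null (-log10 p) = %.2f / %.2f\n",
                g, s$real_min_p, s$r, s$q, s$mode_real, s$mode_null))
  }
  invisible(x)
}

#' Mode of a p-value distribution on the -log10 scale
#'
#' Bins `-log10(p)` into `bins` equal-width bins over `range` (defaults
#' to the range of the supplied values; pass the pooled real-plus-null
#' range to compare two distributions on the same grid) and returns the
#' midpoint of the fullest bin. Ties are broken toward the smaller
#' `-log10` value. Empty bins are never selected.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param bins number of bins, >= 1.
#' @param range optional length-2 range on the -log10 scale.
#' @return the mode estimate on the -log10 p scale.
#' @export
distribution_mode <- function(p_values, bins = 30, range = NULL) {
  stopifnot(length(p_values) >= 1L, bins >= 1)
  lp <- -log10(p_values)
  rng <- range %||% base::range(lp)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  counts <- graphics::hist(pmin(pmax(lp, rng[1L]), rng[2L]),
                           breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  mids[which.max(counts)]   # which.max takes the first (smallest) on ties
}
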