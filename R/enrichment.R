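## Hypergeometric over/under-representation machinery.
##
## The sampling model: a universe of M genes contains N genes of a class
## of interest (e.g. lncRNA); a sample of n genes (e.g. the RRE-enriched
## extreme) contains k class genes.  The probability of the observed
## configuration is
##
##   p(k) = C(n, k) C(M - n, N - k) / C(M, N)
##
## and the two directional tails are
##
##   P  (over)  = sum_{i = k+1}^{n} p(i)     -- strictly greater
##   P' (under) = sum_{i = 1}^{k}   p(i)     -- from i = 1
##
## Both tails deliberately exclude i = 0, so P + P' + p(0) = 1.  Calls
## use p < 0.05 in either direction.  Evaluation goes through R's
## log-space dhyper/phyper, which is stable for genome-scale M.

# Shared parameter validation.
check_hyper_params <- function(M, n, N, k = NULL) {
  stopifnot(M >= 0, n >= 0, N >= 0, n <= M, N <= M)
  if (!is.null(k)) stopifnot(k >= 0, k <= min(n, N))
  invisible(TRUE)
}

#' Hypergeometric probability mass function
#'
#' Probability of observing exactly `k` class genes in a sample of `n`
#' genes drawn without replacement from a universe of `M` genes
#' containing `N` class genes. Values of `k` outside the support return 0.
#'
#' @param k observed class-gene count (may be a vector).
#' @param M universe size.
#' @param n sample size.
#' @param N class genes in the universe.
#' @return probability (vectorised over `k`).
#' @export
#' @examples
#' hypergeom_pmf(3, M = 10, n = 5, N = 4)  # 60/252
hypergeom_pmf <- function(k, M, n, N) {
  check_hyper_params(M, n, N)
  stats::dhyper(k, N, M - N, n)
}

#' Expected class-gene count under random sampling
#'
#' @inheritParams hypergeom_pmf
#' @return `n * N / M` (0 when `M` is 0).
#' @export
expected_count <- function(M, n, N) {
  check_hyper_params(M, n, N)
  if (M == 0) return(0)
  n * N / M
}

#' Hypergeometric over/under-representation test
#'
#' Computes the probability of observing strictly more class genes than
#' `k` (`p_over`) and of observing between 1 and `k` class genes
#' (`p_under`), and calls the class overrepresented when `p_over < alpha`,
#' underrepresented when `p_under < alpha`, else neither.
#'
#' @inheritParams hypergeom_pmf
#' @param k observed class-gene count in the sample.
#' @param alpha significance threshold for either direction, default 0.05.
#' @return an object of class `"enrichment_result"`: a list with
#'   `params` (M, n, N, k), `expected`, `p_over`, `p_under`, `conclusion`.
#' @export
#' @examples
#' over_under_test(k = 3, M = 10, n = 5, N = 4)
over_under_test <- function(k, M, n, N, alpha = 0.05) {
  check_hyper_params(M, n, N, k)
  p_over <- stats::phyper(k, N, M - N, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, N, M - N, n) - stats::dhyper(0, N, M - N, n)
  conclusion <- if (p_over < alpha) "overrepresented"
                else if (p_under < alpha) "underrepresented"
                else "neither"
  structure(list(params = list(M = M, n = n, N = N, k = k),
                 expected = expected_count(M, n, N),
                 p_over = p_over, p_under = p_under,
                 conclusion = conclusion),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Hypergeometric representation test (M=%d, n=%d, N=%d)\n",
              p$M, p$n, p$N))
  cat(sprintf("  observed k = %d, expected = %.2f\n", p$k, x$expected))
  cat(sprintf("  p(over) = %.4g, p(under) = %.4g -> %s\n",
              x$p_over, x$p_under, x$conclusion))
  invisible(x)
}

#' Non-coding RNA representation in the extreme gene sets
#'
#' Runs [over_under_test()] for each gene class of interest in each
#' extreme set of a gene-level trend fit. The universe is the set of
#' genes that entered the fit.
#'
#' @param fit gene-level `"rre_fit"` object.
#' @param genes gene table with `gene_id` and `gene_class`.
#' @param classes gene classes to test, default `c("lncRNA", "miRNA")`.
#' @param alpha threshold passed to [over_under_test()].
#' @return data frame with one row per (group, class): `group`,
#'   `gene_class`, `k`, `N`, `n`, `M`, `expected`, `p_over`, `p_under`,
#'   `conclusion`.
#' @export
ncrna_enrichment <- function(fit, genes, classes = c("lncRNA", "miRNA"),
                             alpha = 0.05) {
  cls <- stats::setNames(genes$gene_class, genes$gene_id)
  universe <- fit$ids
  M <- length(universe)
  ext <- extremes(fit)
  rows <- list()
  for (group in names(ext)) {
    sample_ids <- ext[[group]]
    n <- length(sample_ids)
    for (cc in classes) {
      class_ids <- universe[cls[universe] == cc]
      N <- length(class_ids)
      k <- sum(sample_ids %in% class_ids)
      tst <- over_under_test(k, M, n, N, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        group = group, gene_class = cc, k = k, N = N, n = n, M = M,
        expected = tst$expected, p_over = tst$p_over,
        p_under = tst$p_under, conclusion = tst$conclusion,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Term over-representation test for a selected gene set
#'
#' For each term with `K` members in the universe and `k` members in the
#' selected set, computes the one-sided hypergeometric overrepresentation
#' tail. The `"standard"` variant is `P(X >= k)`; the `"ease"` variant
#' (the conservative "modified Fisher" used by annotation servers)
#' evaluates the same tail at `k - 1`, i.e. discounts one supporting
#' gene. Terms with no universe member are dropped; terms with `k = 0`
#' are reported with p = 1. Benjamini-Hochberg FDR across terms is
#' reported alongside the raw p-values; fold change is observed/expected.
#'
#' @param selected character vector of selected gene ids; must be a
#'   subset of `universe`.
#' @param universe character vector of all gene ids considered.
#' @param terms named list of term member vectors ([read_gmt()]).
#' @param variant `"standard"` or `"ease"`.
#' @return data frame `term`, `k`, `K`, `fold`, `p_value`, `fdr`,
#'   ordered as in `terms`.
#' @export
term_enrichment <- function(selected, universe, terms,
                            variant = c("standard", "ease")) {
  variant <- match.arg(variant)
  if (!all(selected %in% universe)) {
    stop("'selected' must be a subset of 'universe'")
  }
  M <- length(universe)
  n <- length(selected)
  keep_members <- lapply(terms, intersect, universe)
  K <- lengths(keep_members)
  ok <- K > 0L
  keep_members <- keep_members[ok]
  K <- K[ok]
  k <- vapply(keep_members, function(m) sum(m %in% selected), integer(1L))
  keval <- if (variant == "ease") pmax(k - 1L, 0L) else k
  # P(X >= keval) = upper tail at keval - 1
  p <- stats::phyper(keval - 1L, K, M - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  expected <- n * K / M
  data.frame(term = names(keep_members), k = k, K = K,
             fold = ifelse(expected > 0, k / expected, NA_real_),
             p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Matthews correlation coefficient of a 2x2 agreement table
#'
#' `mcc = (a*d - b*c) / sqrt((a+b)(a+c)(d+b)(d+c))`, defined as 0 when
#' any marginal is zero.
#'
#' @param a both-positive count.
#' @param b method-1-positive / method-2-negative count.
#' @param c method-1-negative / method-2-positive count.
#' @param d both-negative count.
#' @return MCC in `[-1, 1]`.
#' @export
#' @examples
#' mcc(3, 4, 1, 7)  # 17/sqrt(2464), about 0.342
mcc <- function(a, b, c, d) {
  if (is.matrix(a) && nrow(a) == 2L && ncol(a) == 2L) {
    d <- a[2L, 2L]; b <- a[1L, 2L]; c <- a[2L, 1L]; a <- a[1L, 1L]
  }
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  denom2 <- (a + b) * (a + c) * (d + b) * (d + c)
  if (denom2 == 0) return(0)
  (a * d - b * c) / sqrt(denom2)
}

#' Concordance of two extreme-set classifications
#'
#' Builds the 2x2 agreement table between two labelings over the items
#' labelled extreme (`enriched` or `deficient`) by both schemes
#' (`enriched` is the positive class) and returns its Matthews
#' correlation coefficient.
#'
#' @param labels1,labels2 named character vectors of labels (values
#'   `enriched`/`deficient`/other); names are item ids. Items not extreme
#'   in both schemes are ignored.
#' @return list with the 2x2 `table` (a, b, c, d), `mcc` and `n_shared`.
#' @export
classification_concordance <- function(labels1, labels2) {
  shared <- intersect(names(labels1), names(labels2))
  l1 <- labels1[shared]; l2 <- labels2[shared]
  keep <- l1 %in% c("enriched", "deficient") &
          l2 %in% c("enriched", "deficient")
  l1 <- l1[keep]; l2 <- l2[keep]
  a <- sum(l1 == "enriched" & l2 == "enriched")
  b <- sum(l1 == "enriched" & l2 == "deficient")
  c <- sum(l1 == "deficient" & l2 == "enriched")
  d <- sum(l1 == "deficient" & l2 == "deficient")
  list(table = c(a = a, b = b, c = c, d = d),
       mcc = if (a + b + c + d >= 1) mcc(a, b, c, d) else NA_real_,
       n_shared = a + b + c + d)
}
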