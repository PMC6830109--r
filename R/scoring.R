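## Gene-level GRE/NGRE and pathway-level PII/NPII scores.
##
## GRE (gene RE-linked enrichment) is the absolute count of H3K4me1 tags
## assigned to retroelement loci in the TSS neighborhood; NGRE is the
## relative score, the RE-linked fraction of all neighborhood tags.  A
## gene with zero neighborhood tags has NGRE undefined (NA), not zero:
## calling such a gene "RE-deficient" would be an artifact of missing
## signal, so NA genes are excluded from NGRE-based analyses and their
## count is reported.

#' Gene scores from tag counts
#'
#' @param counts output of [count_tags()].
#' @return data frame `gene_id`, `cell_line`, `gre`, `ngre`,
#'   `total_tags`; `ngre` is `NA` for genes with zero neighborhood tags.
#' @export
compute_gene_scores <- function(counts) {
  stopifnot(all(counts$re_tags >= 0),
            all(counts$re_tags <= counts$total_tags))
  data.frame(gene_id = counts$gene_id,
             cell_line = counts$cell_line,
             gre = as.numeric(counts$re_tags),
             ngre = ifelse(counts$total_tags > 0,
                           counts$re_tags / counts$total_tags, NA_real_),
             total_tags = counts$total_tags,
             stringsAsFactors = FALSE)
}

#' Average gene scores across cell lines
#'
#' Arithmetic mean of GRE and NGRE gene-by-gene across cell lines. NGRE
#' is averaged over the cell lines where it is defined; a gene with no
#' defined NGRE in any line keeps `NA`.
#'
#' @param scores row-bound per-cell-line tables from
#'   [compute_gene_scores()]; every gene must appear in every cell line.
#' @return one-row-per-gene score table with `cell_line = "aggregate"`.
#' @export
aggregate_cell_lines <- function(scores) {
  lines <- unique(scores$cell_line)
  genes <- unique(scores$gene_id)
  tab <- table(scores$gene_id, scores$cell_line)
  if (any(tab != 1L)) {
    stop("inconsistent gene universes: every gene must appear exactly ",
         "once per cell line")
  }
  gre <- tapply(scores$gre, scores$gene_id, mean)
  ngre <- tapply(scores$ngre, scores$gene_id,
                 function(v) if (all(is.na(v))) NA_real_
                             else mean(v, na.rm = TRUE))
  tt <- tapply(scores$total_tags, scores$gene_id, mean)
  data.frame(gene_id = genes,
             cell_line = "aggregate",
             gre = as.numeric(gre[genes]),
             ngre = as.numeric(ngre[genes]),
             total_tags = as.numeric(tt[genes]),
             stringsAsFactors = FALSE)
}

#' Pathway involvement scores
#'
#' PII is the mean GRE of the pathway's member genes present in the
#' scored universe; NPII is the mean of those members' defined NGRE
#' values. Pathways with no scorable member are omitted (with a message).
#'
#' @param gene_scores aggregate score table ([aggregate_cell_lines()]).
#' @param pathways named list of member gene-id vectors ([read_gmt()]).
#' @param stat `"mean"` (default) or `"sum"` aggregation over members.
#' @return data frame `pathway_id`, `pii`, `npii`, `n_genes_scored`.
#' @export
compute_pathway_scores <- function(gene_scores, pathways,
                                   stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  agg <- if (stat == "mean") function(v) mean(v) else function(v) sum(v)
  gre <- stats::setNames(gene_scores$gre, gene_scores$gene_id)
  ngre <- stats::setNames(gene_scores$ngre, gene_scores$gene_id)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], gene_scores$gene_id)
    if (length(members) == 0L) return(NULL)
    nv <- ngre[members]
    nv <- nv[!is.na(nv)]
    data.frame(pathway_id = pw,
               pii = agg(gre[members]),
               npii = if (length(nv)) agg(nv) else NA_real_,
               n_genes_scored = length(members),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1L)))
  if (dropped > 0L) {
    message(dropped, " pathway(s) had no scorable members and were omitted")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of two gene-indexed score vectors
#'
#' Computed over the intersection of names where both values are defined,
#' with a two-sided p-value from the t transform.
#'
#' @param a,b named numeric vectors (names are gene or pathway ids).
#' @return list with `r`, `p_value` and `n` (shared defined entries).
#' @export
correlate_score_vectors <- function(a, b) {
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(shared) < 3L) {
    stop("need at least 3 shared defined entries, got ", length(shared))
  }
  x <- a[shared]; y <- b[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Pairwise score correlation matrix across cell lines
#'
#' @param scores row-bound per-cell-line score tables.
#' @param value which score column to correlate (`"gre"` or `"ngre"`).
#' @return symmetric correlation matrix with unit diagonal, one
#'   row/column per cell line.
#' @export
score_correlation_matrix <- function(scores, value = c("ngre", "gre")) {
  value <- match.arg(value)
  lines <- unique(scores$cell_line)
  vecs <- lapply(lines, function(cl) {
    s <- scores[scores$cell_line == cl, ]
    stats::setNames(s[[value]], s$gene_id)
  })
  names(vecs) <- lines
  m <- diag(1, length(lines))
  dimnames(m) <- list(lines, lines)
  if (length(lines) > 1L) {
    for (i in seq_along(lines)[-length(lines)]) {
      for (j in (i + 1):length(lines)) {
        r <- correlate_score_vectors(vecs[[i]], vecs[[j]])$r
        m[i, j] <- m[j, i] <- r
      }
    }
  }
  m
}
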