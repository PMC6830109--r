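# Independent oracles, deliberately brute-force and kept apart from the
# implementation paths they check.

# Exhaustive hypergeometric oracle: enumerate every placement of the N
# class genes among M and count class members falling into the fixed
# sample {1..n}.  Returns pmf over k = 0..min(n, N) plus the two tails as
# defined by the package (over: strictly greater; under: from i = 1).
enumerate_hypergeom <- function(M, n, N) {
  ks <- 0:min(n, N)
  if (N == 0L) {
    pmf <- c(1, rep(0, length(ks) - 1L))
  } else {
    placements <- utils::combn(M, N)
    counts <- tabulate(colSums(placements <= n) + 1L,
                       nbins = length(ks))
    pmf <- counts / ncol(placements)
  }
  list(k = ks, pmf = pmf,
       p_over = function(k) sum(pmf[ks > k]),
       p_under = function(k) sum(pmf[ks >= 1 & ks <= k]))
}

# O(genes x tags x REs) reference implementation of tag counting.
brute_force_counts <- function(genes, res, tags, spec = neighborhood_spec()) {
  mids <- floor((tags$start + tags$end) / 2)
  out <- data.frame(gene_id = genes$gene_id, re_tags = 0L, total_tags = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    left <- if (g$strand == "+") spec$upstream else spec$downstream
    right <- if (g$strand == "+") spec$downstream else spec$upstream
    lo <- max(0L, g$tss - left); hi <- g$tss + right
    for (j in seq_len(nrow(tags))) {
      if (tags$chrom[j] != g$chrom) next
      m <- mids[j]
      if (m < lo || m >= hi) next
      out$total_tags[i] <- out$total_tags[i] + 1L
      on_re <- FALSE
      for (r in seq_len(nrow(res))) {
        if (res$chrom[r] == tags$chrom[j] &&
            m >= res$start[r] && m < res$end[r]) {
          on_re <- TRUE
          break
        }
      }
      if (on_re) out$re_tags[i] <- out$re_tags[i] + 1L
    }
  }
  out
}

# Random interval fixtures for the brute-force comparison.
random_interval_fixture <- function(seed, n_genes = 20, n_tags = 200,
                                    n_res = 30) {
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  genes <- make_gene_table(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    tss = sample(5000:95000, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE))
  rs <- sort(sample(0:99000, n_res))
  res <- genomic_intervals(sample(chroms, n_res, replace = TRUE),
                           rs, rs + sample(100:2000, n_res, replace = TRUE))
  ts <- sample(0:99800, n_tags, replace = TRUE)
  tags <- genomic_intervals(sample(chroms, n_tags, replace = TRUE),
                            ts, ts + sample(50:200, n_tags, replace = TRUE))
  list(genes = genes, res = res, tags = tags)
}
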