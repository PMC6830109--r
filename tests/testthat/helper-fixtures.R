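# Fixture builders shared across test files.  Everything is generated in
# code; no binary or stored data.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A minimal gene table TSV.
write_gene_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_gene_table <- function(gene_id, chrom = "chr1", tss, strand = "+",
                            gene_class = "protein_coding") {
  data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
             strand = strand, gene_class = gene_class,
             stringsAsFactors = FALSE)
}

# Small complete synthetic dataset read back through the package readers;
# returns genes, res, per-line score tables, aggregate scores, gene sets
# and the ground truth.
small_sim_scores <- function(seed = 1, ...) {
  cfg <- simulation_config(seed = seed, n_genes = 300, n_chromosomes = 2,
                           chrom_length = 2.5e6, n_cell_lines = 2,
                           n_pathways = 40, n_terms = 40, ...)
  sim <- simulate_epigenome(cfg, out_dir = tempfile("sim"))
  genes <- read_gene_table(sim$paths$genes)
  res <- read_repeatmasker(sim$paths$res)
  per <- do.call(rbind, lapply(names(sim$paths$tags), function(cl) {
    compute_gene_scores(count_tags(genes, res,
                                   read_bed(sim$paths$tags[[cl]]), cl))
  }))
  list(sim = sim, genes = genes, res = res, per_line = per,
       agg = aggregate_cell_lines(per),
       pathways = read_gmt(sim$paths$pathways),
       terms = read_gmt(sim$paths$terms),
       truth = sim$ground_truth)
}
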