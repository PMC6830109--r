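test_that("read_bed maps columns, keeps 0-based half-open coordinates", {
  path <- write_lines_tmp(c(
    "chr1\t100\t200\ttagA\t0\t+",
    "chr2\t0\t50"), ext = ".bed")
  iv <- read_bed(path)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100L, 0L))
  expect_equal(iv$end, c(200L, 50L))
  expect_equal(iv$strand, c("+", "."))
  expect_equal(iv$name, c("tagA", ""))
})

test_that("read_bed handles empty files and rejects malformed lines", {
  empty <- write_lines_tmp(character(0), ext = ".bed")
  expect_equal(nrow(read_bed(empty)), 0L)

  rev_coords <- write_lines_tmp("chr1\t200\t100", ext = ".bed")
  expect_error(read_bed(rev_coords), "line 1.*end <= start")

  non_int <- write_lines_tmp(c("chr1\t10\t20", "chr1\tabc\t30"),
                             ext = ".bed")
  expect_error(read_bed(non_int), "line 2.*non-integer")

  short <- write_lines_tmp("chr1\t10", ext = ".bed")
  expect_error(read_bed(short), "fewer than 3")
})

test_that("BED round trip is lossless", {
  set.seed(42)
  s <- sort(sample(0:10000, 25))
  iv <- genomic_intervals(sample(c("chr1", "chrX"), 25, replace = TRUE),
                          s, s + sample(1:500, 25, replace = TRUE),
                          sample(c("+", "-", "."), 25, replace = TRUE),
                          sprintf("iv%02d", 1:25))
  path <- tempfile(fileext = ".bed")
  write_bed(iv, path)
  expect_equal(read_bed(path), iv)
})

test_that("read_repeatmasker converts .out coordinates and filters classes", {
  rm_out <- write_lines_tmp(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family",
    "",
    "  463   1.3  0.6  1.7  chr1      1001  1100 (5000) +  AluY  SINE/Alu  1 100 (0) 1",
    "  300   2.0  0.1  0.2  chr1      2001  2500 (4000) C  Tigger DNA/hAT  1 500 (0) 2",
    "  999   0.5  0.0  0.0  chr2      5001  6000 (3000) +  L1PA2 LINE/L1  1 1000 (0) 3"),
    ext = ".out")
  iv <- read_repeatmasker(rm_out)
  # DNA/hAT dropped by the default retroelement filter
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(1000L, 5000L))  # 1-based inclusive -> 0-based
  expect_equal(iv$end, c(1100L, 6000L))
  expect_equal(iv$name, c("SINE/Alu", "LINE/L1"))

  # custom filter keeps the DNA transposon
  iv2 <- read_repeatmasker(rm_out, keep_classes = c("DNA"))
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$strand, "-")  # RepeatMasker 'C' means minus strand
})

test_that("read_repeatmasker accepts BED with class in the name column", {
  bed <- write_lines_tmp(c(
    "chr1\t100\t300\tSINE/Alu",
    "chr1\t400\t600\tDNA/hAT",
    "chr1\t700\t900\tLTR/ERV1"), ext = ".bed")
  iv <- read_repeatmasker(bed)
  expect_equal(iv$name, c("SINE/Alu", "LTR/ERV1"))
  garbage <- write_lines_tmp("not a repeat file at all", ext = ".out")
  expect_error(read_repeatmasker(garbage), "unrecognized")
})

test_that("RepeatMasker .out -> BED -> read-back is lossless for coordinates", {
  rm_out <- write_lines_tmp(c(
    "   SW   perc perc perc  query    position in query    matching repeat",
    "score   div. del. ins.  sequence begin end (left)     repeat class/family",
    "",
    "  463   1.3  0.6  1.7  chr3   501  750 (100) +  AluSx  SINE/Alu  1 250 (0) 1"),
    ext = ".out")
  iv <- read_repeatmasker(rm_out)
  path <- tempfile(fileext = ".bed")
  write_bed(iv, path)
  back <- read_bed(path)
  expect_equal(back[c("chrom", "start", "end")],
               iv[c("chrom", "start", "end")])
})

test_that("read_gene_table applies the strand TSS rule and 5'-most collapse", {
  df <- data.frame(chrom = "chr1",
                   txStart = c(100L, 100L, 80L, 200L),
                   txEnd = c(500L, 500L, 400L, 600L),
                   strand = c("+", "-", "+", "+"),
                   gene_id = c("G1", "G2", "G3", "G3"),
                   gene_class = "protein_coding")
  # two + transcripts of G3: 5'-most txStart (80) wins
  genes <- read_gene_table(write_gene_tsv(df))
  expect_equal(genes$tss[genes$gene_id == "G1"], 100L)
  expect_equal(genes$tss[genes$gene_id == "G2"], 499L)
  expect_equal(genes$tss[genes$gene_id == "G3"], 80L)
  expect_equal(nrow(genes), 3L)

  # 5'-most for minus strand is the largest txEnd - 1
  df2 <- data.frame(chrom = "chr1", txStart = c(100L, 300L),
                    txEnd = c(500L, 900L), strand = "-",
                    gene_id = "G4", gene_class = "lncRNA")
  expect_equal(read_gene_table(write_gene_tsv(df2))$tss, 899L)

  # conflicting chromosomes are a data error
  df3 <- data.frame(chrom = c("chr1", "chr2"), txStart = 1L, txEnd = 10L,
                    strand = "+", gene_id = "G5",
                    gene_class = "protein_coding")
  expect_error(read_gene_table(write_gene_tsv(df3)), "multiple")
})

test_that("read_gmt parses, deduplicates and validates", {
  path <- write_lines_tmp(c(
    "PW1\tdesc\tA\tB\tC",
    "",
    "PW2\tdesc\tA\tA\tB",
    "PW3\tthird set\tZ"), ext = ".gmt")
  sets <- read_gmt(path)
  expect_length(sets, 3L)
  expect_equal(sets$PW1, c("A", "B", "C"))
  expect_equal(sets$PW2, c("A", "B"))

  bad <- write_lines_tmp("PWonly\tdesc", ext = ".gmt")
  expect_error(read_gmt(bad), "fewer than 3")
})

test_that("read_gmt agrees with the fgsea GMT reader", {
  skip_if_not_installed("fgsea")
  path <- write_lines_tmp(c("S1\td1\tA\tB", "S2\td2\tC\tD\tE"),
                          ext = ".gmt")
  ours <- read_gmt(path)
  theirs <- fgsea::gmtPathways(path)
  expect_equal(lapply(ours, sort), lapply(theirs[names(ours)], sort),
               ignore_attr = TRUE)
})

test_that("GMT round trip preserves sets and descriptions", {
  sets <- list(A = c("g1", "g2"), B = c("g3"))
  attr(sets, "description") <- c(A = "first", B = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$A, sets$A)
  expect_equal(attr(back, "description")[["B"]], "second")
})
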