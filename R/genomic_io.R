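## Readers and writers for the external formats the pipeline touches.
## All interval coordinates are held 0-based half-open ([start, end)),
## exactly as in BED.  Chromosome names are matched by exact string
## equality throughout the package: no "chr" prefix normalisation is
## attempted, so all inputs of one analysis must share a namespace.

#' Construct a table of genomic intervals
#'
#' The package-wide interval container: a plain data frame with columns
#' `chrom`, `start`, `end`, `strand`, `name`, with `start`/`end` 0-based
#' half-open as in BED.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end exclusive end positions; must satisfy `end > start`.
#' @param strand strand of each interval: `"+"`, `"-"` or `"."`.
#' @param name free-text label per interval.
#' @return a `data.frame` with the five columns above.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = ".", name = "") {
  n <- length(chrom)
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  name <- rep_len(as.character(name), n)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, name = name, stringsAsFactors = FALSE)
}

# Internal: 0-based half-open interval data.frame -> GRanges (1-based closed).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3--BED6 (columns beyond 6 are ignored). Coordinates are kept
#' verbatim in BED's 0-based half-open convention. Lines starting with
#' `#`, `track` or `browser` are skipped.
#'
#' @param path path to a BED file.
#' @return interval data frame as from [genomic_intervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(genomic_intervals())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns")
  }
  if (all(nf == nf[1L])) {
    # uniform column count: vectorised extraction
    m <- matrix(unlist(fields, use.names = FALSE), ncol = nf[1L],
                byrow = TRUE)
    chrom <- m[, 1L]
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    name <- if (nf[1L] >= 4L) m[, 4L] else ""
    strand <- if (nf[1L] >= 6L) m[, 6L] else "."
  } else {
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L] %||% "", ""), "")
    strand <- ifelse(nf >= 6L,
                     vapply(fields, function(f) f[6L] %||% ".", ""), ".")
  }
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed BED line ", idx[which(bad)[1L]],
         ": non-integer coordinates")
  }
  bad <- end <= start
  if (any(bad)) {
    stop("malformed BED line ", idx[which(bad)[1L]], ": end <= start")
  }
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(chrom, start, end, strand, name)
}

#' Write genomic intervals to a BED6 file
#'
#' Inverse of [read_bed()]: writing and re-reading reproduces the interval
#' table exactly.
#'
#' @param x interval data frame ([genomic_intervals()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$chrom, x$start, x$end, x$name, 0L, x$strand)
  old <- options(scipen = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default retroelement classes
#'
#' Repeat classes counted as retroelements: elements mobilised through an
#' RNA intermediate (LINEs, SINEs, LTR elements and SVA/Retroposon
#' composites). DNA transposons are excluded by default; pass a custom
#' `keep_classes` to [read_repeatmasker()] to change the filter.
#'
#' @export
RETROELEMENT_CLASSES <- c("LINE", "SINE", "LTR", "SVA", "Retroposon")

#' Read retroelement annotation (RepeatMasker .out or BED)
#'
#' Accepts either the RepeatMasker `.out` dialect (two header lines plus a
#' blank line, whitespace-separated columns, 1-based inclusive genomic
#' coordinates) or a BED file whose name column carries the repeat
#' class/family (e.g. `SINE/Alu`). RepeatMasker coordinates are converted
#' to 0-based half-open (`begin - 1`, `end`). Only rows whose repeat class
#' or family matches `keep_classes` are retained.
#'
#' @param path path to a RepeatMasker `.out` file or a BED file.
#' @param keep_classes character vector of repeat classes/families to keep;
#'   matching is against both the full `class/family` string and its two
#'   components. Default [RETROELEMENT_CLASSES].
#' @return interval data frame with the `class/family` string in `name`.
#' @export
read_repeatmasker <- function(path, keep_classes = RETROELEMENT_CLASSES) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0L) return(genomic_intervals())
  first <- nonempty[1L]
  looks_bed <- grepl("\t", first, fixed = TRUE) &&
    !is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1L]][2L])))
  if (looks_bed) {
    iv <- read_bed(path)
    return(iv[rm_class_matches(iv$name, keep_classes), , drop = FALSE])
  }
  if (!grepl("^\\s*(SW|score)\\b", first)) {
    stop("unrecognized repeat annotation dialect in ", path,
         " (expected RepeatMasker .out or BED)")
  }
  body <- lines[-seq_len(min(3L, length(lines)))]   # two headers + blank
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(genomic_intervals())
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("unrecognized RepeatMasker row (need >= 11 columns), row ",
         which(nf < 11L)[1L])
  }
  chrom <- vapply(fields, `[`, "", 5L)
  begin <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
  if (anyNA(begin) || anyNA(end)) {
    stop("non-integer coordinates in RepeatMasker row ",
         which(is.na(begin) | is.na(end))[1L])
  }
  strand <- vapply(fields, `[`, "", 9L)
  strand <- ifelse(strand == "C", "-", ifelse(strand == "+", "+", "."))
  cls <- vapply(fields, `[`, "", 11L)
  keep <- rm_class_matches(cls, keep_classes)
  genomic_intervals(chrom[keep], begin[keep] - 1L, end[keep],
                    strand[keep], cls[keep])
}

# Match "class/family" strings against a keep list: the full string, the
# class part and the family part all count.
rm_class_matches <- function(cls, keep_classes) {
  parts <- strsplit(cls, "/", fixed = TRUE)
  vapply(seq_along(cls), function(i) {
    any(c(cls[i], parts[[i]]) %in% keep_classes)
  }, logical(1L))
}

#' Read a gene annotation table
#'
#' Reads a refGene-like TSV with header columns `chrom`, `txStart`,
#' `txEnd`, `strand`, `gene_id`, `gene_class` (`txStart`/`txEnd` 0-based
#' half-open). The reference TSS of a transcript is `txStart` on the `+`
#' strand and `txEnd - 1` on the `-` strand. When a `gene_id` has several
#' transcripts, the 5'-most TSS is kept (minimum for `+`, maximum for
#' `-`); collapse the table yourself beforehand for a different rule.
#'
#' @param path path to the TSV.
#' @return a data frame with one row per gene: `gene_id`, `chrom`, `tss`,
#'   `strand`, `gene_class`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_tsv(path)
  need <- c("chrom", "txStart", "txEnd", "strand", "gene_id", "gene_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  tss <- ifelse(df$strand == "+", df$txStart, df$txEnd - 1L)
  if (any(tss < 0)) stop("negative TSS coordinate in gene table")
  recs <- data.frame(gene_id = as.character(df$gene_id),
                     chrom = as.character(df$chrom),
                     tss = as.integer(tss),
                     strand = df$strand,
                     gene_class = as.character(df$gene_class),
                     stringsAsFactors = FALSE)
  split_recs <- split(recs, recs$gene_id)
  out <- lapply(split_recs, function(g) {
    if (length(unique(g$chrom)) > 1L) {
      stop("gene '", g$gene_id[1L], "' has transcripts on multiple ",
           "chromosomes")
    }
    if (length(unique(g$strand)) > 1L) {
      stop("gene '", g$gene_id[1L], "' has transcripts on both strands")
    }
    # 5'-most TSS across transcripts
    pick <- if (g$strand[1L] == "+") which.min(g$tss) else which.max(g$tss)
    g[pick, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$gene_id, recs$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids. Duplicate ids within a line are
#' removed; empty lines are skipped.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene ids, with per-set
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  idx <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed GMT line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[`, "", 2L), names(sets))
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors of gene ids, optionally
#'   with a `"description"` attribute as produced by [read_gmt()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
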