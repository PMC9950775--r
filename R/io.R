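# Format I/O: GTF (1-based inclusive, gene_id/transcript_id attributes),
# FASTA, and headered TSV tables.

#' Read / write tab-separated tables
#'
#' Headered, UTF-8, dot-decimal TSV with no quoting.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path; sequences are line-wrapped.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Write an annotation as GTF
#'
#' Emits gene, transcript, exon and CDS lines (1-based inclusive) with
#' `gene_id` and `transcript_id` attributes for the reference
#' (all-constitutive) isoform of every gene.
#'
#' @param annotation an `as_annotation`.
#' @param path output GTF path.
#' @export
write_gtf <- function(annotation, path) {
  rows <- list()
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    ex <- .gene_exons(annotation, g$gene_id)
    tx_id <- paste0(g$gene_id, ".1")
    add <- function(type, s, e, phase = NA_integer_) {
      data.frame(chrom = g$chrom, start = s, end = e, type = type,
                 strand = g$strand, gene_id = g$gene_id,
                 transcript_id = tx_id, phase = phase,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add("gene", g$gstart, g$gend)
    rows[[length(rows) + 1]] <- add("transcript", g$gstart, g$gend)
    for (k in seq_len(nrow(ex)))
      rows[[length(rows) + 1]] <- add("exon", ex$gstart[k], ex$gend[k])
    # CDS pieces: exon intersected with the genomic CDS span, walked in
    # transcript order to accumulate the reading-frame phase
    cds_cum <- 0L
    for (k in seq_len(nrow(ex))) {
      s <- max(ex$gstart[k], g$cds_glo); e <- min(ex$gend[k], g$cds_ghi)
      if (s <= e) {
        rows[[length(rows) + 1]] <-
          add("CDS", s, e, phase = (3L - cds_cum %% 3L) %% 3L)
        cds_cum <- cds_cum + (e - s + 1L)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "retrosplice"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read and validate a GTF file
#'
#' Light validation before import: every non-comment line must have 9
#' tab-separated fields, coordinates must satisfy 1 <= start <= end
#' (zero-length or inverted intervals are parse errors), and a `gene_id`
#' attribute must be present; violations raise an error naming the line.
#'
#' @param path GTF file.
#' @return a [GenomicRanges::GRanges] with the GTF attributes as
#'   metadata columns.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9)
      stop("GTF parse error at line ", i, ": expected 9 fields, got ",
           length(fields))
    s <- suppressWarnings(as.integer(fields[4]))
    e <- suppressWarnings(as.integer(fields[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      stop("GTF parse error at line ", i,
           ": invalid interval [", fields[4], ", ", fields[5], "]")
    if (!grepl("gene_id", fields[9], fixed = TRUE))
      stop("GTF parse error at line ", i, ": missing gene_id attribute")
  }
  rtracklayer::import(path, format = "gtf")
}

#' Rebuild an annotation object from emitted artifacts
#'
#' Inverse of [write_annotation()] for the annotation part: reads
#' `genome.fa`, `genes.tsv`, `exons.tsv` and `events.tsv` from a
#' directory and reassembles the `as_annotation` object.
#'
#' @param dir directory previously written by [write_annotation()].
#' @param params generator parameters to attach (defaults to
#'   [sim_params()]; only used by downstream defaults, not by geometry).
#' @return an `as_annotation`.
#' @export
read_annotation <- function(dir, params = sim_params()) {
  structure(list(
    genes = read_tsv_table(file.path(dir, "genes.tsv")),
    exons = read_tsv_table(file.path(dir, "exons.tsv")),
    events = read_tsv_table(file.path(dir, "events.tsv")),
    genome = read_fasta(file.path(dir, "genome.fa")),
    params = params), class = "as_annotation")
}

#' Write all synthetic-data artifacts to a directory
#'
#' Emits the genome FASTA, annotation GTF, events TSV, gene table TSV,
#' and (when given) the truth, junction-count and gene-count TSVs plus a
#' gene-localization side table.
#'
#' @param annotation an `as_annotation`.
#' @param dir output directory (created if needed).
#' @param truth optional `as_truth`.
#' @param junc optional junction-count table.
#' @param gene_counts optional gene-count table.
#' @return the directory, invisibly.
#' @export
write_annotation <- function(annotation, dir, truth = NULL, junc = NULL,
                             gene_counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(annotation$genome, file.path(dir, "genome.fa"))
  write_gtf(annotation, file.path(dir, "annotation.gtf"))
  write_tsv_table(annotation$events, file.path(dir, "events.tsv"))
  write_tsv_table(annotation$genes, file.path(dir, "genes.tsv"))
  write_tsv_table(annotation$exons, file.path(dir, "exons.tsv"))
  if (!is.null(truth)) {
    write_tsv_table(truth$events, file.path(dir, "truth_events.tsv"))
    psi <- data.frame(event_id = rownames(truth$psi), truth$psi,
                      check.names = FALSE)
    write_tsv_table(psi, file.path(dir, "truth_psi.tsv"))
    write_tsv_table(truth$genes, file.path(dir, "truth_genes.tsv"))
    write_tsv_table(
      truth$genes[, c("gene_id", "localization")],
      file.path(dir, "gene_localization.tsv"))
  }
  if (!is.null(junc))
    write_tsv_table(junc, file.path(dir, "junction_counts.tsv"))
  if (!is.null(gene_counts))
    write_tsv_table(gene_counts, file.path(dir, "gene_counts.tsv"))
  invisible(dir)
}
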