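#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write gene models to GFF3
#'
#' Gene models use 0-based half-open coordinates internally; GFF3 output is
#' 1-based closed, one `gene` feature per model.
#'
#' @param genes data.frame with `gene_id`, `contig`, `start`, `end`, `strand`.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand,
    type = "gene",
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `contig`, `start` (0-based), `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(
    gene_id = if (!is.null(gr$ID)) as.character(gr$ID) else paste0("gene", seq_along(gr)),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write intervals to BED (0-based half-open)
#' @param intervals data.frame with `contig`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("contig", "start", "end")]
  if (!is.null(intervals$name)) df$name <- intervals$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_intervals(gr)
}

#' Write truth alignments to SAM
#'
#' Alignments are ungapped single-end records (`<read length>M` CIGAR) with
#' mandatory `@SQ` headers, suitable for `samtools`/Rsamtools consumption.
#'
#' @param aln data.frame with `qname`, `contig`, `pos` (0-based leftmost),
#'   `seq`, `qual`.
#' @param genome named character vector (for `@SQ` lengths).
#' @param path output path.
#' @export
write_sam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  if (nrow(aln) > 0) {
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       aln$qname, aln$contig, aln$pos + 1L,
                       nchar(aln$seq), aln$seq, aln$qual), con)
  }
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM text is converted with [Rsamtools::asBam()] and records are loaded via
#' [Rsamtools::scanBam()]. Only mapped records are returned.
#'
#' @param path SAM or BAM path.
#' @return data.frame with `qname`, `contig`, `pos` (0-based), `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual")
  ))[[1]]
  keep <- !is.na(res$pos)
  data.frame(
    qname = res$qname[keep],
    contig = as.character(res$rname[keep]),
    pos = res$pos[keep] - 1L,
    seq = as.character(res$seq[keep]),
    qual = as.character(res$qual[keep]),
    stringsAsFactors = FALSE
  )
}

#' Write a site-call table to TSV
#' @param x data.frame.
#' @param path output path.
#' @param header optional named list written as `# key: value` comment lines.
#' @export
write_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, as.character, "")), con)
  }
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
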