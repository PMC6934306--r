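#' @importFrom stats density pbinom phyper rbinom runif setNames
#' @importFrom utils write.table read.table head
NULL

BASES <- c("A", "C", "G", "T")

# Fast random DNA string of length n (uniform or GC-weighted).
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a string into a character vector of single bases.
str_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# Encode A/C/G/T -> 1..4 (0 for anything else) for a concatenated base string.
base_codes <- function(bases_raw) {
  code <- integer(256)
  code[as.integer(charToRaw("A")) + 1L] <- 1L
  code[as.integer(charToRaw("C")) + 1L] <- 2L
  code[as.integer(charToRaw("G")) + 1L] <- 3L
  code[as.integer(charToRaw("T")) + 1L] <- 4L
  code[as.integer(bases_raw) + 1L]
}

# data.frame(contig, start, end) [0-based half-open] -> GRanges
intervals_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_intervals <- function(gr) {
  if (length(gr) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Merge overlapping/adjacent intervals; returns sorted 0-based half-open df.
merge_intervals <- function(df) {
  granges_to_intervals(GenomicRanges::reduce(intervals_to_granges(df)))
}

#' Which positions fall inside a set of intervals
#'
#' @param contig character vector of contig names.
#' @param pos integer vector of 0-based positions.
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return logical vector along `pos`.
#' @export
positions_in_intervals <- function(contig, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  gr_pos <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos + 1L, width = 1L))
  IRanges::overlapsAny(gr_pos, intervals_to_granges(intervals))
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
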