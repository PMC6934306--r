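ENZYMES <- list(
  EcoRI = list(motif = "GAATTC", offset = 1L),  # G^AATTC
  MseI  = list(motif = "TTAA",   offset = 1L)   # T^TAA
)

#' Find restriction-enzyme cut positions in a sequence
#'
#' Both recognition motifs are palindromic, so scanning the top strand
#' suffices. A cut position is the 0-based coordinate where the enzyme cleaves
#' (motif occurrence + cut offset): EcoRI cuts G^AATTC, MseI cuts T^TAA.
#'
#' @param sequence a DNA string.
#' @param enzyme `"EcoRI"` or `"MseI"`.
#' @return strictly increasing integer vector of 0-based cut positions.
#' @export
find_cut_sites <- function(sequence, enzyme) {
  if (!enzyme %in% names(ENZYMES)) {
    stop(sprintf("unknown enzyme '%s' (expected EcoRI or MseI)", enzyme))
  }
  e <- ENZYMES[[enzyme]]
  hits <- Biostrings::matchPattern(e$motif, Biostrings::DNAString(sequence))
  starts <- Biostrings::start(hits) - 1L        # 0-based motif starts
  sort(starts + e$offset)
}

#' Predict ddRAD fragments by in silico EcoRI/MseI double digestion
#'
#' For each contig the two enzymes' cut lists are merged; a candidate fragment
#' spans two *consecutive* cuts whose enzymes differ (matching double-digest
#' size-selection practice: fragments between two same-enzyme cuts are
#' discarded) and is retained when longer than 49 bp.
#'
#' @param genome named character vector of contig sequences.
#' @param min_length minimum fragment length retained (default 50).
#' @param max_length optional upper length bound (default `Inf`, off).
#' @return data.frame: `fragment_id`, `contig`, `start`, `end` (0-based
#'   half-open), `flank5_enzyme`, `flank3_enzyme`, `length`, `seq`.
#' @export
predict_fragments <- function(genome, min_length = 50L, max_length = Inf) {
  out <- lapply(names(genome), function(ctg) {
    seq <- genome[[ctg]]
    eco <- find_cut_sites(seq, "EcoRI")
    mse <- find_cut_sites(seq, "MseI")
    cuts <- data.frame(pos = c(eco, mse),
                       enzyme = rep(c("EcoRI", "MseI"),
                                    c(length(eco), length(mse))))
    if (nrow(cuts) < 2) return(NULL)
    cuts <- cuts[order(cuts$pos), ]
    i <- seq_len(nrow(cuts) - 1L)
    keep <- cuts$enzyme[i] != cuts$enzyme[i + 1L]
    start <- cuts$pos[i][keep]
    end <- cuts$pos[i + 1L][keep]
    len <- end - start
    ok <- len >= min_length & len <= max_length
    if (!any(ok)) return(NULL)
    data.frame(
      contig = ctg, start = start[ok], end = end[ok],
      flank5_enzyme = cuts$enzyme[i][keep][ok],
      flank3_enzyme = cuts$enzyme[i + 1L][keep][ok],
      length = len[ok],
      seq = substring(seq, start[ok] + 1L, end[ok]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), start = integer(), end = integer(),
                      flank5_enzyme = character(), flank3_enzyme = character(),
                      length = integer(), seq = character())
  }
  if (nrow(res) > 0) res$fragment_id <- sprintf("frag%05d", seq_len(nrow(res)))
  else res$fragment_id <- character(0)
  res[, c("fragment_id", "contig", "start", "end",
          "flank5_enzyme", "flank3_enzyme", "length", "seq")]
}

# Count exact occurrences of each pattern in the genome (top strand).
count_exact_matches <- function(patterns, genome) {
  counts <- integer(length(patterns))
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    counts <- counts + vapply(patterns, function(p) {
      Biostrings::countPattern(p, subject)
    }, integer(1))
  }
  unname(counts)
}

#' Anchor predicted fragments back to the genome as analysis regions
#'
#' Each fragment sequence is searched against the whole genome; fragments
#' matching exactly one location are kept (`uniquely_anchored = TRUE`), all
#' others are removed — multi-copy fragments cannot be assigned a single
#' region. The default search is exact matching; an identity threshold below 1
#' switches to the seeded mapper ([map_sequence()]) for divergent-copy data.
#' Surviving regions are labelled with coding overlap from the gene models
#' (any overlap of at least one base counts as coding).
#'
#' @param fragments output of [predict_fragments()].
#' @param genome named character vector.
#' @param gene_models optional data.frame (`contig`, `start`, `end`) of coding
#'   intervals for the `coding_overlap` flag.
#' @param min_identity 1 for exact matching (default), else identity cutoff
#'   for the seeded search.
#' @return the surviving fragments with `uniquely_anchored` and
#'   `coding_overlap` columns (predicted ddRAD regions).
#' @export
anchor_fragments <- function(fragments, genome, gene_models = NULL,
                             min_identity = 1) {
  if (nrow(fragments) == 0) {
    fragments$uniquely_anchored <- logical(0)
    fragments$coding_overlap <- logical(0)
    return(fragments)
  }
  if (min_identity >= 1) {
    nmatch <- count_exact_matches(fragments$seq, genome)
  } else {
    idx <- build_seed_index(genome)
    nmatch <- vapply(fragments$seq, function(s) {
      nrow(map_sequence(s, genome, min_identity = min_identity, index = idx))
    }, integer(1))
  }
  keep <- nmatch == 1L
  regions <- fragments[keep, , drop = FALSE]
  regions$uniquely_anchored <- TRUE
  regions$coding_overlap <- if (!is.null(gene_models) && nrow(regions) > 0) {
    IRanges::overlapsAny(intervals_to_granges(regions),
                         intervals_to_granges(gene_models))
  } else {
    rep(FALSE, nrow(regions))
  }
  rownames(regions) <- NULL
  regions
}
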