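#' Label repeated elements by all-vs-all global fragment comparison (M03)
#'
#' Every pair of predicted fragments is compared by end-to-end global
#' alignment; a pair "matches" when global identity (matches over alignment
#' length) reaches `min_identity`, and both members of a matching pair are
#' labelled repeated elements. Pairs whose length ratio already rules out the
#' identity threshold are skipped.
#'
#' @param fragments output of [predict_fragments()] (needs `fragment_id`,
#'   `seq`).
#' @param min_identity global identity threshold (default 0.80).
#' @param match,mismatch,gap alignment scoring (defaults +1/-1/-2).
#' @return character vector of labelled `fragment_id`s.
#' @export
label_m03 <- function(fragments, min_identity = 0.80,
                      match = 1, mismatch = -1, gap = -2) {
  n <- nrow(fragments)
  if (n == 0) return(character(0))
  labelled <- logical(n)
  lens <- nchar(fragments$seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  seqs <- Biostrings::DNAStringSet(fragments$seq)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # identity <= min(l_i, l_j) / max(l_i, l_j) for global alignment
      if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < min_identity) next
      aln <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], type = "global",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap
      )
      if (Biostrings::pid(aln, type = "PID1") / 100 >= min_identity) {
        labelled[i] <- TRUE
        labelled[j] <- TRUE
      }
    }
  }
  fragments$fragment_id[labelled]
}

#' Label repeated elements by genome-wide fragment search (M07)
#'
#' Each fragment is aligned against the whole genome with the seeded mapper;
#' hits require identity at least `min_identity` over at least 90% of the
#' fragment length. The fragment's own locus counts as the first match, so
#' more than one hit (any *additional* locus) earns the label.
#'
#' @param fragments output of [predict_fragments()].
#' @param genome named character vector.
#' @param min_identity hit identity threshold (default 0.80).
#' @param index optional prebuilt [build_seed_index()] of the genome.
#' @return character vector of labelled `fragment_id`s.
#' @export
label_m07 <- function(fragments, genome, min_identity = 0.80, index = NULL) {
  if (nrow(fragments) == 0) return(character(0))
  if (is.null(index)) index <- build_seed_index(genome)
  nhits <- vapply(fragments$seq, function(s) {
    nrow(map_sequence(s, min_identity = min_identity, min_cov = 0.9,
                      index = index))
  }, integer(1))
  fragments$fragment_id[nhits > 1L]
}

#' Label repeated elements by multi-mapping (M12)
#'
#' Seeded mapping of each fragment to the genome, reporting all hits whose
#' alignment score lies within `score_band` units of the best hit (capped at
#' `max_hits`). More than one reported hit earns the label. Medium stringency
#' between [label_m03()] and [label_m07()].
#'
#' @param fragments output of [predict_fragments()].
#' @param genome named character vector.
#' @param score_band score units below the best hit still reported
#'   (default 30).
#' @param min_identity floor identity for candidate hits (default 0.70).
#' @param max_hits report cap (default 100).
#' @param index optional prebuilt [build_seed_index()] of the genome.
#' @return character vector of labelled `fragment_id`s.
#' @export
label_m12 <- function(fragments, genome, score_band = 30, min_identity = 0.70,
                      max_hits = 100L, index = NULL) {
  if (nrow(fragments) == 0) return(character(0))
  if (is.null(index)) index <- build_seed_index(genome)
  nrep <- vapply(fragments$seq, function(s) {
    hits <- map_sequence(s, min_identity = min_identity, min_cov = 0.9,
                         index = index, max_hits = max_hits)
    if (nrow(hits) == 0) return(0L)
    sum(hits$score >= max(hits$score) - score_band)
  }, integer(1))
  fragments$fragment_id[nrep > 1L]
}

#' Label fragments by all three repeat-detection methods
#'
#' @param fragments output of [predict_fragments()].
#' @param genome named character vector.
#' @param ... passed through to the individual methods.
#' @return data.frame: `fragment_id`, logical `M03`, `M07`, `M12`.
#' @export
label_repeats <- function(fragments, genome, ...) {
  index <- build_seed_index(genome)
  m03 <- label_m03(fragments)
  m07 <- label_m07(fragments, genome, index = index)
  m12 <- label_m12(fragments, genome, index = index)
  data.frame(
    fragment_id = fragments$fragment_id,
    M03 = fragments$fragment_id %in% m03,
    M07 = fragments$fragment_id %in% m07,
    M12 = fragments$fragment_id %in% m12,
    stringsAsFactors = FALSE
  )
}

#' Interspersed-repeat mask from k-mer multiplicity
#'
#' Masks every genome position covered by at least one k-mer whose
#' genome-wide occurrence count reaches `multiplicity_threshold`; intervals
#' are merged. An externally supplied BED mask (e.g. from a dedicated repeat
#' annotator) may be passed instead via `external_mask` and takes precedence.
#'
#' @param genome named character vector.
#' @param k k-mer length (>= 11, default 15).
#' @param multiplicity_threshold minimum genome-wide k-mer count to mask
#'   (default 4).
#' @param external_mask optional data.frame (`contig`, `start`, `end`)
#'   returned as-is (merged).
#' @return data.frame of merged mask intervals (0-based half-open).
#' @export
kmer_interspersed_mask <- function(genome, k = 15L, multiplicity_threshold = 4L,
                                   external_mask = NULL) {
  if (!is.null(external_mask)) return(merge_intervals(external_mask))
  if (k < 11L) stop("k must be >= 11")
  if (k > min(nchar(genome))) stop("k longer than the shortest contig")
  per_ctg <- if (k <= 15L) {
    lapply(genome, function(s) kmer_int_codes(s, k))   # integer-coded k-mers
  } else {
    lapply(genome, function(s) {
      n <- nchar(s) - k + 1L
      km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
      km[grepl("[^ACGT]", km)] <- NA
      km
    })
  }
  all_codes <- unlist(per_ctg, use.names = FALSE)
  all_codes <- all_codes[!is.na(all_codes)]
  if (is.numeric(all_codes)) all_codes <- all_codes[all_codes >= 0]
  srt <- sort(all_codes, method = "radix")
  r <- rle(srt)
  frequent <- r$values[r$lengths >= multiplicity_threshold]
  if (length(frequent) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  masks <- lapply(seq_along(genome), function(i) {
    cc <- per_ctg[[i]]
    hit <- which(!is.na(cc) & cc %in% frequent) - 1L   # 0-based k-mer starts
    if (length(hit) == 0) return(NULL)
    data.frame(contig = names(genome)[i], start = hit, end = hit + k)
  })
  merge_intervals(do.call(rbind, masks))
}
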