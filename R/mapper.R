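# Integer codes for all k-mers of a sequence; -1 marks k-mers containing
# non-ACGT characters. k is limited to 15 (4^15 < 2^31).
kmer_int_codes <- function(seq, k) {
  codes <- base_codes(charToRaw(seq)) - 1L   # 0..3; -1 for non-ACGT
  n <- nchar(seq) - k + 1L
  if (n <= 0L) return(numeric(0))
  pow <- 4^((k - 1L):0L)
  out <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- bad | cj < 0L
    out <- out + pmax(cj, 0L) * pow[j]
  }
  out[bad] <- -1
  out
}

#' Build a seed index over a set of target sequences
#'
#' Indexes every `seed_len`-mer of the targets for the seed-and-extend mapper
#' [map_sequence()]. Build once, reuse across queries.
#'
#' @param targets named character vector of sequences.
#' @param seed_len seed k-mer length (max 15; default 11).
#' @return an object of class `seed_index`.
#' @export
build_seed_index <- function(targets, seed_len = 11L) {
  stopifnot(seed_len >= 5L, seed_len <= 15L)
  codes <- numeric(0); pos <- integer(0); ctg <- integer(0)
  for (i in seq_along(targets)) {
    cc <- kmer_int_codes(targets[[i]], seed_len)
    keep <- cc >= 0
    codes <- c(codes, cc[keep])
    pos <- c(pos, which(keep) - 1L)
    ctg <- c(ctg, rep(i, sum(keep)))
  }
  ord <- order(codes)
  structure(list(seed_len = seed_len, targets = targets,
                 codes = codes[ord], pos = pos[ord], ctg = ctg[ord]),
            class = "seed_index")
}

# All (contig, diagonal) candidates for one oriented query.
seed_candidates <- function(query, index, step) {
  k <- index$seed_len
  qlen <- nchar(query)
  if (qlen < k) return(NULL)
  offs <- unique(c(seq(0L, qlen - k, by = step), qlen - k))
  qc <- kmer_int_codes(query, k)[offs + 1L]
  ok <- qc >= 0
  offs <- offs[ok]; qc <- qc[ok]
  if (length(qc) == 0) return(NULL)
  lo <- findInterval(qc - 0.5, index$codes) + 1L
  hi <- findInterval(qc + 0.5, index$codes)
  n <- pmax(hi - lo + 1L, 0L)
  if (sum(n) == 0) return(NULL)
  rows <- sequence(n) - 1L + rep(lo, n)
  qoff <- rep(offs, n)
  unique(data.frame(ctg = index$ctg[rows],
                    diag = index$pos[rows] - qoff))
}

# Ungapped extension of a query along one diagonal of one target.
score_diagonal <- function(query, target, diag) {
  qlen <- nchar(query)
  tlen <- nchar(target)
  q_from <- max(0L, -diag)                 # clip to target bounds
  q_to <- min(qlen, tlen - diag)
  span <- q_to - q_from
  if (span <= 0) return(NULL)
  qs <- charToRaw(substr(query, q_from + 1L, q_to))
  ts <- charToRaw(substr(target, diag + q_from + 1L, diag + q_to))
  matches <- sum(qs == ts)
  list(t_start = diag + q_from, t_end = diag + q_to, span = span,
       matches = matches, identity = matches / span,
       score = matches - (span - matches))
}

#' Map a query sequence against target sequences (seed-and-extend)
#'
#' Ungapped seed-and-extend alignment on both strands: exact `seed_len`-mer
#' seeds define candidate diagonals, each diagonal is scored by direct base
#' comparison, and hits with identity at least `min_identity` over at least
#' `min_cov` of the query length are reported. Overlapping hits on the same
#' target keep only the best-scoring one. A query is "uniquely mapped" when
#' exactly one hit is returned.
#'
#' @param query a DNA string.
#' @param targets named character vector, or NULL when `index` is given.
#' @param min_identity minimum identity over the aligned span.
#' @param min_cov minimum aligned fraction of the query (default 0.9).
#' @param index optional prebuilt [build_seed_index()] of the targets.
#' @param step seed spacing along the query (default 5).
#' @param both_strands also search the reverse complement (default TRUE).
#' @param max_hits cap on reported hits (default 100).
#' @return data.frame of hits: `target`, `t_start`, `t_end` (0-based
#'   half-open), `strand`, `q_start`, `identity`, `score`, sorted by
#'   decreasing score.
#' @export
map_sequence <- function(query, targets = NULL, min_identity = 0.9,
                         min_cov = 0.9, index = NULL, step = 5L,
                         both_strands = TRUE, max_hits = 100L) {
  if (is.null(query) || !nzchar(query)) stop("empty query sequence")
  if (is.null(index)) index <- build_seed_index(targets, min(11L, nchar(query)))
  qlen <- nchar(query)
  queries <- list(`+` = query)
  if (both_strands) queries$`-` <- revcomp(query)
  hits <- list()
  for (strand in names(queries)) {
    q <- queries[[strand]]
    cand <- seed_candidates(q, index, step)
    if (is.null(cand)) next
    if (nrow(cand) > 5000L) cand <- cand[seq_len(5000L), ]
    for (i in seq_len(nrow(cand))) {
      tname <- names(index$targets)[cand$ctg[i]]
      sc <- score_diagonal(q, index$targets[[cand$ctg[i]]], cand$diag[i])
      if (is.null(sc)) next
      if (sc$span >= min_cov * qlen && sc$identity >= min_identity) {
        hits[[length(hits) + 1L]] <- data.frame(
          target = tname, t_start = sc$t_start, t_end = sc$t_end,
          strand = strand, q_start = max(0L, -cand$diag[i]),
          identity = sc$identity, score = sc$score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(target = character(), t_start = integer(),
                      t_end = integer(), strand = character(),
                      q_start = integer(), identity = numeric(),
                      score = numeric()))
  }
  df <- do.call(rbind, hits)
  df <- df[order(-df$score), , drop = FALSE]
  # collapse hits overlapping >50% on the same target (keep best score)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$target[i] == df$target[j]) {
        ov <- min(df$t_end[i], df$t_end[j]) - max(df$t_start[i], df$t_start[j])
        if (ov > 0.5 * (df$t_end[i] - df$t_start[i])) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  head(df, max_hits)
}
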