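#' Quality-filter RNA-seq reads
#'
#' Removes reads containing Ns, trims 3' ends while base quality is below
#' `trim_qual`, and retains reads longer than `min_len - 1` bases.
#'
#' @param reads data.frame (`id`, `seq`, `qual`) or FASTQ path.
#' @param min_len minimum retained read length (default 50).
#' @param trim_qual 3' trimming quality threshold (default 20).
#' @return filtered data.frame (`id`, `seq`, `qual`).
#' @export
qc_filter_reads <- function(reads, min_len = 50L, trim_qual = 20L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  keep <- !grepl("N", reads$seq, fixed = TRUE)
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0) return(reads[, c("id", "seq", "qual")])
  newlen <- vapply(reads$qual, function(q) {
    ph <- as.integer(charToRaw(q)) - 33L
    good <- which(ph >= trim_qual)
    if (length(good) == 0) 0L else max(good)
  }, integer(1))
  reads$seq <- substr(reads$seq, 1L, newlen)
  reads$qual <- substr(reads$qual, 1L, newlen)
  reads <- reads[newlen >= min_len, , drop = FALSE]
  rownames(reads) <- NULL
  reads[, c("id", "seq", "qual")]
}

#' Build a De Bruijn graph from reads
#'
#' Nodes are k-mers with read-support counts; edges link k-mers overlapping by
#' k-1 bases as observed consecutively in reads. k-mers seen fewer than
#' `solidity` times are removed (the solidity filter). The graph is stranded
#' by default (stranded library); with `stranded = FALSE` every read also
#' contributes its reverse complement.
#'
#' @param reads data.frame with `seq`, or character vector of sequences.
#' @param k odd k-mer size >= 15 (default 41).
#' @param solidity minimum k-mer count kept (default 2).
#' @param stranded logical (default TRUE).
#' @return object of class `debruijn_graph`.
#' @export
build_graph <- function(reads, k = 41L, solidity = 2L, stranded = TRUE) {
  if (k %% 2L == 0L || k < 15L) {
    stop("k must be odd and >= 15 (odd k avoids palindromic k-mer ambiguity)")
  }
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (!stranded) seqs <- c(seqs, revcomp(seqs))
  seqs <- seqs[nchar(seqs) >= k]
  kml <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  all_km <- unlist(kml, use.names = FALSE)
  all_km <- all_km[!grepl("[^ACGT]", all_km)]
  srt <- sort(all_km, method = "radix")
  r <- rle(srt)
  solid <- r$lengths >= solidity
  node_names <- r$values[solid]
  node_counts <- r$lengths[solid]
  cnt <- new.env(hash = TRUE, size = max(length(node_names), 1L))
  for (i in seq_along(node_names)) assign(node_names[i], node_counts[i], envir = cnt)
  # edges: consecutive k-mers within reads, both endpoints solid
  from <- unlist(lapply(kml, function(x) x[-length(x)]), use.names = FALSE)
  to <- unlist(lapply(kml, function(x) x[-1L]), use.names = FALSE)
  ok <- from %in% node_names & to %in% node_names
  from <- from[ok]; to <- to[ok]
  adj <- new.env(hash = TRUE, size = max(length(node_names), 1L))
  if (length(from) > 0) {
    pair_key <- paste(from, to, sep = " ")
    upair <- unique(pair_key)
    uf <- sub(" .*$", "", upair)
    ut <- sub("^.* ", "", upair)
    sp <- split(ut, uf)
    for (nm in names(sp)) assign(nm, sp[[nm]], envir = adj)
  }
  structure(list(k = k, solidity = solidity, stranded = stranded,
                 nodes = setNames(node_counts, node_names),
                 counts = cnt, adj = adj),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  n_edges <- sum(vapply(ls(x$adj), function(nm) length(get(nm, envir = x$adj)),
                        integer(1)))
  cat(sprintf("De Bruijn graph: k = %d, %d solid nodes (s >= %d), %d edges, %s\n",
              x$k, length(x$nodes), x$solidity, n_edges,
              if (x$stranded) "stranded" else "unstranded"))
  invisible(x)
}

graph_succ <- function(graph, node) {
  if (exists(node, envir = graph$adj, inherits = FALSE)) {
    get(node, envir = graph$adj)
  } else {
    character(0)
  }
}

graph_count <- function(graph, nodes) {
  vapply(nodes, function(n) get(n, envir = graph$counts), integer(1))
}

#' Enumerate Type0a SNP bubbles
#'
#' Finds pairs of vertex-disjoint simple paths of exactly k nodes between a
#' shared source and a shared sink. Each pair spells two sequences of length
#' 2k-1 differing by exactly one base at the centre offset k-1 — the De
#' Bruijn signature of an isolated substitution. Per-path support is the
#' maximum node count along the path, a proxy for the number of reads
#' sharing at least one path k-mer: it keeps allele totals comparable across
#' positions, where a minimum would deflate support near transcript ends and
#' distort minor-allele fractions.
#'
#' @param graph a [build_graph()] result.
#' @param max_bubbles safety cap (default 100000).
#' @return data.frame: `bubble_id`, `path_upper`, `path_lower` (upper =
#'   lexicographically smaller), `allele_upper`, `allele_lower`,
#'   `count_upper`, `count_lower`, `k`.
#' @export
find_type0a_bubbles <- function(graph, max_bubbles = 100000L) {
  k <- graph$k
  res <- list()
  spell <- function(path) {
    paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
  }
  # lockstep walk: extend both paths with the same base each step
  walk <- function(pu, pv) {
    if (length(pu) == k) {
      u <- pu[k]; v <- pv[k]
      sink <- intersect(graph_succ(graph, u), graph_succ(graph, v))
      if (length(sink) == 0) return(NULL)
      list(list(pu = pu, pv = pv))
    } else {
      out <- list()
      su <- graph_succ(graph, pu[length(pu)])
      sv <- graph_succ(graph, pv[length(pv)])
      if (length(su) == 0 || length(sv) == 0) return(NULL)
      for (c_next in intersect(substr(su, k, k), substr(sv, k, k))) {
        nu <- su[substr(su, k, k) == c_next][1]
        nv <- sv[substr(sv, k, k) == c_next][1]
        if (nu %in% pu || nv %in% pv || nu == nv) next  # simple, disjoint
        out <- c(out, walk(c(pu, nu), c(pv, nv)))
      }
      out
    }
  }
  for (s in names(graph$nodes)) {
    succ <- graph_succ(graph, s)
    if (length(succ) < 2L) next
    for (i in seq_len(length(succ) - 1L)) {
      for (j in (i + 1L):length(succ)) {
        pairs <- walk(succ[i], succ[j])
        for (p in pairs) {
          seq_u <- spell(p$pu)
          seq_v <- spell(p$pv)
          if (seq_u > seq_v) { tmp <- p$pu; p$pu <- p$pv; p$pv <- tmp
                               tmp <- seq_u; seq_u <- seq_v; seq_v <- tmp }
          res[[length(res) + 1L]] <- data.frame(
            path_upper = seq_u, path_lower = seq_v,
            allele_upper = substr(seq_u, k, k),
            allele_lower = substr(seq_v, k, k),
            count_upper = max(graph_count(graph, p$pu)),
            count_lower = max(graph_count(graph, p$pv)),
            stringsAsFactors = FALSE
          )
          if (length(res) >= max_bubbles) break
        }
      }
    }
    if (length(res) >= max_bubbles) break
  }
  if (length(res) == 0) {
    return(data.frame(bubble_id = character(), path_upper = character(),
                      path_lower = character(), allele_upper = character(),
                      allele_lower = character(), count_upper = integer(),
                      count_lower = integer(), k = integer()))
  }
  df <- unique(do.call(rbind, res))
  df$bubble_id <- sprintf("bubble%05d", seq_len(nrow(df)))
  df$k <- k
  rownames(df) <- NULL
  df[, c("bubble_id", "path_upper", "path_lower", "allele_upper",
         "allele_lower", "count_upper", "count_lower", "k")]
}

# Map one bubble path and classify placement; returns hit info + flags.
bubble_hit <- function(seq, index, min_identity, ambiguity_gap = 0.02) {
  hits <- map_sequence(seq, min_identity = min_identity, index = index)
  if (nrow(hits) == 0) {
    return(list(n = 0L, ambiguous = FALSE, hit = NULL))
  }
  ambiguous <- nrow(hits) > 1L &&
    (hits$identity[1] - hits$identity[2]) < ambiguity_gap
  list(n = nrow(hits), ambiguous = nrow(hits) > 1L || ambiguous,
       hit = hits[1, ])
}

# Transcript/genome coordinate of the bubble centre base for one hit.
center_coordinate <- function(hit, qlen, center) {
  if (hit$strand == "+") {
    hit$t_start + (center - hit$q_start)
  } else {
    hit$t_start + ((qlen - 1L - center) - hit$q_start)
  }
}

#' Filter bubbles against a reference transcriptome
#'
#' Applies the coverage and placement filters: total read coverage of at
#' least `min_total` (6), each allele observed at least `min_allele` times
#' (2), both alleles reaching the minor-allele fraction `min_freq` (0.1 — the
#' same recorded-allele rule that defines a bi-allelic position in genome
#' data; isolated duplicate sequencing errors sit far below it), a
#' phred-scaled minor-allele quality of at least `min_quality` under the
#' binomial error model (the RNA counterpart of the genome-side quality
#' floor), a single
#' unambiguous transcriptome placement (identity >= `min_identity` over >=
#' 90% of the path; more than one qualifying hit, or a best-hit identity
#' margin under 2%, is ambiguous), and membership in the curated reference
#' (no hit = removed).
#'
#' @param bubbles from [find_type0a_bubbles()].
#' @param transcriptome named character vector (one transcript per gene).
#' @param min_total minimum `count_upper + count_lower` (default 6).
#' @param min_allele minimum per-allele count (default 2).
#' @param min_freq minimum minor-allele fraction (default 0.1).
#' @param min_quality minimum [site_quality()] of the minor allele against
#'   the binomial error model (default 30, the same phred-scaled floor used
#'   for genome calls; rejects minor counts explainable by sequencing error
#'   at the observed support).
#' @param error_rate error model for the quality filter (default 0.01, as in
#'   [classify_sites()]).
#' @param min_identity transcriptome mapping identity (default 0.80).
#' @param index optional prebuilt [build_seed_index()] of the transcriptome.
#' @return retained bubbles with `transcript_id`, `t_pos` (0-based transcript
#'   coordinate of the variant), `t_strand`, `allele_upper_t`,
#'   `allele_lower_t` (alleles in transcript orientation).
#' @export
filter_bubbles <- function(bubbles, transcriptome, min_total = 6L,
                           min_allele = 2L, min_freq = 0.1,
                           min_quality = 30, error_rate = 0.01,
                           min_identity = 0.80, index = NULL) {
  if (nrow(bubbles) == 0) return(cbind(bubbles, transcript_id = character(0),
                                       t_pos = integer(0), t_strand = character(0),
                                       allele_upper_t = character(0),
                                       allele_lower_t = character(0)))
  total <- bubbles$count_upper + bubbles$count_lower
  minor <- pmin(bubbles$count_upper, bubbles$count_lower)
  keep <- total >= min_total & minor >= min_allele &
    ifelse(total > 0, minor / total, 0) >= min_freq
  keep <- keep & site_quality(minor, total, error_rate) >= min_quality
  bubbles <- bubbles[keep, , drop = FALSE]
  if (nrow(bubbles) == 0) return(cbind(bubbles, transcript_id = character(0),
                                       t_pos = integer(0), t_strand = character(0),
                                       allele_upper_t = character(0),
                                       allele_lower_t = character(0)))
  if (is.null(index)) index <- build_seed_index(transcriptome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- lapply(seq_len(nrow(bubbles)), function(i) {
    b <- bubbles[i, ]
    center <- b$k - 1L
    qlen <- nchar(b$path_upper)
    h <- bubble_hit(b$path_upper, index, min_identity)
    if (h$n != 1L || h$ambiguous) return(NULL)
    tpos <- center_coordinate(h$hit, qlen, center)
    tlen <- nchar(transcriptome[[h$hit$target]])
    if (tpos < 0L || tpos >= tlen) return(NULL)
    if (h$hit$strand == "+") {
      au <- b$allele_upper; al <- b$allele_lower
    } else {
      au <- unname(comp[b$allele_upper]); al <- unname(comp[b$allele_lower])
    }
    cbind(b, data.frame(transcript_id = h$hit$target, t_pos = tpos,
                        t_strand = h$hit$strand,
                        allele_upper_t = au, allele_lower_t = al,
                        stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(bubbles[0, ], transcript_id = character(0),
                 t_pos = integer(0), t_strand = character(0),
                 allele_upper_t = character(0), allele_lower_t = character(0))
  }
  rownames(out) <- NULL
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the given strand
#'
#' Longest ATG-to-stop ORF across the three frames of the supplied sequence
#' (stranded library: the transcript orientation is the coding strand); ties
#' resolve to the 5'-most start. The interval includes the stop codon.
#'
#' @param transcript a DNA string (>= 3 bases).
#' @return list (`start`, `end` 0-based half-open, `frame`) or NULL when no
#'   complete ORF exists.
#' @export
find_best_orf <- function(transcript) {
  L <- nchar(transcript)
  if (L < 3L) stop("transcript shorter than one codon")
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(transcript, starts + 1L, starts + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    open_from <- NA_integer_
    for (ci in seq_len(n_codons)) {
      if (is.na(open_from) && is_atg[ci]) open_from <- ci
      if (!is.na(open_from) && is_stop[ci]) {
        cand <- list(start = starts[open_from], end = starts[ci] + 3L,
                     frame = frame)
        len <- cand$end - cand$start
        if (is.null(best) || len > best$end - best$start ||
            (len == best$end - best$start && cand$start < best$start)) {
          best <- cand
        }
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Classify the codon effect of a bubble SNP
#'
#' Uses the variant's transcript coordinate: inside the ORF, both alleles'
#' codons are translated with the standard genetic code (identical amino acid
#' = synonymous, else nonsynonymous); outside the ORF (or with no ORF) the
#' effect is noncoding. The centre base decides coding status for bubbles
#' spanning an ORF boundary.
#'
#' @param bubble one row of a [filter_bubbles()] result.
#' @param transcript the transcript sequence (haplotype-1 reference version).
#' @param orf optional precomputed [find_best_orf()] result.
#' @return `"synonymous"`, `"nonsynonymous"` or `"noncoding"`.
#' @export
classify_effect <- function(bubble, transcript, orf = NULL) {
  tpos <- bubble$t_pos
  if (tpos < 0L || tpos >= nchar(transcript)) {
    stop("variant offset outside transcript bounds")
  }
  if (is.null(orf)) orf <- find_best_orf(transcript)
  if (is.null(orf) || tpos < orf$start || tpos >= orf$end) return("noncoding")
  codon_idx <- (tpos - orf$start) %/% 3L
  cstart <- orf$start + 3L * codon_idx
  codon <- substr(transcript, cstart + 1L, cstart + 3L)
  off <- tpos - cstart
  c1 <- codon; substr(c1, off + 1L, off + 1L) <- bubble$allele_upper_t
  c2 <- codon; substr(c2, off + 1L, off + 1L) <- bubble$allele_lower_t
  aa <- Biostrings::GENETIC_CODE[c(c1, c2)]
  if (any(is.na(aa))) return("noncoding")
  if (aa[1] == aa[2]) "synonymous" else "nonsynonymous"
}

#' Place bubbles on the reference genome
#'
#' Maps each bubble path to the genome (identity >= `min_identity` over >=
#' 90% of the path); uniquely mapped bubbles receive the genome coordinate of
#' their centre base (strand-resolved) and genome-orientation alleles.
#' Multi-hit and unmapped bubbles are flagged and excluded from consistency
#' analysis (reported separately).
#'
#' @param bubbles a bubble table (from [filter_bubbles()] or
#'   [find_type0a_bubbles()]).
#' @param genome named character vector.
#' @param min_identity genome mapping identity (default 0.90).
#' @param index optional prebuilt [build_seed_index()] of the genome.
#' @return `bubbles` with `genome_contig`, `genome_pos` (NA unless uniquely
#'   mapped), `genome_alleles` (sorted, slash-joined, genome orientation) and
#'   `genome_mapping` (`"unique"`, `"multi"`, `"unmapped"`, `"ambiguous"`).
#' @export
bubble_genome_positions <- function(bubbles, genome, min_identity = 0.90,
                                    index = NULL) {
  if (is.null(index)) index <- build_seed_index(genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (nrow(bubbles) == 0) {
    bubbles$genome_contig <- character(0)
    bubbles$genome_pos <- integer(0)
    bubbles$genome_alleles <- character(0)
    bubbles$genome_mapping <- character(0)
    return(bubbles)
  }
  bubbles$genome_contig <- NA_character_
  bubbles$genome_pos <- NA_integer_
  bubbles$genome_alleles <- NA_character_
  bubbles$genome_mapping <- "unmapped"
  for (i in seq_len(nrow(bubbles))) {
    b <- bubbles[i, ]
    h <- bubble_hit(b$path_upper, index, min_identity)
    if (h$n == 0L) next
    if (h$n > 1L || h$ambiguous) {
      bubbles$genome_mapping[i] <- if (h$n > 1L) "multi" else "ambiguous"
      next
    }
    center <- b$k - 1L
    gpos <- center_coordinate(h$hit, nchar(b$path_upper), center)
    glen <- nchar(genome[[h$hit$target]])
    if (gpos < 0L || gpos >= glen) next
    if (h$hit$strand == "+") {
      a <- c(b$allele_upper, b$allele_lower)
    } else {
      a <- unname(comp[c(b$allele_upper, b$allele_lower)])
    }
    bubbles$genome_contig[i] <- h$hit$target
    bubbles$genome_pos[i] <- gpos
    bubbles$genome_alleles[i] <- paste(sort(a), collapse = "/")
    bubbles$genome_mapping[i] <- "unique"
  }
  bubbles
}

#' Reference-free RNA bi-allele discovery, end to end
#'
#' QC-filters the reads, builds the De Bruijn graph, enumerates Type0a
#' bubbles, applies the transcriptome filters, predicts codon effects, and
#' places retained bubbles on the genome.
#'
#' @param reads data.frame (`id`, `seq`, `qual`) or FASTQ path.
#' @param transcriptome named character vector (curated reference).
#' @param genome optional named character vector for genomic placement.
#' @param k k-mer size (default 41).
#' @param solidity k-mer solidity threshold (default 2).
#' @param min_len,trim_qual QC parameters (see [qc_filter_reads()]).
#' @return list: `bubbles` (all found), `retained` (post-filter, with
#'   `effect` and genome placement), `rna_sites` (uniquely genome-placed
#'   bi-allelic positions: `contig`, `pos`, `alleles`).
#' @export
discover_rna_biallelic <- function(reads, transcriptome, genome = NULL,
                                   k = 41L, solidity = 2L, min_len = 50L,
                                   trim_qual = 20L) {
  reads <- qc_filter_reads(reads, min_len = min_len, trim_qual = trim_qual)
  graph <- build_graph(reads, k = k, solidity = solidity)
  bubbles <- find_type0a_bubbles(graph)
  tindex <- build_seed_index(transcriptome)
  retained <- filter_bubbles(bubbles, transcriptome, index = tindex)
  if (nrow(retained) > 0) {
    orfs <- lapply(transcriptome, find_best_orf)
    retained$effect <- vapply(seq_len(nrow(retained)), function(i) {
      classify_effect(retained[i, ], transcriptome[[retained$transcript_id[i]]],
                      orf = orfs[[retained$transcript_id[i]]])
    }, "")
  } else {
    retained$effect <- character(0)
  }
  rna_sites <- NULL
  if (!is.null(genome)) {
    retained <- bubble_genome_positions(retained, genome)
    uniq <- retained[retained$genome_mapping == "unique", , drop = FALSE]
    rna_sites <- data.frame(contig = uniq$genome_contig, pos = uniq$genome_pos,
                            alleles = uniq$genome_alleles,
                            count_upper = uniq$count_upper,
                            count_lower = uniq$count_lower,
                            stringsAsFactors = FALSE)
  }
  list(bubbles = bubbles, retained = retained, rna_sites = rna_sites,
       n_reads = nrow(reads), k = k)
}
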