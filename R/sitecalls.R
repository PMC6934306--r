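#' Per-position base counts from ungapped alignments (pileup)
#'
#' Tallies A/C/G/T counts at every covered reference position from aligned
#' read bases with base quality at least `min_bq`. Accepts the in-memory
#' alignment table emitted by the simulators or a SAM/BAM path (loaded via
#' Rsamtools).
#'
#' @param alignments data.frame (`contig`, `pos` 0-based, `seq`, `qual`) or a
#'   SAM/BAM file path.
#' @param genome named character vector; contigs must cover the alignments.
#' @param min_bq minimum base quality counted (default 13).
#' @return data.frame: `contig`, `pos` (0-based), `A`, `C`, `G`, `T`,
#'   `depth` (sum of counted bases), covered positions only.
#' @export
pileup_allele_counts <- function(alignments, genome, min_bq = 13L) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments)
  }
  bad <- setdiff(unique(alignments$contig), names(genome))
  if (length(bad) > 0) {
    stop(sprintf("alignment contig '%s' not found in genome", bad[1]))
  }
  out <- lapply(names(genome), function(ctg) {
    aln <- alignments[alignments$contig == ctg, , drop = FALSE]
    if (nrow(aln) == 0) return(NULL)
    lens <- nchar(aln$seq)
    posv <- sequence(lens) - 1L + rep(aln$pos, lens)
    bases <- charToRaw(paste(aln$seq, collapse = ""))
    quals <- as.integer(charToRaw(paste(aln$qual, collapse = ""))) - 33L
    code <- base_codes(bases)
    keep <- code > 0L & quals >= min_bq
    posv <- posv[keep]; code <- code[keep]
    if (length(posv) == 0) return(NULL)
    L <- nchar(genome[[ctg]])
    counts <- tabulate((posv) * 4L + code, nbins = 4L * L)
    m <- matrix(counts, ncol = 4L, byrow = TRUE,
                dimnames = list(NULL, BASES))
    depth <- as.integer(rowSums(m))
    covered <- which(depth > 0L)
    data.frame(contig = ctg, pos = covered - 1L,
               A = m[covered, "A"], C = m[covered, "C"],
               G = m[covered, "G"], T = m[covered, "T"],
               depth = depth[covered],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), depth = integer())
  }
  res
}

#' Phred-scaled site quality from a binomial error model
#'
#' The minor-allele count is tested against sequencing error alone:
#' `q = -10 log10 P(X >= minor_count)` with
#' `X ~ Binomial(depth, error_rate / 3)` (a specific substitution appears
#' with one third of the per-base error rate). Capped at 999. Plays the
#' filtering role of a caller's phred-scaled site quality.
#'
#' @param minor_count count of the second-most-frequent allele.
#' @param depth total counted depth.
#' @param error_rate per-base substitution error probability.
#' @return phred-scaled quality (vectorised).
#' @export
site_quality <- function(minor_count, depth, error_rate = 0.01) {
  if (any(error_rate <= 0) || any(error_rate >= 1)) {
    stop("error_rate must be in (0, 1)")
  }
  if (any(minor_count < 0) || any(minor_count > depth)) {
    stop("minor_count must be within [0, depth]")
  }
  p <- pbinom(minor_count - 1, depth, error_rate / 3, lower.tail = FALSE)
  q <- -10 * log10(p)
  q[minor_count == 0] <- 0
  pmin(q, 999)
}

#' Classify covered positions as NA/mono/bi/tri/tetra-allelic
#'
#' Applies the study's site rules: depth below `min_depth` gives `NA`; alleles
#' with frequency (count/depth) at least `min_freq` are "recorded"; one
#' recorded allele is mono-allelic; two or more recorded alleles whose
#' second-largest count passes [site_quality()] `>= min_quality` classify as
#' bi/tri/tetra-allelic by recorded-allele count (otherwise mono — the
#' quality filter removes the variant record). No allelic-ratio filter beyond
#' `min_freq` is applied. Raw fractions are kept (no renormalisation).
#'
#' @param counts pileup table from [pileup_allele_counts()].
#' @param min_depth minimum depth for a call (default 10).
#' @param min_freq minimum allele frequency recorded (default 0.1).
#' @param min_quality minimum phred-scaled site quality for a poly-allelic
#'   call (default 30).
#' @param error_rate error model for [site_quality()] (default 0.01).
#' @return `counts` with added columns `n_alleles`, `alleles` (slash-joined,
#'   by decreasing count then base), `freq1`, `freq2` (top-two recorded
#'   allele frequencies; `freq2` NA for mono), `qual`, `class`
#'   (`"NA"`/`"mono"`/`"bi"`/`"tri"`/`"tetra"`).
#' @export
classify_sites <- function(counts, min_depth = 10L, min_freq = 0.1,
                           min_quality = 30, error_rate = 0.01) {
  n <- nrow(counts)
  if (n == 0) {
    counts$n_alleles <- integer(0); counts$alleles <- character(0)
    counts$freq1 <- numeric(0); counts$freq2 <- numeric(0)
    counts$qual <- numeric(0); counts$class <- character(0)
    return(counts)
  }
  m <- as.matrix(counts[, BASES])
  depth <- counts$depth
  freq <- m / depth
  recorded <- freq >= min_freq & m > 0L
  n_rec <- rowSums(recorded)
  # order alleles by count desc then base (ties affect reporting only)
  ord <- t(apply(m, 1L, order, decreasing = TRUE))
  first <- m[cbind(seq_len(n), ord[, 1L])]
  second <- m[cbind(seq_len(n), ord[, 2L])]
  qual <- numeric(n)
  multi <- n_rec >= 2L
  qual[multi] <- site_quality(second[multi], depth[multi], error_rate)
  cls <- rep("mono", n)
  cls[n_rec >= 2L & qual >= min_quality] <-
    c("bi", "tri", "tetra")[pmin(n_rec[n_rec >= 2L & qual >= min_quality] - 1L, 3L)]
  cls[depth < min_depth] <- "NA"
  alleles <- vapply(seq_len(n), function(i) {
    rec <- ord[i, ][recorded[i, ord[i, ]]]
    paste(BASES[rec], collapse = "/")
  }, "")
  top2 <- t(vapply(seq_len(n), function(i) {
    rec <- ord[i, ][recorded[i, ord[i, ]]]
    c(if (length(rec) >= 1) freq[i, rec[1]] else NA_real_,
      if (length(rec) >= 2) freq[i, rec[2]] else NA_real_)
  }, numeric(2)))
  counts$n_alleles <- n_rec
  counts$alleles <- alleles
  counts$freq1 <- top2[, 1L]
  counts$freq2 <- top2[, 2L]
  counts$qual <- qual
  counts$class <- cls
  counts
}

#' Call sites from alignments in one step
#'
#' Convenience wrapper: [pileup_allele_counts()] then [classify_sites()].
#'
#' @inheritParams pileup_allele_counts
#' @inheritParams classify_sites
#' @export
call_sites <- function(alignments, genome, min_bq = 13L, min_depth = 10L,
                       min_freq = 0.1, min_quality = 30, error_rate = 0.01) {
  classify_sites(pileup_allele_counts(alignments, genome, min_bq),
                 min_depth = min_depth, min_freq = min_freq,
                 min_quality = min_quality, error_rate = error_rate)
}

#' Ingest pre-called variants from a VCF file
#'
#' Keeps SNP records only (indels and MNPs are dropped), applies
#' QUAL >= `min_quality`, depth >= `min_depth` and allele fraction >=
#' `min_freq`, and classifies by recorded-allele count. Per-allele depths are
#' taken from `AO`/`RO` (or `AD`) annotations.
#'
#' @param path VCF file path.
#' @param min_depth,min_freq,min_quality as in [classify_sites()].
#' @return site-call data.frame (`contig`, `pos` 0-based, `depth`,
#'   `n_alleles`, `alleles`, `freq1`, `freq2`, `qual`, `class`).
#' @export
ingest_vcf <- function(path, min_depth = 10L, min_freq = 0.1,
                       min_quality = 30) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(), pos = integer(), depth = integer(),
                      n_alleles = integer(), alleles = character(),
                      freq1 = numeric(), freq2 = numeric(),
                      qual = numeric(), class = character()))
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ro <- suppressWarnings(as.integer(vcfR::extract.info(v, "RO")))
  ao_raw <- vcfR::extract.info(v, "AO")
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  out <- lapply(seq_len(nrow(fix)), function(i) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (nchar(ref) != 1L || any(nchar(alts) != 1L) ||
        !ref %in% BASES || !all(alts %in% BASES)) {
      return(NULL)  # indel or MNP
    }
    if (is.na(qual[i]) || qual[i] < min_quality) return(NULL)
    depth <- dp[i]
    if (is.na(depth) || depth < min_depth) return(NULL)
    ao <- suppressWarnings(as.integer(strsplit(ao_raw[i], ",", fixed = TRUE)[[1]]))
    cnt <- setNames(rep(0L, 4L), BASES)
    cnt[ref] <- if (!is.na(ro[i])) ro[i] else depth - sum(ao, na.rm = TRUE)
    cnt[alts] <- ao[seq_along(alts)]
    freq <- cnt / depth
    rec <- which(freq >= min_freq & cnt > 0L)
    rec <- rec[order(-cnt[rec], BASES[rec])]
    n_rec <- length(rec)
    cls <- if (n_rec <= 1L) "mono" else c("bi", "tri", "tetra")[min(n_rec - 1L, 3L)]
    data.frame(
      contig = fix$CHROM[i], pos = as.integer(fix$POS[i]) - 1L,
      depth = depth, n_alleles = n_rec,
      alleles = paste(BASES[rec], collapse = "/"),
      freq1 = if (n_rec >= 1) unname(freq[rec[1]]) else NA_real_,
      freq2 = if (n_rec >= 2) unname(freq[rec[2]]) else NA_real_,
      qual = qual[i], class = cls, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), pos = integer(), depth = integer(),
                      n_alleles = integer(), alleles = character(),
                      freq1 = numeric(), freq2 = numeric(),
                      qual = numeric(), class = character())
  }
  res
}

#' Bi-allelic position density in covered analysis regions
#'
#' Density (per kb) = 1000 x (bi-allelic positions in non-masked, coding,
#' predicted ddRAD regions) / (positions in those regions with depth >=
#' `min_depth`).
#'
#' @param calls classified site table (from [classify_sites()]).
#' @param regions predicted ddRAD regions (`contig`, `start`, `end`).
#' @param mask optional repeat-mask intervals excluded from both counts.
#' @param coding optional coding intervals (gene models); when supplied with
#'   `coding_only = TRUE`, analysis is restricted to them.
#' @param coding_only restrict to coding intervals (default TRUE).
#' @param min_depth coverage floor for the denominator (default 10).
#' @return list: `density_per_kb` (NA when the denominator is 0),
#'   `n_biallelic`, `n_covered`.
#' @export
biallelic_density <- function(calls, regions, mask = NULL, coding = NULL,
                              coding_only = TRUE, min_depth = 10L) {
  keep <- positions_in_intervals(calls$contig, calls$pos, regions)
  if (!is.null(mask) && nrow(mask) > 0) {
    keep <- keep & !positions_in_intervals(calls$contig, calls$pos, mask)
  }
  if (coding_only && !is.null(coding)) {
    keep <- keep & positions_in_intervals(calls$contig, calls$pos, coding)
  }
  sub <- calls[keep, , drop = FALSE]
  n_cov <- sum(sub$depth >= min_depth)
  n_bi <- sum(sub$class == "bi")
  list(
    density_per_kb = if (n_cov == 0) NA_real_ else 1000 * n_bi / n_cov,
    n_biallelic = n_bi, n_covered = n_cov
  )
}

#' Allele-frequency distribution at bi-allelic sites
#'
#' For every bi-allelic site with depth at least `min_depth_threshold`, one of
#' the two recorded allele frequencies is chosen uniformly at random (seeded)
#' and appended; raising the threshold never adds values. Returns the value
#' list plus a kernel-density estimate and a 0.01-bin histogram.
#'
#' @param calls classified site table.
#' @param min_depth_threshold minimum depth for inclusion (default 10).
#' @param seed seed for the random allele choice (default 1).
#' @return object of class `freq_distribution`: list with `threshold`,
#'   `values`, `density` (stats::density, NULL if < 2 values), `histogram`
#'   (counts over breaks `seq(0, 1, 0.01)`), `modal_bin` (midpoint of the
#'   fullest bin).
#' @export
frequency_distribution <- function(calls, min_depth_threshold = 10L, seed = 1L) {
  bi <- calls[calls$class == "bi" & calls$depth >= min_depth_threshold, ,
              drop = FALSE]
  values <- numeric(0)
  if (nrow(bi) > 0) {
    values <- with_seed(seed, {
      pick2 <- runif(nrow(bi)) < 0.5
      ifelse(pick2, bi$freq2, bi$freq1)
    })
  }
  breaks <- seq(0, 1, by = 0.01)
  h <- if (length(values) > 0) {
    # left-closed bins [a, b): a frequency of exactly 0.50 falls in [0.50, 0.51)
    graphics::hist(values, breaks = breaks, right = FALSE, plot = FALSE)
  } else {
    NULL
  }
  kde <- if (length(values) >= 2 && stats::sd(values) > 0) {
    density(values, from = 0, to = 1)
  } else {
    NULL
  }
  # the mode is read from the kernel-density estimate (the curve the analysis
  # plots): with a 0.01-bin histogram the raw fullest bin jitters by several
  # bin widths at typical site counts. modal_bin is the midpoint of the bin
  # containing the KDE mode.
  modal <- if (!is.null(kde)) {
    m <- kde$x[which.max(kde$y)]
    min(floor(m * 100), 99) / 100 + 0.005
  } else if (!is.null(h) && any(h$counts > 0)) {
    h$mids[which.max(h$counts)]
  } else {
    NA_real_
  }
  structure(list(
    threshold = min_depth_threshold,
    values = values,
    density = kde,
    histogram = h,
    modal_bin = modal
  ), class = "freq_distribution")
}

#' @export
print.freq_distribution <- function(x, ...) {
  cat(sprintf("Allele-frequency distribution: %d values (min depth %d), modal bin %.3f\n",
              length(x$values), x$threshold, x$modal_bin))
  invisible(x)
}

#' @export
plot.freq_distribution <- function(x, ...) {
  if (length(x$values) < 2) {
    warning("too few values to plot")
    return(invisible(x))
  }
  plot(x$density, main = sprintf("Allele frequencies (depth >= %d)", x$threshold),
       xlab = "allele frequency", ...)
  invisible(x)
}

#' Fraction of predicted regions covered by reads
#'
#' A region counts as covered when its mean depth (zero-depth positions
#' included) is at least `min_mean`.
#'
#' @param depths per-position depth table (`contig`, `pos`, `depth`), e.g.
#'   from [pileup_allele_counts()].
#' @param regions predicted ddRAD regions.
#' @param min_mean mean-coverage threshold (default 10).
#' @return list: `n_regions`, `n_covered`, `fraction`, per-region `mean_depth`.
#' @export
region_coverage <- function(depths, regions, min_mean = 10) {
  if (nrow(regions) == 0) {
    return(list(n_regions = 0L, n_covered = 0L, fraction = NA_real_,
                mean_depth = numeric(0)))
  }
  gr_pos <- GenomicRanges::GRanges(depths$contig,
                                   IRanges::IRanges(depths$pos + 1L, width = 1L))
  gr_reg <- intervals_to_granges(regions)
  ov <- GenomicRanges::findOverlaps(gr_pos, gr_reg)
  tot <- rep(0, nrow(regions))
  agg <- tapply(depths$depth[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov), sum)
  tot[as.integer(names(agg))] <- agg
  mean_depth <- tot / (regions$end - regions$start)
  n_cov <- sum(mean_depth >= min_mean)
  list(n_regions = nrow(regions), n_covered = n_cov,
       fraction = n_cov / nrow(regions), mean_depth = mean_depth)
}

#' Flag problematic genome regions
#'
#' Flags (a) fixed windows whose mean depth exceeds `fold` times the
#' genome-wide mean (collapsed repeats attract excess mapped reads) and (b)
#' neighbourhoods within `window` bases of any run of Ns (unsolved assembly
#' regions). Output intervals are merged.
#'
#' @param depths per-position depth table (`contig`, `pos`, `depth`).
#' @param genome named character vector (for N runs and lengths).
#' @param window window size in bases (default 100).
#' @param fold depth-excess multiplier (default 2.0).
#' @return merged data.frame of flagged intervals (0-based half-open).
#' @export
flag_problematic_regions <- function(depths, genome, window = 100L, fold = 2.0) {
  lim <- nchar(genome)[depths$contig]
  depths <- depths[!is.na(lim) & depths$pos < lim, , drop = FALSE]
  genome_len <- sum(nchar(genome))
  mean_depth <- sum(depths$depth) / genome_len
  flags <- list()
  for (ctg in names(genome)) {
    L <- nchar(genome[[ctg]])
    d <- depths[depths$contig == ctg & depths$pos < nchar(genome[[ctg]]), ,
                drop = FALSE]
    if (nrow(d) > 0 && mean_depth > 0) {
      win <- d$pos %/% window
      sums <- tapply(d$depth, win, sum)
      wi <- as.integer(names(sums))
      wlen <- pmin((wi + 1L) * window, L) - wi * window
      hot <- wi[sums / wlen > fold * mean_depth]
      if (length(hot) > 0) {
        flags[[length(flags) + 1L]] <- data.frame(
          contig = ctg, start = hot * window,
          end = pmin((hot + 1L) * window, L))
      }
    }
    nr <- gregexpr("N+", genome[[ctg]])[[1]]
    if (nr[1] != -1L) {
      ns <- as.integer(nr) - 1L
      ne <- ns + attr(nr, "match.length")
      flags[[length(flags) + 1L]] <- data.frame(
        contig = ctg, start = pmax(0L, ns - window),
        end = pmin(L, ne + window))
    }
  }
  if (length(flags) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  merge_intervals(do.call(rbind, flags))
}
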