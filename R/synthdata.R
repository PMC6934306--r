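#' Simulation configuration for a synthetic heterokaryon study
#'
#' Defines the conditions under which a synthetic heterokaryon (or homokaryon)
#' dataset is generated: a haploid genome carrying two nucleus genotypes mixed
#' at ratio `ratio_p`, planted SNPs in the density range observed for
#' *Rhizophagus irregularis* single-copy coding regions (roughly 1--2.8 per
#' kb), interspersed and duplicated repeats, and whole-genome (WG), ddRAD and
#' RNA read sets.
#'
#' @param genome_length genome size in bases (single contig); minimum 10000.
#' @param gc_fraction GC content of the random background sequence.
#' @param n_genes number of non-overlapping single-exon gene models.
#' @param gene_length length of each gene model, bases.
#' @param n_duplications number of exact segmental duplications to plant.
#' @param duplication_length length of each duplicated segment, bases.
#' @param n_interspersed number of copies of the interspersed repeat element.
#' @param element_length length of the interspersed element, bases.
#' @param n_snps SNPs planted between the two nucleus genotypes.
#' @param ratio_p proportion of nucleus genotype 1 in the mixture (0--1).
#' @param wg_depth,ddrad_depth,rna_depth mean fold-coverage of each read set.
#' @param read_length read length in bases (single-end).
#' @param error_rate per-base substitution error probability.
#' @param min_snp_spacing minimum distance between planted SNPs, bases.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_fraction = 0.3,
                       n_genes = 60L,
                       gene_length = 1200L,
                       n_duplications = 2L,
                       duplication_length = 2000L,
                       n_interspersed = 20L,
                       element_length = 500L,
                       n_snps = 300L,
                       ratio_p = 0.5,
                       wg_depth = 30,
                       ddrad_depth = 30,
                       rna_depth = 50,
                       read_length = 100L,
                       error_rate = 0.005,
                       min_snp_spacing = 100L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    n_duplications = as.integer(n_duplications),
    duplication_length = as.integer(duplication_length),
    n_interspersed = as.integer(n_interspersed),
    element_length = as.integer(element_length),
    n_snps = as.integer(n_snps), ratio_p = ratio_p,
    wg_depth = wg_depth, ddrad_depth = ddrad_depth, rna_depth = rna_depth,
    read_length = as.integer(read_length), error_rate = error_rate,
    min_snp_spacing = as.integer(min_snp_spacing), seed = as.integer(seed)
  )
  if (cfg$ratio_p < 0 || cfg$ratio_p > 1) stop("ratio_p must be in [0, 1]")
  if (cfg$n_snps < 0) stop("n_snps must be >= 0")
  if (any(c(cfg$wg_depth, cfg$ddrad_depth, cfg$rna_depth) < 0)) {
    stop("depths must be >= 0")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

# Sample n non-overlapping intervals of length len in [0, L), avoiding
# `forbidden` (data.frame contig/start/end) with `pad` clearance. Draws a
# start uniformly from the exact set of still-feasible positions, so
# placement only fails when the genome genuinely has no room left.
place_intervals <- function(L, n, len, forbidden = NULL, pad = 0L,
                            what = "interval") {
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer()))
  }
  placed <- if (!is.null(forbidden) && nrow(forbidden) > 0) {
    data.frame(start = pmax(0L, forbidden$start - pad),
               end = pmin(L, forbidden$end + pad))
  } else {
    data.frame(start = integer(), end = integer())
  }
  out_start <- integer(n)
  for (g in seq_len(n)) {
    # free gaps between already-occupied intervals
    occ <- placed[order(placed$start), , drop = FALSE]
    if (nrow(occ) > 0) occ$end <- cummax(occ$end)   # tolerate overlaps
    gaps <- data.frame(start = c(0L, occ$end), end = c(occ$start, L))
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    slots <- pmax(gaps$end - gaps$start - len + 1L, 0L)  # feasible starts/gap
    if (nrow(gaps) == 0L || sum(slots) == 0L) {
      stop(sprintf(
        "genome too short to place %d non-overlapping %ss of length %d in %d bases",
        n, what, len, L))
    }
    gi <- sample.int(nrow(gaps), 1L, prob = slots)
    s <- gaps$start[gi] + sample.int(slots[gi], 1L) - 1L
    out_start[g] <- s
    placed <- rbind(placed, data.frame(start = max(0L, s - pad),
                                       end = min(L, s + len + pad)))
  }
  data.frame(contig = "chr1", start = sort(out_start),
             end = sort(out_start) + len, stringsAsFactors = FALSE)
}

#' Simulate a reference genome with planted repeats and gene models
#'
#' Generates a random background sequence, overwrites it with
#' `n_interspersed` exact copies of one interspersed repeat element and with
#' `n_duplications` exact segmental duplications (source segment copied to a
#' second locus), then places non-overlapping gene models outside all repeat
#' intervals. Both copies of every duplication and every element instance are
#' recorded as truth repeat intervals.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `gene_models`
#'   (data.frame: gene_id, contig, start, end, strand; 0-based half-open),
#'   `repeats` (data.frame: contig, start, end, kind) and `expression_levels`
#'   (per-gene relative abundances, log-normal).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  if (L < 10000L) stop("genome_length must be >= 10000")
  with_seed(config$seed, {
    seq <- random_dna(L, config$gc_fraction)

    # interspersed element: one consensus, exact copies
    inter <- place_intervals(L, config$n_interspersed, config$element_length,
                             what = "interspersed repeat")
    if (nrow(inter) > 0) {
      element <- random_dna(config$element_length, config$gc_fraction)
      for (i in seq_len(nrow(inter))) {
        substr(seq, inter$start[i] + 1L, inter$end[i]) <- element
      }
      inter$kind <- "interspersed"
    } else {
      inter$kind <- character(0)
    }

    # segmental duplications: pick a source outside existing repeats, copy it
    dup <- data.frame(contig = character(), start = integer(),
                      end = integer(), kind = character())
    if (config$n_duplications > 0) {
      loci <- place_intervals(L, 2L * config$n_duplications,
                              config$duplication_length,
                              forbidden = inter, what = "duplication")
      ord <- sample.int(nrow(loci))  # random source/target pairing
      for (i in seq_len(config$n_duplications)) {
        src <- loci[ord[2L * i - 1L], ]
        tgt <- loci[ord[2L * i], ]
        substr(seq, tgt$start + 1L, tgt$end) <-
          substr(seq, src$start + 1L, src$end)
        dup <- rbind(dup, data.frame(contig = "chr1",
                                     start = c(src$start, tgt$start),
                                     end = c(src$end, tgt$end),
                                     kind = "duplication"))
      }
    }
    repeats <- rbind(inter[, c("contig", "start", "end", "kind")], dup)
    repeats <- repeats[order(repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL

    genes <- place_intervals(L, config$n_genes, config$gene_length,
                             forbidden = repeats, pad = 10L, what = "gene")
    gene_models <- data.frame(
      gene_id = sprintf("gene%03d", seq_len(nrow(genes))),
      contig = genes$contig, start = genes$start, end = genes$end,
      strand = sample(c("+", "-"), nrow(genes), replace = TRUE),
      stringsAsFactors = FALSE
    )
    expression <- stats::rlnorm(nrow(genes), meanlog = 0, sdlog = 0.5)

    list(genome = c(chr1 = seq), gene_models = gene_models,
         repeats = repeats,
         expression_levels = setNames(expression, gene_models$gene_id))
  })
}

# Positions within +/- pad of any EcoRI/MseI motif occurrence (0-based).
motif_exclusion_mask <- function(seq, pad = 6L) {
  L <- nchar(seq)
  mask <- rep(FALSE, L)
  for (motif in c("GAATTC", "TTAA")) {
    m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      for (s in as.integer(m)) {
        lo <- max(1L, s - pad)
        hi <- min(L, s + nchar(motif) - 1L + pad)
        mask[lo:hi] <- TRUE
      }
    }
  }
  mask
}

# Would substituting base `alt` at 0-based `pos` create an EcoRI/MseI motif?
creates_motif <- function(seq, pos, alt) {
  lo <- max(0L, pos - 6L)
  hi <- min(nchar(seq), pos + 7L)
  window <- substr(seq, lo + 1L, hi)
  substr(window, pos - lo + 1L, pos - lo + 1L) <- alt
  grepl("GAATTC", window, fixed = TRUE) || grepl("TTAA", window, fixed = TRUE)
}

#' Plant heterokaryon SNPs between two nucleus genotypes
#'
#' Haplotype 1 is the reference; haplotype 2 differs at exactly `n_snps`
#' positions. SNP positions avoid a +/-6 base window around every EcoRI/MseI
#' recognition motif and substitutions that would create a new motif, so both
#' haplotypes share a single in silico digest map. Planted SNPs keep a minimum
#' spacing (`min_snp_spacing`) so each one forms an isolated substitution.
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return an object of class `hk_truth`: list with `haplotype1`,
#'   `haplotype2`, `snp_table` (contig, pos 0-based, allele1, allele2,
#'   in_coding, in_repeat, transcribed), `gene_models`, `repeats`,
#'   `expression_levels`, `config`.
#' @export
plant_heterokaryon_snps <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  seq1 <- sim$genome[[1]]
  contig <- names(sim$genome)[1]
  L <- nchar(seq1)
  with_seed(config$seed + 1L, {
    excl <- motif_exclusion_mask(seq1)
    eligible <- which(!excl) - 1L   # 0-based
    if (config$n_snps > 0 && length(eligible) < config$n_snps) {
      stop("n_snps exceeds the number of eligible positions")
    }
    chosen <- integer(0)
    alt <- character(0)
    seq2 <- seq1
    pool <- sample(eligible)
    taken <- logical(L)
    spacing <- config$min_snp_spacing
    i <- 1L
    while (length(chosen) < config$n_snps && i <= length(pool)) {
      p <- pool[i]; i <- i + 1L
      lo <- max(1L, p + 1L - spacing); hi <- min(L, p + 1L + spacing)
      if (any(taken[lo:hi])) next
      ref_base <- substr(seq1, p + 1L, p + 1L)
      if (!ref_base %in% BASES) next
      for (a in sample(setdiff(BASES, ref_base))) {
        if (!creates_motif(seq1, p, a)) {
          chosen <- c(chosen, p)
          alt <- c(alt, a)
          taken[p + 1L] <- TRUE
          substr(seq2, p + 1L, p + 1L) <- a
          break
        }
      }
    }
    if (length(chosen) < config$n_snps) {
      stop("n_snps exceeds the number of eligible positions at this spacing")
    }
    ord <- order(chosen)
    chosen <- chosen[ord]; alt <- alt[ord]
    snp_table <- data.frame(
      contig = rep(contig, length(chosen)),
      pos = chosen,
      allele1 = if (length(chosen)) substring(seq1, chosen + 1L, chosen + 1L) else character(0),
      allele2 = alt %||% character(0),
      stringsAsFactors = FALSE
    )
    snp_table$in_coding <- positions_in_intervals(snp_table$contig, snp_table$pos,
                                                  sim$gene_models)
    snp_table$in_repeat <- positions_in_intervals(snp_table$contig, snp_table$pos,
                                                  sim$repeats)
    snp_table$transcribed <- snp_table$in_coding
    structure(list(
      haplotype1 = setNames(seq1, contig),
      haplotype2 = setNames(seq2, contig),
      snp_table = snp_table,
      gene_models = sim$gene_models,
      repeats = sim$repeats,
      expression_levels = sim$expression_levels,
      config = config
    ), class = "hk_truth")
  })
}

#' @export
print.hk_truth <- function(x, ...) {
  cat(sprintf("Synthetic heterokaryon truth: %d bp genome, %d planted SNPs, p = %.2f\n",
              nchar(x$haplotype1[[1]]), nrow(x$snp_table), x$config$ratio_p))
  cat(sprintf("  %d gene models, %d repeat intervals, %d coding SNPs\n",
              nrow(x$gene_models), nrow(x$repeats), sum(x$snp_table$in_coding)))
  invisible(x)
}

# Apply substitution errors at `error_rate` to a vector of read sequences.
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  big <- charToRaw(paste(seqs, collapse = ""))
  idx <- which(runif(length(big)) < error_rate)
  if (length(idx) > 0) {
    # substitute with one of the three other bases, uniformly
    alt <- matrix(charToRaw("CGTAGTACTACG"), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    cur <- base_codes(big[idx])
    ok <- cur > 0L
    pick <- sample.int(3L, sum(ok), replace = TRUE)
    big[idx[ok]] <- alt[cbind(cur[ok], pick)]
  }
  str <- rawToChar(big)
  ends <- cumsum(lens)
  substring(str, ends - lens + 1L, ends)
}

# Draw reads from the two haplotypes at given genomic start positions.
reads_from_haplotypes <- function(truth, starts, lens, prefix) {
  p <- truth$config$ratio_p
  hap1 <- runif(length(starts)) < p
  seq1 <- truth$haplotype1[[1]]
  seq2 <- truth$haplotype2[[1]]
  seqs <- character(length(starts))
  if (any(hap1)) {
    seqs[hap1] <- substring(seq1, starts[hap1] + 1L, starts[hap1] + lens[hap1])
  }
  if (any(!hap1)) {
    seqs[!hap1] <- substring(seq2, starts[!hap1] + 1L, starts[!hap1] + lens[!hap1])
  }
  seqs <- apply_errors(seqs, truth$config$error_rate)
  qual <- vapply(lens, function(n) strrep("F", n), "")  # constant Q37
  data.frame(
    id = sprintf("%s_%06d", prefix, seq_along(starts)),
    contig = names(truth$haplotype1)[1],
    pos = starts, seq = seqs, qual = qual,
    haplotype = ifelse(hap1, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Simulate whole-genome reads from a heterokaryon
#'
#' Each read is drawn from haplotype 1 with probability `ratio_p`, otherwise
#' from haplotype 2, at a uniform random genomic position, with substitution
#' errors at `error_rate`. Truth alignments record the generating coordinates,
#' so no read mapper is needed downstream.
#'
#' @param truth an `hk_truth`.
#' @param config the [sim_config()]; `seed_offset` distinguishes replicates.
#' @param seed_offset added to the stage seed so replicate read sets differ.
#' @return list with `reads` (id, seq, qual) and `alignments`
#'   (qname, contig, pos 0-based, seq, qual, haplotype).
#' @export
simulate_wg_reads <- function(truth, config = truth$config, seed_offset = 0L) {
  if (config$wg_depth <= 0) stop("wg_depth must be > 0")
  L <- nchar(truth$haplotype1[[1]])
  rl <- config$read_length
  n <- round(config$wg_depth * L / rl)
  with_seed(config$seed + 2L + seed_offset, {
    starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    df <- reads_from_haplotypes(truth, starts, rep(rl, n), "wg")
    list(reads = df[, c("id", "seq", "qual")],
         alignments = data.frame(qname = df$id, contig = df$contig,
                                 pos = df$pos, seq = df$seq, qual = df$qual,
                                 haplotype = df$haplotype,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate ddRAD reads restricted to predicted fragments
#'
#' Reads are sampled only from within the supplied predicted ddRAD fragments
#' (from [predict_fragments()] on the reference), from both haplotypes at
#' ratio `ratio_p`; every position outside all fragments receives zero ddRAD
#' coverage. Reads are truncated at fragment ends.
#'
#' @param truth an `hk_truth`.
#' @param fragments data.frame with `contig`, `start`, `end` (0-based
#'   half-open), e.g. from [predict_fragments()].
#' @param config the [sim_config()].
#' @param seed_offset added to the stage seed so replicate read sets differ.
#' @return list with `reads` and `alignments` as in [simulate_wg_reads()].
#' @export
simulate_ddrad_reads <- function(truth, fragments, config = truth$config,
                                 seed_offset = 0L) {
  if (is.null(fragments) || nrow(fragments) == 0) {
    stop("fragment list is empty: run predict_fragments() on the reference")
  }
  rl <- config$read_length
  widths <- fragments$end - fragments$start
  total <- sum(widths)
  n <- round(config$ddrad_depth * total / rl)
  with_seed(config$seed + 3L + seed_offset, {
    fi <- sample.int(nrow(fragments), n, replace = TRUE, prob = widths)
    offs <- floor(runif(n) * widths[fi])
    starts <- fragments$start[fi] + offs
    lens <- pmin(rl, fragments$end[fi] - starts)
    df <- reads_from_haplotypes(truth, starts, lens, "rad")
    list(reads = df[, c("id", "seq", "qual")],
         alignments = data.frame(qname = df$id, contig = df$contig,
                                 pos = df$pos, seq = df$seq, qual = df$qual,
                                 haplotype = df$haplotype,
                                 stringsAsFactors = FALSE))
  })
}

# Transcript sequence of one gene from one haplotype (strand-resolved).
transcript_seq <- function(hapseq, gene) {
  s <- substr(hapseq, gene$start + 1L, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

#' Simulate RNA-seq reads and the matching reference transcriptome
#'
#' One transcript per gene is extracted from each haplotype (strand-resolved);
#' reads are drawn from the genotype-1 transcript with probability `ratio_p`,
#' except for genes listed in `single_allele_genes`, which express only
#' allele 1 (negative controls). The emitted reference transcriptome holds the
#' haplotype-1 version of every gene and stands in for an assembled-transcript
#' reference.
#'
#' @param truth an `hk_truth`.
#' @param config the [sim_config()].
#' @param single_allele_genes character vector of gene ids expressing only
#'   haplotype 1.
#' @param seed_offset added to the stage seed so replicate read sets differ.
#' @return list with `reads`, `transcriptome` (named character vector),
#'   `transcript_truth` (gene-level table) and `rna_snps` (planted SNPs in
#'   transcript coordinates with strand-resolved alleles).
#' @export
simulate_rna_reads <- function(truth, config = truth$config,
                               single_allele_genes = character(),
                               seed_offset = 0L) {
  genes <- truth$gene_models
  if (nrow(genes) == 0) stop("gene_models is empty")
  rl <- config$read_length
  t1 <- vapply(seq_len(nrow(genes)),
               function(i) transcript_seq(truth$haplotype1[[1]], genes[i, ]), "")
  t2 <- vapply(seq_len(nrow(genes)),
               function(i) transcript_seq(truth$haplotype2[[1]], genes[i, ]), "")
  names(t1) <- names(t2) <- genes$gene_id
  lens <- nchar(t1)
  expr <- truth$expression_levels[genes$gene_id]
  total_reads <- round(config$rna_depth * sum(lens) / rl)
  with_seed(config$seed + 4L + seed_offset, {
    gi <- sample.int(nrow(genes), total_reads, replace = TRUE,
                     prob = expr * lens / sum(expr * lens))
    single <- genes$gene_id[gi] %in% single_allele_genes
    hap1 <- runif(total_reads) < config$ratio_p
    hap1[single] <- TRUE
    tlen <- lens[gi]
    span <- pmin(rl, tlen)
    offs <- floor(runif(total_reads) * (tlen - span + 1L))
    seqs <- character(total_reads)
    if (any(hap1)) {
      seqs[hap1] <- substring(t1[gi[hap1]], offs[hap1] + 1L, offs[hap1] + span[hap1])
    }
    if (any(!hap1)) {
      seqs[!hap1] <- substring(t2[gi[!hap1]], offs[!hap1] + 1L, offs[!hap1] + span[!hap1])
    }
    seqs <- apply_errors(seqs, config$error_rate)
    reads <- data.frame(
      id = sprintf("rna_%06d", seq_len(total_reads)),
      seq = seqs,
      qual = vapply(span, function(n) strrep("F", n), ""),
      gene_id = genes$gene_id[gi],
      haplotype = ifelse(hap1, 1L, 2L),
      stringsAsFactors = FALSE
    )
    # planted SNPs in transcript coordinates
    snp <- truth$snp_table[truth$snp_table$in_coding, , drop = FALSE]
    rna_snps <- NULL
    if (nrow(snp) > 0) {
      hit <- lapply(seq_len(nrow(snp)), function(i) {
        g <- genes[genes$start <= snp$pos[i] & genes$end > snp$pos[i], ]
        if (nrow(g) == 0) return(NULL)
        g <- g[1, ]
        if (g$strand == "+") {
          data.frame(gene_id = g$gene_id, tpos = snp$pos[i] - g$start,
                     allele1_t = snp$allele1[i], allele2_t = snp$allele2[i],
                     contig = snp$contig[i], pos = snp$pos[i],
                     strand = g$strand, stringsAsFactors = FALSE)
        } else {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          data.frame(gene_id = g$gene_id, tpos = (g$end - 1L) - snp$pos[i],
                     allele1_t = unname(comp[snp$allele1[i]]),
                     allele2_t = unname(comp[snp$allele2[i]]),
                     contig = snp$contig[i], pos = snp$pos[i],
                     strand = g$strand, stringsAsFactors = FALSE)
        }
      })
      rna_snps <- do.call(rbind, hit)
    }
    transcript_truth <- data.frame(
      gene_id = genes$gene_id, length = lens,
      n_reads = tabulate(gi, nbins = nrow(genes)),
      single_allele = genes$gene_id %in% single_allele_genes,
      stringsAsFactors = FALSE
    )
    list(reads = reads[, c("id", "seq", "qual", "gene_id", "haplotype")],
         transcriptome = t1,
         transcript_truth = transcript_truth,
         rna_snps = rna_snps)
  })
}

#' Write a complete synthetic study to disk
#'
#' Emits genome FASTA, transcriptome FASTA, gene GFF3, truth-repeat BED,
#' WG/ddRAD/RNA FASTQ, truth SAM alignments, and TSV truth tables.
#'
#' @param truth an `hk_truth`.
#' @param outdir output directory (created if missing).
#' @param fragments predicted ddRAD fragments (for the ddRAD sample); if NULL
#'   they are predicted from the reference.
#' @return invisibly, a named list of written paths.
#' @export
write_synthetic_study <- function(truth, outdir, fragments = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- truth$config
  if (is.null(fragments)) fragments <- predict_fragments(truth$haplotype1)
  wg <- simulate_wg_reads(truth)
  rad <- simulate_ddrad_reads(truth, fragments)
  rna <- simulate_rna_reads(truth)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.gff3"),
    repeats = file.path(outdir, "repeats_truth.bed"),
    snps = file.path(outdir, "snp_truth.tsv"),
    wg_fastq = file.path(outdir, "wg.fastq"),
    wg_sam = file.path(outdir, "wg.sam"),
    rad_fastq = file.path(outdir, "ddrad.fastq"),
    rad_sam = file.path(outdir, "ddrad.sam"),
    rna_fastq = file.path(outdir, "rna.fastq"),
    transcriptome = file.path(outdir, "transcriptome.fa"),
    expression = file.path(outdir, "expression_truth.tsv")
  )
  write_fasta(truth$haplotype1, paths$genome)
  write_gff3(truth$gene_models, paths$genes)
  write_bed(truth$repeats, paths$repeats)
  write_tsv(truth$snp_table, paths$snps, header = list(seed = cfg$seed))
  write_fastq(wg$reads, paths$wg_fastq)
  write_sam(wg$alignments, truth$haplotype1, paths$wg_sam)
  write_fastq(rad$reads, paths$rad_fastq)
  write_sam(rad$alignments, truth$haplotype1, paths$rad_sam)
  write_fastq(rna$reads[, c("id", "seq", "qual")], paths$rna_fastq)
  write_fasta(rna$transcriptome, paths$transcriptome)
  write_tsv(rna$transcript_truth, paths$expression, header = list(seed = cfg$seed))
  invisible(paths)
}
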