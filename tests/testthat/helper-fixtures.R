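# Shared fixtures and independent oracles. Heavy simulations are built once
# per test run and cached.

.fixtures <- new.env()

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small genome config for fast unit tests.
small_cfg <- function(...) {
  args <- list(genome_length = 50000L, n_genes = 20L, gene_length = 1000L,
               n_duplications = 1L, duplication_length = 1500L,
               n_interspersed = 5L, element_length = 400L,
               n_snps = 60L, seed = 3L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

small_truth <- function() {
  cached("small_truth", {
    cfg <- small_cfg()
    plant_heterokaryon_snps(simulate_genome(cfg), cfg)
  })
}

# Heterokaryon study at the reference conditions: 200 kb, 300 planted SNPs,
# p = 0.5, 30x WG, 0.5% error.
het_study <- function() {
  cached("het_study", {
    cfg <- sim_config(genome_length = 200000L, n_genes = 60L,
                      gene_length = 1200L, n_snps = 300L, ratio_p = 0.5,
                      wg_depth = 30, error_rate = 0.005, seed = 42L)
    truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
    regions <- anchor_fragments(predict_fragments(truth$haplotype1),
                                truth$haplotype1, truth$gene_models)
    mask <- kmer_interspersed_mask(truth$haplotype1)
    wg <- simulate_wg_reads(truth)
    calls <- call_sites(wg$alignments, truth$haplotype1)
    list(cfg = cfg, truth = truth, regions = regions, mask = mask,
         wg = wg, calls = calls)
  })
}

hom_study <- function() {
  cached("hom_study", {
    cfg <- sim_config(genome_length = 200000L, n_genes = 60L,
                      gene_length = 1200L, n_snps = 0L, ratio_p = 0.5,
                      wg_depth = 30, error_rate = 0.005, seed = 43L)
    truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
    regions <- anchor_fragments(predict_fragments(truth$haplotype1),
                                truth$haplotype1, truth$gene_models)
    mask <- kmer_interspersed_mask(truth$haplotype1)
    wg <- simulate_wg_reads(truth)
    calls <- call_sites(wg$alignments, truth$haplotype1)
    list(cfg = cfg, truth = truth, regions = regions, mask = mask,
         calls = calls)
  })
}

# RNA study with >= 100 transcribed planted SNPs at 50x transcript coverage.
rna_study <- function() {
  cached("rna_study", {
    cfg <- sim_config(genome_length = 200000L, n_genes = 100L,
                      gene_length = 1000L, n_snps = 300L, ratio_p = 0.5,
                      rna_depth = 50, error_rate = 0.005, seed = 11L)
    truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
    rna <- simulate_rna_reads(truth)
    res <- discover_rna_biallelic(rna$reads[, c("id", "seq", "qual")],
                                  rna$transcriptome, truth$haplotype1,
                                  k = 21L)
    list(cfg = cfg, truth = truth, rna = rna, res = res)
  })
}

# ---- independent oracles ------------------------------------------------

# Brute-force digest: regex scan of both motifs, consecutive-cut assembly.
oracle_fragments <- function(seq, min_len = 50L) {
  cuts <- data.frame(pos = integer(), enzyme = character())
  for (e in list(c("GAATTC", "EcoRI"), c("TTAA", "MseI"))) {
    m <- gregexpr(e[1], seq, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      cuts <- rbind(cuts, data.frame(pos = as.integer(m) - 1L + 1L,
                                     enzyme = e[2]))
    }
  }
  if (nrow(cuts) < 2) {
    return(data.frame(start = integer(), end = integer(),
                      e5 = character(), e3 = character()))
  }
  cuts <- cuts[order(cuts$pos), ]
  out <- data.frame(start = integer(), end = integer(),
                    e5 = character(), e3 = character())
  for (i in seq_len(nrow(cuts) - 1L)) {
    if (cuts$enzyme[i] != cuts$enzyme[i + 1L] &&
        cuts$pos[i + 1L] - cuts$pos[i] >= min_len) {
      out <- rbind(out, data.frame(start = cuts$pos[i], end = cuts$pos[i + 1L],
                                   e5 = cuts$enzyme[i], e3 = cuts$enzyme[i + 1L]))
    }
  }
  out
}

# Naive nested-loop pileup over alignment records.
oracle_pileup <- function(aln, positions) {
  counts <- matrix(0L, nrow = length(positions), ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (r in seq_len(nrow(aln))) {
    s <- aln$seq[r]
    for (o in seq_len(nchar(s))) {
      p <- aln$pos[r] + o - 1L
      idx <- match(p, positions)
      if (!is.na(idx)) {
        b <- substr(s, o, o)
        if (b %in% colnames(counts)) counts[idx, b] <- counts[idx, b] + 1L
      }
    }
  }
  counts
}

# Exhaustive upper-tail hypergeometric probability by subset enumeration.
oracle_hyper <- function(N, K, n, x) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= x))
}

# Brute-force Type0a bubble enumeration: all pairs of simple k-node paths
# between shared neighbours, via DFS over the full adjacency.
oracle_bubbles <- function(graph) {
  k <- graph$k
  nodes <- names(graph$nodes)
  succ <- function(n) {
    if (exists(n, envir = graph$adj, inherits = FALSE)) get(n, envir = graph$adj)
    else character(0)
  }
  paths_from <- function(start) {
    out <- list()
    dfs <- function(path) {
      if (length(path) == k) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nx in succ(path[length(path)])) {
        if (!nx %in% path) dfs(c(path, nx))
      }
    }
    dfs(start)
    out
  }
  spell <- function(path) paste0(path[1], paste(substr(path[-1], k, k),
                                                collapse = ""))
  found <- list()
  for (s in nodes) {
    sc <- succ(s)
    if (length(sc) < 2) next
    all_paths <- unlist(lapply(sc, paths_from), recursive = FALSE)
    if (length(all_paths) < 2) next
    for (a in seq_len(length(all_paths) - 1L)) {
      for (b in (a + 1L):length(all_paths)) {
        pu <- all_paths[[a]]; pv <- all_paths[[b]]
        if (length(intersect(pu, pv)) > 0) next
        su <- spell(pu); sv <- spell(pv)
        d <- which(strsplit(su, "")[[1]] != strsplit(sv, "")[[1]])
        if (length(d) != 1L || d != k) next
        if (length(intersect(succ(pu[k]), succ(pv[k]))) == 0) next
        key <- paste(sort(c(su, sv)), collapse = "|")
        found[[key]] <- sort(c(su, sv))
      }
    }
  }
  found
}

# Brute-force longest ORF: scan every ATG, walk codons to the first stop.
oracle_orf <- function(seq) {
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s in seq_len(L - 2L)) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s
    while (p + 2L <= L) {
      codon <- substr(seq, p, p + 2L)
      if (codon %in% stops && p > s) {
        len <- p + 3L - s
        if (is.null(best) || len > best$len ||
            (len == best$len && s - 1L < best$start)) {
          best <- list(start = s - 1L, end = p + 2L, len = len)
        }
        break
      }
      p <- p + 3L
    }
  }
  if (is.null(best)) NULL else list(start = best$start, end = best$end)
}

random_seq <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

snp_keys <- function(snp_table) paste0(snp_table$contig, ":", snp_table$pos)
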