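test_that("read QC removes Ns, trims 3' ends, enforces minimum length", {
  reads <- data.frame(
    id = c("n_read", "lowq", "clean"),
    seq = c(paste0(strrep("A", 40), "N", strrep("A", 59)),
            strrep("A", 100), strrep("A", 100)),
    qual = c(strrep("F", 100),
             paste0(strrep("F", 40), strrep("#", 60)),   # last 60 bases Q2
             strrep("F", 100)),
    stringsAsFactors = FALSE
  )
  out <- qc_filter_reads(reads)
  expect_identical(out$id, "clean")         # N dropped; trimmed to 40 < 50
  expect_identical(out$seq, strrep("A", 100))
  # a 3' tail above Q20 survives trimming
  keep <- data.frame(id = "r", seq = strrep("A", 60),
                     qual = paste0(strrep("F", 55), strrep("#", 5)))
  expect_identical(nchar(qc_filter_reads(keep)$seq), 55L)
})

test_that("graph construction obeys k-mer, edge and solidity rules", {
  expect_error(build_graph("ACGT", k = 14L), "odd")
  expect_error(build_graph("ACGT", k = 16L), "odd")

  r <- random_seq(15, seed = 101)
  g1 <- build_graph(c(r, r), k = 15L, solidity = 2L)
  expect_identical(length(g1$nodes), 1L)

  # two reads overlapping by k-1 -> 2 nodes, 1 edge
  s <- random_seq(16, seed = 102)
  g2 <- build_graph(rep(c(substr(s, 1, 15), substr(s, 2, 16)), 2),
                    k = 15L, solidity = 2L)
  expect_identical(length(g2$nodes), 2L)

  # a k-mer seen once is absent under solidity 2
  g3 <- build_graph(c(r, random_seq(15, seed = 103)), k = 15L, solidity = 2L)
  expect_false(random_seq(15, seed = 103) %in% names(g3$nodes))
})

test_that("bubble finder recovers isolated substitutions exactly", {
  set.seed(111)
  base <- random_seq(100, seed = 112)
  alt <- base
  old <- substr(alt, 50, 50)
  substr(alt, 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  mk_reads <- function(s) {
    vapply(1:(nchar(s) - 39), function(i) substr(s, i, i + 39), "")
  }
  reads <- c(rep(mk_reads(base), 2), rep(mk_reads(alt), 2))
  g <- build_graph(reads, k = 15L, solidity = 2L)
  b <- find_type0a_bubbles(g)
  expect_identical(nrow(b), 1L)
  expect_identical(nchar(b$path_upper), 29L)   # 2k-1
  expect_setequal(c(b$allele_upper, b$allele_lower),
                  c(old, substr(alt, 50, 50)))
  expect_identical(hetkaryo:::hamming(b$path_upper, b$path_lower), 1L)

  # identical sequences give no bubbles
  g0 <- build_graph(rep(mk_reads(base), 2), k = 15L, solidity = 2L)
  expect_identical(nrow(find_type0a_bubbles(g0)), 0L)

  # two SNPs >= k apart give two bubbles
  alt2 <- base
  for (p in c(30, 70)) {
    substr(alt2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(alt2, p, p))[1]
  }
  g2 <- build_graph(c(rep(mk_reads(base), 2), rep(mk_reads(alt2), 2)),
                    k = 15L, solidity = 2L)
  expect_identical(nrow(find_type0a_bubbles(g2)), 2L)
})

test_that("bubble finder equals brute-force two-path enumeration", {
  # several random two-haplotype transcripts, small graphs
  for (seed in c(121, 122, 123)) {
    base <- random_seq(150, seed = seed)
    alt <- base
    p <- 40 + (seed %% 3) * 30
    substr(alt, p, p) <- setdiff(c("A", "C", "G", "T"), substr(alt, p, p))[1]
    reads <- c(vapply(1:(150 - 34), function(i) substr(base, i, i + 34), ""),
               vapply(1:(150 - 34), function(i) substr(alt, i, i + 34), ""))
    g <- build_graph(rep(reads, 2), k = 15L, solidity = 2L)
    expect_lt(length(g$nodes), 500)
    got <- find_type0a_bubbles(g)
    want <- oracle_bubbles(g)
    got_keys <- vapply(seq_len(nrow(got)), function(i) {
      paste(sort(c(got$path_upper[i], got$path_lower[i])), collapse = "|")
    }, "")
    expect_setequal(got_keys, names(want))
  }
})

test_that("bubble filters apply coverage, allele and placement rules", {
  tx <- c(t1 = random_seq(300, seed = 131))
  mk <- function(cu, cl, pos = 150L) {
    path_u <- substr(tx[[1]], pos - 14L, pos + 14L)
    path_l <- path_u
    substr(path_l, 15L, 15L) <- setdiff(c("A", "C", "G", "T"),
                                        substr(path_u, 15L, 15L))[1]
    data.frame(bubble_id = "b", path_upper = path_u, path_lower = path_l,
               allele_upper = substr(path_u, 15, 15),
               allele_lower = substr(path_l, 15, 15),
               count_upper = cu, count_lower = cl, k = 15L,
               stringsAsFactors = FALSE)
  }
  expect_identical(nrow(filter_bubbles(mk(3L, 2L), tx)), 0L)  # total 5 < 6
  expect_identical(nrow(filter_bubbles(mk(5L, 1L), tx)), 0L)  # allele 1 < 2
  kept <- filter_bubbles(mk(4L, 2L), tx)                      # retained
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$transcript_id, "t1")
  expect_identical(kept$t_pos, 149L)
  # minor fraction below 0.1 is not a bi-allelic position
  expect_identical(nrow(filter_bubbles(mk(50L, 2L), tx)), 0L)
  # a bubble matching two transcripts is ambiguous and removed
  tx2 <- c(tx, t2 = tx[[1]])
  expect_identical(nrow(filter_bubbles(mk(4L, 2L), tx2)), 0L)
})

test_that("ORF finder matches the exhaustive oracle", {
  orf <- find_best_orf("ATGAAATAA")
  expect_identical(orf$start, 0L)
  expect_identical(orf$end, 9L)
  expect_null(find_best_orf("CCCCCCCCC"))   # no ATG, no ORF
  expect_error(find_best_orf("AT"), "codon")
  for (seed in 141:148) {
    s <- random_seq(1000, seed = seed, gc = 0.5)
    got <- find_best_orf(s)
    want <- oracle_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
    }
  }
})

test_that("codon-effect calls match an independent translation oracle", {
  # GCT -> GCC is synonymous (Ala), AAA -> AGA is nonsynonymous (Lys -> Arg)
  tx <- paste0("ATG", "GCT", "AAA", "TAA")
  orf <- find_best_orf(tx)
  bub <- function(tpos, a1, a2) {
    data.frame(t_pos = tpos, allele_upper_t = a1, allele_lower_t = a2)
  }
  expect_identical(classify_effect(bub(5L, "T", "C"), tx, orf), "synonymous")
  expect_identical(classify_effect(bub(7L, "A", "G"), tx, orf), "nonsynonymous")
  # outside the ORF: noncoding
  tx2 <- paste0("CCCCCC", tx, "CCCCCC")
  orf2 <- find_best_orf(tx2)
  expect_identical(classify_effect(bub(1L, "C", "G"), tx2, orf2), "noncoding")
  expect_error(classify_effect(bub(99L, "A", "G"), tx, orf), "bounds")

  # all 576 single-base codon substitutions vs seqinr translation
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    for (off in 0:2) {
      for (alt in setdiff(bases, substr(codon, off + 1, off + 1))) {
        codon2 <- codon
        substr(codon2, off + 1, off + 1) <- alt
        tx3 <- paste0("ATG", codon, "TAATAA")
        orf3 <- list(start = 0L, end = 9L, frame = 0L)
        got <- classify_effect(bub(3L + off, substr(codon, off + 1, off + 1),
                                   alt), tx3, orf3)
        aa1 <- seqinr::translate(strsplit(codon, "")[[1]])
        aa2 <- seqinr::translate(strsplit(codon2, "")[[1]])
        want <- if (aa1 == aa2) "synonymous" else "nonsynonymous"
        expect_identical(got, want, label = paste(codon, off, alt))
      }
    }
  }
})

test_that("genome placement resolves strand and flags duplicates", {
  st <- rna_study()
  truth <- st$truth
  ret <- st$res$retained
  expect_gt(nrow(ret), 0)
  uniq <- ret[ret$genome_mapping == "unique", ]
  tk <- snp_keys(truth$snp_table)
  keys <- paste0(uniq$genome_contig, ":", uniq$genome_pos)
  hit <- match(keys, tk)
  matched <- uniq[!is.na(hit), ]
  snp <- truth$snp_table[hit[!is.na(hit)], ]
  # genome-orientation allele pairs equal planted pairs, strand-resolved:
  # reverse-strand genes must come out correct too
  want <- vapply(seq_len(nrow(snp)), function(i) {
    paste(sort(c(snp$allele1[i], snp$allele2[i])), collapse = "/")
  }, "")
  expect_identical(matched$genome_alleles, want)
  g <- truth$gene_models
  strands <- g$strand[match(matched$transcript_id, g$gene_id)]
  expect_true(all(c("+", "-") %in% strands))   # both strands exercised

  # a bubble from inside a duplicated segment is flagged multi
  set.seed(151)
  gseq <- random_seq(5000, seed = 152)
  seg <- substr(gseq, 1001, 1200)
  substr(gseq, 3001, 3200) <- seg
  path_u <- substr(seg, 50, 78)
  path_l <- path_u
  substr(path_l, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                    substr(path_u, 15, 15))[1]
  bub <- data.frame(bubble_id = "b", path_upper = path_u, path_lower = path_l,
                    allele_upper = substr(path_u, 15, 15),
                    allele_lower = substr(path_l, 15, 15),
                    count_upper = 10L, count_lower = 10L, k = 15L,
                    stringsAsFactors = FALSE)
  placed <- bubble_genome_positions(bub, c(chr1 = gseq))
  expect_identical(placed$genome_mapping, "multi")
})

test_that("homokaryon RNA yields essentially no retained bubbles", {
  cfg <- small_cfg(n_snps = 0L, rna_depth = 50, seed = 61L)
  truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
  rna <- simulate_rna_reads(truth)
  res <- discover_rna_biallelic(rna$reads[, c("id", "seq", "qual")],
                                rna$transcriptome, truth$haplotype1, k = 21L)
  # filters suppress duplicate sequencing-error bubbles
  expect_lte(nrow(res$retained), ceiling(nrow(truth$gene_models) / 100))
})
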