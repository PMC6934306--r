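test_that("seeded simulation is deterministic and honours repeat counts", {
  cfg <- small_cfg()
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1$genome, sim2$genome)
  expect_identical(sim1$gene_models, sim2$gene_models)

  none <- small_cfg(n_duplications = 0L, n_interspersed = 0L)
  expect_identical(nrow(simulate_genome(none)$repeats), 0L)

  one <- small_cfg(n_duplications = 1L, duplication_length = 2000L,
                   n_interspersed = 0L)
  sim <- simulate_genome(one)
  dup <- sim$repeats[sim$repeats$kind == "duplication", ]
  expect_identical(nrow(dup), 2L)
  seqs <- substring(sim$genome[[1]], dup$start + 1L, dup$end)
  expect_identical(seqs[1], seqs[2])
  expect_identical(unique(dup$end - dup$start), 2000L)
})

test_that("planted SNPs give the exact Hamming distance and avoid motifs", {
  truth <- small_truth()
  h1 <- strsplit(truth$haplotype1[[1]], "")[[1]]
  h2 <- strsplit(truth$haplotype2[[1]], "")[[1]]
  diff <- which(h1 != h2)
  expect_identical(length(diff), 60L)
  expect_identical(diff - 1L, truth$snp_table$pos)
  expect_true(all(truth$snp_table$allele1 != truth$snp_table$allele2))
  # both haplotypes share one digest map
  expect_identical(find_cut_sites(truth$haplotype1[[1]], "EcoRI"),
                   find_cut_sites(truth$haplotype2[[1]], "EcoRI"))
  expect_identical(find_cut_sites(truth$haplotype1[[1]], "MseI"),
                   find_cut_sites(truth$haplotype2[[1]], "MseI"))

  cfg0 <- small_cfg(n_snps = 0L)
  hom <- plant_heterokaryon_snps(simulate_genome(cfg0), cfg0)
  expect_identical(hom$haplotype1, hom$haplotype2)
})

test_that("planted SNP density lands in the field-realistic range", {
  # 300 SNPs on 200 kb = 1.5/kb, inside the observed 0.66-2.8/kb span
  cfg <- sim_config()
  expect_equal(1000 * cfg$n_snps / cfg$genome_length, 1.5)
})

test_that("WG reads recover the nucleus ratio and target depth", {
  st <- het_study()
  truth <- st$truth
  aln <- st$wg$alignments
  expect_identical(nrow(aln), nrow(st$wg$reads))   # conservation

  # expected allele-1 fraction at planted SNPs ~ Binomial(depth, p)
  snp <- truth$snp_table
  key <- paste0(st$calls$contig, ":", st$calls$pos)
  idx <- match(snp_keys(snp), key)
  covered <- !is.na(idx)
  a1 <- st$calls[idx[covered], ]
  m <- as.matrix(a1[, c("A", "C", "G", "T")])
  frac1 <- m[cbind(seq_len(nrow(a1)), match(snp$allele1[covered], colnames(m)))] /
    a1$depth
  se <- sqrt(0.25 / mean(a1$depth)) / sqrt(nrow(a1))
  expect_lt(abs(mean(frac1) - 0.5), 3 * se + 0.01)

  # truth alignments reproduce the configured mean depth within 10%
  mean_depth <- sum(nchar(aln$seq)) / nchar(truth$haplotype1[[1]])
  expect_lt(abs(mean_depth - st$cfg$wg_depth) / st$cfg$wg_depth, 0.10)
})

test_that("error-free p=1 reads match haplotype 1 exactly", {
  cfg <- small_cfg(error_rate = 0, ratio_p = 1, wg_depth = 2)
  truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
  wg <- simulate_wg_reads(truth)
  ok <- vapply(seq_len(nrow(wg$alignments)), function(i) {
    a <- wg$alignments[i, ]
    substr(truth$haplotype1[[1]], a$pos + 1L, a$pos + nchar(a$seq)) == a$seq
  }, logical(1))
  expect_true(all(ok))
})

test_that("ddRAD reads are confined to predicted fragments", {
  st <- het_study()
  frag <- predict_fragments(st$truth$haplotype1)
  rad <- simulate_ddrad_reads(st$truth, frag)
  aln <- rad$alignments
  gr_reads <- GenomicRanges::GRanges(
    aln$contig, IRanges::IRanges(aln$pos + 1L, width = nchar(aln$seq)))
  gr_frag <- GenomicRanges::GRanges(
    frag$contig, IRanges::IRanges(frag$start + 1L, frag$end))
  within <- IRanges::overlapsAny(gr_reads, gr_frag, type = "within")
  expect_true(all(within))
  expect_error(simulate_ddrad_reads(st$truth, frag[0, ]), "empty")
})

test_that("RNA reads: SNP-free genes are invariant, single-allele flag works", {
  truth <- small_truth()
  rna <- simulate_rna_reads(truth)
  coding_snps <- truth$snp_table[truth$snp_table$in_coding, ]
  g <- truth$gene_models
  has_snp <- vapply(seq_len(nrow(g)), function(i) {
    any(coding_snps$pos >= g$start[i] & coding_snps$pos < g$end[i])
  }, logical(1))
  # transcripts of SNP-free genes are identical between haplotypes
  for (i in which(!has_snp)[1:3]) {
    t1 <- rna$transcriptome[[g$gene_id[i]]]
    s2 <- substr(truth$haplotype2[[1]], g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") {
      s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s2)))
    }
    expect_identical(t1, s2)
  }
  # single-allele genes emit no haplotype-2 reads
  sag <- g$gene_id[which(has_snp)[1]]
  rna2 <- simulate_rna_reads(truth, single_allele_genes = sag)
  expect_true(all(rna2$reads$haplotype[rna2$reads$gene_id == sag] == 1L))
})

test_that("allele fraction at transcribed SNPs converges to ratio_p", {
  st <- rna_study()
  ret <- st$res$retained
  tk <- snp_keys(st$truth$snp_table[st$truth$snp_table$transcribed, ])
  keys <- paste0(ret$genome_contig, ":", ret$genome_pos)
  tp <- ret[keys %in% tk, ]
  frac <- tp$count_upper / (tp$count_upper + tp$count_lower)
  # allele orientation is arbitrary per bubble; fold to the minor fraction
  expect_gt(nrow(tp), 80)
  expect_lt(abs(mean(pmin(frac, 1 - frac)) - 0.5), 0.06)
})

test_that("written study files are byte-identical under one seed", {
  cfg <- small_cfg(genome_length = 20000L, n_genes = 6L, gene_length = 800L,
                   n_snps = 20L, n_interspersed = 3L, element_length = 300L,
                   duplication_length = 1000L, wg_depth = 10, ddrad_depth = 10,
                   rna_depth = 10)
  truth <- plant_heterokaryon_snps(simulate_genome(cfg), cfg)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_synthetic_study(truth, d1)
  p2 <- write_synthetic_study(truth, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(ratio_p = 1.2), "ratio_p")
  expect_error(sim_config(n_snps = -1), "n_snps")
  expect_error(sim_config(wg_depth = -3), "depths")
  expect_error(simulate_genome(sim_config(genome_length = 5000L)), ">= 10000")
  toomany <- small_cfg(n_snps = 60000L)
  expect_error(plant_heterokaryon_snps(simulate_genome(toomany), toomany),
               "eligible")
})
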