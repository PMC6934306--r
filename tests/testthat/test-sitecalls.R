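test_that("pileup counts single reads and matches the nested-loop oracle", {
  genome <- c(chr1 = strrep("T", 50))
  aln <- data.frame(qname = "r1", contig = "chr1", pos = 0L,
                    seq = "AAAA", qual = "FFFF", stringsAsFactors = FALSE)
  pc <- pileup_allele_counts(aln, genome)
  expect_identical(pc$pos, 0:3)
  expect_identical(pc$A, rep(1L, 4))
  expect_identical(pc$depth, rep(1L, 4))

  # ten error-free reads over one position give depth 10
  aln10 <- data.frame(qname = sprintf("r%d", 1:10), contig = "chr1",
                      pos = 0L, seq = strrep("ACGT", 3),
                      qual = strrep("F", 12), stringsAsFactors = FALSE)
  pc10 <- pileup_allele_counts(aln10, genome)
  expect_true(all(pc10$depth == 10L))

  # oracle equivalence on a real simulated sample (spot positions)
  st <- het_study()
  aln_wg <- st$wg$alignments
  pos <- sort(sample(st$truth$snp_table$pos, 25))
  want <- oracle_pileup(aln_wg, pos)
  got <- st$calls[match(pos, st$calls$pos), c("A", "C", "G", "T")]
  expect_identical(unname(as.matrix(got)), unname(want))

  expect_error(pileup_allele_counts(
    data.frame(qname = "r", contig = "chrX", pos = 0L, seq = "A", qual = "F"),
    genome), "chrX")
})

test_that("base-quality floor excludes low-quality bases from counts", {
  genome <- c(chr1 = strrep("T", 10))
  # second base has quality 5 (char '&'), below the floor of 13
  aln <- data.frame(qname = "r1", contig = "chr1", pos = 0L,
                    seq = "AA", qual = "F&", stringsAsFactors = FALSE)
  pc <- pileup_allele_counts(aln, genome, min_bq = 13L)
  expect_identical(pc$pos, 0L)
  expect_identical(pc$A, 1L)
})

test_that("site quality follows the exact binomial tail", {
  expect_equal(site_quality(0, 20), 0)
  # closed form at depth 20, minor 2, error 0.01 (e3 = 1/300)
  e3 <- 0.01 / 3
  p <- 1 - (1 - e3)^20 - 20 * e3 * (1 - e3)^19
  expect_equal(site_quality(2, 20, 0.01), -10 * log10(p), tolerance = 1e-10)
  # a 50:50 site at 30x is far beyond error expectation
  expect_gt(site_quality(15, 30, 0.01), 30)
  expect_error(site_quality(5, 3), "minor_count")
  expect_error(site_quality(1, 10, 0), "error_rate")
})

test_that("site classification applies depth, frequency and quality rules", {
  counts <- data.frame(
    contig = "chr1", pos = 0:4,
    A = c(9L, 15L, 19L, 5L, 30L), C = c(0L, 0L, 1L, 3L, 0L),
    G = c(0L, 0L, 0L, 2L, 0L), T = c(0L, 15L, 0L, 0L, 0L))
  counts$depth <- counts$A + counts$C + counts$G + counts$T
  cls <- classify_sites(counts)
  expect_identical(cls$class, c("NA", "bi", "mono", "tri", "mono"))
  expect_equal(cls$freq1[2], 0.5)
  expect_equal(cls$freq2[2], 0.5)
  expect_identical(cls$alleles[2], "A/T")
  expect_identical(cls$alleles[4], "A/C/G")
  # purity: same counts, same classification
  expect_identical(classify_sites(counts)$class, cls$class)

  # a multi-allele site failing the quality filter falls back to mono
  weak <- data.frame(contig = "chr1", pos = 0L, A = 90L, C = 10L,
                     G = 0L, T = 0L, depth = 100L)
  expect_identical(classify_sites(weak, error_rate = 0.2)$class, "mono")
  expect_identical(classify_sites(weak, error_rate = 0.001)$class, "bi")
})

test_that("VCF ingestion filters QUAL, depth, frequency and indels", {
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"ref obs\">",
           "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t101\t.\tA\tG\t50\t.\tDP=30;RO=15;AO=15",
           "chr1\t201\t.\tA\tG\t29\t.\tDP=30;RO=15;AO=15",
           "chr1\t301\t.\tAT\tA\t50\t.\tDP=30;RO=15;AO=15",
           "chr1\t401\t.\tC\tT\t80\t.\tDP=40;RO=38;AO=2",
           "chr1\t501\t.\tC\tT\t80\t.\tDP=9;RO=5;AO=4")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  got <- ingest_vcf(f)
  expect_identical(got$pos, c(100L, 400L))       # QUAL<30, indel, depth<10 gone
  expect_identical(got$class, c("bi", "mono"))   # 2/40 = 0.05 < 0.1
  expect_identical(got$alleles[1], "A/G")
})

test_that("bi-allelic density arithmetic and sentinels", {
  regions <- data.frame(contig = "chr1", start = 0L, end = 60000L)
  calls <- data.frame(contig = "chr1", pos = 0:49999,
                      depth = 30L, class = "mono", stringsAsFactors = FALSE)
  calls$class[1:33] <- "bi"
  d <- biallelic_density(calls, regions, coding_only = FALSE)
  expect_equal(d$density_per_kb, 0.66)   # 33 bi / 50,000 covered
  expect_identical(d$n_biallelic, 33L)

  none <- biallelic_density(calls[0, ], regions, coding_only = FALSE)
  expect_true(is.na(none$density_per_kb))   # undefined, not zero

  zero <- calls; zero$class <- "mono"
  expect_equal(biallelic_density(zero, regions,
                                 coding_only = FALSE)$density_per_kb, 0)
})

test_that("density recovers the planted coding SNP density", {
  st <- het_study()
  truth <- st$truth
  d <- biallelic_density(st$calls, data.frame(contig = "chr1", start = 0L,
                                              end = st$cfg$genome_length),
                         mask = truth$repeats, coding = truth$gene_models)
  coding_len <- sum(truth$gene_models$end - truth$gene_models$start)
  planted <- 1000 * sum(truth$snp_table$in_coding & !truth$snp_table$in_repeat) /
    coding_len
  expect_lt(abs(d$density_per_kb - planted) / planted, 0.15)
})

test_that("allele-frequency distribution: fixed values, subset property", {
  calls <- data.frame(contig = "chr1", pos = 0:99, depth = rep(c(20L, 60L), 50),
                      class = "bi", freq1 = 0.5, freq2 = 0.5,
                      stringsAsFactors = FALSE)
  fd <- frequency_distribution(calls, 10)
  expect_true(all(fd$values == 0.5))
  expect_equal(fd$modal_bin, 0.505)   # bin [0.50, 0.51)

  # raising the threshold never adds values
  sizes <- vapply(c(10, 20, 40, 60), function(th) {
    length(frequency_distribution(calls, th)$values)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # seeded: same seed, same random allele choice
  calls$freq1 <- runif(100); calls$freq2 <- 1 - calls$freq1
  expect_identical(frequency_distribution(calls, 10, seed = 4)$values,
                   frequency_distribution(calls, 10, seed = 4)$values)
})

test_that("heterokaryon p=0.5 gives a modal frequency bin near 0.5", {
  st <- het_study()
  fd <- frequency_distribution(st$calls, 10, seed = 1)
  expect_true(fd$modal_bin >= 0.45 && fd$modal_bin <= 0.55)
})

test_that("region coverage uses mean depth over the full region width", {
  regions <- data.frame(contig = "chr1", start = c(0L, 100L),
                        end = c(100L, 200L))
  depths <- data.frame(contig = "chr1", pos = 0:199, depth = 30L)
  rc <- region_coverage(depths, regions)
  expect_equal(rc$fraction, 1.0)
  # mean 9.9 is not covered ("greater, or equal to, 10")
  depths$depth <- c(rep(9L, 90), rep(18L, 10), rep(30L, 100))
  rc2 <- region_coverage(depths, regions)   # region 1 mean = 9.9
  expect_equal(rc2$mean_depth[1], 9.9)
  expect_identical(rc2$n_covered, 1L)
})

test_that("ddRAD coverage marks only fragment-overlapping regions as covered", {
  st <- het_study()
  frag <- predict_fragments(st$truth$haplotype1)
  rad <- simulate_ddrad_reads(st$truth, frag)
  depths <- pileup_allele_counts(rad$alignments, st$truth$haplotype1)
  # regions away from any fragment must not be covered
  gr_f <- GenomicRanges::GRanges(frag$contig,
                                 IRanges::IRanges(frag$start + 1L, frag$end))
  probe <- data.frame(contig = "chr1",
                      start = seq(0L, st$cfg$genome_length - 500L, by = 4000L))
  probe$end <- probe$start + 400L
  gr_p <- GenomicRanges::GRanges(probe$contig,
                                 IRanges::IRanges(probe$start + 1L, probe$end))
  off <- !IRanges::overlapsAny(gr_p, gr_f)
  rc <- region_coverage(depths, probe)
  expect_true(all(rc$mean_depth[off] == 0))
})

test_that("problematic regions flag N runs and depth spikes", {
  g <- c(chr1 = paste0(random_seq(4999, seed = 91), "NNN",
                       random_seq(5198, seed = 92)))
  depths <- data.frame(contig = "chr1", pos = 0:10199, depth = 30L)
  fl <- flag_problematic_regions(depths, g)
  expect_identical(nrow(fl), 1L)
  expect_identical(fl$start, 4899L)
  expect_identical(fl$end, 5102L)   # [N run - window, N run end + window)

  # constant depth, N-free genome: nothing flagged
  g0 <- c(chr1 = random_seq(10000, seed = 93))
  expect_identical(nrow(flag_problematic_regions(depths, g0)), 0L)

  # a collapsed 3-copy repeat shows ~3x local depth and is flagged
  depths2 <- depths
  depths2$depth[3001:3400] <- 90L
  fl2 <- flag_problematic_regions(depths2, g0)
  expect_true(any(fl2$start <= 3000 & fl2$end >= 3400))
})
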