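# Sequencing-based quantification: k-mer read classification, profiles,
# enrichment domains, uncut sites, length proxy, coverage table.

test_that("k-mer positive read counting applies the >=2-window rule", {
  ks <- kmer_set(kmers = c("ACGTACGTACGTACGTAC", "TTTTGGGGCCCCAAAATT"), k = 18)
  # two distinct set k-mers at disjoint positions -> positive
  r_pos <- paste0("ACGTACGTACGTACGTAC", "GGGGG", "TTTTGGGGCCCCAAAATT")
  # exactly one matching window -> negative at min_hits = 2
  r_one <- paste0("ACGTACGTACGTACGTAC", strrep("G", 30))
  res <- count_kmer_positive_reads(c(r_pos, r_one), ks, min_hits = 2)
  expect_equal(res$n_positive, 1L)
  expect_equal(res$n_total, 2L)
  # a repeated k-mer counts per window by default, once under distinct=TRUE
  r_rep <- paste0("ACGTACGTACGTACGTAC", strrep("G", 10), "ACGTACGTACGTACGTAC")
  expect_equal(count_kmer_positive_reads(r_rep, ks)$n_positive, 1L)
  expect_equal(count_kmer_positive_reads(r_rep, ks, distinct = TRUE)$n_positive, 0L)
  # reads shorter than k count in the total, never positive
  res2 <- count_kmer_positive_reads(c("ACGT", r_pos), ks)
  expect_equal(res2$n_total, 2L)
  expect_equal(res2$n_positive, 1L)
  # N windows never match
  r_n <- paste0("ACGTACGTACGTACGTAC", "N", "ACGTACGTACGTACGTAC")
  expect_equal(count_kmer_positive_reads(r_n, ks)$n_positive, 1L)  # 2 clean windows
})

test_that("k-mer counting and set construction are strand-invariant", {
  set.seed(5)
  mono <- random_dna(171)
  ks <- kmer_set(monomers = mono, k = 18)
  reads <- vapply(1:40, function(i) {
    if (i <= 25) { s <- sample(100, 1); substring(paste0(mono, mono), s, s + 99) }
    else random_dna(100)
  }, "")
  fwd <- count_kmer_positive_reads(reads, ks)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  rev <- count_kmer_positive_reads(rc, ks)
  expect_equal(fwd$n_positive, rev$n_positive)
  expect_equal(fwd$n_total, rev$n_total)
  expect_equal(fwd$n_positive, 25L)
})

test_that("10 synthetic reads with 4 positives give fraction 0.4", {
  ks <- kmer_set(kmers = c("ACGTACGTACGTACGTAC", "TTTTGGGGCCCCAAAATT"), k = 18)
  pos <- paste0("ACGTACGTACGTACGTAC", "AA", "TTTTGGGGCCCCAAAATT")
  neg <- strrep("GA", 25)
  res <- count_kmer_positive_reads(c(rep(pos, 4), rep(neg, 6)), ks)
  expect_equal(res$fraction, 0.4)
})

test_that("log2 profile: identity, 32-fold bin, zero bins, errors", {
  s <- binned_counts("chr1", c(0, 2000, 4000), c(10, 20, 30))
  expect_true(all(binned_log2_profile(s, s)$log2_ratio == 0))
  # one bin 32x the reference with totals equalized elsewhere
  r2 <- binned_counts("chr1", c(0, 2000, 4000, 6000), c(1, 100, 131, 0))
  s2 <- binned_counts("chr1", c(0, 2000, 4000, 6000), c(32, 100, 100, 0))
  pr <- binned_log2_profile(s2, r2, pseudocount = 1e-9)
  expect_equal(pr$log2_ratio[pr$bin_start == 0], 5, tolerance = 0.01)
  # both-zero bin -> exactly 0
  expect_equal(pr$log2_ratio[pr$bin_start == 6000], 0)
  # missing bins in one input are zeros
  short <- binned_counts("chr1", 0, 10)
  pr2 <- binned_log2_profile(short, s)
  expect_equal(nrow(pr2), 3L)
  expect_error(binned_log2_profile(s, binned_counts("chr1", 0, 5, bin_width = 1000)),
               "bin_width")
})

test_that("domain calling: thresholds strict, gaps, min_bins, mirroring", {
  prof <- function(folds, chrom = "chr1") {
    structure(data.frame(chrom = chrom,
                         bin_start = 2000 * (seq_along(folds) - 1),
                         fold = folds),
              bin_width = 2000)
  }
  # all above threshold -> one domain spanning everything
  d <- call_domains(prof(rep(6, 5)))
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(0, 10000))
  # folds [6,6,1,6]: two domains at gap 0, one at gap 1
  d2 <- call_domains(prof(c(6, 6, 1, 6)))
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$start, c(0, 6000))
  d3 <- call_domains(prof(c(6, 6, 1, 6)), max_gap_bins = 1)
  expect_equal(nrow(d3), 1L)
  expect_equal(c(d3$start, d3$end), c(0, 8000))
  # strictly greater than: all folds == 5 -> nothing
  expect_equal(nrow(call_domains(prof(rep(5, 4)))), 0L)
  expect_equal(nrow(call_domains(prof(c(6, 6, 1, 6)), min_bins = 3)), 0L)
  # reversing bin order mirrors the domains
  folds <- c(1, 6, 6, 1, 6, 1)
  fwd <- call_domains(prof(folds))
  rev <- call_domains(prof(rev(folds)))
  n <- length(folds) * 2000
  expect_equal(sort(n - rev$end), sort(fwd$start))
  expect_equal(sort(n - rev$start), sort(fwd$end))
})

test_that("domain coverage of labeled regions", {
  regions <- region_set(rep("chr1", 2), c(0, 10000), c(4000, 14000),
                        label = c("cen_region", "HOR"))
  doms <- data.frame(chrom = "chr1", start = c(1000, 10000), end = c(2000, 14000))
  cov <- domain_region_coverage(doms, regions)
  expect_equal(cov$proportion, c(0.25, 1.0))
  expect_equal(cov$covered_bp, c(1000, 4000))
  none <- domain_region_coverage(doms[0, , drop = FALSE], regions)
  expect_equal(none$covered_bp, c(0, 0))
  only_hor <- domain_region_coverage(doms, regions, label = "HOR")
  expect_equal(nrow(only_hor), 1L)
})

test_that("uncut site fraction counts overlapping occurrences in reads", {
  # reference read with overlapping ScrFI candidates: CCCGG + CCGGG overlap,
  # both counted (reads are observations, no greedy rule)
  ref <- c("AAACCCGGGAAA", "CCAGGTTCCTGG")  # 2 + 2 occurrences of CCNGG
  expect_equal(nrow(compile_pattern_hits("CCNGG", "AAACCCGGGAAA")), 2L)
  samp_same <- ref
  res <- uncut_site_fraction(samp_same, ref, "ScrFI")
  expect_equal(res$pct_of_reference, c(100, 100))
  # engineered site-free sample -> 0%
  res0 <- uncut_site_fraction(c("ATATATATAT", "TTTTTTTT"), ref, "ScrFI")
  expect_equal(res0$pct_of_reference, c(0, 0))
  # 40 reference vs 6 sample occurrences -> 15%
  ref40 <- rep("AACCAGGAA", 40)
  smp6 <- c(rep("AACCAGGAA", 6), rep("AAAAAAAAA", 34))
  res15 <- uncut_site_fraction(smp6, ref40, "ScrFI")
  expect_equal(res15$pct_of_reference, c(15, 15))
  # zero reference occurrences -> undefined (NA), not infinity
  resna <- uncut_site_fraction(ref, c("ATATAT"), "ScrFI")
  expect_true(all(is.na(resna$pct_of_reference)))
})

test_that("length-proxy percent change between conditions", {
  a <- c(cen1 = 100, cen2 = 150, cen3 = 120, cen4 = 10)
  b <- c(cen1 = 100, cen2 = 100, cen3 = 160, cen4 = 0, cen5 = 5)
  lc <- length_change(a, b)
  expect_equal(lc$pct_change[lc$region == "cen1"], 0)
  expect_equal(lc$pct_change[lc$region == "cen2"], 50)
  expect_equal(lc$pct_change[lc$region == "cen3"], -25)
  expect_true(is.na(lc$pct_change[lc$region == "cen4"]))
  expect_false("cen5" %in% lc$region)
})

test_that("coverage threshold table is non-increasing and correct", {
  expect_equal(coverage_threshold_table(rep(20, 8), c(1, 10))$pct_bins, c(100, 100))
  expect_equal(coverage_threshold_table(c(0, 5, 15, 25), 10)$pct_bins, 50)
  expect_equal(coverage_threshold_table(c(0, 5, 15, 25), 0)$pct_bins, 100)
  set.seed(9)
  cov <- rpois(200, 12)
  tab <- coverage_threshold_table(cov, c(0, 1, 5, 10, 20, 30))
  expect_true(all(diff(tab$pct_bins) <= 0))
})
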