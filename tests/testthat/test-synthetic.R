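# Synthetic-data generators: determinism, truth records, recovery.

test_that("monomer generation is site-free, deterministic, right length", {
  m <- make_monomer(171, forbidden_enzymes = "BstUI", seed = 4)
  expect_equal(nchar(m), 171L)
  expect_equal(nrow(find_sites(paste0(m, m), digestion_plan("BstUI"))), 0L)
  expect_identical(make_monomer(171, forbidden_enzymes = "BstUI", seed = 4), m)
  expect_false(identical(make_monomer(171, forbidden_enzymes = "BstUI", seed = 5), m))
  expect_error(make_monomer(2000, gc = 0.5,
                            forbidden_enzymes = enzyme_panel("AT", "AT"),
                            seed = 1, max_attempts = 3),
               "attempts")
})

test_that("toy genomes satisfy their own truth records", {
  spec <- toy_genome_spec(monomer_length = 171, hor_unit = 4, array_copies = 50,
                          background_length = 307800, seed = 2)
  toy <- make_toy_genome(spec)
  expect_equal(toy$truth$target_fraction, 0.10)
  expect_equal(toy$truth$genome_bp, sum(width(toy$genome)))
  # target fraction recomputable exactly from genome + regions
  expect_equal(baseline_fraction(toy$genome, toy$regions),
               toy$truth$target_fraction)
  # arrays are site-free for the forbidden enzymes
  plan <- digestion_plan(spec$forbidden_enzymes)
  for (p in region_sequences(toy$genome, toy$regions))
    expect_equal(nrow(find_sites(p$sequence, plan)), 0L)
  # background carries sites at roughly the requested spacing
  comp <- region_complement(toy$genome, toy$regions)
  bg <- region_sequences(toy$genome, comp)
  n_sites <- sum(vapply(bg, function(p) nrow(find_sites(p$sequence, plan)), 0L))
  expect_gt(n_sites, 0.8 * 307800 / 500)
  # determinism
  toy2 <- make_toy_genome(spec)
  expect_identical(as.character(toy$genome), as.character(toy2$genome))
})

test_that("divergence 0 gives identical monomers; divergence stays site-free", {
  spec0 <- toy_genome_spec(hor_unit = 1, array_copies = 10,
                           background_length = 2000, seed = 3)
  toy <- make_toy_genome(spec0)
  arr <- as.character(region_sequences(toy$genome, toy$regions)[[1]]$sequence)
  monos <- substring(arr, seq(1, nchar(arr), 171), seq(171, nchar(arr), 171))
  expect_equal(length(unique(monos)), 1L)
  specd <- toy_genome_spec(hor_unit = 1, array_copies = 10,
                           background_length = 2000,
                           divergence_rate = 0.02, seed = 3)
  toyd <- make_toy_genome(specd)
  arrd <- region_sequences(toyd$genome, toyd$regions)[[1]]$sequence
  expect_equal(nrow(find_sites(arrd, digestion_plan(specd$forbidden_enzymes))), 0L)
})

test_that("size-selected read simulation: eligibility, substrings, determinism", {
  frags <- Biostrings::DNAStringSet(c(big = strrep("ACGT", 2500),
                                      small = strrep("TTTT", 100)))
  expect_error(simulate_size_selected_reads(frags, min_length = 1e6,
                                            n_reads = 10, read_length = 50),
               "size selection")
  reads <- simulate_size_selected_reads(frags, min_length = 5000, n_reads = 20,
                                        read_length = 50, seed = 6)
  expect_equal(length(reads), 20L)
  expect_true(all(width(reads) == 50))
  # single eligible fragment: every read is a substring of it
  for (r in as.character(reads))
    expect_true(grepl(r, strrep("ACGT", 2500), fixed = TRUE))
  reads2 <- simulate_size_selected_reads(frags, min_length = 5000, n_reads = 20,
                                         read_length = 50, seed = 6)
  expect_identical(as.character(reads), as.character(reads2))
  # FASTQ output round-trips through the standard reader
  path <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(reads, path)
  back <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_equal(as.character(back), as.character(reads), ignore_attr = TRUE)
})

test_that("read origin follows fragment bp share (law of large numbers)", {
  set.seed(8)
  frags <- Biostrings::DNAStringSet(c(target = random_dna(30000),
                                      background = random_dna(10000)))
  reads <- simulate_size_selected_reads(frags, min_length = 5000,
                                        n_reads = 10000, read_length = 100,
                                        seed = 8)
  frac <- mean(attr(reads, "source_label") == "target")
  # 99% binomial CI around 0.75
  expect_lt(abs(frac - 0.75), 2.576 * sqrt(0.75 * 0.25 / 10000))
})

test_that("methylation simulation recovers its own family effects", {
  regions <- region_set(rep("chr1", 2), c(0, 3e6), c(1e6, 4e6),
                        label = c("alpha_sat", "HSATII"))
  sim <- simulate_methylation(regions, coverage = 30, n_sites = 4000, seed = 15)
  expect_equal(nrow(sim$wt), nrow(sim$ko))
  expect_true(all(sim$wt$n_meth <= sim$wt$n_valid))
  # determinism
  sim2 <- simulate_methylation(regions, coverage = 30, n_sites = 4000, seed = 15)
  expect_identical(sim$wt, sim2$wt)
  # zero drop -> classify_changes essentially all unchanged at high coverage
  fp0 <- list(alpha_sat = list(mean_wt = 70, relative_drop = 0, dispersion = 50),
              HSATII = list(mean_wt = 70, relative_drop = 0, dispersion = 50))
  sim0 <- simulate_methylation(regions, fp0, coverage = 200, n_sites = 1000, seed = 16)
  cc0 <- classify_changes(sim0$wt, sim0$ko)
  prop_unchanged <- cc0$summary$proportion[cc0$summary$class == "unchanged"]
  expect_gt(prop_unchanged, 0.95)
  # full drop from high WT -> nearly all non-excluded sites decreased
  fp1 <- list(alpha_sat = list(mean_wt = 80, relative_drop = 1, dispersion = 50),
              HSATII = list(mean_wt = 80, relative_drop = 1, dispersion = 50))
  sim1 <- simulate_methylation(regions, fp1, coverage = 200, n_sites = 1000, seed = 17)
  cc1 <- classify_changes(sim1$wt, sim1$ko)
  prop_dec <- cc1$summary$proportion[cc1$summary$class == "decreased"]
  expect_gt(prop_dec, 0.99)
})
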