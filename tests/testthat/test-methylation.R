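# Per-CpG methylation frequency, change classification, family aggregation,
# dip-region detection.

test_that("site frequency definition and guards", {
  expect_equal(site_frequency(5, 10), 50)
  expect_equal(site_frequency(0, 7), 0)
  expect_equal(site_frequency(7, 7), 100)
  expect_true(is.na(site_frequency(0, 0)))
  expect_error(site_frequency(8, 7), "exceed")
  expect_error(site_frequency(-1, 7))
})

test_that("change classification applies the strict threshold rules", {
  wt <- meth_sites("chr1", c(100, 200, 300, 400, 500),
                   n_valid = c(20, 9, 20, 20, 20),
                   n_meth = c(10, 5, 6, 10, 10))   # freqs 50, 55.6, 30, 50, 50
  ko <- meth_sites("chr1", c(100, 200, 300, 400, 500),
                   n_valid = c(20, 20, 20, 20, 20),
                   n_meth = c(9, 10, 2, 15, 5))    # freqs 45, 50, 10, 75, 25
  cc <- classify_changes(wt, ko)
  cls <- setNames(as.character(cc$sites$class), cc$sites$pos)
  expect_equal(cls[["100"]], "unchanged")   # |delta| = 5 <= 10
  expect_equal(cls[["200"]], "excluded")    # coverage 9, strict > 10
  expect_equal(cls[["300"]], "excluded")    # WT freq 30, strict > 40
  expect_equal(cls[["400"]], "increased")   # +25
  expect_equal(cls[["500"]], "decreased")   # -25
  # boundary: delta exactly +-10 and coverage exactly 10 / freq exactly 40
  wt2 <- meth_sites("chr1", c(1, 2, 3, 4), c(20, 20, 10, 20), c(10, 10, 9, 8))
  ko2 <- meth_sites("chr1", c(1, 2, 3, 4), c(20, 20, 20, 20), c(12, 8, 9, 8))
  cc2 <- classify_changes(wt2, ko2)
  cls2 <- as.character(cc2$sites$class)
  expect_equal(cls2[1], "unchanged")  # delta exactly +10
  expect_equal(cls2[2], "unchanged")  # delta exactly -10
  expect_equal(cls2[3], "excluded")   # coverage exactly 10
  expect_equal(cls2[4], "excluded")   # WT freq exactly 40
})

test_that("classification partitions the joined set; WT vs WT is unchanged", {
  set.seed(77)
  n <- 400
  pos <- sort(sample(1e6, n))
  nv <- rpois(n, 25) + 1
  wt <- meth_sites("chr1", pos, nv, rbinom(n, nv, 0.6))
  nv2 <- rpois(n, 25) + 1
  ko <- meth_sites("chr1", pos[1:300], nv2[1:300], rbinom(300, nv2[1:300], 0.4))
  cc <- classify_changes(wt, ko)
  expect_equal(cc$n_joined, 300L)
  expect_equal(sum(cc$summary$count), cc$n_joined)  # exact partition
  expect_equal(nlevels(cc$sites$class), 4L)
  # (WT, WT): every non-excluded site unchanged
  self <- classify_changes(wt, wt)
  expect_equal(sum(self$summary$count), self$n_joined)
  expect_equal(self$summary$proportion[self$summary$class == "unchanged"], 1)
  expect_equal(self$summary$count[self$summary$class == "increased"], 0L)
  expect_equal(self$summary$count[self$summary$class == "decreased"], 0L)
})

test_that("family aggregation: per-family and overall means, other label", {
  regions <- region_set(rep("chr1", 2), c(0, 1000), c(500, 1500),
                        label = c("alpha_sat", "HSATII"))
  sites <- meth_sites("chr1",
                      c(10, 20, 1100, 1200, 5000, 5001),
                      n_valid = rep(10, 6),
                      n_meth = c(8, 8, 2, 2, 5, 5))
  agg <- aggregate_by_family(sites, regions)
  get <- function(f) agg$mean_freq[agg$family == f]
  expect_equal(get("alpha_sat"), 80)
  expect_equal(get("HSATII"), 20)
  expect_equal(get("other"), 50)
  # equal site counts in two families with means 80 and 20 -> overall 50
  expect_equal(get("overall"), mean(c(80, 80, 20, 20, 50, 50)))
  # empty family absent from the output
  expect_false("HOR" %in% agg$family)
  # all sites one family, one frequency
  one <- aggregate_by_family(meth_sites("chr1", 1:5, 10, 5), regions[0])
  expect_equal(one$mean_freq[one$family == "other"], 50)
})

test_that("dip-region detection needs low runs with high flanks", {
  # uniformly high track: no dips
  pos <- seq(0, 2e5, by = 100)
  high <- find_dip_regions(pos, rep(90, length(pos)),
                           window_bp = 10000, low_threshold = 50,
                           min_len_bp = 20000)
  expect_equal(nrow(high), 0L)
  # uniformly low track: no dips (no high flanks)
  low <- find_dip_regions(pos, rep(10, length(pos)),
                          window_bp = 10000, low_threshold = 50,
                          min_len_bp = 20000)
  expect_equal(nrow(low), 0L)
  # engineered plateau of twice min_len is recovered
  freqs <- ifelse(pos >= 80000 & pos < 120000, 10, 90)
  dips <- find_dip_regions(pos, freqs, window_bp = 10000,
                           low_threshold = 50, min_len_bp = 20000)
  expect_equal(nrow(dips), 1L)
  # the dip interval contains the engineered plateau core
  expect_lte(dips$start, 85000)
  expect_gte(dips$end, 115000)
  expect_lt(dips$mean_freq, 50)
  # plateau shorter than min_len is rejected
  freqs2 <- ifelse(pos >= 80000 & pos < 88000, 10, 90)
  expect_equal(nrow(find_dip_regions(pos, freqs2, window_bp = 4000,
                                     low_threshold = 50, min_len_bp = 20000)), 0L)
})

test_that("methylation table TSV round trip", {
  tab <- meth_sites("chr1", c(5, 9), c(12, 30), c(6, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_meth_table(tab, path)
  back <- read_meth_table(path)
  expect_equal(back$freq, c(50, 0))
  expect_equal(back$pos, c(5, 9))
  writeLines("chrom\tpos\tbad", path)
  expect_error(read_meth_table(path), "n_valid")
})
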