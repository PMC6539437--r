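test_that("quality/depth filtering is inclusive, both-pool, order-preserving", {
  rec <- tibble::tibble(
    chrom = "c", pos = 1:4, ref = "G", alt = "A",
    qual = c(99, 100, 228, 228),
    ref_a = c(25, 5, 5, 40), alt_a = c(25, 5, 4, 0),
    ref_b = c(25, 5, 50, 30), alt_b = c(25, 5, 50, 6)
  )
  kept <- filter_snps(rec, scan_config())
  # qual 99 out; qual 100 with depths exactly 10/10 in; depth 9 in pool A out
  expect_equal(kept$pos, c(2, 4))
  # brute-force re-count on a random fixture
  rnd <- random_records(1000, seed = 13)
  kept <- filter_snps(rnd, scan_config())
  manual <- rnd[rnd$qual >= 100 & rnd$ref_a + rnd$alt_a >= 10 &
                  rnd$ref_b + rnd$alt_b >= 10, ]
  expect_identical(kept, manual)
})

test_that("SNP-index and delta arithmetic", {
  expect_equal(snp_index(10, 0), 0)
  expect_equal(snp_index(0, 12), 1)
  expect_equal(snp_index(7, 3), 0.3)
  expect_error(snp_index(0, 0), "zero depth")
  expect_equal(delta_snp_index(1 / 3, 1), 2 / 3)
  expect_equal(delta_snp_index(0.5, 0.5), 0)
  expect_equal(delta_snp_index(1, 0), -1)
  # invariant: delta = index_b - index_a to machine precision
  stats <- compute_snp_stats(filter_snps(random_records(500, seed = 7)))
  expect_equal(stats$delta, stats$index_b - stats$index_a)
  expect_true(all(stats$fisher_p > 0 & stats$fisher_p <= 1))
})

test_that("Fisher exact p matches enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_p(10, 0, 0, 10),
               fisher_enum_oracle(10, 0, 0, 10))
  withr::with_seed(17, {
    for (i in 1:200) {
      tab <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
      if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
      p <- fisher_exact_p(tab[1], tab[2], tab[3], tab[4])
      expect_equal(p, fisher_enum_oracle(tab[1], tab[2], tab[3], tab[4]))
      ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(p, min(ft, 1), tolerance = 1e-10)
    }
  })
  expect_error(fisher_exact_p(0, 0, 0, 0), "all-zero")
})

test_that("sliding windows anchor at bp 1 with half-open spans", {
  mk <- function(pos, delta = 0.5) {
    tibble::tibble(
      chrom = "c", pos = pos, depth_a = 30, depth_b = 30,
      index_a = 0.25, index_b = 0.75, delta = delta, fisher_p = 0.5,
      ci_lower = -0.4, ci_upper = 0.4
    )
  }
  cfg <- scan_config()
  # membership: first window [1, 2e6) holds 10 kb and 60 kb, not 2010 kb
  w <- sliding_windows(mk(c(1e4, 6e4, 2.01e6)), cfg,
                       chrom_lengths = c(c = 3e6))
  expect_equal(w$n_snps[1], 2L)
  expect_equal(w$start[2], 50001)
  # constant field: every non-empty window mean equals it
  expect_true(all(w$mean_delta[w$n_snps > 0] == 0.5))
  expect_true(all(is.na(w$mean_delta[w$n_snps == 0])))
  # window count formula vs brute force on a 1 Mb toy
  w1 <- sliding_windows(mk(5e5), cfg, chrom_lengths = c(c = 1e6))
  expect_equal(nrow(w1), (1e6 - 1) %/% 5e4 + 1)
  brute <- sum(vapply(seq(1, 1e6, by = 5e4), function(s) s <= 1e6, logical(1)))
  expect_equal(nrow(w1), brute)
  # terminal windows truncate at the chromosome end
  expect_equal(max(w1$end), 1e6)
  expect_error(sliding_windows(mk(c(2e6, 1e6)), cfg), "sorted")
})

test_that("null band straddles zero, narrows with depth, vanishes in the limit", {
  cfg <- scan_config(seed = 5)
  ci <- null_delta_ci(c(10, 80), c(10, 80), cfg)
  expect_true(all(ci$ci_lower <= 0 & ci$ci_upper >= 0))
  expect_true(all(abs(ci$ci_lower) <= 1 & abs(ci$ci_upper) <= 1))
  width <- ci$ci_upper - ci$ci_lower
  expect_lt(width[2], width[1]) # depth 80 narrower than depth 10
  big <- null_delta_ci(10000, 10000,
                       scan_config(bulk_chromosomes = 10000, seed = 5))
  expect_lt(big$ci_upper - big$ci_lower, 0.1)
  expect_error(scan_config(n_reps = 500), "n_reps")
  # memoisation: repeated depths get identical bounds
  ci2 <- null_delta_ci(c(10, 10, 80), c(10, 10, 80), cfg)
  expect_identical(ci2[1, ], ci2[2, ])
})

test_that("candidate-region calling merges adjacent significant windows and ranks by peak", {
  w <- tibble::tibble(
    chrom = "c",
    start = c(1, 50001, 100001, 150001),
    end = c(2e6, 2050000, 2100000, 2150000),
    n_snps = c(5L, 5L, 0L, 5L),
    mean_index_a = 0.3, mean_index_b = 0.9,
    mean_delta = c(0.6, 0.7, NA, 0.5),
    mean_p = c(0.01, 0.01, NA, 0.2),
    ci_lower = -0.35, ci_upper = 0.35
  )
  cfg <- scan_config()
  regions <- call_candidate_regions(w, cfg)
  # window 3 empty, window 4 fails the p criterion: windows 1-2 merge
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, 1)
  expect_equal(regions$end, 2050000)
  expect_equal(regions$peak_delta, 0.7)
  # null scan: delta 0 everywhere -> no regions
  w0 <- dplyr::mutate(w, mean_delta = 0, mean_p = 0.5)
  expect_equal(nrow(call_candidate_regions(w0, cfg)), 0)
  # two chromosomes do not merge
  w2 <- dplyr::mutate(w[c(1, 2), ], chrom = c("c1", "c2"))
  expect_equal(nrow(call_candidate_regions(w2, cfg)), 2)
})

test_that("a full scan recovers the planted locus as a single region", {
  cfg <- cross_config(seed = 101)
  sim <- simulate_cross(cfg)
  scan <- mutmap_scan(sim$records, scan_config(seed = 101),
                      chrom_lengths = cfg$chrom_lengths)
  expect_equal(nrow(scan$regions), 1)
  expect_equal(scan$regions$chrom, cfg$causal_chrom)
  expect_lte(scan$regions$start, cfg$causal_pos)
  expect_gte(scan$regions$end, cfg$causal_pos)
  g <- glance(scan)
  expect_equal(g$n_regions, 1L)
  expect_lte(g$n_kept, g$n_input)
  expect_s3_class(tidy(scan), "tbl_df")
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
  # determinism of the whole scan
  scan2 <- mutmap_scan(sim$records, scan_config(seed = 101),
                       chrom_lengths = cfg$chrom_lengths)
  expect_identical(scan$windows, scan2$windows)
  # outputs
  dir <- withr::local_tempdir()
  paths <- write_scan(scan, dir)
  expect_true(all(file.exists(paths)))
  bed <- read.delim(paths[["bed"]], header = FALSE)
  expect_equal(bed$V2[1], scan$regions$start[1] - 1) # 0-based BED start
})
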