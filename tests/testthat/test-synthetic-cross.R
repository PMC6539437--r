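test_that("founder SNP draw matches its Poisson intensity and always carries the causal site", {
  cfg <- cross_config(seed = 11) # 100 Mb at 5 SNPs/Mb -> expect ~500
  counts <- vapply(1:5, function(s) {
    snps <- simulate_parent_snps(cross_config(seed = s))
    expect_true(any(snps$causal &
                      snps$chrom == cfg$causal_chrom &
                      snps$pos == cfg$causal_pos))
    expect_false(any(duplicated(snps[c("chrom", "pos")])))
    expect_true(all(diff(snps$pos[snps$chrom == "chr01"]) > 0))
    nrow(snps)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 500), 4 * sqrt(500))
  # EMS spectrum: G->A and C->T only
  snps <- simulate_parent_snps(cfg)
  expect_true(all(paste0(snps$ref, snps$alt) %in% c("GA", "CT")))
})

test_that("identical seeds give identical simulations", {
  a <- simulate_cross(small_cross(seed = 5))
  b <- simulate_cross(small_cross(seed = 5))
  expect_identical(a$records, b$records)
  expect_identical(a$pools, b$pools)
  c <- simulate_cross(small_cross(seed = 6))
  expect_false(identical(a$records, c$records))
})

test_that("F2 genotypes segregate 1:2:1 and phenotypes 3:1", {
  cfg <- cross_config(n_f2 = 800, seed = 21)
  pop <- simulate_f2(cfg)
  g <- drop(genotype_at(pop, "chr02", 25e6)) # unlinked locus
  cnt <- tabulate(g + 1L, nbins = 3)
  expect_gt(chisq.test(cnt, p = c(1, 2, 1) / 4)$p.value, 0.01)
  ph <- table(factor(pop$phenotype, levels = c("wild", "mutant")))
  expect_gt(chisq.test(as.numeric(ph), p = c(3, 1) / 4)$p.value, 0.01)
  # recessive penetrant phenotype: mutant iff homozygous at the causal locus
  expect_true(all((pop$phenotype == "mutant") == (pop$causal_genotype == 2L)))
})

test_that("recombination follows the Haldane map function", {
  cfg <- cross_config(n_f2 = 1500, seed = 31)
  pop <- simulate_f2(cfg)
  # loci 40 Mb apart at 2.5 cM/Mb = 100 cM -> r = 0.5 * (1 - exp(-2))
  g <- pop$gametes$chr01
  orig <- function(pos) {
    vapply(seq_along(g$starts), function(i) {
      (g$starts[i] + findInterval(pos, g$breaks[[i]])) %% 2L
    }, integer(1))
  }
  rec <- mean(orig(5e6) != orig(45e6))
  r_exp <- haldane_r(1)
  se <- sqrt(r_exp * (1 - r_exp) / (2 * cfg$n_f2))
  expect_lt(abs(rec - r_exp), 4 * se)
})

test_that("bulking selects by phenotype and fails loudly when a class is short", {
  cfg <- small_cross(seed = 41, n_f2 = 400)
  pop <- simulate_f2(cfg)
  pools <- build_bulks(pop, cfg)
  expect_length(pools$pool_a, 20)
  expect_length(pools$pool_b, 20)
  expect_true(all(pop$causal_genotype[pools$pool_b] == 2L))
  expect_true(all(pop$phenotype[pools$pool_a] == "wild"))
  # mutant-allele frequency among wild-phenotype bulks averages 1/3
  freqs <- vapply(1:12, function(s) {
    cfg_s <- small_cross(seed = s, n_f2 = 400)
    p <- simulate_f2(cfg_s)
    po <- build_bulks(p, cfg_s)
    mean(drop(genotype_at(p, "chrA", cfg_s$causal_pos))[po$pool_a]) / 2
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 1 / 3), 0.05)
  # forced shortage
  starved <- pop
  starved$phenotype[] <- "wild"
  expect_error(build_bulks(starved, cfg), "resimulate with larger n_f2")
  expect_error(cross_config(n_f2 = 60, bulk_size = 20), "n_f2")
})

test_that("pooled reads reflect true bulk allele frequencies", {
  cfg <- small_cross(seed = 51, error_rate = 0, n_f2 = 400)
  sim <- simulate_cross(cfg)
  causal <- dplyr::filter(sim$records, pos == cfg$causal_pos)
  # epsilon = 0 and every Pool B plant homozygous: all reads are alt
  expect_equal(causal$ref_b, 0L)
  expect_gt(causal$alt_b, 0)
  # no selection on a null cross: both pools average index ~0.5; bulk
  # frequencies are correlated along a chromosome, so average over seeds
  idx <- vapply(52:57, function(s) {
    null_sim <- simulate_cross(
      cross_config(chrom_lengths = c(chrA = 20e6), causal_chrom = "chrA",
                   causal_pos = 10e6, n_f2 = 400, error_rate = 0, seed = s),
      phenotype_blind = TRUE
    )
    r <- dplyr::filter(null_sim$records, ref_a + alt_a > 0,
                       ref_b + alt_b > 0)
    c(mean(r$alt_a / (r$ref_a + r$alt_a)), mean(r$alt_b / (r$ref_b + r$alt_b)))
  }, numeric(2))
  expect_lt(abs(mean(idx[1, ]) - 0.5), 0.08)
  expect_lt(abs(mean(idx[2, ]) - 0.5), 0.08)
  expect_equal(unique(sim$records$qual), cfg$quality)
})

test_that("marker genotyping of the recessive class behaves at the causal, unlinked and linked positions", {
  markers <- tibble::tibble(
    marker = c("m_causal", "m_unlinked", "m_linked"),
    chrom = c("chr01", "chr02", "chr01"),
    pos = c(30e6, 25e6, 38e6)
  )
  cfg <- cross_config(n_f2 = 800, markers = markers, seed = 61)
  pop <- simulate_f2(cfg)
  geno <- simulate_marker_genotypes(pop, cfg)
  at <- function(m) geno$genotype[geno$marker == m]
  expect_true(all(at("m_causal") == "B"))
  cnt <- table(factor(at("m_unlinked"), levels = c("A", "H", "B")))
  expect_gt(chisq.test(as.numeric(cnt), p = c(1, 2, 1) / 4)$p.value, 0.01)
  # linked marker 8 Mb = 20 cM away: r_hat near Haldane r(0.2)
  s <- count_recombinants(dplyr::filter(geno, marker == "m_linked"))
  r_exp <- haldane_r(0.2)
  se <- sqrt(r_exp * (1 - r_exp) / (2 * s$n_scored))
  expect_lt(abs(s$r_hat - r_exp), 4 * se)
  # missing rate thins calls
  cfg_m <- cross_config(n_f2 = 400, markers = markers, missing_rate = 0.2,
                        seed = 62)
  pop_m <- simulate_f2(cfg_m)
  geno_m <- simulate_marker_genotypes(pop_m, cfg_m)
  expect_gt(mean(is.na(geno_m$genotype)), 0.1)
})
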