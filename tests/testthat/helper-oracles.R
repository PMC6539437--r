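# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided Fisher p by explicit enumeration of all 2x2
# tables with the observed margins, using choose() directly (independent
# of the package's dhyper-based path).
fisher_enum_oracle <- function(ref_a, alt_a, ref_b, alt_b) {
  row_a <- ref_a + alt_a
  row_b <- ref_b + alt_b
  col_alt <- alt_a + alt_b
  tot <- row_a + row_b
  xs <- max(0, col_alt - row_b):min(row_a, col_alt)
  prob <- choose(row_a, xs) * choose(row_b, col_alt - xs) /
    choose(tot, col_alt)
  p_obs <- choose(row_a, alt_a) * choose(row_b, alt_b) / choose(tot, col_alt)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Haldane map function: recombination fraction at d Morgans.
haldane_r <- function(d_morgans) 0.5 * (1 - exp(-2 * d_morgans))

# A small single-chromosome cross for fast tests.
small_cross <- function(seed = 1, n_f2 = 200, ...) {
  cross_config(
    chrom_lengths = c(chrA = 20e6), causal_chrom = "chrA",
    causal_pos = 10e6, n_f2 = n_f2, seed = seed, ...
  )
}

# Random SNP record fixture with controllable quality/depth spread.
random_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      chrom = "chr01",
      pos = sort(sample.int(5e7, n)),
      ref = "G", alt = "A",
      qual = sample(c(50, 99, 100, 228), n, replace = TRUE),
      ref_a = rpois(n, 12), alt_a = rpois(n, 12),
      ref_b = rpois(n, 12), alt_b = rpois(n, 12)
    )
  })
}

# Marker summaries shaped like the soybean chromosome-04 panel, with a
# synthetic co-segregating marker inside the target interval.
gm04_marker_summaries <- function() {
  panel <- read_marker_panel()
  counts <- c(14L, 9L, 4L, 3L, 1L, 1L, 2L) # recombinants per panel marker
  s <- tibble::tibble(
    marker = panel$marker, chrom = panel$chrom, pos = panel$pos,
    n_scored = 197L, recombinants = counts
  )
  dplyr::bind_rows(
    s,
    tibble::tibble(marker = "synthetic_interior", chrom = "Gm04",
                   pos = 51060000, n_scored = 197L, recombinants = 0L)
  ) |>
    dplyr::arrange(pos) |>
    dplyr::mutate(r_hat = recombinants / (2 * n_scored))
}

read_marker_panel <- function() {
  readr::read_tsv(
    system.file("extdata", "ssr_markers_gm04.tsv", package = "mutmapr"),
    col_types = readr::cols()
  )
}

lm1_gff <- function() {
  system.file("extdata", "lm1_candidate_genes.gff3", package = "mutmapr")
}
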