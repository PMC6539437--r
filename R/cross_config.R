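#' Configuration of a simulated EMS-mutant x wild-type F2 cross
#'
#' Bundles every parameter of the forward simulation: the genome, the
#' recombination map, the causal locus, the mutation load, the population
#' and bulk sizes, the pooled-sequencing model, and the marker panel.
#' Defaults describe a desk-scale experiment: a two-chromosome 100-Mb
#' genome carrying ~500 EMS-induced SNPs, 400 F2 plants, bulks of 20
#' wild-type and 20 mutant plants sequenced to a mean depth of 30x.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param causal_chrom,causal_pos Chromosome and 1-based bp position of the
#'   recessive causal locus.
#' @param cm_per_mb Uniform recombination rate in cM per Mb (Haldane map,
#'   no interference).
#' @param snp_density Expected EMS SNPs per Mb on the mutant haplotype.
#' @param n_f2 Number of F2 plants to simulate.
#' @param bulk_size Plants per phenotypic bulk.
#' @param mean_depth Mean sequencing depth per SNP per pool (Poisson).
#' @param error_rate Per-read probability of reporting the wrong allele.
#' @param penetrance Probability that a homozygous-mutant plant expresses
#'   the mutant phenotype (1 = fully penetrant).
#' @param quality Constant call-quality score attached to every simulated
#'   SNP record (the analysis filter acts on it).
#' @param markers Optional marker panel: a data frame with columns
#'   `marker`, `chrom`, `pos` (bp). `NULL` for none.
#' @param missing_rate Probability a marker genotype call is missing.
#' @param seed Integer seed; every stochastic stage derives its stream
#'   from it, so equal seeds give byte-identical results.
#'
#' @return An object of class `cross_config` (a validated named list).
#' @examples
#' cfg <- cross_config(seed = 1)
#' cfg$chrom_lengths
#' @export
cross_config <- function(chrom_lengths = c(chr01 = 50e6, chr02 = 50e6),
                         causal_chrom = "chr01",
                         causal_pos = 30e6,
                         cm_per_mb = 2.5,
                         snp_density = 5,
                         n_f2 = 400,
                         bulk_size = 20,
                         mean_depth = 30,
                         error_rate = 0.003,
                         penetrance = 1,
                         quality = 228,
                         markers = NULL,
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- structure(
    list(
      chrom_lengths = chrom_lengths, causal_chrom = causal_chrom,
      causal_pos = causal_pos, cm_per_mb = cm_per_mb,
      snp_density = snp_density, n_f2 = n_f2, bulk_size = bulk_size,
      mean_depth = mean_depth, error_rate = error_rate,
      penetrance = penetrance, quality = quality, markers = markers,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "cross_config"
  )
  validate_cross_config(cfg)
}

validate_cross_config <- function(cfg) {
  cl <- cfg$chrom_lengths
  if (is.null(names(cl)) || any(!nzchar(names(cl))) || any(cl <= 0)) {
    abort("`chrom_lengths` must be a named vector of positive lengths.")
  }
  if (!cfg$causal_chrom %in% names(cl)) {
    abort(sprintf("causal chromosome '%s' is not in the genome.", cfg$causal_chrom))
  }
  if (cfg$causal_pos < 1 || cfg$causal_pos > cl[[cfg$causal_chrom]]) {
    abort("causal locus position lies outside its chromosome.")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5) {
    abort("`error_rate` must satisfy 0 <= error_rate < 0.5.")
  }
  if (cfg$mean_depth <= 0) abort("`mean_depth` must be positive.")
  if (cfg$snp_density <= 0) abort("`snp_density` must be positive.")
  if (cfg$penetrance < 0 || cfg$penetrance > 1) abort("`penetrance` must be in [0, 1].")
  if (cfg$bulk_size < 1) abort("`bulk_size` must be at least 1.")
  # bulks must be fillable in expectation under 3:1 segregation
  expected_mutant <- cfg$n_f2 * 0.25 * cfg$penetrance
  if (cfg$bulk_size > expected_mutant) {
    abort(paste0(
      "`bulk_size` exceeds the expected number of mutant-phenotype F2 ",
      "plants (n_f2/4); increase `n_f2`."
    ))
  }
  if (!is.null(cfg$markers)) {
    m <- cfg$markers
    need <- c("marker", "chrom", "pos")
    if (!all(need %in% names(m))) {
      abort("`markers` needs columns marker, chrom, pos.")
    }
    if (!all(m$chrom %in% names(cl))) abort("marker on unknown chromosome.")
    if (any(m$pos < 1 | m$pos > cl[m$chrom])) abort("marker position out of range.")
  }
  cfg
}

#' @export
print.cross_config <- function(x, ...) {
  cat("<cross_config>\n")
  cat("  genome: ", length(x$chrom_lengths), " chromosome(s), ",
      format(sum(x$chrom_lengths) / 1e6, digits = 4), " Mb total\n", sep = "")
  cat("  causal locus: ", x$causal_chrom, ":", format(x$causal_pos, big.mark = ","),
      "\n", sep = "")
  cat("  map: ", x$cm_per_mb, " cM/Mb (Haldane)\n", sep = "")
  cat("  EMS SNP density: ", x$snp_density, "/Mb; F2: ", x$n_f2,
      "; bulks: ", x$bulk_size, "+", x$bulk_size, "\n", sep = "")
  cat("  depth: ", x$mean_depth, "x; error: ", x$error_rate,
      "; seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic per-stage seed stream derived from the config seed.
stage_seed <- function(seed, stage) {
  offs <- c(snps = 1L, f2 = 2L, bulks = 3L, reads = 4L, markers = 5L,
            null = 6L, pheno = 7L)
  if (!stage %in% names(offs)) abort(paste0("unknown seed stage: ", stage))
  (as.integer(seed) + 97561L * offs[[stage]]) %% 2147483629L
}
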