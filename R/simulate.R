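#' Draw the EMS-induced SNP positions of the mutant founder
#'
#' SNP positions are a homogeneous Poisson point process at the configured
#' density along each chromosome; the causal locus is always included.
#' EMS overwhelmingly induces G:C -> A:T transitions, so reference alleles
#' are drawn from {G, C} with the corresponding transition as the mutant
#' allele.
#'
#' @param config A [cross_config()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `causal`,
#'   sorted by chromosome and position; positions are unique.
#' @examples
#' snps <- simulate_parent_snps(cross_config(seed = 1))
#' nrow(snps)
#' @export
simulate_parent_snps <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  withr::with_seed(stage_seed(config$seed, "snps"), {
    per_chrom <- purrr::imap(config$chrom_lengths, function(len, chrom) {
      n <- rpois(1, config$snp_density * len / 1e6)
      pos <- sort(unique(ceiling(runif(n) * len)))
      tibble(chrom = chrom, pos = pos)
    })
    snps <- bind_rows(per_chrom)
    causal <- tibble(chrom = config$causal_chrom, pos = config$causal_pos)
    snps <- bind_rows(snps, causal) %>%
      distinct(.data$chrom, .data$pos) %>%
      arrange(match(.data$chrom, names(config$chrom_lengths)), .data$pos)
    ref <- sample(c("G", "C"), nrow(snps), replace = TRUE)
    snps %>%
      mutate(
        ref = ref,
        alt = ifelse(ref == "G", "A", "T"),
        causal = .data$chrom == config$causal_chrom &
          .data$pos == config$causal_pos
      )
  })
}

#' Simulate an F2 population by meiosis with Haldane crossovers
#'
#' Each F2 plant is the union of two independent gametes of a uniformly
#' heterozygous F1. Per gamete and chromosome, the crossover count is
#' Poisson with mean equal to the genetic length in Morgans (uniform
#' cM/Mb map, no interference) and crossover positions are uniform in bp.
#' Phenotype is mutant iff the plant is homozygous for the mutant allele
#' at the causal locus (subject to `penetrance`).
#'
#' @param config A [cross_config()].
#' @return An object of class `f2_population` holding the gamete segment
#'   structure, per-plant causal genotypes and phenotypes.
#' @examples
#' pop <- simulate_f2(cross_config(n_f2 = 100, seed = 1))
#' table(pop$phenotype)
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  n_gam <- 2L * config$n_f2
  gametes <- withr::with_seed(stage_seed(config$seed, "f2"), {
    purrr::imap(config$chrom_lengths, function(len, chrom) {
      morgans <- len / 1e6 * config$cm_per_mb / 100
      n_xo <- rpois(n_gam, morgans)
      breaks <- purrr::map(n_xo, function(k) sort(runif(k) * len))
      starts <- sample(0:1, n_gam, replace = TRUE)
      list(starts = starts, breaks = breaks)
    })
  })
  pop <- structure(
    list(
      config = config, n_f2 = config$n_f2, gametes = gametes
    ),
    class = "f2_population"
  )
  g_causal <- drop(genotype_at(pop, config$causal_chrom, config$causal_pos))
  pheno <- withr::with_seed(stage_seed(config$seed, "pheno"), {
    expressed <- rbinom(config$n_f2, 1, config$penetrance) == 1
    ifelse(g_causal == 2L & expressed, "mutant", "wild")
  })
  pop$causal_genotype <- g_causal
  pop$phenotype <- pheno
  pop
}

#' @export
print.f2_population <- function(x, ...) {
  cat("<f2_population> ", x$n_f2, " plants; ",
      sum(x$phenotype == "mutant"), " mutant / ",
      sum(x$phenotype == "wild"), " wild phenotype\n", sep = "")
  invisible(x)
}

#' Mutant-allele dosage of every plant at given positions
#'
#' @param pop An [simulate_f2()] population.
#' @param chrom Chromosome name.
#' @param pos Vector of bp positions on that chromosome.
#' @return Integer matrix, `n_f2` rows by `length(pos)` columns, of
#'   mutant-allele dosages in {0, 1, 2}.
#' @export
genotype_at <- function(pop, chrom, pos) {
  g <- pop$gametes[[chrom]]
  if (is.null(g)) abort(paste0("no chromosome '", chrom, "' in population."))
  n_gam <- length(g$starts)
  origins <- vapply(seq_len(n_gam), function(i) {
    (g$starts[i] + findInterval(pos, g$breaks[[i]])) %% 2L
  }, integer(length(pos)))
  if (length(pos) == 1L) origins <- matrix(origins, nrow = 1L)
  # gametes 2i-1 and 2i form plant i
  odd <- origins[, seq(1L, n_gam, by = 2L), drop = FALSE]
  even <- origins[, seq(2L, n_gam, by = 2L), drop = FALSE]
  t(odd + even)
}

#' Select the wild-type and mutant phenotypic bulks
#'
#' Pool A is `bulk_size` wild-phenotype plants and Pool B `bulk_size`
#' mutant-phenotype plants, drawn uniformly at random under the config
#' seed. With `phenotype_blind = TRUE` both pools are drawn from the whole
#' population irrespective of phenotype — the no-selection null used to
#' check the scan's false-positive behaviour.
#'
#' @param pop An [simulate_f2()] population.
#' @param config The [cross_config()] used to build `pop`.
#' @param phenotype_blind Draw pools ignoring phenotype (default FALSE).
#' @return A list with integer plant-index vectors `pool_a` and `pool_b`.
#' @export
build_bulks <- function(pop, config, phenotype_blind = FALSE) {
  stopifnot(inherits(pop, "f2_population"))
  withr::with_seed(stage_seed(config$seed, "bulks"), {
    if (phenotype_blind) {
      idx <- sample(pop$n_f2, 2L * config$bulk_size)
      return(list(pool_a = sort(idx[seq_len(config$bulk_size)]),
                  pool_b = sort(idx[-seq_len(config$bulk_size)])))
    }
    wild <- which(pop$phenotype == "wild")
    mut <- which(pop$phenotype == "mutant")
    if (length(wild) < config$bulk_size || length(mut) < config$bulk_size) {
      abort(paste0(
        "not enough plants of each phenotype class to fill the bulks ",
        "(", length(wild), " wild, ", length(mut), " mutant; need ",
        config$bulk_size, " each): resimulate with larger n_f2."
      ))
    }
    list(pool_a = sort(sample(wild, config$bulk_size)),
         pool_b = sort(sample(mut, config$bulk_size)))
  })
}

#' Simulate pooled short-read allele counts at every SNP
#'
#' Per SNP and pool, read depth is Poisson(`mean_depth`); each read
#' reports the mutant allele with probability `q(1-e) + (1-q)e`, where
#' `q` is the true mutant-allele frequency over the pool's `2*bulk_size`
#' chromosomes and `e` the per-read error rate.
#'
#' @param pop An [simulate_f2()] population.
#' @param pools Bulk membership from [build_bulks()].
#' @param snps SNP table from [simulate_parent_snps()].
#' @param config The [cross_config()].
#' @return A tibble of SNP records: `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `ref_a`, `alt_a`, `ref_b`, `alt_b`. Zero-depth draws yield records
#'   with zero counts; downstream filtering removes them.
#' @export
simulate_bulk_reads <- function(pop, pools, snps, config) {
  stopifnot(inherits(pop, "f2_population"))
  q_of <- function(idx) {
    per_chrom <- purrr::map(split(snps, snps$chrom), function(s) {
      d <- genotype_at(pop, s$chrom[1], s$pos)[idx, , drop = FALSE]
      tibble(chrom = s$chrom, pos = s$pos, q = colSums(d) / (2 * length(idx)))
    })
    bind_rows(per_chrom)
  }
  qa <- q_of(pools$pool_a)
  qb <- q_of(pools$pool_b)
  out <- snps %>%
    left_join(rename(qa, q_a = "q"), by = c("chrom", "pos")) %>%
    left_join(rename(qb, q_b = "q"), by = c("chrom", "pos"))
  withr::with_seed(stage_seed(config$seed, "reads"), {
    eps <- config$error_rate
    n <- nrow(out)
    dep_a <- rpois(n, config$mean_depth)
    dep_b <- rpois(n, config$mean_depth)
    alt_a <- rbinom(n, dep_a, out$q_a * (1 - eps) + (1 - out$q_a) * eps)
    alt_b <- rbinom(n, dep_b, out$q_b * (1 - eps) + (1 - out$q_b) * eps)
    out %>%
      mutate(
        qual = config$quality,
        ref_a = dep_a - alt_a, alt_a = alt_a,
        ref_b = dep_b - alt_b, alt_b = alt_b
      ) %>%
      select("chrom", "pos", "ref", "alt", "qual",
             "ref_a", "alt_a", "ref_b", "alt_b")
  })
}

#' Genotype the configured marker panel in mutant-phenotype plants
#'
#' Mirrors recessive-class fine mapping: only phenotypically mutant F2
#' plants are genotyped. Codes are `A` (wild-parent homozygote), `H`
#' (heterozygote), `B` (mutant-parent homozygote); an optional missing
#' rate blanks calls to `NA`.
#'
#' @param pop An [simulate_f2()] population.
#' @param config The [cross_config()]; must carry a marker panel.
#' @return A tibble `plant_id`, `marker`, `chrom`, `pos`, `genotype`.
#' @export
simulate_marker_genotypes <- function(pop, config) {
  stopifnot(inherits(pop, "f2_population"))
  if (is.null(config$markers)) abort("no marker panel in the config.")
  mut <- which(pop$phenotype == "mutant")
  panel <- as_tibble(config$markers)
  per_chrom <- purrr::map(split(panel, panel$chrom), function(m) {
    d <- genotype_at(pop, m$chrom[1], m$pos)[mut, , drop = FALSE]
    tidyr::expand_grid(i = seq_along(mut), j = seq_len(nrow(m))) %>%
      mutate(
        plant_id = paste0("P", sprintf("%03d", mut[.data$i])),
        marker = m$marker[.data$j],
        chrom = m$chrom[.data$j],
        pos = m$pos[.data$j],
        genotype = c("A", "H", "B")[d[cbind(.data$i, .data$j)] + 1L]
      ) %>%
      select(-"i", -"j")
  })
  out <- bind_rows(per_chrom) %>% arrange(.data$plant_id, .data$chrom, .data$pos)
  if (config$missing_rate > 0) {
    out <- withr::with_seed(stage_seed(config$seed, "markers"), {
      mutate(out, genotype = ifelse(
        runif(dplyr::n()) < config$missing_rate, NA_character_, .data$genotype
      ))
    })
  }
  out
}

#' Run the whole cross simulation in one call
#'
#' Chains [simulate_parent_snps()], [simulate_f2()], [build_bulks()],
#' [simulate_bulk_reads()] and (if a marker panel is configured)
#' [simulate_marker_genotypes()].
#'
#' @param config A [cross_config()].
#' @param phenotype_blind Passed to [build_bulks()]; TRUE gives a
#'   no-selection null dataset.
#' @return A list of class `bsa_simulation`: `config`, `snps`,
#'   `population`, `pools`, `records`, and `marker_genotypes` (or NULL).
#' @examples
#' sim <- simulate_cross(cross_config(n_f2 = 200, seed = 7))
#' head(sim$records)
#' @export
simulate_cross <- function(config, phenotype_blind = FALSE) {
  snps <- simulate_parent_snps(config)
  pop <- simulate_f2(config)
  pools <- build_bulks(pop, config, phenotype_blind = phenotype_blind)
  records <- simulate_bulk_reads(pop, pools, snps, config)
  geno <- if (!is.null(config$markers)) simulate_marker_genotypes(pop, config)
  structure(
    list(config = config, snps = snps, population = pop, pools = pools,
         records = records, marker_genotypes = geno),
    class = "bsa_simulation"
  )
}

#' @export
print.bsa_simulation <- function(x, ...) {
  cat("<bsa_simulation> ", nrow(x$records), " SNP records; bulks ",
      length(x$pools$pool_a), "+", length(x$pools$pool_b), "\n", sep = "")
  invisible(x)
}
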