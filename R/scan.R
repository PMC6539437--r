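#' Configuration of the delta(SNP-index) genome scan
#'
#' @param min_depth Minimum read depth (ref+alt) required in *both* pools.
#' @param min_qual Minimum call quality.
#' @param window Sliding-window size in bp.
#' @param step Sliding step in bp.
#' @param ci_level Confidence level for the simulated null band.
#' @param n_reps Null-simulation replicates per distinct depth pair
#'   (at least 1000; empirical quantiles are unstable below that).
#' @param bulk_chromosomes Chromosomes per pool under the null
#'   (2 x plants per bulk; default 40 for 20-plant bulks).
#' @param p_threshold Window mean Fisher-p threshold for region calling.
#' @param window_ci `"per-snp"` (window band = mean of the per-SNP bands,
#'   the default) or `"window-depth"` (band computed at the window's mean
#'   depths).
#' @param merge_gap Maximum bp gap between significant windows merged
#'   into one region. Defaults to the window size: the window mean is a
#'   `window`-scale smoother, so gaps below that scale are not resolved
#'   by the scan and belong to the same signal.
#' @param seed Seed for the null simulation.
#' @return An object of class `scan_config`.
#' @examples
#' scan_config(seed = 1)
#' @export
scan_config <- function(min_depth = 10, min_qual = 100,
                        window = 2e6, step = 5e4,
                        ci_level = 0.95, n_reps = 10000,
                        bulk_chromosomes = 40, p_threshold = 0.05,
                        window_ci = c("per-snp", "window-depth"),
                        merge_gap = NULL,
                        seed = 1L) {
  if (step > window) abort("`step` must not exceed `window`.")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` must be in (0, 1).")
  if (n_reps < 1000) abort("`n_reps` must be >= 1000.")
  structure(
    list(min_depth = min_depth, min_qual = min_qual, window = window,
         step = step, ci_level = ci_level, n_reps = n_reps,
         bulk_chromosomes = bulk_chromosomes, p_threshold = p_threshold,
         window_ci = match.arg(window_ci),
         merge_gap = merge_gap %||% window, seed = as.integer(seed)),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config> depth >=", x$min_depth, "| qual >=", x$min_qual,
      "| window", x$window / 1e6, "Mb / step", x$step / 1e3, "kb | CI",
      x$ci_level, "(", x$n_reps, "reps ) | p <", x$p_threshold, "\n")
  invisible(x)
}

#' Filter SNP records on call quality and per-pool depth
#'
#' Keeps records with `qual >= min_qual` and read depth (ref + alt)
#' `>= min_depth` in *both* pools (a SNP unusable in one pool cannot
#' yield a delta). Thresholds are inclusive; input order is preserved.
#'
#' @param records SNP record tibble.
#' @param config A [scan_config()].
#' @return The filtered tibble.
#' @export
filter_snps <- function(records, config = scan_config()) {
  records %>%
    filter(
      .data$qual >= config$min_qual,
      .data$ref_a + .data$alt_a >= config$min_depth,
      .data$ref_b + .data$alt_b >= config$min_depth
    )
}

#' SNP-index: fraction of reads carrying the alternate allele
#'
#' @param ref,alt Reference and alternate read counts (vectorised).
#' @return `alt / (ref + alt)`; zero total depth is an error — exclude
#'   such records before calling.
#' @examples
#' snp_index(7, 3) # 0.3
#' @export
snp_index <- function(ref, alt) {
  if (any(ref + alt <= 0)) abort("SNP-index is undefined at zero depth.")
  alt / (ref + alt)
}

#' delta(SNP-index): mutant-pool index minus wild-type-pool index
#'
#' @param index_a Pool A (wild-type bulk) SNP-index.
#' @param index_b Pool B (mutant bulk) SNP-index.
#' @return `index_b - index_a`.
#' @export
delta_snp_index <- function(index_a, index_b) {
  index_b - index_a
}

#' Per-SNP index statistics
#'
#' Adds per-pool depths and SNP-indices, delta(SNP-index), and the
#' two-sided Fisher exact p for the 2x2 allele-count table of the two
#' pools.
#'
#' @param records Filtered SNP record tibble (positive depth both pools).
#' @return The tibble with `depth_a`, `depth_b`, `index_a`, `index_b`,
#'   `delta`, `fisher_p` appended.
#' @export
compute_snp_stats <- function(records) {
  records %>%
    mutate(
      depth_a = .data$ref_a + .data$alt_a,
      depth_b = .data$ref_b + .data$alt_b,
      index_a = snp_index(.data$ref_a, .data$alt_a),
      index_b = snp_index(.data$ref_b, .data$alt_b),
      delta = delta_snp_index(.data$index_a, .data$index_b),
      fisher_p = fisher_exact_p(.data$ref_a, .data$alt_a,
                                .data$ref_b, .data$alt_b)
    )
}

#' Simulated null confidence band for delta(SNP-index)
#'
#' Monte-Carlo band under "no locus anywhere": per replicate, each pool's
#' true alternate-allele frequency is the mean of `bulk_chromosomes`
#' independent fair-coin draws (an unselected F2 bulk), alt counts are
#' Binomial(depth, frequency), and delta is the difference of the two
#' simulated indices. Bounds are the symmetric empirical quantiles at the
#' configured level, computed once per distinct `(depth_a, depth_b)` pair
#' and reused (memoisation), all under the config seed.
#'
#' @param depth_a,depth_b Per-pool read depths (vectorised; >= 1).
#' @param config A [scan_config()].
#' @return Tibble `depth_a, depth_b, ci_lower, ci_upper`, one row per
#'   input element, bounds satisfying `lower <= 0 <= upper`.
#' @export
null_delta_ci <- function(depth_a, depth_b, config = scan_config()) {
  if (any(depth_a < 1) || any(depth_b < 1)) abort("depths must be >= 1.")
  pairs <- distinct(tibble(depth_a = depth_a, depth_b = depth_b))
  reps <- config$n_reps
  alpha <- (1 - config$ci_level) / 2
  bc <- config$bulk_chromosomes
  bounds <- withr::with_seed(stage_seed(config$seed, "null"), {
    purrr::pmap(pairs, function(depth_a, depth_b) {
      qa <- rbinom(reps, bc, 0.5) / bc
      qb <- rbinom(reps, bc, 0.5) / bc
      delta <- rbinom(reps, depth_b, qb) / depth_b -
        rbinom(reps, depth_a, qa) / depth_a
      q <- unname(quantile(delta, c(alpha, 1 - alpha), names = FALSE))
      tibble(ci_lower = q[1], ci_upper = q[2])
    })
  })
  pairs <- dplyr::bind_cols(pairs, bind_rows(bounds))
  tibble(depth_a = depth_a, depth_b = depth_b) %>%
    left_join(pairs, by = c("depth_a", "depth_b"))
}

#' Average per-SNP statistics over sliding genomic windows
#'
#' Windows are anchored at bp 1 on every chromosome, advance by `step`,
#' and span `[start, start + window)` half-open over 1-based positions;
#' the terminal windows are truncated at the chromosome end. Per window
#' the arithmetic means of the two indices, delta, Fisher p and the null
#' band bounds are taken over the SNPs it contains; empty windows carry
#' `n_snps = 0` and `NA` means.
#'
#' @param snp_stats Tibble from [compute_snp_stats()] with `ci_lower`,
#'   `ci_upper` attached, sorted by chromosome then position.
#' @param config A [scan_config()].
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   absent each chromosome's largest SNP position is used.
#' @return Window tibble: `chrom, start, end, n_snps, mean_index_a,
#'   mean_index_b, mean_delta, mean_p, ci_lower, ci_upper`.
#' @export
sliding_windows <- function(snp_stats, config = scan_config(),
                            chrom_lengths = NULL) {
  by_chrom <- split(snp_stats, factor(snp_stats$chrom,
                                      levels = unique(snp_stats$chrom)))
  purrr::map(by_chrom, function(s) {
    if (is.unsorted(s$pos, strictly = FALSE)) {
      abort("SNP records must be sorted by position within chromosome.")
    }
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[s$chrom[1]]] else max(s$pos)
    starts <- 1 + config$step * (0:((len - 1) %/% config$step))
    i1 <- findInterval(starts - 1, s$pos) + 1
    i2 <- findInterval(starts + config$window - 1, s$pos)
    n <- pmax(i2 - i1 + 1, 0)
    wmean <- function(v) {
      cs <- c(0, cumsum(v))
      out <- (cs[i2 + 1] - cs[i1]) / n
      out[n == 0] <- NA_real_
      out
    }
    tibble(
      chrom = s$chrom[1],
      start = starts,
      end = pmin(starts + config$window - 1, len),
      n_snps = as.integer(n),
      mean_index_a = wmean(s$index_a),
      mean_index_b = wmean(s$index_b),
      mean_delta = wmean(s$delta),
      mean_p = wmean(s$fisher_p),
      ci_lower = if (config$window_ci == "per-snp") wmean(s$ci_lower) else NA_real_,
      ci_upper = if (config$window_ci == "per-snp") wmean(s$ci_upper) else NA_real_,
      mean_depth_a = wmean(s$depth_a),
      mean_depth_b = wmean(s$depth_b)
    )
  }) %>%
    bind_rows()
}

# Band at the window's rounded mean depths (the alternative window_ci mode).
window_depth_ci <- function(windows, config) {
  nz <- windows$n_snps > 0
  ci <- null_delta_ci(pmax(round(windows$mean_depth_a[nz]), 1),
                      pmax(round(windows$mean_depth_b[nz]), 1), config)
  windows$ci_lower[nz] <- ci$ci_lower
  windows$ci_upper[nz] <- ci$ci_upper
  windows
}

#' Call candidate regions from significant windows
#'
#' A window is significant iff it contains at least one SNP, its mean
#' delta exceeds its upper null band bound, and its mean Fisher p is
#' below the threshold. Significant windows on a chromosome that
#' overlap, touch, or lie within `merge_gap` of one another (default one
#' window size — sub-window gaps are below the scan's resolution) merge
#' into one region spanning min start to max end. Regions are ranked by
#' peak window mean delta (ties by genomic order).
#'
#' @param windows Window tibble from [sliding_windows()] with band bounds.
#' @param config A [scan_config()].
#' @return Region tibble: `chrom, start, end, n_windows, peak_delta,
#'   min_p` (zero rows when nothing is significant).
#' @export
call_candidate_regions <- function(windows, config = scan_config()) {
  sig <- windows %>%
    filter(.data$n_snps > 0,
           .data$mean_delta > .data$ci_upper,
           .data$mean_p < config$p_threshold)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), peak_delta = numeric(),
                  min_p = numeric()))
  }
  sig %>%
    arrange(match(.data$chrom, unique(windows$chrom)), .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(gap = .data$start >
             dplyr::lag(.data$end, default = -Inf) + 1 + config$merge_gap,
           run = cumsum(.data$gap)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(), peak_delta = max(.data$mean_delta),
      min_p = min(.data$mean_p), .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$peak_delta), .data$chrom, .data$start) %>%
    select(-"run")
}

#' Run the full delta(SNP-index) scan
#'
#' Filters records, computes per-SNP indices, deltas, Fisher p-values and
#' simulated null bands, averages them over sliding windows, and calls
#' candidate regions.
#'
#' @param records SNP record tibble (from [read_variant_table()] or
#'   [simulate_bulk_reads()]).
#' @param config A [scan_config()].
#' @param chrom_lengths Optional named chromosome lengths for windowing.
#' @return An object of class `mutmap_scan`: `snps` (per-SNP stats),
#'   `windows`, `regions`, `config`, `n_input`, `n_kept`, with `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @examples
#' sim <- simulate_cross(cross_config(n_f2 = 200, seed = 3))
#' scan <- mutmap_scan(sim$records, scan_config(n_reps = 1000, seed = 3),
#'                     chrom_lengths = sim$config$chrom_lengths)
#' scan$regions
#' @export
mutmap_scan <- function(records, config = scan_config(),
                        chrom_lengths = NULL) {
  kept <- filter_snps(records, config)
  snps <- compute_snp_stats(kept)
  ci <- null_delta_ci(snps$depth_a, snps$depth_b, config)
  snps$ci_lower <- ci$ci_lower
  snps$ci_upper <- ci$ci_upper
  windows <- sliding_windows(snps, config, chrom_lengths)
  if (config$window_ci == "window-depth") {
    windows <- window_depth_ci(windows, config)
  }
  windows <- windows %>%
    mutate(significant = .data$n_snps > 0 &
             .data$mean_delta > .data$ci_upper &
             .data$mean_p < config$p_threshold)
  regions <- call_candidate_regions(windows, config)
  structure(
    list(snps = snps, windows = windows, regions = regions,
         config = config, n_input = nrow(records), n_kept = nrow(kept)),
    class = "mutmap_scan"
  )
}

#' @export
print.mutmap_scan <- function(x, ...) {
  cat("<mutmap_scan> ", x$n_kept, "/", x$n_input, " SNPs kept; ",
      sum(x$windows$significant), " significant window(s); ",
      nrow(x$regions), " candidate region(s)\n", sep = "")
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

#' @method tidy mutmap_scan
#' @export
tidy.mutmap_scan <- function(x, ...) {
  x$windows
}

#' @method glance mutmap_scan
#' @export
glance.mutmap_scan <- function(x, ...) {
  tibble(
    n_input = x$n_input, n_kept = x$n_kept,
    n_windows = nrow(x$windows),
    n_nonempty = sum(x$windows$n_snps > 0),
    n_significant = sum(x$windows$significant),
    n_regions = nrow(x$regions),
    peak_delta = if (nrow(x$regions)) max(x$regions$peak_delta) else NA_real_
  )
}

#' Write scan outputs (per-SNP TSV, window TSV, regions BED and TSV)
#'
#' The BED file uses the 0-based half-open convention; the report TSV
#' keeps 1-based inclusive coordinates.
#'
#' @param scan A [mutmap_scan()] result.
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    snps = file.path(dir, "snp_index.tsv"),
    windows = file.path(dir, "windows.tsv"),
    regions = file.path(dir, "regions.tsv"),
    bed = file.path(dir, "regions.bed")
  )
  readr::write_tsv(scan$snps, paths[["snps"]])
  readr::write_tsv(scan$windows, paths[["windows"]])
  readr::write_tsv(scan$regions, paths[["regions"]])
  bed <- scan$regions %>%
    mutate(start0 = format(.data$start - 1, scientific = FALSE, trim = TRUE),
           end0 = format(.data$end, scientific = FALSE, trim = TRUE))
  writeLines(
    if (nrow(bed)) paste(bed$chrom, bed$start0, bed$end0,
                         paste0("region", seq_len(nrow(bed))), sep = "\t")
    else character(0),
    paths[["bed"]]
  )
  invisible(paths)
}
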