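#' Screen a marker panel for polymorphism between the parents
#'
#' Retains markers whose two parental calls differ and are both
#' non-missing — the usable subset for mapping in the cross.
#'
#' @param parents Data frame with columns `marker`, `parent_a`,
#'   `parent_b` (call per parent; `NA` = missing).
#' @return The polymorphic subset, same columns.
#' @export
polymorphic_screen <- function(parents) {
  need <- c("marker", "parent_a", "parent_b")
  if (!all(need %in% names(parents))) {
    abort("`parents` needs columns marker, parent_a, parent_b.")
  }
  parents %>%
    filter(!is.na(.data$parent_a), !is.na(.data$parent_b),
           .data$parent_a != .data$parent_b)
}

#' Count recombinant chromosomes per marker in the recessive class
#'
#' All genotyped plants are phenotypically mutant, hence homozygous for
#' the mutant allele at the causal locus; each marker genotype therefore
#' reveals recombination directly: `B` (mutant homozygote) contributes 0
#' recombinant chromosomes, `H` 1, and `A` (wild homozygote) 2. Missing
#' calls are excluded per marker. The recombination fraction estimate is
#' `recombinants / (2 * plants scored)`.
#'
#' @param genotypes Marker genotype tibble (`plant_id, marker, chrom,
#'   pos, genotype`) for one or many markers.
#' @return One summary row per marker: `marker, chrom, pos, n_scored,
#'   n_wild_hom, n_het, n_mut_hom, recombinants, r_hat, cosegregating`,
#'   sorted by position.
#' @examples
#' g <- tibble::tibble(plant_id = paste0("P", 1:4), marker = "m1",
#'                     chrom = "chr01", pos = 100,
#'                     genotype = c("H", "B", "B", "A"))
#' count_recombinants(g) # 3 recombinant chromosomes, r_hat = 3/8
#' @export
count_recombinants <- function(genotypes) {
  bad <- setdiff(unique(genotypes$genotype), c("A", "H", "B", NA))
  if (length(bad)) {
    abort(paste0("genotype symbol(s) outside {A,H,B,NA}: ",
                 paste(bad, collapse = ", ")))
  }
  genotypes %>%
    filter(!is.na(.data$genotype)) %>%
    group_by(.data$marker, .data$chrom, .data$pos) %>%
    summarise(
      n_scored = dplyr::n(),
      n_wild_hom = sum(.data$genotype == "A"),
      n_het = sum(.data$genotype == "H"),
      n_mut_hom = sum(.data$genotype == "B"),
      .groups = "drop"
    ) %>%
    mutate(
      recombinants = .data$n_het + 2L * .data$n_wild_hom,
      r_hat = .data$recombinants / (2 * .data$n_scored),
      cosegregating = .data$recombinants == 0L
    ) %>%
    arrange(.data$chrom, .data$pos)
}

#' Delimit the causal interval from per-marker recombinant counts
#'
#' With markers ordered by physical position, the locus lies inside the
#' run of co-segregating (zero-recombinant) markers; the interval is
#' bracketed by the nearest flanking marker on each side that shows at
#' least one recombinant. If no marker co-segregates, the run of markers
#' attaining the minimum recombinant count plays the same role. A locus
#' with recombinants on one side only cannot be bracketed and is an
#' error.
#'
#' @param summaries Marker summary tibble from [count_recombinants()]
#'   (one chromosome).
#' @return A one-row tibble: `left_marker, left_pos, right_marker,
#'   right_pos, span_kb` (span start-to-start, kb, 2 decimals kept raw —
#'   rounding is a printing concern).
#' @examples
#' s <- tibble::tibble(marker = c("m1", "m2", "m3"), chrom = "c",
#'                     pos = c(100, 200, 300), recombinants = c(1L, 0L, 2L),
#'                     r_hat = c(0.1, 0, 0.2))
#' delimit_interval(s)
#' @export
delimit_interval <- function(summaries) {
  if (length(unique(summaries$chrom)) != 1) {
    abort("interval delimitation expects markers of a single chromosome.")
  }
  s <- arrange(summaries, .data$pos)
  target <- min(s$recombinants)
  in_run <- s$recombinants == target
  # use the first maximal run of minimal-count markers
  runs <- rle(in_run)
  ends <- cumsum(runs$lengths)
  first <- which(runs$values)[1]
  run_hi <- ends[first]
  run_lo <- run_hi - runs$lengths[first] + 1
  left <- if (run_lo > 1) run_lo - 1 else NA_integer_
  right <- if (run_hi < nrow(s)) run_hi + 1 else NA_integer_
  if (is.na(left) || is.na(right)) {
    abort("locus not bracketed: recombinant markers on one side only.")
  }
  tibble(
    left_marker = s$marker[left], left_pos = s$pos[left],
    right_marker = s$marker[right], right_pos = s$pos[right],
    span_kb = interval_width(s$pos[left], s$pos[right])
  )
}

#' Physical interval width in kb
#'
#' @param left,right Interval endpoints in bp, `left <= right`.
#' @return `(right - left) / 1000`; report to 2 decimals.
#' @examples
#' interval_width(51035485, 51111716) # 76.231
#' @export
interval_width <- function(left, right) {
  if (any(right < left)) abort("`right` must be >= `left`.")
  (right - left) / 1000
}

#' Fine-map a recessive locus from a marker genotype table
#'
#' Convenience wrapper: [count_recombinants()] per marker, then
#' [delimit_interval()] on the marker of one chromosome.
#'
#' @param genotypes Marker genotype tibble of mutant-phenotype plants.
#' @return A list of class `finemap_result`: `markers` (per-marker
#'   summaries) and `interval` (one-row tibble).
#' @export
finemap <- function(genotypes) {
  markers <- count_recombinants(genotypes)
  structure(
    list(markers = markers, interval = delimit_interval(markers)),
    class = "finemap_result"
  )
}

#' @export
print.finemap_result <- function(x, ...) {
  cat("<finemap_result> ", nrow(x$markers), " markers; interval ",
      x$interval$left_marker, " - ", x$interval$right_marker, " (",
      sprintf("%.2f", x$interval$span_kb), " kb)\n", sep = "")
  invisible(x)
}

#' @method tidy finemap_result
#' @export
tidy.finemap_result <- function(x, ...) {
  x$markers
}

#' @method glance finemap_result
#' @export
glance.finemap_result <- function(x, ...) {
  dplyr::bind_cols(
    x$interval,
    tibble(n_markers = nrow(x$markers),
           n_cosegregating = sum(x$markers$recombinants ==
                                   min(x$markers$recombinants)))
  )
}
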