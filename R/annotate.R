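#' Load gene models from GFF3 or BED
#'
#' GFF3 is read via rtracklayer (gene-type records, or all records if
#' none are typed `gene`); BED likewise, with its 0-based half-open
#' coordinates converted to the 1-based inclusive convention used
#' throughout the package. Models are returned sorted by chromosome and
#' start.
#'
#' @param path Annotation file (`.gff`, `.gff3` or `.bed`).
#' @return Tibble `gene_id, chrom, start, end, strand, annotation`
#'   (annotation `"Unknown"` where the file carries none).
#' @examples
#' gff <- system.file("extdata", "lm1_candidate_genes.gff3",
#'                    package = "mutmapr")
#' load_genes(gff)
#' @export
load_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read annotations.")
  }
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  gr <- if (is_bed) rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gr)
  if (!is_bed && "type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  }
  id <- if (!is_bed && "ID" %in% names(df)) df$ID
        else if ("name" %in% names(df)) df$name
        else paste0("gene", seq_len(nrow(df)))
  ann <- if ("description" %in% names(df)) df$description
         else if ("Note" %in% names(df)) as.character(df$Note)
         else rep("Unknown", nrow(df))
  ann[is.na(ann) | ann == ""] <- "Unknown"
  out <- tibble(
    gene_id = as.character(id), chrom = as.character(df$seqnames),
    start = as.numeric(df$start), end = as.numeric(df$end),
    strand = as.character(df$strand), annotation = ann
  )
  if (any(out$start > out$end)) {
    bad <- which(out$start > out$end)[1]
    abort(paste0("start > end for record ", out$gene_id[bad]))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write gene models as BED (0-based half-open)
#'
#' @param genes Gene model tibble (see [load_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                   as.integer(genes$start) - 1L, as.integer(genes$end),
                   genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Genes overlapping a mapped interval
#'
#' Any-overlap semantics against the closed interval `[left, right]`:
#' a gene is reported iff `start <= right` and `end >= left`. Containment
#' is not required — a gene straddling an interval edge counts.
#'
#' @param genes Gene model tibble.
#' @param chrom Chromosome of the interval.
#' @param left,right Interval bounds, bp, 1-based inclusive.
#' @return The overlapping subset in positional order.
#' @export
genes_in_interval <- function(genes, chrom, left, right) {
  if (right < left) abort("`right` must be >= `left`.")
  genes %>%
    filter(.data$chrom == !!chrom, .data$start <= right, .data$end >= left) %>%
    arrange(.data$start)
}

#' Assemble the final mapping report
#'
#' Combines the genome-scan candidate region, the fine-mapped interval
#' and the candidate gene list into one structured report; optionally
#' writes it as JSON plus a candidate-gene TSV.
#'
#' @param region One-row region tibble from [call_candidate_regions()]
#'   (or NULL if the scan stage was skipped).
#' @param interval One-row interval tibble from [delimit_interval()].
#' @param genes Gene tibble from [genes_in_interval()].
#' @param dir Optional output directory.
#' @return A list of class `mapping_report` (`region`, `interval`,
#'   `genes`, `n_genes`), invisibly writing `report.json` and
#'   `candidate_genes.tsv` when `dir` is given.
#' @export
mapping_report <- function(region, interval, genes, dir = NULL) {
  report <- structure(
    list(region = region, interval = interval, genes = genes,
         n_genes = nrow(genes)),
    class = "mapping_report"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        region = region, interval = interval,
        n_genes = nrow(genes), genes = genes
      ),
      file.path(dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    readr::write_tsv(genes, file.path(dir, "candidate_genes.tsv"))
  }
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report>\n")
  if (!is.null(x$region) && nrow(x$region)) {
    cat(sprintf("  scan region: %s:%s-%s\n", x$region$chrom[1],
                format(x$region$start[1], big.mark = ","),
                format(x$region$end[1], big.mark = ",")))
  }
  cat(sprintf("  fine interval: %s - %s (%.2f kb)\n",
              x$interval$left_marker, x$interval$right_marker,
              x$interval$span_kb))
  cat("  candidate genes: ", x$n_genes, "\n", sep = "")
  if (x$n_genes > 0) {
    print(select(x$genes, "gene_id", "start", "end", "strand", "annotation"))
  }
  invisible(x)
}
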