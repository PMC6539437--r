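#' Run the whole mapping pipeline into an output directory
#'
#' Orchestrates the stages end to end: simulate the cross (or read a
#' provided variant table), test phenotype segregation against 3:1, run
#' the delta(SNP-index) scan, fine-map from the recessive-class marker
#' genotypes, and intersect the fine interval with a gene annotation.
#' Every stochastic stage derives its stream from `cross$seed`, so a
#' fixed seed gives byte-identical outputs; a run manifest with file
#' checksums is always written, including on failure (with the failing
#' stage recorded).
#'
#' @param cross A [cross_config()].
#' @param scan A [scan_config()].
#' @param out_dir Output directory (created).
#' @param annotation Optional gene annotation path (GFF3/BED) for the
#'   candidate-gene stage.
#' @param stages Character subset of
#'   `c("simulate", "segtest", "scan", "finemap", "genes")`.
#' @param variants Optional variant table path used by the scan stage
#'   when `"simulate"` is not among the stages.
#' @return A list of class `pipeline_result` with the per-stage results
#'   and the manifest, invisibly.
#' @export
run_pipeline <- function(cross = cross_config(), scan = scan_config(),
                         out_dir,
                         annotation = NULL,
                         stages = c("simulate", "segtest", "scan",
                                    "finemap", "genes"),
                         variants = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  status <- list(failed_stage = NULL, error = NULL)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  run_stage <- function(name, expr) {
    if (!name %in% stages) return(NULL)
    logf("stage %s", name)
    tryCatch(expr, error = function(e) {
      status$failed_stage <<- name
      status$error <<- conditionMessage(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  on.exit({
    manifest <- list(
      package = "mutmapr",
      version = as.character(utils::packageVersion("mutmapr")),
      seed = cross$seed,
      stages = stages,
      failed_stage = status$failed_stage,
      error = status$error,
      config_hash = digest_config(cross, scan),
      files = file_checksums(out_dir)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }, add = TRUE)

  res$simulation <- run_stage("simulate", {
    sim <- simulate_cross(cross)
    write_simulation(sim, file.path(out_dir, "simulation"))
    logf("  %d SNP records, %d/%d wild/mutant plants", nrow(sim$records),
         sum(sim$population$phenotype == "wild"),
         sum(sim$population$phenotype == "mutant"))
    sim
  })

  res$segregation <- run_stage("segtest", {
    if (is.null(res$simulation)) abort("segtest needs the simulate stage.")
    ph <- res$simulation$population$phenotype
    st <- segregation_test(c(sum(ph == "wild"), sum(ph == "mutant")),
                           c(3, 1), classes = c("wild", "mutant"))
    readr::write_tsv(glance(st), file.path(out_dir, "segregation.tsv"))
    st
  })

  res$scan <- run_stage("scan", {
    records <- if (!is.null(res$simulation)) res$simulation$records
      else if (!is.null(variants)) read_variant_table(variants)
      else abort("scan needs either the simulate stage or `variants`.")
    lens <- if (!is.null(res$simulation)) cross$chrom_lengths else NULL
    sc <- mutmap_scan(records, scan, chrom_lengths = lens)
    paths <- write_scan(sc, file.path(out_dir, "scan"))
    grDevices::pdf(file.path(out_dir, "scan", "scan.pdf"), width = 9,
                   height = 6)
    print(autoplot(sc))
    grDevices::dev.off()
    logf("  %d windows, %d significant, %d region(s)", nrow(sc$windows),
         sum(sc$windows$significant), nrow(sc$regions))
    sc
  })

  res$finemap <- run_stage("finemap", {
    if (is.null(res$simulation) || is.null(res$simulation$marker_genotypes)) {
      abort("finemap needs a simulated cross with a marker panel.")
    }
    fm <- finemap(res$simulation$marker_genotypes)
    readr::write_tsv(fm$markers, file.path(out_dir, "marker_summary.tsv"))
    readr::write_tsv(fm$interval, file.path(out_dir, "interval.tsv"))
    logf("  interval %s - %s (%.2f kb)", fm$interval$left_marker,
         fm$interval$right_marker, fm$interval$span_kb)
    fm
  })

  res$genes <- run_stage("genes", {
    if (is.null(annotation)) NULL else {
      if (is.null(res$finemap)) abort("genes stage needs the finemap stage.")
      genes <- load_genes(annotation)
      iv <- res$finemap$interval
      hits <- genes_in_interval(genes, unique(res$finemap$markers$chrom)[1],
                                iv$left_pos, iv$right_pos)
      mapping_report(
        region = if (!is.null(res$scan)) head(res$scan$regions, 1),
        interval = iv, genes = hits, dir = out_dir
      )
    }
  })

  invisible(structure(c(res, list(out_dir = out_dir)),
                      class = "pipeline_result"))
}

digest_config <- function(cross, scan) {
  # stable fingerprint of both configs without an extra dependency
  txt <- paste(utils::capture.output({
    utils::str(unclass(cross)); utils::str(unclass(scan))
  }), collapse = "\n")
  as.character(sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 2^31)
}

file_checksums <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json", "run.log",
                                         "scan.pdf")]
  sums <- tools::md5sum(files)
  as.list(setNames(unname(sums), sub(paste0("^", dir, "/?"), "", files)))
}
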