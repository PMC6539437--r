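#' Write and read bulk SNP allele-count tables
#'
#' Two on-disk dialects carry the same records: a plain TSV
#' (`chrom, pos, ref, alt, qual, ref_a, alt_a, ref_b, alt_b`) and a
#' two-sample VCF 4.2 (samples POOLA, POOLB with per-sample `AD` and
#' `DP`; `QUAL` carries the call quality). Reading either back yields the
#' identical tibble.
#'
#' @param records SNP record tibble (see [simulate_bulk_reads()]).
#' @param path Output file path.
#' @param chrom_lengths Optional named vector for VCF `##contig` headers.
#' @return `path`, invisibly.
#' @name snp_io
NULL

#' @rdname snp_io
#' @export
write_snp_tsv <- function(records, path) {
  readr::write_tsv(records[, snp_cols()], path)
  invisible(path)
}

#' @rdname snp_io
#' @export
write_snp_vcf <- function(records, path, chrom_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmapr",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "POOLA", "POOLB", sep = "\t")
  )
  body <- if (nrow(records) == 0) character(0) else {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
            records$chrom, as.integer(records$pos), records$ref, records$alt,
            format(records$qual, trim = TRUE),
            records$ref_a, records$alt_a, records$ref_a + records$alt_a,
            records$ref_b, records$alt_b, records$ref_b + records$alt_b)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

snp_cols <- function() {
  c("chrom", "pos", "ref", "alt", "qual", "ref_a", "alt_a", "ref_b", "alt_b")
}

#' @rdname snp_io
#' @export
read_snp_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      ref = readr::col_character(), alt = readr::col_character(),
      qual = readr::col_double(), ref_a = readr::col_integer(),
      alt_a = readr::col_integer(), ref_b = readr::col_integer(),
      alt_b = readr::col_integer()
    )
  )
}

#' @rdname snp_io
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_snp_tbl())
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic site(s) skipped.")
  }
  samples <- colnames(v@gt)[-1]
  if (length(samples) != 2) abort("expected exactly two samples in the VCF.")
  ad <- vcfR::extract.gt(v, element = "AD")
  bad <- which(is.na(ad), arr.ind = TRUE)
  if (length(bad)) {
    abort(sprintf("missing AD field at %s:%s", fix$CHROM[bad[1, 1]],
                  fix$POS[bad[1, 1]]))
  }
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(purrr::map_chr(parts, 1)),
         alt = as.integer(purrr::map_chr(parts, function(p) p[2])))
  }
  a <- split_ad(ad[, 1])
  b <- split_ad(ad[, 2])
  out <- tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF,
    alt = fix$ALT, qual = as.numeric(fix$QUAL),
    ref_a = a$ref, alt_a = a$alt, ref_b = b$ref, alt_b = b$alt
  )
  out[!multi, ]
}

empty_snp_tbl <- function() {
  tibble(
    chrom = character(), pos = numeric(), ref = character(),
    alt = character(), qual = numeric(), ref_a = integer(),
    alt_a = integer(), ref_b = integer(), alt_b = integer()
  )
}

#' Read a bulk allele-count table, VCF or TSV
#'
#' Dispatches on file extension: `.vcf` (or `.vcf.gz`) via [read_snp_vcf()],
#' anything else via [read_snp_tsv()].
#'
#' @param path Input file.
#' @return SNP record tibble.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) read_snp_vcf(path) else read_snp_tsv(path)
}

#' Write and read marker genotype tables
#'
#' TSV with columns `plant_id, marker, chrom, pos, genotype`; genotype is
#' `A`/`H`/`B` or `NA` for a missing call.
#'
#' @param genotypes Marker genotype tibble.
#' @param path File path.
#' @return `path` invisibly (write); the tibble (read).
#' @name marker_io
NULL

#' @rdname marker_io
#' @export
write_marker_tsv <- function(genotypes, path) {
  readr::write_tsv(genotypes, path)
  invisible(path)
}

#' @rdname marker_io
#' @export
read_marker_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      plant_id = readr::col_character(), marker = readr::col_character(),
      chrom = readr::col_character(), pos = readr::col_double(),
      genotype = readr::col_character()
    )
  )
}

#' Write every simulation artefact of one cross to a directory
#'
#' @param sim A [simulate_cross()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "bsa_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tsv = file.path(dir, "bulk_snps.tsv"),
    vcf = file.path(dir, "bulk_snps.vcf")
  )
  write_snp_tsv(sim$records, paths[["tsv"]])
  write_snp_vcf(sim$records, paths[["vcf"]],
                chrom_lengths = sim$config$chrom_lengths)
  if (!is.null(sim$marker_genotypes)) {
    paths[["markers"]] <- file.path(dir, "marker_genotypes.tsv")
    write_marker_tsv(sim$marker_genotypes, paths[["markers"]])
  }
  paths
}
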