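#' Read phased parental genotypes from a VCF
#'
#' Expects a VCF with exactly two samples (mother, father), biallelic SNPs
#' and phased GT fields.  Multiallelic or unphased records are dropped with
#' a message; records must be coordinate-sorted within chromosomes.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param maternal_sample,paternal_sample Sample names; default to the first
#'   and second sample in the file.
#' @return A named list of [site_grid()]s, one per chromosome.
#' @export
read_parental_vcf <- function(path, maternal_sample = NULL,
                              paternal_sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  maternal_sample <- maternal_sample %||% samples[1]
  paternal_sample <- paternal_sample %||% samples[2]
  if (!all(c(maternal_sample, paternal_sample) %in% samples)) {
    stop("sample(s) not found in VCF: expected ", maternal_sample, " and ",
      paternal_sample, call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep_bi <- vcfR::is.biallelic(v)
  gm <- gt[, maternal_sample]
  gp <- gt[, paternal_sample]
  phased <- !is.na(gm) & !is.na(gp) & grepl("|", gm, fixed = TRUE) &
    grepl("|", gp, fixed = TRUE)
  drop <- sum(!keep_bi | !phased)
  if (drop > 0) {
    message("dropping ", drop, " multiallelic/unphased/missing record(s)")
  }
  keep <- keep_bi & phased
  chroms <- vcfR::getCHROM(v)[keep]
  pos <- vcfR::getPOS(v)[keep]
  split_al <- function(g) {
    parts <- strsplit(g, "|", fixed = TRUE)
    list(h0 = as.numeric(vapply(parts, `[`, "", 1)),
      h1 = as.numeric(vapply(parts, `[`, "", 2)))
  }
  m <- split_al(gm[keep])
  p <- split_al(gp[keep])
  out <- purrr::map(stats::setNames(unique(chroms), unique(chroms)),
    function(ch) {
      i <- chroms == ch
      if (is.unsorted(pos[i], strictly = TRUE)) {
        stop("VCF records not sorted on chromosome ", ch, call. = FALSE)
      }
      site_grid(ch, pos[i], m$h0[i], m$h1[i], p$h0[i], p$h1[i])
    })
  out
}

#' Write a phased parental VCF
#'
#' Minimal VCFv4.2 writer for simulated parental haplotypes (two samples,
#' biallelic SNPs, phased GT only, placeholder alleles A/B).
#'
#' @param grids A [site_grid()] or list of them.
#' @param path Output path (plain text).
#' @param maternal_sample,paternal_sample Sample names to write.
#' @return `path`, invisibly.
#' @export
write_parental_vcf <- function(grids, path, maternal_sample = "MOTHER",
                               paternal_sample = "FATHER") {
  if (inherits(grids, "site_grid") || is.data.frame(grids)) {
    grids <- list(grids)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgtkaryo",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", maternal_sample, paternal_sample, sep = "\t")
  )
  body <- purrr::map(grids, function(g) {
    g <- as_site_grid(g)
    sprintf("%s\t%d\t.\tA\tB\t.\tPASS\t.\tGT\t%d|%d\t%d|%d",
      g$chrom, as.integer(g$pos), g$m0, g$m1, g$p0, g$p1)
  })
  writeLines(c(header, unlist(body)), path)
  invisible(path)
}

#' Read and write embryo BAF tables
#'
#' The interchange format is a TSV with a versioned header comment line
#' (`# pgtkaryo_baf v1`) and columns `embryo_id`, `chrom`, `pos`, `baf`
#' (empty = missing).
#'
#' @param x A BAF tibble.
#' @param path File path.
#' @return `read_baf_tsv()` returns the tibble; `write_baf_tsv()` returns
#'   `path` invisibly.
#' @export
write_baf_tsv <- function(x, path) {
  writeLines("# pgtkaryo_baf v1", path)
  readr::write_tsv(x[, c("embryo_id", "chrom", "pos", "baf")], path,
    append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_baf_tsv
#' @export
read_baf_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      embryo_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      baf = readr::col_double()
    ))
}

#' Write per-chromosome karyotype calls as TSV
#'
#' @param calls A calls table from [infer_karyotypes()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Write segmental calls as BED
#'
#' BED uses 0-based half-open coordinates; grid positions are 1-based, so
#' starts are shifted by one.  The score column is `round(1000 * posterior)`.
#'
#' @param segments A segment table from [detect_segments()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- sprintf("%s\t%d\t%d\t%s\t%d", segments$chrom,
    as.integer(segments$start_bp - 1), as.integer(segments$end_bp - 1),
    paste0(segments$embryo_id, ":", segments$segment_class),
    as.integer(round(1000 * segments$local_posterior)))
  writeLines(bed, path)
  invisible(path)
}

#' Write crossover calls as a BED-like TSV
#'
#' @param calls A crossover table from [call_crossovers()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_crossovers_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}
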