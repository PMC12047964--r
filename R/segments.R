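#' Detect segmental aneuploidies from the MAP path
#'
#' Scans the per-site MAP state path for contiguous runs whose ploidy class
#' differs from the chromosome's majority class (the class covering the most
#' sites; ties broken by the larger aggregate posterior) and keeps a run as
#' a segmental call when all three filters hold: (1) it contains at least
#' `min_snps` SNPs, (2) the local posterior supporting its class within the
#' segment exceeds `min_posterior` (segment mean by default; per-site
#' minimum with `posterior_rule = "min"`), and (3) it spans at least
#' `min_len_bp`.  Chromosomes with a passing segment should be excluded from
#' whole-chromosome aneuploidy analyses.
#'
#' Segment coordinates are half-open: `start_bp` is the position of the
#' first divergent SNP and `end_bp` the position of the first SNP after the
#' run (or one past the last divergent SNP at the chromosome end).
#'
#' @param fit A `karyotype_fit`.
#' @param min_snps Minimum SNPs per segment (default 100).
#' @param min_posterior Minimum local class posterior (default 0.8).
#' @param min_len_bp Minimum segment length in bp (default 5e6).
#' @param posterior_rule `"mean"` (default) or `"min"` aggregation of the
#'   per-site class posterior within the segment.
#' @return A tibble of segmental calls in coordinate order: `embryo_id`,
#'   `chrom`, `start_bp`, `end_bp`, `n_snps`, `segment_class`,
#'   `local_posterior`.
#' @export
detect_segments <- function(fit, min_snps = 100, min_posterior = 0.8,
                            min_len_bp = 5e6,
                            posterior_rule = c("mean", "min")) {
  stopifnot(inherits(fit, "karyotype_fit"))
  posterior_rule <- match.arg(posterior_rule)
  cls <- fit$map_class
  tab <- table(cls)
  top <- names(tab)[tab == max(tab)]
  majority <- if (length(top) == 1) {
    top
  } else {
    top[which.max(fit$class_posteriors[top])]
  }
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != majority
  agg <- if (posterior_rule == "mean") mean else min
  out <- purrr::pmap_dfr(
    list(starts[keep], ends[keep], runs$values[keep]),
    function(s, e, cl) {
      idx <- s:e
      start_bp <- fit$positions[s]
      end_bp <- if (e < length(fit$positions)) {
        fit$positions[e + 1]
      } else {
        fit$positions[e] + 1
      }
      lp <- agg(fit$class_site_posteriors[idx, cl])
      tibble::tibble(
        embryo_id = fit$embryo_id, chrom = fit$chrom,
        start_bp = start_bp, end_bp = end_bp,
        n_snps = length(idx), segment_class = cl, local_posterior = lp
      )
    }
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(embryo_id = character(), chrom = character(),
      start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
      segment_class = character(), local_posterior = numeric()))
  }
  out |>
    dplyr::filter(.data$n_snps >= min_snps,
      .data$local_posterior > min_posterior,
      .data$end_bp - .data$start_bp >= min_len_bp) |>
    dplyr::arrange(.data$start_bp)
}
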