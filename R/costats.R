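#' Law-of-total-variance decomposition of crossover counts
#'
#' Decomposes the variance of per-embryo total crossover counts,
#' `Var(sum_k CO_k) = sum_k Var(CO_k) + sum_{i != j} Cov(CO_i, CO_j)`,
#' into the total variance `A`, the independent per-chromosome component
#' `B`, and the inter-chromosomal covariance `C = A - B`.  A ratio `C/A`
#' well above 0 means a substantial share of the variance in genome-wide
#' crossover counts comes from positive covariance between chromosomes —
#' nucleus-wide covariation.  Sample (n-1) estimators are used throughout,
#' so the identity `A = B + C` holds exactly.
#'
#' @param counts Numeric matrix (or data frame) of crossover counts,
#'   embryos in rows, chromosomes in columns.
#' @return A one-row tibble: `A`, `B`, `C`, `c_over_a`, `n_embryos`,
#'   `n_chromosomes`.
#' @examples
#' m <- matrix(rpois(200, 2), 50, 4)
#' variance_decomposition(m)
#' @export
variance_decomposition <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 embryos", call. = FALSE)
  if (ncol(counts) < 2) stop("need at least 2 chromosomes", call. = FALSE)
  V <- stats::cov(counts)
  A <- stats::var(rowSums(counts))
  B <- sum(diag(V))
  C <- sum(V) - B
  tibble::tibble(A = A, B = B, C = C, c_over_a = C / A,
    n_embryos = nrow(counts), n_chromosomes = ncol(counts))
}

#' One-way intraclass correlation of crossover counts
#'
#' Classical one-way random-effects intraclass correlation of per-chromosome
#' crossover counts grouped by embryo, with the one-way ANOVA F test:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)` with `k` chromosomes per
#' embryo.  Negative estimates (no between-embryo variance) are clamped
#' at 0.
#'
#' @inheritParams variance_decomposition
#' @return A one-row tibble: `icc`, `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
intraclass_correlation <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 embryos", call. = FALSE)
  if (ncol(counts) < 2) stop("need at least 2 chromosomes", call. = FALSE)
  n <- nrow(counts)
  k <- ncol(counts)
  gm <- mean(counts)
  rm <- rowMeans(counts)
  msb <- k * sum((rm - gm)^2) / (n - 1)
  msw <- sum((counts - rm)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- msb / msw
  tibble::tibble(
    icc = max(icc, 0),
    f_statistic = f, df1 = n - 1, df2 = n * (k - 1),
    p_value = stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  )
}

#' Permuted-pool independence null for crossover counts
#'
#' Destroys inter-chromosomal covariance while preserving each
#' chromosome's marginal count distribution: every column is resampled
#' (with replacement) from its own pool of embryos.  Deterministic given
#' `seed`.
#'
#' @inheritParams variance_decomposition
#' @param seed Seed for the resampling (local to this call).
#' @return A matrix of the same shape as `counts`.
#' @export
permuted_null <- function(counts, seed = 1) {
  counts <- as.matrix(counts)
  withr::local_seed(seed)
  apply(counts, 2, function(col) sample(col, length(col), replace = TRUE))
}

#' Mean crossover count per meiosis
#'
#' Arithmetic mean of autosome-wide crossover counts per embryo, optionally
#' stratified by the parent of origin and restricted to euploid embryos.
#'
#' @inheritParams variance_decomposition
#' @param parent Optional character vector (one entry per row of `counts`)
#'   giving the parent of origin of each meiosis.
#' @param euploid Optional logical vector (one entry per row); only `TRUE`
#'   rows enter the mean.
#' @return A tibble with `parent`, `mean_crossovers`, `n_embryos`.
#' @export
mean_crossover_count <- function(counts, parent = NULL, euploid = NULL) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  parent <- parent %||% rep("all", length(tot))
  keep <- euploid %||% rep(TRUE, length(tot))
  if (!any(keep)) stop("need at least one euploid embryo", call. = FALSE)
  tibble::tibble(parent = parent[keep], total = tot[keep]) |>
    dplyr::group_by(.data$parent) |>
    dplyr::summarise(mean_crossovers = mean(.data$total),
      n_embryos = dplyr::n(), .groups = "drop")
}
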