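#' Posterior probability that a trisomy carries both parental homologs
#'
#' For a called maternal (paternal) trisomy, the BPH states are the trisomy
#' tuples containing both distinct homologs of the trisomic parent (e.g.
#' `(m0, m1, p0)` and `(m0, m1, p1)` for a maternal trisomy, 2 of its 6
#' states); the remaining states carry a single duplicated homolog (SPH).
#' At each site the BPH posterior mass is renormalized against the total
#' trisomy-class mass, and the statistic is the mean of this per-site ratio
#' along the chromosome.  BPH content is the signature of a meiotic-origin
#' error; SPH-only chromosomes are candidate mitotic errors.
#'
#' @param fit A `karyotype_fit` whose call (or `class` argument) is a
#'   trisomy.
#' @param class Trisomy class to interrogate; defaults to the fitted call.
#' @return A probability in `[0, 1]`.
#' @export
posterior_bph <- function(fit, class = NULL) {
  stopifnot(inherits(fit, "karyotype_fit"))
  class <- class %||% fit$call
  if (is.na(class) || !class %in% c("trisomy_maternal", "trisomy_paternal",
    "trisomy_x")) {
    stop("BPH posterior is defined only for trisomy calls", call. = FALSE)
  }
  states <- fit$states
  in_class <- states$class == class
  parent_pref <- if (class == "trisomy_paternal") "p" else "m"
  hapmat <- cbind(states$hap1, states$hap2, states$hap3)
  bph <- in_class & apply(hapmat, 1, function(h) {
    all(paste0(parent_pref, 0:1) %in% h)
  })
  cls_mass <- rowSums(fit$gamma[, in_class, drop = FALSE])
  bph_mass <- rowSums(fit$gamma[, bph, drop = FALSE])
  ok <- cls_mass > 1e-12
  if (!any(ok)) return(NA_real_)
  mean(bph_mass[ok] / cls_mass[ok])
}

#' Label trisomy calls as meiotic or candidate-mitotic
#'
#' Applies the BPH-posterior threshold `alpha`: trisomies with
#' `p_bph >= alpha` are labelled meiotic, the rest candidate mitotic.  The
#' shipped default `alpha = 0.340` is the threshold at which an inferred-
#' mitotic set of trisomies retains a null maternal-age effect in the
#' reference cohort; recalibrate with [calibrate_alpha()] when cohort data
#' are available.
#'
#' @param records A data frame with a `p_bph` column (e.g. one row per
#'   trisomy call).
#' @param alpha Threshold in `[0, 1]`.
#' @return The input with `origin` (`"meiotic"`/`"mitotic_candidate"`) and
#'   `alpha_used` columns appended.
#' @export
classify_origin <- function(records, alpha = 0.340) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1,
    "p_bph" %in% names(records))
  dplyr::mutate(tibble::as_tibble(records),
    origin = ifelse(.data$p_bph >= alpha, "meiotic", "mitotic_candidate"),
    alpha_used = alpha)
}

#' Calibrate the BPH threshold against the maternal-age effect
#'
#' Mitotic aneuploidies show no maternal-age effect, while meiotic ones rise
#' steeply with age.  For each threshold `alpha` on a grid of `grid_size`
#' points in `[0, 1]`, trisomies with `p_bph < alpha` are labelled mitotic,
#' the per-mother counts of affected embryos are regressed on maternal age
#' with a binomial (logistic) model, and the age effect is deemed
#' significantly positive when `beta - 2 * se(beta) > 0`.  The calibrated
#' threshold is the largest `alpha` that still maintains the null age
#' effect.
#'
#' @param records One row per embryo: columns `mother_id`, `maternal_age`,
#'   and `p_bph` (the embryo's trisomy BPH posterior, `NA` for embryos
#'   without a trisomy call).
#' @param grid_size Number of grid points (default 100).
#' @return A list of class `alpha_calibration`: `alpha` (the calibrated
#'   threshold) and `grid` (a tibble of `alpha`, `n_mitotic`, `beta`, `se`,
#'   `significant`).
#' @export
calibrate_alpha <- function(records, grid_size = 100) {
  stopifnot(all(c("mother_id", "maternal_age", "p_bph") %in% names(records)))
  if (length(unique(records$maternal_age)) < 2) {
    stop("need at least 2 distinct maternal ages", call. = FALSE)
  }
  if (!any(!is.na(records$p_bph))) {
    stop("need at least one trisomy record (non-missing p_bph)",
      call. = FALSE)
  }
  alphas <- seq(0, 1, length.out = grid_size)
  rows <- purrr::map_dfr(alphas, function(a) {
    per <- records |>
      dplyr::group_by(.data$mother_id, .data$maternal_age) |>
      dplyr::summarise(
        n = dplyr::n(),
        k = sum(!is.na(.data$p_bph) & .data$p_bph < a),
        .groups = "drop"
      )
    if (sum(per$k) == 0) {
      return(tibble::tibble(alpha = a, n_mitotic = 0, beta = NA_real_,
        se = NA_real_, significant = FALSE))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(k, n - k) ~ maternal_age,
        family = stats::binomial(), data = per)),
      error = function(e) NULL
    )
    if (is.null(fit) || !"maternal_age" %in% rownames(summary(fit)$coefficients)) {
      return(tibble::tibble(alpha = a, n_mitotic = sum(per$k),
        beta = NA_real_, se = NA_real_, significant = FALSE))
    }
    co <- summary(fit)$coefficients["maternal_age", ]
    tibble::tibble(alpha = a, n_mitotic = sum(per$k),
      beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
      significant = is.finite(co["Estimate"]) && is.finite(co["Std. Error"]) &&
        co["Estimate"] - 2 * co["Std. Error"] > 0)
  })
  null_ok <- !rows$significant
  if (all(rows$n_mitotic == 0)) {
    warning("no threshold yields any mitotic label; returning alpha = 1")
    alpha_star <- 1
  } else if (!any(null_ok)) {
    alpha_star <- alphas[1]
  } else {
    alpha_star <- max(alphas[null_ok])
  }
  structure(list(alpha = alpha_star, grid = rows),
    class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("<alpha_calibration> alpha* = %.3f (%d grid points)\n",
    x$alpha, nrow(x$grid)))
  invisible(x)
}

#' @export
tidy.alpha_calibration <- function(x, ...) x$grid
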