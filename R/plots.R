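#' Plot a karyotype fit
#'
#' BAF observations along the chromosome coloured by the MAP ploidy class,
#' with the call and fitted noise in the subtitle.
#'
#' @param object A `karyotype_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.karyotype_fit <- function(object, ...) {
  df <- tibble::tibble(
    pos = object$positions, baf = object$baf,
    map_class = object$map_class
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$baf,
    colour = .data$map_class)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "position (Mbp)", y = "B-allele frequency", colour = "MAP class",
      title = paste(object$embryo_id, object$chrom, sep = " / "),
      subtitle = sprintf("call: %s; pi0 = %.2f, sigma = %.2f",
        if (is.na(object$call)) "no-call" else object$call,
        object$noise$pi0, object$noise$sigma)
    ) +
    ggplot2::theme_minimal()
}

#' Per-site ploidy-class posterior track
#'
#' Stacked per-site posterior mass of each ploidy class along the
#' chromosome; useful for spotting segmental events.
#'
#' @param fit A `karyotype_fit`.
#' @return A ggplot object.
#' @export
plot_class_posteriors <- function(fit) {
  stopifnot(inherits(fit, "karyotype_fit"))
  df <- tibble::as_tibble(fit$class_site_posteriors) |>
    dplyr::mutate(pos = fit$positions) |>
    tidyr::pivot_longer(-"pos", names_to = "class", values_to = "posterior")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$posterior,
    fill = .data$class)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "position (Mbp)", y = "posterior", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot an alpha-calibration grid
#'
#' Age-effect estimate (with +/- 2 SE band) across the BPH-threshold grid,
#' with the calibrated threshold marked.
#'
#' @param object An `alpha_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alpha_calibration <- function(object, ...) {
  df <- object$grid[!is.na(object$grid$beta), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$beta - 2 * .data$se,
      ymax = .data$beta + 2 * .data$se), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$alpha, colour = "red") +
    ggplot2::labs(x = "BPH posterior threshold alpha",
      y = "maternal-age effect (logit scale)") +
    ggplot2::theme_minimal()
}
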