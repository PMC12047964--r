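#' Array-noise parameters of the BAF emission model
#'
#' `pi0` is the weight of the point masses at the intensity boundaries (the
#' fraction of fully homozygous genotypes observed at exactly 0 or 1) and
#' `sigma` the scale of the truncated-normal component on `[0, 1]`.
#'
#' @param pi0 Point-mass weight, in (0, 1).
#' @param sigma Truncated-normal scale, > 0.
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(0.5, 0.2)
#' @export
noise_params <- function(pi0, sigma) {
  stopifnot(is.numeric(pi0), length(pi0) == 1, pi0 > 0, pi0 < 1,
    is.numeric(sigma), length(sigma) == 1, sigma > 0)
  structure(list(pi0 = pi0, sigma = sigma), class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> pi0 = %.4g, sigma = %.4g\n", x$pi0, x$sigma))
  invisible(x)
}

# width of the exact-boundary bin used to put point masses and continuous
# densities on a common dominating measure (must match the C++ backend)
baf_atom_width <- 1e-6

as_noise <- function(noise) {
  if (inherits(noise, "noise_params")) return(noise)
  if (is.list(noise) || is.numeric(noise)) {
    return(noise_params(noise[["pi0"]], noise[["sigma"]]))
  }
  stop("cannot interpret `noise`", call. = FALSE)
}

#' Log-density of an observed BAF value under a hidden state
#'
#' The emission model given the copied haplotypes: with expected dosage
#' `mu = (M + P) / K`, the observation follows a truncated normal on
#' `[0, 1]` centred on `mu`, mixed with a point mass of weight `pi0` at the
#' boundary (at 0 when `mu = 0`, at 1 otherwise; see `else_atom`).  Under
#' nullisomy (`k = 0`) the observation is truncated normal around 1/2 with
#' no point mass.
#'
#' Boundary observations (`baf` exactly 0 or 1) are point-mass events and are
#' scored on the mixed dominating measure (atoms at 0 and 1 plus Lebesgue):
#' a state with an atom at the observed boundary contributes
#' `pi0 / w + (1 - pi0) * f(boundary)` with bin width `w = 1e-6` (below the
#' reporting precision of array intensities), while a state without one
#' contributes its continuous density there.  The width is a shared constant,
#' so it cancels between states except through atom presence; it is what
#' makes `pi0` identifiable by maximum likelihood.  Interior observations use
#' only the continuous part.  Missing observations return 0 (unit
#' likelihood).
#'
#' @param baf Observed BAF values in `[0, 1]` (`NA` = missing).
#' @param mu Conditional expected dosages (ignored where `k == 0`).
#' @param k Local copy numbers (0-3); recycled against `baf`.
#' @param noise A [noise_params()] object.
#' @param else_atom Placement of the boundary atom for intermediate dosages
#'   (`0 < mu < 1`): `"none"` (default) uses the pure truncated normal, so
#'   point masses occur only at homozygous dosages; `"delta1_as_printed"`
#'   adds a `pi0` atom at 1 for intermediate dosages as well.
#' @return Numeric vector of log-densities.
#' @examples
#' emission_logdensity(0.5, mu = NA, k = 0, noise = noise_params(0.5, 0.2))
#' @export
emission_logdensity <- function(baf, mu, k, noise,
                                else_atom = c("none", "delta1_as_printed")) {
  else_atom <- match.arg(else_atom)
  noise <- as_noise(noise)
  n <- max(length(baf), length(mu), length(k))
  baf <- rep_len(as.numeric(baf), n)
  mu <- rep_len(as.numeric(mu), n)
  k <- rep_len(as.integer(k), n)
  if (any(!is.na(baf) & (baf < 0 | baf > 1))) {
    stop("BAF values must lie in [0, 1]", call. = FALSE)
  }
  pi0 <- noise$pi0
  sigma <- noise$sigma
  tn <- function(x, m) {
    stats::dnorm(x, m, sigma, log = TRUE) -
      log(stats::pnorm(1, m, sigma) - stats::pnorm(0, m, sigma))
  }
  out <- numeric(n)
  miss <- is.na(baf)
  out[miss] <- 0
  i <- which(!miss)
  for (j in i) {
    b <- baf[j]
    if (k[j] == 0L) {
      out[j] <- tn(b, 0.5)
      next
    }
    m <- mu[j]
    lcont <- tn(b, m)
    atom_at <- if (m == 0) 0 else if (m == 1) 1 else {
      if (else_atom == "delta1_as_printed") 1 else NA_real_
    }
    if (is.na(atom_at)) {
      out[j] <- lcont
    } else if (b == atom_at) {
      out[j] <- log(pi0 / baf_atom_width + (1 - pi0) * exp(lcont))
    } else {
      out[j] <- log1p(-pi0) + lcont
    }
  }
  out
}

# states x sites matrix of emission log densities (C++ backend)
emission_matrix <- function(grid, states, baf, noise, else_atom) {
  dm <- dosage_matrix(grid, states)
  mu <- dm$mu
  mu[is.na(mu)] <- -1  # nullisomy rows; ignored when k == 0
  emission_matrix_cpp(mu, dm$k, as.numeric(baf), noise$pi0, noise$sigma,
    identical(else_atom, "delta1_as_printed"))
}
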