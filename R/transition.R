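#' Transition-model parameters
#'
#' Off-diagonal transition probabilities of the HMM scale linearly with the
#' physical gap between adjacent markers: rate `r` per bp between states of
#' the same ploidy class (a recombination-like switch of the copied
#' haplotype) and rate `a` per bp between ploidy classes, with `a << r` so
#' that an inter-class switch needs sustained evidence.
#'
#' @param r Within-ploidy transition rate per bp per generation
#'   (default `1e-8`, i.e. 1 cM/Mbp).
#' @param a Inter-ploidy transition rate per bp (default `1e-10`).
#' @return An object of class `transition_params`.
#' @examples
#' transition_params()
#' @export
transition_params <- function(r = 1e-8, a = 1e-10) {
  stopifnot(is.numeric(r), is.numeric(a), length(r) == 1, length(a) == 1)
  if (!(a > 0 && a < r && r < 1)) {
    stop("need 0 < a < r < 1", call. = FALSE)
  }
  structure(list(r = r, a = a), class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf("<transition_params> r = %.3g /bp, a = %.3g /bp\n", x$r, x$a))
  invisible(x)
}

#' Full transition matrix for one inter-site gap
#'
#' Off-diagonals are `r * d` between states of the same ploidy class and
#' `a * d` across classes; the diagonal absorbs the remainder so every row
#' sums to exactly 1.  For pathological gaps where the linear form would
#' exhaust a row (off-diagonal mass > 0.99) each off-diagonal switches to
#' the rate-to-probability transform `1 - exp(-rate * d)` and the row is
#' capped, keeping the matrix stochastic.
#'
#' @param group Vector of per-state ploidy-class labels (one entry per
#'   state); states with equal labels transit at rate `r`, others at `a`.
#' @param d Physical distance in bp (>= 0).
#' @param params A [transition_params()] object.
#' @return A `length(group)` x `length(group)` row-stochastic matrix.
#' @export
transition_matrix <- function(group, d, params = transition_params()) {
  stopifnot(d >= 0)
  S <- length(group)
  qs <- params$r * d
  qd <- params$a * d
  nG <- table(factor(group, levels = unique(group)))
  worst <- max(qs * (nG[as.character(group)] - 1) +
    qd * (S - nG[as.character(group)]))
  if (worst > 0.99) {
    qs <- 1 - exp(-params$r * d)
    qd <- 1 - exp(-params$a * d)
  }
  A <- matrix(qd, S, S)
  same <- outer(group, group, "==")
  A[same] <- qs
  diag(A) <- 0
  rs <- rowSums(A)
  cap <- rs > 0.99
  if (any(cap)) {
    A[cap, ] <- A[cap, , drop = FALSE] * (0.99 / rs[cap])
    rs[cap] <- 0.99
  }
  diag(A) <- 1 - rs
  A
}

#' Log transition probability between two hidden states
#'
#' @param state_j,state_k Row indices into the state table (or single-row
#'   state tibbles from [karyotype_states()]).
#' @param d Physical distance in bp (>= 0); `d = 0` forces a self-transition.
#' @param params A [transition_params()] object.
#' @param states The state table defining the full space (needed for the
#'   diagonal normalization); defaults to the autosome space.
#' @return The log transition probability.
#' @examples
#' st <- karyotype_states()
#' transition_logprob(4, 5, d = 1e6, states = st)
#' @export
transition_logprob <- function(state_j, state_k, d,
                               params = transition_params(),
                               states = karyotype_states()) {
  if (d < 0) stop("distance must be non-negative", call. = FALSE)
  idx <- function(s) {
    if (is.data.frame(s)) {
      i <- match(s$state[1], states$state)
      if (is.na(i)) stop("state not in the supplied state space", call. = FALSE)
      i
    } else {
      as.integer(s)
    }
  }
  j <- idx(state_j)
  kk <- idx(state_k)
  A <- transition_matrix(states$class, d, params)
  log(A[j, kk])
}
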