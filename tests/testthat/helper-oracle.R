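# Brute-force oracles and tiny fixtures shared across test files.

# A small deterministic site grid (no simulation involved).
toy_grid <- function(L = 3, chrom = "toy") {
  set_alleles <- function(bits) rep_len(bits, L)
  site_grid(
    chrom, seq(1e5, by = 5e4, length.out = L),
    m0 = set_alleles(c(0, 1, 1, 0)),
    m1 = set_alleles(c(1, 1, 0, 0)),
    p0 = set_alleles(c(0, 0, 1, 1)),
    p1 = set_alleles(c(1, 0, 0, 1))
  )
}

# Exhaustive-enumeration total likelihood: sums the joint probability of
# every hidden path explicitly (uniform prior over states).  Only feasible
# for tiny L; used as the correctness oracle for the forward recursion.
oracle_loglik <- function(grid, baf, noise, trans = transition_params(),
                          chromosome_type = "autosome",
                          else_atom = "none") {
  states <- karyotype_states(chromosome_type)
  S <- nrow(states)
  L <- nrow(grid)
  E <- matrix(0, S, L)
  for (s in seq_len(S)) {
    labs <- na.omit(c(states$hap1[s], states$hap2[s], states$hap3[s]))
    mu <- if (states$k[s] == 0) {
      rep(NA_real_, L)
    } else {
      Reduce(`+`, lapply(labs, function(h) grid[[h]])) / states$k[s]
    }
    E[s, ] <- exp(emission_logdensity(baf, mu, states$k[s], noise, else_atom))
  }
  d <- diff(grid$pos)
  A <- lapply(d, function(di) transition_matrix(states$class, di, trans))
  idx <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  p <- rep(1 / S, nrow(idx))
  for (i in seq_len(L)) p <- p * E[idx[, i], i]
  for (i in 2:L) p <- p * A[[i - 1]][cbind(idx[, i - 1], idx[, i])]
  log(sum(p))
}

# Minimal hand-built karyotype_fit for the segmental detector (no HMM run).
fake_fit <- function(map_class, positions, classes, site_posterior = NULL,
                     class_posteriors = NULL) {
  L <- length(map_class)
  stopifnot(length(positions) == L)
  csp <- matrix(0, L, length(classes), dimnames = list(NULL, classes))
  for (cl in classes) {
    csp[, cl] <- ifelse(map_class == cl, 0.95, 0.02)
  }
  if (!is.null(site_posterior)) {
    for (i in seq_len(L)) csp[i, map_class[i]] <- site_posterior[i]
  }
  cp <- class_posteriors %||% colMeans(csp)
  cp <- cp / sum(cp)
  structure(list(
    embryo_id = "fx", chrom = "chrF",
    map_class = map_class, positions = positions,
    class_site_posteriors = csp,
    class_posteriors = cp
  ), class = "karyotype_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
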