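#' Total log-likelihood of an embryo's BAF under the joint HMM
#'
#' Runs the scaled forward algorithm over the full hidden-state space (all
#' ploidy classes jointly), summing over every copying path.
#'
#' @param baf Embryo BAF: a data frame with `pos`/`baf` columns or a numeric
#'   vector aligned to the grid (`NA` = missing).
#' @param grid A [site_grid()].
#' @param noise A [noise_params()] object.
#' @param trans A [transition_params()] object.
#' @param chromosome_type `"autosome"`, `"X"` or `"Y"`.
#' @param classes Optional character vector restricting the state space to a
#'   subset of ploidy classes (used e.g. to score a single-class model).
#' @param else_atom See [emission_logdensity()].
#' @return The log-likelihood (a scalar).
#' @export
karyotype_loglik <- function(baf, grid, noise, trans = transition_params(),
                             chromosome_type = "autosome", classes = NULL,
                             else_atom = "none") {
  grid <- as_site_grid(grid)
  noise <- as_noise(noise)
  b <- align_baf(baf, grid)
  states <- karyotype_states(chromosome_type)
  if (!is.null(classes)) {
    bad <- setdiff(classes, states$class)
    if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "),
      call. = FALSE)
    states <- states[states$class %in% classes, ]
  }
  logE <- emission_matrix(grid, states, b, noise, else_atom)
  d <- diff(grid$pos)
  hmm_fb_cpp(logE, class_group(states), d, trans$r, trans$a, FALSE)$loglik
}

# integer ploidy-class group ids in the fixed enumeration order (transitions
# run at rate r within a class and a across classes)
class_group <- function(states) {
  as.integer(factor(states$class, levels = unique(states$class)))
}

#' Maximum-likelihood estimation of the array-noise parameters
#'
#' Maximizes the joint forward likelihood over `(pi0, sigma)` with a bounded
#' quasi-Newton search (L-BFGS-B), started from the best point of a fixed
#' 3 x 3 grid (`pi0` in 0.2/0.5/0.8, `sigma` in 0.05/0.15/0.3) so that the
#' estimate is deterministic.
#'
#' @inheritParams karyotype_loglik
#' @param bounds Named list with `pi0` and `sigma` ranges.
#' @param min_sites Minimum number of non-missing observations required.
#' @return A [noise_params()] object with attributes `convergence`
#'   (0 = converged) and `loglik`.
#' @export
fit_noise <- function(baf, grid, trans = transition_params(),
                      chromosome_type = "autosome",
                      bounds = list(pi0 = c(1e-3, 1 - 1e-3),
                                    sigma = c(5e-3, 0.5)),
                      min_sites = 50,
                      else_atom = "none") {
  grid <- as_site_grid(grid)
  b <- align_baf(baf, grid)
  if (sum(!is.na(b)) < min_sites) {
    stop("need at least ", min_sites, " non-missing sites to fit noise",
      call. = FALSE)
  }
  states <- karyotype_states(chromosome_type)
  dm <- dosage_matrix(grid, states)
  mu <- dm$mu
  mu[is.na(mu)] <- -1
  d <- diff(grid$pos)
  atom <- identical(else_atom, "delta1_as_printed")
  grp <- class_group(states)
  nll <- function(par) {
    logE <- emission_matrix_cpp(mu, dm$k, b, par[1], par[2], atom)
    -hmm_fb_cpp(logE, grp, d, trans$r, trans$a, FALSE)$loglik
  }
  starts <- expand.grid(pi0 = c(0.2, 0.5, 0.8), sigma = c(0.05, 0.15, 0.3))
  vals <- apply(starts, 1, nll)
  best <- as.numeric(starts[which.min(vals), ])
  opt <- stats::optim(best, nll, method = "L-BFGS-B",
    lower = c(bounds$pi0[1], bounds$sigma[1]),
    upper = c(bounds$pi0[2], bounds$sigma[2]),
    control = list(factr = 1e9))
  if (opt$value > min(vals) + 1e-9) {
    # local refine should never lose to its own start; keep the better point
    opt$par <- best
    opt$value <- min(vals)
    opt$convergence <- 52L
  }
  out <- noise_params(opt$par[1], opt$par[2])
  attr(out, "convergence") <- opt$convergence
  attr(out, "loglik") <- -opt$value
  out
}

#' Infer the karyotype of one embryo chromosome
#'
#' Runs the forward-backward algorithm over the joint state space, aggregates
#' per-site state posteriors into ploidy-class posteriors (the mean over
#' sites of the summed within-class posterior mass), extracts the per-site
#' MAP state path, and assigns a high-confidence call when the top class
#' posterior exceeds `posterior_threshold` and the Bayes factor against the
#' runner-up class is at least `min_bayes_factor`.
#'
#' @inheritParams karyotype_loglik
#' @param noise A [noise_params()] object, or `NULL` to fit it by maximum
#'   likelihood first (see [fit_noise()]).
#' @param posterior_threshold Minimum top-class posterior for a call (0.9).
#' @param min_bayes_factor Minimum ratio of top to second class posterior (2).
#' @param embryo_id,chrom Optional labels carried into the result (taken from
#'   `baf`/`grid` columns when present).
#' @param map_rule `"posterior"` (default): per-site posterior argmax, ties
#'   broken by the fixed state order; `"viterbi"`: global Viterbi path.
#' @return An object of class `karyotype_fit`; see [tidy.karyotype_fit()] and
#'   [glance.karyotype_fit()].
#' @examples
#' \donttest{
#' sim <- sim_parents(n_snps = 500, contig_len_bp = 5e6, seed = 1)
#' emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.1), seed = 2)
#' fit <- infer_karyotype(emb$baf, sim$phased, noise = noise_params(0.5, 0.1))
#' fit$call
#' }
#' @export
infer_karyotype <- function(baf, grid, noise = NULL,
                            trans = transition_params(),
                            chromosome_type = "autosome",
                            posterior_threshold = 0.9, min_bayes_factor = 2,
                            embryo_id = NULL, chrom = NULL,
                            map_rule = c("posterior", "viterbi"),
                            else_atom = "none") {
  map_rule <- match.arg(map_rule)
  grid <- as_site_grid(grid)
  if (is.data.frame(baf)) {
    embryo_id <- embryo_id %||% baf$embryo_id[1] %||% "embryo"
  }
  embryo_id <- embryo_id %||% "embryo"
  chrom <- chrom %||% grid$chrom[1]
  b <- align_baf(baf, grid)
  if (is.null(noise)) {
    noise <- fit_noise(b, grid, trans, chromosome_type, else_atom = else_atom)
  } else {
    noise <- as_noise(noise)
  }
  states <- karyotype_states(chromosome_type)
  logE <- emission_matrix(grid, states, b, noise, else_atom)
  d <- diff(grid$pos)
  fb <- hmm_fb_cpp(logE, class_group(states), d, trans$r, trans$a, TRUE)
  gamma <- t(fb$gamma)  # sites x states
  cls <- states$class
  class_site <- vapply(unique(cls), function(cl) {
    rowSums(gamma[, cls == cl, drop = FALSE])
  }, numeric(nrow(gamma)))
  class_post <- colMeans(class_site)
  class_post <- class_post / sum(class_post)
  ord <- order(class_post, decreasing = TRUE)
  top <- class_post[ord[1]]
  second <- class_post[ord[2]]
  bf <- if (second <= 0) Inf else top / second
  call <- if (top > posterior_threshold && bf >= min_bayes_factor) {
    names(class_post)[ord[1]]
  } else {
    NA_character_
  }
  map_idx <- if (map_rule == "posterior") {
    apply(gamma, 1, which.max)
  } else {
    viterbi_path(logE, states$class, d, trans)
  }
  structure(list(
    embryo_id = embryo_id, chrom = chrom,
    class_posteriors = class_post,
    call = call, bayes_factor = bf,
    noise = noise, trans = trans,
    chromosome_type = chromosome_type,
    states = states,
    gamma = gamma,
    class_site_posteriors = class_site,
    map_path = map_idx,
    map_class = states$class[map_idx],
    positions = grid$pos,
    baf = b,
    loglik = fb$loglik,
    else_atom = else_atom
  ), class = "karyotype_fit")
}

# Viterbi decoding in R (optional alternative to the per-site MAP rule)
viterbi_path <- function(logE, group, d, trans) {
  S <- nrow(logE)
  L <- ncol(logE)
  delta <- logE[, 1] - log(S)
  back <- matrix(0L, S, L)
  for (i in 2:L) {
    A <- log(transition_matrix(group, d[i - 1], trans))
    cand <- delta + A  # S x S: from j to k
    back[, i] <- apply(cand, 2, which.max)
    delta <- cand[cbind(back[, i], seq_len(S))] + logE[, i]
  }
  path <- integer(L)
  path[L] <- which.max(delta)
  for (i in L:2) path[i - 1] <- back[path[i], i]
  path
}

#' @export
print.karyotype_fit <- function(x, ...) {
  cat(sprintf("<karyotype_fit> %s / %s (%d sites)\n", x$embryo_id, x$chrom,
    length(x$positions)))
  cat(sprintf("  call: %s (bayes factor %.3g)\n",
    if (is.na(x$call)) "no-call" else x$call, x$bayes_factor))
  cat(sprintf("  noise: pi0 = %.3f, sigma = %.3f\n",
    x$noise$pi0, x$noise$sigma))
  cp <- sort(x$class_posteriors, decreasing = TRUE)
  cat("  class posteriors:\n")
  for (i in seq_along(cp)) {
    cat(sprintf("    %-24s %.4f\n", names(cp)[i], cp[i]))
  }
  invisible(x)
}

#' Tidy a karyotype fit into one row per ploidy class
#'
#' @param x A `karyotype_fit`.
#' @param ... Unused.
#' @return A tibble with `embryo_id`, `chrom`, `class`, `posterior`.
#' @export
tidy.karyotype_fit <- function(x, ...) {
  tibble::tibble(
    embryo_id = x$embryo_id, chrom = x$chrom,
    class = names(x$class_posteriors),
    posterior = unname(x$class_posteriors)
  )
}

#' One-row summary of a karyotype fit
#'
#' @param x A `karyotype_fit`.
#' @param ... Unused.
#' @return A one-row tibble: identifiers, call, top posterior, Bayes factor,
#'   fitted noise parameters, log-likelihood and the number of (non-missing)
#'   sites, plus one `posterior_<class>` column per ploidy class.
#' @export
glance.karyotype_fit <- function(x, ...) {
  cp <- as.list(x$class_posteriors)
  names(cp) <- paste0("posterior_", names(cp))
  dplyr::bind_cols(
    tibble::tibble(
      embryo_id = x$embryo_id, chrom = x$chrom,
      call = x$call,
      posterior_max = max(x$class_posteriors),
      bayes_factor = x$bayes_factor,
      pi0_hat = x$noise$pi0, sigma_hat = x$noise$sigma,
      loglik = x$loglik,
      n_sites = length(x$positions),
      n_observed = sum(!is.na(x$baf))
    ),
    tibble::as_tibble(cp)
  )
}

#' Karyotype inference across many embryos and chromosomes
#'
#' Convenience wrapper: splits a long BAF table by embryo (and chromosome,
#' when `grids` is a named list of per-chromosome site grids), fits noise and
#' infers the karyotype for each, and binds the [glance.karyotype_fit()]
#' rows.
#'
#' @param baf_tbl Long BAF table with columns `embryo_id`, `chrom`, `pos`,
#'   `baf`.
#' @param grids A single [site_grid()] or a named list keyed by chromosome.
#' @inheritParams infer_karyotype
#' @param keep_fits Keep the full `karyotype_fit` objects as an attribute
#'   `fits` of the result (default `FALSE`).
#' @return A tibble with one row per embryo x chromosome.
#' @export
infer_karyotypes <- function(baf_tbl, grids, noise = NULL,
                             trans = transition_params(),
                             posterior_threshold = 0.9, min_bayes_factor = 2,
                             keep_fits = FALSE,
                             else_atom = "none") {
  if (inherits(grids, "site_grid") || is.data.frame(grids)) {
    grids <- stats::setNames(list(as_site_grid(grids)),
      as_site_grid(grids)$chrom[1])
  }
  pieces <- baf_tbl |>
    dplyr::group_by(.data$embryo_id, .data$chrom) |>
    dplyr::group_split()
  fits <- purrr::map(pieces, function(p) {
    g <- grids[[as.character(p$chrom[1])]]
    if (is.null(g)) stop("no site grid for chromosome ", p$chrom[1],
      call. = FALSE)
    infer_karyotype(p, g, noise = noise, trans = trans,
      posterior_threshold = posterior_threshold,
      min_bayes_factor = min_bayes_factor,
      else_atom = else_atom)
  })
  out <- purrr::map_dfr(fits, glance.karyotype_fit)
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Embryo-level quality control of karyotype calls
#'
#' Flags embryos with inadequate data or outlying noise: an embryo is
#' excluded when it has nullisomy calls on `max_nullisomy` (default 5) or
#' more chromosomes, or when its mean fitted `sigma` lies more than
#' `sigma_sd` (default 3) standard deviations from the cohort-wide mean.
#' Per-chromosome no-calls (posterior below threshold or Bayes factor below
#' 2) are retained as no-calls; other chromosomes of the embryo are kept.
#'
#' @param calls A calls table as produced by [infer_karyotypes()] (needs
#'   `embryo_id`, `call`, `sigma_hat`).
#' @param max_nullisomy Nullisomy-call count at which an embryo is excluded.
#' @param sigma_sd Number of cohort SDs beyond which mean `sigma` excludes.
#' @return A tibble with one row per embryo: `embryo_id`, `n_chromosomes`,
#'   `n_nullisomy`, `mean_sigma`, `exclude`, `reasons`.
#' @export
qc_embryos <- function(calls, max_nullisomy = 5, sigma_sd = 3) {
  per <- calls |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(
      n_chromosomes = dplyr::n(),
      n_nullisomy = sum(.data$call %in% "nullisomy"),
      mean_sigma = mean(.data$sigma_hat),
      .groups = "drop"
    )
  if (nrow(per) < 2) {
    warning("cohort too small for the sigma outlier filter; skipping it")
    mu <- NA_real_
    sd_ <- NA_real_
  } else {
    mu <- mean(per$mean_sigma)
    sd_ <- stats::sd(per$mean_sigma)
  }
  per |>
    dplyr::mutate(
      null_fail = .data$n_nullisomy >= max_nullisomy,
      sigma_fail = !is.na(sd_) & sd_ > 0 &
        abs(.data$mean_sigma - mu) > sigma_sd * sd_,
      exclude = .data$null_fail | .data$sigma_fail,
      reasons = dplyr::case_when(
        .data$null_fail & .data$sigma_fail ~ "nullisomy_count;sigma_outlier",
        .data$null_fail ~ "nullisomy_count",
        .data$sigma_fail ~ "sigma_outlier",
        TRUE ~ ""
      )
    ) |>
    dplyr::select(-"null_fail", -"sigma_fail")
}
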