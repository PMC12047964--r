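#' Informative sites for parent-specific crossover calling
#'
#' A site is informative for a maternal crossover when the maternal
#' genotype is heterozygous and the paternal genotype homozygous (and
#' symmetrically for paternal crossovers): there the transmitted focal-
#' parent haplotype can be read from the embryo signal.
#'
#' @param grid A [site_grid()].
#' @param parent `"maternal"` or `"paternal"`.
#' @return Integer vector of row indices into `grid`.
#' @export
informative_sites <- function(grid, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  grid <- as_site_grid(grid)
  if (parent == "maternal") {
    which(grid$m0 != grid$m1 & grid$p0 == grid$p1)
  } else {
    which(grid$p0 != grid$p1 & grid$m0 == grid$m1)
  }
}

# per-site log-likelihoods of the embryo BAF under transmitted focal-parent
# allele x = 0 / 1, at the informative sites `idx` (disomy, other parent
# contributes its homozygous allele)
transmission_loglik <- function(baf, grid, idx, parent, noise, else_atom) {
  q <- if (parent == "maternal") grid$p0[idx] else grid$m0[idx]
  b <- baf[idx]
  list(
    l0 = emission_logdensity(b, (0 + q) / 2, 2, noise, else_atom),
    l1 = emission_logdensity(b, (1 + q) / 2, 2, noise, else_atom)
  )
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# per-site llr component: log P(same transmitted allele) - log P(different),
# marginalizing the transmitted allele x of the focal parent per site
site_dllr <- function(lt, ls) {
  same <- logsumexp2(lt$l0 + ls$l0, lt$l1 + ls$l1)
  diff <- logsumexp2(lt$l0 + ls$l1, lt$l1 + ls$l0)
  same - diff
}

#' Transmission log-likelihood ratio at a pair of informative sites
#'
#' Compares the likelihood that the template and a sibling embryo received
#' the *same* focal-parent allele at both sites of the pair against the
#' likelihood that they received *different* alleles, marginalizing the
#' transmitted allele per site under the emission model.  Positive values
#' support identical transmission across the pair; a sign flip along the
#' chromosome marks a crossover.
#'
#' @param template,sibling Embryo BAF (data frame with `pos`/`baf`, or a
#'   numeric vector aligned to `grid`).
#' @param sites Length-2 integer vector of grid row indices; both must be
#'   informative for `parent`.
#' @param grid A [site_grid()].
#' @param noise_t,noise_nt [noise_params()] for template and sibling.
#' @param parent `"maternal"` or `"paternal"`.
#' @param else_atom See [emission_logdensity()].
#' @return The log-likelihood ratio (a scalar; 0 when all observations are
#'   missing).
#' @export
llr_pair <- function(template, sibling, sites, grid, noise_t, noise_nt,
                     parent = c("maternal", "paternal"),
                     else_atom = "none") {
  parent <- match.arg(parent)
  grid <- as_site_grid(grid)
  stopifnot(length(sites) == 2)
  inf <- informative_sites(grid, parent)
  if (!all(sites %in% inf)) {
    stop("both sites must be informative for the ", parent, " parent",
      call. = FALSE)
  }
  bt <- align_baf(template, grid)
  bs <- align_baf(sibling, grid)
  lt <- transmission_loglik(bt, grid, sites, parent, as_noise(noise_t),
    else_atom)
  ls <- transmission_loglik(bs, grid, sites, parent, as_noise(noise_nt),
    else_atom)
  sum(site_dllr(lt, ls))
}

# candidate crossover intervals of one template relative to one sibling:
# sign changes of the pairwise llr across adjacent informative-site pairs,
# grouped into clusters spanning at most `max_cluster_pairs` pairs; odd
# parity => one crossover spanning the cluster
candidate_switches <- function(dllr, pos_inf, max_cluster_pairs = 5) {
  m <- length(dllr)
  if (m < 2) return(NULL)
  pair_llr <- dllr[-length(dllr)] + dllr[-1]  # one value per adjacent pair
  sgn <- sign(pair_llr)
  # zero llr (e.g. missing data) inherits the preceding informative sign
  for (j in seq_along(sgn)) {
    if (sgn[j] == 0 && j > 1) sgn[j] <- sgn[j - 1]
  }
  for (j in rev(seq_along(sgn))) {
    if (sgn[j] == 0 && j < length(sgn)) sgn[j] <- sgn[j + 1]
  }
  if (all(sgn == 0)) return(NULL)
  changes <- which(sgn[-length(sgn)] != sgn[-1])  # boundary between pair j, j+1
  if (!length(changes)) return(NULL)
  out <- list()
  i <- 1
  while (i <= length(changes)) {
    j1 <- changes[i]
    grp <- j1
    while (i < length(changes) && changes[i + 1] - j1 < max_cluster_pairs) {
      i <- i + 1
      grp <- c(grp, changes[i])
    }
    if (length(grp) %% 2 == 1) {
      jlast <- grp[length(grp)]
      out[[length(out) + 1]] <- c(left = pos_inf[j1],
        right = pos_inf[min(jlast + 2, length(pos_inf))])
    }
    i <- i + 1
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Call parent-specific crossovers across sibling embryos
#'
#' For every template embryo, compares transmitted focal-parent alleles
#' against each sibling via the pairwise transmission log-likelihood ratio
#' over adjacent informative sites, turns sign changes into candidate
#' switch clusters (clusters spanning up to `max_cluster_pairs` adjacent
#' pairs; an odd number of sign changes marks one crossover, an even number
#' none), and keeps a candidate only when it is supported by a strict
#' majority of the sibling embryos — a template crossover is visible
#' against every sibling, whereas a crossover in a single sibling is not.
#'
#' The reported interval is the intersection of the supporting candidate
#' intervals, each spanning from the informative site before the switch
#' cluster to the informative site after it.
#'
#' @param baf_tbl Long BAF table (`embryo_id`, `pos`, `baf`) of the embryos
#'   disomic for this chromosome (restrict to such embryos before calling).
#' @param grid A [site_grid()].
#' @param parent `"maternal"` or `"paternal"`.
#' @param noise A single [noise_params()] used for all embryos, a named list
#'   keyed by `embryo_id`, or `NULL` to fit per embryo.
#' @param min_siblings Minimum number of non-template disomic siblings
#'   required per template (default 3); chromosomes below it are skipped
#'   with a message.
#' @param max_cluster_pairs Switch-cluster span in adjacent informative
#'   pairs (default 5).
#' @param templates Embryo ids to use as templates (default: all).
#' @param else_atom See [emission_logdensity()].
#' @return A tibble of crossover calls: `parent`, `template_embryo_id`,
#'   `chrom`, `left_bp`, `right_bp`, `n_supporting_siblings`,
#'   `n_total_siblings`.
#' @export
call_crossovers <- function(baf_tbl, grid, parent = c("maternal", "paternal"),
                            noise = NULL, min_siblings = 3,
                            max_cluster_pairs = 5, templates = NULL,
                            else_atom = "none") {
  parent <- match.arg(parent)
  grid <- as_site_grid(grid)
  ids <- unique(baf_tbl$embryo_id)
  empty <- tibble::tibble(parent = character(),
    template_embryo_id = character(), chrom = character(),
    left_bp = numeric(), right_bp = numeric(),
    n_supporting_siblings = integer(), n_total_siblings = integer())
  if (length(ids) < min_siblings + 1) {
    message("skipping chromosome ", grid$chrom[1], ": only ", length(ids),
      " disomic embryos (< ", min_siblings + 1, ")")
    return(empty)
  }
  inf <- informative_sites(grid, parent)
  if (length(inf) < 3) {
    message("skipping chromosome ", grid$chrom[1],
      ": too few informative sites")
    return(empty)
  }
  bafs <- purrr::map(stats::setNames(ids, ids), function(id) {
    align_baf(baf_tbl[baf_tbl$embryo_id == id, ], grid)
  })
  get_noise <- function(id) {
    if (is.null(noise)) return(fit_noise(bafs[[id]], grid,
      else_atom = else_atom))
    if (inherits(noise, "noise_params")) return(noise)
    as_noise(noise[[id]])
  }
  noises <- purrr::map(stats::setNames(ids, ids), get_noise)
  tll <- purrr::map(stats::setNames(ids, ids), function(id) {
    transmission_loglik(bafs[[id]], grid, inf, parent, noises[[id]],
      else_atom)
  })
  pos_inf <- grid$pos[inf]
  templates <- templates %||% ids
  purrr::map_dfr(templates, function(t_id) {
    sibs <- setdiff(ids, t_id)
    cands <- purrr::map(sibs, function(s_id) {
      dllr <- site_dllr(tll[[t_id]], tll[[s_id]])
      candidate_switches(dllr, pos_inf, max_cluster_pairs)
    })
    names(cands) <- sibs
    rows <- purrr::imap_dfr(cands, function(m, s_id) {
      if (is.null(m)) return(NULL)
      tibble::tibble(sibling = s_id, left = m[, "left"], right = m[, "right"])
    })
    if (nrow(rows) == 0) return(NULL)
    rows <- dplyr::arrange(rows, .data$left, .data$right)
    # greedy overlap clustering on the running intersection
    grp <- integer(nrow(rows))
    g <- 0
    cur_right <- -Inf
    for (i in seq_len(nrow(rows))) {
      if (rows$left[i] >= cur_right) {
        g <- g + 1
        cur_right <- rows$right[i]
      } else {
        cur_right <- min(cur_right, rows$right[i])
      }
      grp[i] <- g
    }
    rows$grp <- grp
    rows |>
      dplyr::group_by(.data$grp) |>
      dplyr::summarise(
        left_bp = max(.data$left), right_bp = min(.data$right),
        n_supporting_siblings = dplyr::n_distinct(.data$sibling),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n_supporting_siblings > length(sibs) / 2) |>
      dplyr::transmute(
        parent = parent, template_embryo_id = t_id,
        chrom = grid$chrom[1],
        left_bp = .data$left_bp, right_bp = .data$right_bp,
        n_supporting_siblings = .data$n_supporting_siblings,
        n_total_siblings = length(sibs)
      )
  })
}

#' Crossover-count matrix from crossover calls
#'
#' @param calls A crossover-call table from [call_crossovers()] (possibly
#'   bound over chromosomes and parents).
#' @param embryo_ids Embryos to include as rows (defaults to those present);
#'   embryos without calls get zero counts.
#' @param chroms Chromosomes to include as columns (defaults to those
#'   present).
#' @return A named integer matrix, embryos x chromosomes.
#' @export
crossover_count_matrix <- function(calls, embryo_ids = NULL, chroms = NULL) {
  embryo_ids <- embryo_ids %||% sort(unique(calls$template_embryo_id))
  chroms <- chroms %||% sort(unique(calls$chrom))
  m <- matrix(0L, length(embryo_ids), length(chroms),
    dimnames = list(embryo_ids, chroms))
  if (nrow(calls)) {
    tab <- table(factor(calls$template_embryo_id, levels = embryo_ids),
      factor(calls$chrom, levels = chroms))
    m[] <- as.integer(tab)
  }
  m
}
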