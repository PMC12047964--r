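#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used to give every simulated replicate its
#' own reproducible stream: `child = (seed + 104729 * counter) mod (2^31 - 1)`,
#' mapped away from 0.
#'
#' @param seed Master seed (integer-valued scalar).
#' @param counter Replicate counter (integer-valued scalar or vector).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, counter) {
  s <- (as.double(seed) + 104729 * as.double(counter)) %% (2^31 - 1)
  as.integer(ifelse(s == 0, 1, s))
}

#' Simulate phased parental haplotypes for one contig
#'
#' Draws marker positions uniformly along the contig, per-site allele
#' frequencies from `af`, and the four parental haplotypes as independent
#' Bernoulli draws (Hardy-Weinberg equilibrium).  A second, phase-corrupted
#' copy of the grid is produced by applying switch errors independently to
#' each parent's haplotype pair: at each site a switch occurs with
#' probability `switch_error_rate` and swaps the two haplotypes from that
#' site onward.  The corrupted copy stands in for population-phased
#' haplotypes at inference time; the clean copy is the transmission truth.
#'
#' @param n_snps Number of markers (default 4000).
#' @param contig_len_bp Contig length in bp (default 35e6).
#' @param switch_error_rate Per-site phasing switch probability (default
#'   0.03, an upper bound for population-based phasing).
#' @param af Either a length-2 numeric range for uniform allele-frequency
#'   draws (default `c(0.05, 0.95)`) or a function `f(n)` returning `n`
#'   frequencies (e.g. sampled from an empirical array AF distribution).
#' @param chrom Chromosome label for the simulated contig.
#' @param seed Optional seed (local to this call).
#' @return A list with elements `truth` and `phased` (both [site_grid()]s)
#'   and `n_switches` (per-parent switch counts).
#' @examples
#' sim <- sim_parents(n_snps = 100, contig_len_bp = 1e6, seed = 1)
#' @export
sim_parents <- function(n_snps = 4000, contig_len_bp = 35e6,
                        switch_error_rate = 0.03, af = c(0.05, 0.95),
                        chrom = "sim1", seed = NULL) {
  stopifnot(n_snps >= 2, switch_error_rate >= 0, switch_error_rate <= 0.5)
  if (!is.null(seed)) withr::local_seed(seed)
  pos <- sort(sample.int(contig_len_bp, n_snps))
  freq <- if (is.function(af)) af(n_snps) else stats::runif(n_snps, af[1], af[2])
  haps <- replicate(4, stats::rbinom(n_snps, 1, freq))
  truth <- site_grid(chrom, pos, haps[, 1], haps[, 2], haps[, 3], haps[, 4],
    contig_len_bp = contig_len_bp)
  apply_switches <- function(h0, h1) {
    sw <- stats::rbinom(n_snps - 1, 1, switch_error_rate)
    flip <- c(0, cumsum(sw)) %% 2 == 1
    list(h0 = ifelse(flip, h1, h0), h1 = ifelse(flip, h0, h1),
      n = sum(sw))
  }
  m <- apply_switches(truth$m0, truth$m1)
  p <- apply_switches(truth$p0, truth$p1)
  phased <- site_grid(chrom, pos, m$h0, m$h1, p$h0, p$h1,
    contig_len_bp = contig_len_bp)
  list(truth = truth, phased = phased,
    n_switches = c(maternal = m$n, paternal = p$n))
}

#' Simulate one meiotic transmission from a parent
#'
#' Crossovers occur as a Poisson process along the contig with rate `r` per
#' bp (so the expected count is `r * contig_len_bp`); the transmitted
#' haplotype alternates between the parent's two haplotypes at each
#' crossover.
#'
#' @param grid A truth [site_grid()].
#' @param parent `"maternal"` or `"paternal"`.
#' @param r Crossover rate per bp (default 1e-8).
#' @param n_crossovers Force an exact crossover count (otherwise Poisson).
#' @param crossover_positions Force exact crossover positions in bp.
#' @param start_hap Starting haplotype index (0/1; default random).
#' @param seed Optional seed (local to this call).
#' @return A list: `hap` (0/1 haplotype index per site), `alleles`
#'   (transmitted allele per site), `crossovers` (positions in bp), `parent`.
#' @export
sim_meiosis <- function(grid, parent = c("maternal", "paternal"), r = 1e-8,
                        n_crossovers = NULL, crossover_positions = NULL,
                        start_hap = NULL, seed = NULL) {
  parent <- match.arg(parent)
  if (!is.null(seed)) withr::local_seed(seed)
  len <- contig_length(grid)
  if (is.null(crossover_positions)) {
    n_co <- n_crossovers %||% stats::rpois(1, r * len)
    crossover_positions <- sort(stats::runif(n_co, 0, len))
  } else {
    crossover_positions <- sort(crossover_positions)
  }
  start_hap <- start_hap %||% stats::rbinom(1, 1, 0.5)
  n_before <- findInterval(grid$pos, crossover_positions)
  hap <- (start_hap + n_before) %% 2
  h0 <- if (parent == "maternal") grid$m0 else grid$p0
  h1 <- if (parent == "maternal") grid$m1 else grid$p1
  list(hap = hap, alleles = ifelse(hap == 0, h0, h1),
    crossovers = crossover_positions, parent = parent)
}

#' Draw BAF observations from the emission model
#'
#' Samples one observation per site given the expected dosages and copy
#' numbers: truncated normal around 1/2 for `k = 0`; otherwise a boundary
#' point mass with probability `pi0` at homozygous dosages (at 0 when
#' `mu = 0`, at 1 when `mu = 1`) and a truncated normal around `mu` with
#' probability `1 - pi0`.  Intermediate dosages draw the pure truncated
#' normal unless `else_atom = "delta1_as_printed"`, which adds the `pi0`
#' atom at 1 there too (matching that emission convention).  With
#' `noise = NULL` the observation is the noiseless dosage itself.
#'
#' @param mu Expected dosages (ignored where `k == 0`).
#' @param k Copy numbers (recycled).
#' @param noise A [noise_params()] object or `NULL` for noiseless values.
#' @param else_atom See [emission_logdensity()].
#' @return Numeric vector of BAF values in `[0, 1]`.
#' @export
draw_baf <- function(mu, k, noise = NULL,
                     else_atom = c("none", "delta1_as_printed")) {
  else_atom <- match.arg(else_atom)
  n <- max(length(mu), length(k))
  mu <- rep_len(as.numeric(mu), n)
  k <- rep_len(as.integer(k), n)
  if (is.null(noise)) {
    return(ifelse(k == 0L, 0.5, mu))
  }
  noise <- as_noise(noise)
  sigma <- noise$sigma
  tn_draw <- function(m) {
    lo <- stats::pnorm(0, m, sigma)
    hi <- stats::pnorm(1, m, sigma)
    u <- stats::runif(length(m))
    pmin(pmax(stats::qnorm(lo + u * (hi - lo), m, sigma), 0), 1)
  }
  centre <- ifelse(k == 0L, 0.5, mu)
  atom_at <- rep(NA_real_, n)
  atom_at[k > 0L & mu == 0] <- 0
  atom_at[k > 0L & mu == 1] <- 1
  if (else_atom == "delta1_as_printed") {
    atom_at[k > 0L & mu > 0 & mu < 1] <- 1
  }
  hit <- !is.na(atom_at) & stats::runif(n) < noise$pi0
  b <- numeric(n)
  b[hit] <- atom_at[hit]
  b[!hit] <- tn_draw(centre[!hit])
  b
}

# internal: strand set (list of meiosis results) for a ploidy class
sim_strands <- function(grid, class, r, origin = c("BPH", "SPH")) {
  origin <- match.arg(origin)
  mei <- function(parent, ...) sim_meiosis(grid, parent, r = r, ...)
  switch(class,
    nullisomy = list(),
    disomy = list(mei("maternal"), mei("paternal")),
    monosomy_maternal_loss = list(mei("paternal")),
    monosomy_paternal_loss = list(mei("maternal")),
    trisomy_maternal = {
      extra <- if (origin == "BPH") {
        list(mei("maternal", start_hap = 0), mei("maternal", start_hap = 1))
      } else {
        one <- mei("maternal")
        list(one, one)
      }
      c(extra, list(mei("paternal")))
    },
    trisomy_paternal = {
      extra <- if (origin == "BPH") {
        list(mei("paternal", start_hap = 0), mei("paternal", start_hap = 1))
      } else {
        one <- mei("paternal")
        list(one, one)
      }
      c(list(mei("maternal")), extra)
    },
    stop("unsupported class for simulation: ", class, call. = FALSE)
  )
}

strand_mu <- function(strands, n_sites) {
  k <- length(strands)
  if (k == 0) {
    return(list(mu = rep(NA_real_, n_sites), k = 0L))
  }
  tot <- Reduce(`+`, purrr::map(strands, "alleles"))
  list(mu = tot / k, k = as.integer(k))
}

#' Simulate an embryo chromosome under a given karyotype
#'
#' Builds the transmitted strand set for the class (meioses with crossovers
#' at rate `r`), forms the per-site expected dosage, and draws BAF
#' observations from the emission model via [draw_baf()].  Trisomies carry
#' either both parental homologs (`origin = "BPH"`, two independent meioses
#' of the trisomic parent, the meiotic signature) or a duplicated single
#' homolog (`origin = "SPH"`, the mitotic signature).
#'
#' @param grid A truth [site_grid()].
#' @param class Ploidy class: `"nullisomy"`, `"monosomy_maternal_loss"`,
#'   `"monosomy_paternal_loss"`, `"disomy"`, `"trisomy_maternal"`,
#'   `"trisomy_paternal"`.
#' @param noise A [noise_params()] object (`NULL` for noiseless dosages).
#' @param origin Trisomy homolog content, `"BPH"` (default) or `"SPH"`.
#' @param r Crossover rate per bp for the simulated meioses.
#' @param embryo_id Identifier stored in the output table.
#' @param seed Optional seed (local to this call).
#' @param else_atom See [emission_logdensity()].
#' @return A list with `baf` (tibble `embryo_id`, `chrom`, `pos`, `baf`) and
#'   `truth` (class, origin, crossover positions per strand, noise used).
#' @export
sim_embryo <- function(grid, class, noise = noise_params(0.5, 0.2),
                       origin = "BPH", r = 1e-8, embryo_id = "embryo1",
                       seed = NULL, else_atom = "none") {
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- as_site_grid(grid)
  strands <- sim_strands(grid, class, r, origin)
  sm <- strand_mu(strands, nrow(grid))
  b <- draw_baf(sm$mu, sm$k, noise, else_atom)
  list(
    baf = tibble::tibble(embryo_id = embryo_id, chrom = grid$chrom,
      pos = grid$pos, baf = b),
    truth = list(embryo_id = embryo_id, true_class = class,
      true_origin = if (grepl("^trisomy", class)) origin else NA_character_,
      crossovers = purrr::map(strands,
        ~ list(parent = .x$parent, positions = .x$crossovers)),
      noise = noise)
  )
}

#' Simulate a multi-cell mosaic biopsy
#'
#' All cells share the same transmitted haplotypes (one embryo); a random
#' (or fixed) number of cells carries the focal aneuploidy, derived from the
#' disomic strand set by dropping the lost homolog (monosomy) or duplicating
#' the transmitted homolog of the affected parent (trisomy, mitotic-style).
#' Each cell's BAF vector is drawn independently from the emission model and
#' the biopsy signal is the per-site arithmetic mean across cells.
#'
#' @param grid A truth [site_grid()].
#' @param aneuploid_class The focal aneuploidy class (a monosomy or trisomy
#'   class label as in [sim_embryo()]).
#' @param n_cells Biopsy size (typically 5 or 10).
#' @param p_mosaic Expected aneuploid cell fraction; the aneuploid cell
#'   count is drawn Binomial(`n_cells`, `p_mosaic`) unless `n_aneuploid`
#'   fixes it.
#' @param n_aneuploid Optional fixed number of aneuploid cells.
#' @param noise A [noise_params()] object.
#' @param r Crossover rate per bp for the underlying meioses.
#' @param embryo_id Identifier stored in the output table.
#' @param seed Optional seed (local to this call).
#' @param else_atom See [emission_logdensity()].
#' @return As [sim_embryo()], with `truth$n_aneuploid_cells` and
#'   `truth$n_cells` recorded.
#' @export
sim_mosaic_biopsy <- function(grid, aneuploid_class, n_cells = 10,
                              p_mosaic = NULL, n_aneuploid = NULL,
                              noise = noise_params(0.5, 0.2), r = 1e-8,
                              embryo_id = "embryo1", seed = NULL,
                              else_atom = "none") {
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- as_site_grid(grid)
  n_aneu <- n_aneuploid %||% stats::rbinom(1, n_cells, p_mosaic)
  dis <- sim_strands(grid, "disomy", r)
  names(dis) <- c("maternal", "paternal")
  aneu <- switch(aneuploid_class,
    monosomy_maternal_loss = dis["paternal"],
    monosomy_paternal_loss = dis["maternal"],
    trisomy_maternal = c(dis, dis["maternal"]),
    trisomy_paternal = c(dis, dis["paternal"]),
    stop("unsupported mosaic class: ", aneuploid_class, call. = FALSE)
  )
  mu_d <- strand_mu(dis, nrow(grid))
  mu_a <- strand_mu(aneu, nrow(grid))
  cells <- c(
    replicate(n_cells - n_aneu,
      draw_baf(mu_d$mu, mu_d$k, noise, else_atom), simplify = FALSE),
    replicate(n_aneu,
      draw_baf(mu_a$mu, mu_a$k, noise, else_atom), simplify = FALSE)
  )
  b <- Reduce(`+`, cells) / n_cells
  list(
    baf = tibble::tibble(embryo_id = embryo_id, chrom = grid$chrom,
      pos = grid$pos, baf = b),
    truth = list(embryo_id = embryo_id, true_class = aneuploid_class,
      n_cells = n_cells, n_aneuploid_cells = n_aneu, noise = noise)
  )
}

#' Simulate an embryo carrying one segmental aneuploidy
#'
#' The chromosome is disomic except inside `[start_bp, end_bp)`, where the
#' dosage follows the segmental class (homolog dropped for a monosomy,
#' transmitted homolog duplicated for a trisomy).
#'
#' @inheritParams sim_mosaic_biopsy
#' @param class Segmental class (monosomy or trisomy label).
#' @param start_bp,end_bp Segment bounds in bp (`0 <= start < end <= contig
#'   length`); both `NULL` draws a random 6-10 Mbp segment.
#' @return As [sim_embryo()], with `truth$segment` recording the interval.
#' @export
sim_segmental <- function(grid, class, start_bp = NULL, end_bp = NULL,
                          noise = noise_params(0.5, 0.2), r = 1e-8,
                          embryo_id = "embryo1", seed = NULL,
                          else_atom = "none") {
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- as_site_grid(grid)
  len <- contig_length(grid)
  if (is.null(start_bp)) {
    seg_len <- stats::runif(1, 6e6, min(1e7, len))
    start_bp <- stats::runif(1, 0, len - seg_len)
    end_bp <- start_bp + seg_len
  }
  stopifnot(start_bp >= 0, end_bp > start_bp, end_bp <= len)
  dis <- sim_strands(grid, "disomy", r)
  names(dis) <- c("maternal", "paternal")
  aneu <- switch(class,
    monosomy_maternal_loss = dis["paternal"],
    monosomy_paternal_loss = dis["maternal"],
    trisomy_maternal = c(dis, dis["maternal"]),
    trisomy_paternal = c(dis, dis["paternal"]),
    stop("unsupported segmental class: ", class, call. = FALSE)
  )
  mu_d <- strand_mu(dis, nrow(grid))
  mu_a <- strand_mu(aneu, nrow(grid))
  inside <- grid$pos >= start_bp & grid$pos < end_bp
  mu <- ifelse(inside, mu_a$mu, mu_d$mu)
  k <- ifelse(inside, mu_a$k, mu_d$k)
  b <- draw_baf(mu, k, noise, else_atom)
  list(
    baf = tibble::tibble(embryo_id = embryo_id, chrom = grid$chrom,
      pos = grid$pos, baf = b),
    truth = list(embryo_id = embryo_id, true_class = "segmental",
      segment = list(class = class, start_bp = start_bp, end_bp = end_bp,
        n_snps = sum(inside)),
      noise = noise)
  )
}

#' Simulate a family of disomic sibling embryos
#'
#' Convenience generator for the crossover caller: each sibling is a
#' disomic embryo with its own maternal and paternal meioses on the shared
#' parental grid.
#'
#' @param grid A truth [site_grid()].
#' @param n_embryos Number of sibling embryos.
#' @param noise A [noise_params()] object or `NULL` for noiseless values.
#' @param r Crossover rate per bp.
#' @param seed Optional seed (local to this call).
#' @param crossovers Optional list (one element per embryo) of lists with
#'   `maternal` and/or `paternal` crossover positions to force.
#' @param else_atom See [emission_logdensity()].
#' @return A list with `baf` (long tibble over all embryos) and `truth`
#'   (per-embryo crossover positions by parent).
#' @export
sim_family <- function(grid, n_embryos = 5, noise = NULL, r = 1e-8,
                       seed = NULL, crossovers = NULL,
                       else_atom = "none") {
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- as_site_grid(grid)
  sims <- purrr::map(seq_len(n_embryos), function(i) {
    forced <- if (!is.null(crossovers) && length(crossovers) >= i) {
      crossovers[[i]]
    } else {
      NULL
    }
    mat <- sim_meiosis(grid, "maternal", r = r,
      crossover_positions = forced$maternal)
    pat <- sim_meiosis(grid, "paternal", r = r,
      crossover_positions = forced$paternal)
    sm <- strand_mu(list(mat, pat), nrow(grid))
    b <- draw_baf(sm$mu, sm$k, noise, else_atom)
    list(
      baf = tibble::tibble(embryo_id = sprintf("embryo%02d", i),
        chrom = grid$chrom, pos = grid$pos, baf = b),
      truth = list(embryo_id = sprintf("embryo%02d", i),
        maternal = mat$crossovers, paternal = pat$crossovers,
        maternal_start_hap = mat$hap[1], paternal_start_hap = pat$hap[1])
    )
  })
  list(baf = purrr::map_dfr(sims, "baf"), truth = purrr::map(sims, "truth"))
}
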