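#' Hidden-state space of the haplotype-copying HMM
#'
#' Each hidden state is a tuple of parental haplotype labels (drawn from
#' `m0`, `m1`, `p0`, `p1`, with repetition allowed for trisomies) naming which
#' haplotypes the embryo chromosome copies at a locus.  States are grouped
#' into ploidy classes; the tuple size `k` is the local copy number.
#'
#' For autosomes the six classes are: nullisomy (empty tuple), monosomy with
#' maternal loss (a single paternal haplotype), monosomy with paternal loss
#' (a single maternal haplotype), disomy (one haplotype from each parent),
#' maternal trisomy (two maternal slots, one paternal) and paternal trisomy
#' (one maternal slot, two paternal).  The X chromosome uses a reduced space
#' reflecting a single possible paternal X (`p0`), and the Y chromosome has
#' only absence/presence of `p0`.
#'
#' @param chromosome_type `"autosome"`, `"X"` or `"Y"`.
#' @return A tibble with one row per hidden state, in a fixed documented
#'   order (this order breaks MAP ties deterministically): columns `class`,
#'   `state` (label such as `"m0/p1"`), `hap1`, `hap2`, `hap3` (haplotype
#'   labels or `NA`), and `k` (tuple size, 0-3).
#' @examples
#' karyotype_states()
#' karyotype_states("Y")
#' @export
karyotype_states <- function(chromosome_type = c("autosome", "X", "Y")) {
  chromosome_type <- match.arg(chromosome_type)
  st <- function(class, ...) {
    tuples <- list(...)
    tibble::tibble(
      class = class,
      hap1 = purrr::map_chr(tuples, ~ .x[1] %||% NA_character_),
      hap2 = purrr::map_chr(tuples, ~ if (length(.x) >= 2) .x[2] else NA_character_),
      hap3 = purrr::map_chr(tuples, ~ if (length(.x) >= 3) .x[3] else NA_character_),
      k = purrr::map_int(tuples, length)
    )
  }
  tab <- switch(chromosome_type,
    autosome = dplyr::bind_rows(
      st("nullisomy", character(0)),
      st("monosomy_maternal_loss", "p0", "p1"),
      st("monosomy_paternal_loss", "m0", "m1"),
      st("disomy",
        c("m0", "p0"), c("m0", "p1"), c("m1", "p0"), c("m1", "p1")),
      st("trisomy_maternal",
        c("m0", "m0", "p0"), c("m0", "m1", "p0"), c("m1", "m1", "p0"),
        c("m0", "m0", "p1"), c("m0", "m1", "p1"), c("m1", "m1", "p1")),
      st("trisomy_paternal",
        c("m0", "p0", "p0"), c("m0", "p0", "p1"), c("m0", "p1", "p1"),
        c("m1", "p0", "p0"), c("m1", "p0", "p1"), c("m1", "p1", "p1"))
    ),
    X = dplyr::bind_rows(
      st("loss_x", character(0)),
      st("single_paternal_x", "p0"),
      st("single_maternal_x", "m0", "m1"),
      st("disomy_biparental_x", c("m0", "p0"), c("m1", "p0")),
      st("upd_maternal_x", c("m0", "m0"), c("m0", "m1"), c("m1", "m1")),
      st("trisomy_x",
        c("m0", "m0", "p0"), c("m0", "m1", "p0"), c("m1", "m1", "p0"))
    ),
    Y = dplyr::bind_rows(
      st("loss_y", character(0)),
      st("presence_y", "p0")
    )
  )
  tab$state <- ifelse(
    tab$k == 0L, "-",
    paste_drop_na(tab$hap1, tab$hap2, tab$hap3)
  )
  tab[, c("class", "state", "hap1", "hap2", "hap3", "k")]
}

paste_drop_na <- function(a, b, c) {
  vapply(seq_along(a), function(i) {
    x <- c(a[i], b[i], c[i])
    paste(x[!is.na(x)], collapse = "/")
  }, character(1))
}

#' Enumerate the hidden states of one ploidy class
#'
#' @param ploidy_class A class label as used by [karyotype_states()], e.g.
#'   `"disomy"`, `"trisomy_maternal"`, `"presence_y"`.
#' @param chromosome_type `"autosome"`, `"X"` or `"Y"`.
#' @return The rows of [karyotype_states()] belonging to that class, in the
#'   fixed enumeration order.
#' @examples
#' enumerate_states("disomy", "autosome")
#' @export
enumerate_states <- function(ploidy_class, chromosome_type = "autosome") {
  tab <- karyotype_states(chromosome_type)
  if (!ploidy_class %in% tab$class) {
    stop("unknown ploidy class '", ploidy_class, "' for chromosome type '",
      chromosome_type, "'", call. = FALSE)
  }
  tab[tab$class == ploidy_class, ]
}

#' Per-state expected allelic dosage along a site grid
#'
#' Computes, for every hidden state and site, the conditional expected BAF
#' mu = (M + P) / K, where M and P are the summed alternative-allele counts
#' of the copied maternal and paternal haplotypes.  Nullisomy rows (k = 0)
#' are returned as `NA`.
#'
#' @param grid A site grid (see [site_grid()]).
#' @param states A state table from [karyotype_states()].
#' @return A list with `mu` (states x sites matrix) and `k` (integer vector).
#' @keywords internal
dosage_matrix <- function(grid, states) {
  hap <- rbind(m0 = grid$m0, m1 = grid$m1, p0 = grid$p0, p1 = grid$p1)
  L <- ncol(hap)
  S <- nrow(states)
  mu <- matrix(NA_real_, nrow = S, ncol = L)
  for (s in seq_len(S)) {
    if (states$k[s] == 0L) next
    labs <- stats::na.omit(c(states$hap1[s], states$hap2[s], states$hap3[s]))
    tot <- colSums(hap[labs, , drop = FALSE])
    mu[s, ] <- tot / states$k[s]
  }
  list(mu = mu, k = as.integer(states$k))
}
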