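#' Construct and validate a phased parental site grid
#'
#' A site grid is the per-chromosome marker scaffold the whole package works
#' on: ordered physical positions plus the four phased parental haplotype
#' allele vectors (`m0`, `m1` maternal; `p0`, `p1` paternal; alleles coded
#' 0/1).  Sites at which any required parental allele is missing are dropped
#' (with a message), since the copying model needs all four alleles.
#'
#' @param chrom Chromosome label (length 1).
#' @param pos Integer-valued physical positions in bp, strictly increasing.
#' @param m0,m1,p0,p1 Binary allele vectors, one entry per position.
#' @param contig_len_bp Optional contig length in bp (defaults to `max(pos)`),
#'   stored as an attribute and used by the simulator and transition model.
#' @return A tibble of class `site_grid` with columns
#'   `chrom`, `pos`, `m0`, `m1`, `p0`, `p1`.
#' @examples
#' site_grid("chr21", c(100, 200, 300),
#'   m0 = c(0, 1, 0), m1 = c(1, 1, 0),
#'   p0 = c(0, 0, 1), p1 = c(0, 0, 1))
#' @export
site_grid <- function(chrom, pos, m0, m1, p0, p1, contig_len_bp = NULL) {
  stopifnot(length(chrom) == 1)
  n <- length(pos)
  if (!all(lengths(list(m0, m1, p0, p1)) == n)) {
    stop("all four haplotype vectors must match the number of positions",
      call. = FALSE)
  }
  g <- tibble::tibble(
    chrom = as.character(chrom), pos = as.numeric(pos),
    m0 = as.numeric(m0), m1 = as.numeric(m1),
    p0 = as.numeric(p0), p1 = as.numeric(p1)
  )
  drop <- !stats::complete.cases(g[, c("m0", "m1", "p0", "p1")])
  if (any(drop)) {
    message("dropping ", sum(drop), " site(s) with missing parental alleles")
    g <- g[!drop, ]
  }
  validate_site_grid(g)
  attr(g, "contig_len_bp") <- contig_len_bp %||% max(g$pos)
  class(g) <- c("site_grid", class(g))
  g
}

validate_site_grid <- function(g) {
  if (nrow(g) < 2) stop("a site grid needs at least 2 sites", call. = FALSE)
  if (is.unsorted(g$pos, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  al <- as.matrix(g[, c("m0", "m1", "p0", "p1")])
  if (!all(al %in% c(0, 1))) {
    stop("haplotype alleles must be 0 or 1", call. = FALSE)
  }
  invisible(g)
}

as_site_grid <- function(g, contig_len_bp = NULL) {
  if (inherits(g, "site_grid")) return(g)
  need <- c("chrom", "pos", "m0", "m1", "p0", "p1")
  if (!all(need %in% names(g))) {
    stop("a site grid needs columns: ", paste(need, collapse = ", "),
      call. = FALSE)
  }
  site_grid(g$chrom[1], g$pos, g$m0, g$m1, g$p0, g$p1,
    contig_len_bp = contig_len_bp %||% attr(g, "contig_len_bp"))
}

contig_length <- function(grid) {
  attr(grid, "contig_len_bp") %||% max(grid$pos)
}

#' Align an embryo BAF table to a site grid
#'
#' Joins an embryo's BAF observations to the grid by position; grid sites
#' with no observation become missing (`NA`) and contribute unit likelihood.
#'
#' @param baf A data frame with columns `pos` and `baf` (values in `[0, 1]`
#'   or `NA`); extra columns (`embryo_id`, `chrom`) are ignored.
#' @param grid A [site_grid()].
#' @return A numeric vector of length `nrow(grid)` with `NA` for missing.
#' @export
align_baf <- function(baf, grid) {
  if (is.numeric(baf)) {
    if (length(baf) != nrow(grid)) {
      stop("numeric baf must have one value per grid site", call. = FALSE)
    }
    b <- as.numeric(baf)
  } else {
    stopifnot(all(c("pos", "baf") %in% names(baf)))
    b <- baf$baf[match(grid$pos, baf$pos)]
  }
  ok <- is.na(b) | (b >= 0 & b <= 1)
  if (!all(ok)) stop("BAF values must lie in [0, 1]", call. = FALSE)
  b
}
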