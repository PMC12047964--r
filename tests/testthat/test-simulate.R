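test_that("child_seed is deterministic, vectorized and in range", {
  expect_identical(child_seed(1, 1:5), child_seed(1, 1:5))
  expect_false(any(duplicated(child_seed(1, 1:1000))))
  s <- child_seed(123, 0:500)
  expect_true(all(s >= 1 & s <= 2^31 - 2))
  expect_type(s, "integer")
})

test_that("sim_parents is seeded and reproducible", {
  a <- sim_parents(n_snps = 500, seed = 1)
  b <- sim_parents(n_snps = 500, seed = 1)
  expect_identical(a$truth, b$truth)
  expect_identical(a$phased, b$phased)
  expect_false(identical(a$truth, sim_parents(n_snps = 500, seed = 2)$truth))
  # positions sorted and within the contig
  expect_true(all(diff(a$truth$pos) > 0))
  expect_lte(max(a$truth$pos), 35e6)
})

test_that("switch errors occur at the configured per-site rate", {
  counts <- vapply(1:30, function(i) {
    sum(sim_parents(n_snps = 1000, switch_error_rate = 0.03,
      seed = child_seed(50, i))$n_switches)
  }, numeric(1))
  # 2 parents x 999 gap sites x 0.03 = 59.94 expected switches per rep
  exp_mean <- 2 * 999 * 0.03
  se <- sqrt(2 * 999 * 0.03 * 0.97 / 30)
  expect_lt(abs(mean(counts) - exp_mean), 3 * se)
  # rate 0 leaves the phased grid identical to truth
  clean <- sim_parents(n_snps = 300, switch_error_rate = 0, seed = 51)
  expect_identical(clean$truth, clean$phased)
  expect_equal(unname(clean$n_switches), c(0L, 0L))
})

test_that("sim_meiosis transmits haplotypes with Poisson crossovers", {
  sim <- sim_parents(n_snps = 300, seed = 52)
  g <- sim$truth
  # zero crossovers: the transmitted alleles are one parental haplotype
  m0 <- sim_meiosis(g, "maternal", n_crossovers = 0, start_hap = 0, seed = 53)
  expect_identical(m0$alleles, g$m0)
  expect_length(m0$crossovers, 0)
  m1 <- sim_meiosis(g, "paternal", n_crossovers = 0, start_hap = 1, seed = 54)
  expect_identical(m1$alleles, g$p1)
  # a forced crossover switches haplotype exactly at the breakpoint
  mx <- sim_meiosis(g, "maternal", crossover_positions = 17e6,
    start_hap = 0, seed = 55)
  pre <- g$pos < 17e6
  expect_identical(mx$alleles[pre], g$m0[pre])
  expect_identical(mx$alleles[!pre], g$m1[!pre])
  # free crossover count is Poisson(r * contig length)
  n_co <- vapply(1:200, function(i) {
    length(sim_meiosis(g, "maternal", r = 1e-7,
      seed = child_seed(56, i))$crossovers)
  }, numeric(1))
  expect_lt(abs(mean(n_co) - 3.5), 3 * sqrt(3.5 / 200))
})

test_that("draw_baf reproduces the emission conventions", {
  withr::local_seed(57)
  # noiseless: dosage itself, and 1/2 for nullisomy
  expect_equal(draw_baf(c(0, 0.5, 1, NA), c(2, 2, 2, 0), NULL),
    c(0, 0.5, 1, 0.5))
  n <- noise_params(0.4, 0.1)
  # homozygous sites hit the boundary atom at rate pi0
  b_hom <- draw_baf(rep(0, 2e4), 2, n)
  expect_lt(abs(mean(b_hom == 0) - 0.4), 0.02)
  expect_true(all(b_hom >= 0 & b_hom <= 1))
  # under the default convention intermediate dosages never hit a boundary
  b_het <- draw_baf(rep(0.5, 2e4), 2, n)
  expect_equal(sum(b_het %in% c(0, 1)), 0)
  # interior draws follow the truncated normal around mu
  ks <- suppressWarnings(stats::ks.test(b_het,
    function(q) {
      (stats::pnorm(q, 0.5, 0.1) - stats::pnorm(0, 0.5, 0.1)) /
        (stats::pnorm(1, 0.5, 0.1) - stats::pnorm(0, 0.5, 0.1))
    }))
  expect_gt(ks$p.value, 0.001)
  # the printed convention adds a rate-pi0 atom at 1 for intermediate mu
  b_print <- draw_baf(rep(0.5, 2e4), 2, n, else_atom = "delta1_as_printed")
  expect_lt(abs(mean(b_print == 1) - 0.4), 0.02)
  expect_equal(sum(b_print == 0), 0)
})

test_that("sim_embryo records its truth and draws the right dosages", {
  sim <- sim_parents(n_snps = 300, seed = 58)
  emb <- sim_embryo(sim$truth, "monosomy_paternal_loss", noise = NULL,
    seed = 59)
  expect_equal(emb$truth$true_class, "monosomy_paternal_loss")
  expect_true(is.na(emb$truth$true_origin))
  # noiseless monosomy BAF is the transmitted maternal allele (0/1)
  expect_true(all(emb$baf$baf %in% c(0, 1)))
  tri <- sim_embryo(sim$truth, "trisomy_maternal", noise = NULL,
    origin = "SPH", r = 1e-12, seed = 60)
  expect_equal(tri$truth$true_origin, "SPH")
  # SPH dosage: duplicated maternal homolog + one paternal => mu in {0,1/3,2/3,1}
  expect_true(all(tri$baf$baf %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_equal(length(tri$truth$crossovers), 3)
  null <- sim_embryo(sim$truth, "nullisomy", noise = NULL, seed = 61)
  expect_true(all(null$baf$baf == 0.5))
})

test_that("mosaic biopsies mix disomic and aneuploid cells", {
  sim <- sim_parents(n_snps = 300, seed = 62)
  bio <- sim_mosaic_biopsy(sim$truth, "monosomy_maternal_loss",
    n_cells = 10, n_aneuploid = 9, noise = NULL, seed = 63)
  expect_equal(bio$truth$n_aneuploid_cells, 9)
  expect_equal(bio$truth$n_cells, 10)
  # noiseless mean of 9 haploid (0/1) + 1 disomic cell stays on a lattice
  expect_true(all(abs(bio$baf$baf * 20 - round(bio$baf$baf * 20)) < 1e-12))
  # p_mosaic draws a Binomial count when n_aneuploid is free
  ns <- vapply(1:100, function(i) {
    sim_mosaic_biopsy(sim$truth, "trisomy_maternal", n_cells = 10,
      p_mosaic = 0.3, noise = NULL,
      seed = child_seed(64, i))$truth$n_aneuploid_cells
  }, numeric(1))
  expect_lt(abs(mean(ns) - 3), 3 * sqrt(10 * 0.3 * 0.7 / 100))
})

test_that("segmental simulation perturbs dosage only inside the interval", {
  sim <- sim_parents(n_snps = 500, seed = 65)
  seg <- sim_segmental(sim$truth, "monosomy_paternal_loss",
    start_bp = 10e6, end_bp = 18e6, noise = NULL, seed = 66)
  inside <- sim$truth$pos >= 10e6 & sim$truth$pos < 18e6
  expect_equal(seg$truth$segment$start_bp, 10e6)
  expect_equal(seg$truth$segment$end_bp, 18e6)
  expect_equal(seg$truth$segment$n_snps, sum(inside))
  # inside: haploid maternal alleles (0/1); outside: disomic {0,1/2,1}
  expect_true(all(seg$baf$baf[inside] %in% c(0, 1)))
  expect_true(all(seg$baf$baf[!inside] %in% c(0, 0.5, 1)))
  # het maternal sites inside must show a haploid (boundary) signal
  het_in <- inside & sim$truth$m0 != sim$truth$m1
  expect_gt(sum(het_in), 0)
  expect_true(all(seg$baf$baf[het_in] %in% c(0, 1)))
  # random segments fall in the 6-10 Mbp range
  lens <- vapply(1:20, function(i) {
    s <- sim_segmental(sim$truth, "trisomy_maternal", noise = NULL,
      seed = child_seed(67, i))$truth$segment
    s$end_bp - s$start_bp
  }, numeric(1))
  expect_true(all(lens >= 6e6 & lens <= 1e7))
})

test_that("sim_family honors forced crossovers and labels embryos", {
  sim <- sim_parents(n_snps = 300, seed = 68)
  fam <- sim_family(sim$truth, n_embryos = 3, noise = NULL, seed = 69,
    crossovers = list(
      list(maternal = c(8e6, 21e6), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = 15e6),
      list(maternal = numeric(0), paternal = numeric(0))))
  expect_equal(purrr::map_chr(fam$truth, "embryo_id"),
    sprintf("embryo%02d", 1:3))
  expect_equal(fam$truth[[1]]$maternal, c(8e6, 21e6))
  expect_equal(fam$truth[[2]]$paternal, 15e6)
  expect_length(fam$truth[[3]]$maternal, 0)
  expect_equal(nrow(fam$baf), 3 * 300)
  expect_true(all(fam$baf$baf %in% c(0, 0.5, 1)))
})
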