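test_that("informative sites follow the het/hom definition", {
  g <- site_grid("c", c(100, 200, 300, 400),
    m0 = c(0, 0, 1, 0), m1 = c(1, 1, 1, 1),
    p0 = c(0, 0, 0, 1), p1 = c(0, 1, 1, 1))
  # site 1: m het, p hom -> maternal; site 2: both het -> neither;
  # site 3: m hom, p het -> paternal; site 4: m het, p hom -> maternal
  expect_equal(informative_sites(g, "maternal"), c(1L, 4L))
  expect_equal(informative_sites(g, "paternal"), 3L)
})

test_that("llr_pair signs reflect shared vs opposite transmission", {
  # all sites maternal-informative: m = (0,1), p = (0,0)
  g <- site_grid("c", c(1e5, 2e5, 3e5),
    m0 = c(0, 0, 0), m1 = c(1, 1, 1),
    p0 = c(0, 0, 0), p1 = c(0, 0, 0))
  n <- noise_params(0.5, 0.05)
  # template transmits m0 (baf ~ 0); sibling same at both sites -> llr > 0
  tmpl <- c(0, 0, 0)
  sib_same <- c(0, 0, 0)
  expect_gt(llr_pair(tmpl, sib_same, c(1, 2), g, n, n, "maternal"), 0)
  # sibling transmitting m1 at both sites (baf ~ 0.5 here) -> llr < 0
  sib_diff <- c(0.5, 0.5, 0.5)
  expect_lt(llr_pair(tmpl, sib_diff, c(1, 2), g, n, n, "maternal"), 0)
  # a pair straddling the sibling's switch mixes one agreeing and one
  # disagreeing site; the flanking pairs carry the sign information, so the
  # clean-side pair past the switch is still negative
  sib_switch <- c(0, 0.5, 0.5)
  expect_lt(llr_pair(tmpl, sib_switch, c(2, 3), g, n, n, "maternal"), 0)
  # missing observations at both sites: unit likelihoods, llr exactly 0
  expect_equal(llr_pair(c(NA, NA, 0), c(NA, NA, 0), c(1, 2), g, n, n,
    "maternal"), 0)
  # non-informative sites are rejected
  g2 <- site_grid("c", c(1e5, 2e5), m0 = c(0, 0), m1 = c(1, 0),
    p0 = c(0, 0), p1 = c(0, 0))
  expect_error(llr_pair(c(0, 0), c(0, 0), c(1, 2), g2, n, n, "maternal"),
    "informative")
})

test_that("a forced template crossover is called with its interval", {
  sim <- sim_parents(seed = 33)
  fam <- sim_family(sim$truth, n_embryos = 5, noise = NULL, seed = 34,
    crossovers = list(list(maternal = 17e6, paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0))))
  n <- noise_params(0.5, 0.05)
  calls <- call_crossovers(fam$baf, sim$truth, "maternal", noise = n,
    templates = "embryo01")
  expect_equal(nrow(calls), 1)
  expect_lte(calls$left_bp, 17e6)
  expect_gt(calls$right_bp, 17e6)
  expect_gt(calls$n_supporting_siblings, 2)
  expect_equal(calls$n_total_siblings, 4L)
  # a crossover-free template yields no calls
  calls2 <- call_crossovers(fam$baf, sim$truth, "maternal", noise = n,
    templates = "embryo02")
  expect_equal(nrow(calls2), 0)
})

test_that("a single-sibling switch is removed by the majority rule", {
  sim <- sim_parents(seed = 35)
  # the crossover lives in ONE sibling, not the template
  fam <- sim_family(sim$truth, n_embryos = 5, noise = NULL, seed = 36,
    crossovers = list(list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = 17e6, paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0)),
      list(maternal = numeric(0), paternal = numeric(0))))
  n <- noise_params(0.5, 0.05)
  calls <- call_crossovers(fam$baf, sim$truth, "maternal", noise = n,
    templates = "embryo01")
  expect_equal(nrow(calls), 0)
})

test_that("too few siblings or informative sites skips the chromosome", {
  sim <- sim_parents(n_snps = 200, contig_len_bp = 4e6, seed = 37)
  fam <- sim_family(sim$truth, n_embryos = 3, noise = NULL, seed = 38)
  expect_message(
    calls <- call_crossovers(fam$baf, sim$truth, "maternal",
      noise = noise_params(0.5, 0.05)),
    "only 3 disomic embryos"
  )
  expect_equal(nrow(calls), 0)
  # a grid with no informative maternal sites
  g <- site_grid("c", seq(1e5, 4e5, by = 1e5),
    m0 = c(0, 0, 1, 1), m1 = c(0, 0, 1, 1),
    p0 = c(0, 1, 0, 1), p1 = c(1, 0, 1, 0))
  baf <- tibble::tibble(
    embryo_id = rep(sprintf("e%d", 1:4), each = 4),
    pos = rep(g$pos, 4), baf = rep(0.5, 16))
  expect_message(
    calls2 <- call_crossovers(baf, g, "maternal",
      noise = noise_params(0.5, 0.05)),
    "too few informative sites"
  )
  expect_equal(nrow(calls2), 0)
})

test_that("crossover count matrix tallies calls per embryo and chromosome", {
  calls <- tibble::tibble(
    parent = "maternal",
    template_embryo_id = c("e1", "e1", "e2"),
    chrom = c("c1", "c2", "c1"),
    left_bp = c(1, 1, 1), right_bp = c(2, 2, 2),
    n_supporting_siblings = 3L, n_total_siblings = 4L
  )
  m <- crossover_count_matrix(calls, embryo_ids = c("e1", "e2", "e3"),
    chroms = c("c1", "c2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["e1", "c1"], 1L)
  expect_equal(m["e1", "c2"], 1L)
  expect_equal(m["e2", "c2"], 0L)
  expect_equal(sum(m["e3", ]), 0L)
})

test_that("noiseless multi-family crossover calling is exact", {
  # recall = precision = 1.0 for crossovers flanked by informative sites
  n <- noise_params(0.5, 0.05)
  found <- 0L
  expected <- 0L
  false_pos <- 0L
  for (f in 1:4) {
    sim <- sim_parents(n_snps = 2000, seed = child_seed(40, f))
    fam <- sim_family(sim$truth, n_embryos = 5, noise = NULL,
      seed = child_seed(41, f))
    for (parent in c("maternal", "paternal")) {
      inf <- informative_sites(sim$truth, parent)
      pos_inf <- sim$truth$pos[inf]
      calls <- call_crossovers(fam$baf, sim$truth, parent, noise = n)
      for (tr in fam$truth) {
        truth_co <- tr[[parent]]
        # detection needs a flanking LLR pair on each side, i.e. at least
        # two informative sites left and right of the crossover
        truth_co <- truth_co[truth_co > pos_inf[2] &
          truth_co < pos_inf[length(pos_inf) - 1]]
        mine <- calls[calls$template_embryo_id == tr$embryo_id, ]
        expected <- expected + length(truth_co)
        for (co in truth_co) {
          found <- found +
            any(mine$left_bp <= co & mine$right_bp > co)
        }
        false_pos <- false_pos + sum(!sapply(seq_len(nrow(mine)),
          function(i) any(truth_co >= mine$left_bp[i] &
            truth_co < mine$right_bp[i])))
      }
    }
  }
  expect_gt(expected, 0)
  expect_equal(found, expected)
  expect_equal(false_pos, 0L)
})
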