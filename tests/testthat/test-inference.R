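test_that("forward likelihood matches exhaustive path enumeration", {
  n <- noise_params(0.4, 0.18)
  for (L in c(3, 4)) {
    g <- toy_grid(L)
    baf <- c(0.1, 1, 0.45, 0)[seq_len(L)]
    expect_equal(
      karyotype_loglik(baf, g, n),
      oracle_loglik(g, baf, n),
      tolerance = 1e-8
    )
  }
  # reduced chromosome-type spaces
  g <- toy_grid(3)
  baf <- c(0.3, 0.9, 0)
  for (ct in c("X", "Y")) {
    expect_equal(
      karyotype_loglik(baf, g, n, chromosome_type = ct),
      oracle_loglik(g, baf, n, chromosome_type = ct),
      tolerance = 1e-8
    )
  }
  # the printed delta_1 emission convention goes through the same recursion
  expect_equal(
    karyotype_loglik(baf, g, n, else_atom = "delta1_as_printed"),
    oracle_loglik(g, baf, n, else_atom = "delta1_as_printed"),
    tolerance = 1e-8
  )
})

test_that("forward and backward recursions agree", {
  sim <- sim_parents(n_snps = 300, contig_len_bp = 5e6, seed = 3)
  emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.15), seed = 4)
  fit <- infer_karyotype(emb$baf, sim$phased,
    noise = noise_params(0.5, 0.15))
  st <- karyotype_states("autosome")
  logE <- pgtkaryo:::emission_matrix(sim$phased, st,
    align_baf(emb$baf, sim$phased), noise_params(0.5, 0.15), "none")
  fb <- pgtkaryo:::hmm_fb_cpp(logE, pgtkaryo:::class_group(st),
    diff(sim$phased$pos), 1e-8, 1e-10, TRUE)
  expect_equal(fb$loglik, fb$loglik_backward, tolerance = 1e-8)
  expect_equal(fit$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("posteriors are normalized and translation-invariant", {
  sim <- sim_parents(n_snps = 200, contig_len_bp = 4e6, seed = 5)
  emb <- sim_embryo(sim$truth, "trisomy_maternal", noise_params(0.5, 0.15),
    seed = 6)
  n <- noise_params(0.5, 0.15)
  fit <- infer_karyotype(emb$baf, sim$phased, noise = n)
  expect_equal(sum(fit$class_posteriors), 1, tolerance = 1e-6)
  expect_equal(unname(rowSums(fit$gamma)), rep(1, nrow(fit$gamma)),
    tolerance = 1e-6)
  # shift every position by a constant: only gaps matter
  g2 <- site_grid(sim$phased$chrom[1], sim$phased$pos + 123456,
    sim$phased$m0, sim$phased$m1, sim$phased$p0, sim$phased$p1)
  fit2 <- infer_karyotype(align_baf(emb$baf, sim$phased), g2, noise = n)
  expect_equal(fit2$class_posteriors, fit$class_posteriors,
    tolerance = 1e-10)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("restricted state spaces obey the uniform-prior bound", {
  sim <- sim_parents(n_snps = 200, contig_len_bp = 4e6, seed = 7)
  emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.1), seed = 8)
  n <- noise_params(0.5, 0.1)
  full <- karyotype_loglik(emb$baf, sim$phased, n)
  st <- karyotype_states("autosome")
  # restricting to all classes is a no-op
  expect_equal(karyotype_loglik(emb$baf, sim$phased, n,
    classes = unique(st$class)), full, tolerance = 1e-10)
  # with a uniform prior over the included states, dropping paths can raise
  # the loglik by at most the prior renormalization log(S_full / S_sub)
  for (cls in list("nullisomy", "disomy", c("disomy", "trisomy_maternal"))) {
    n_sub <- sum(st$class %in% cls)
    expect_lte(karyotype_loglik(emb$baf, sim$phased, n, classes = cls),
      full + log(nrow(st) / n_sub) + 1e-9)
  }
  expect_error(karyotype_loglik(emb$baf, sim$phased, n, classes = "tetra"),
    "unknown class")
})

test_that("all-missing data has log-likelihood 0", {
  g <- toy_grid(5)
  n <- noise_params(0.5, 0.2)
  expect_equal(karyotype_loglik(rep(NA_real_, 5), g, n), 0, tolerance = 1e-12)
})

test_that("clean disomy is called with high posterior", {
  sim <- sim_parents(n_snps = 1000, contig_len_bp = 20e6, seed = 9)
  emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.1), seed = 10)
  fit <- infer_karyotype(emb$baf, sim$phased)
  expect_equal(fit$call, "disomy")
  expect_gt(fit$class_posteriors["disomy"], 0.9)
  expect_gte(fit$bayes_factor, 2)
})

test_that("noise MLE recovers the generating parameters", {
  sim <- sim_parents(seed = 11)
  emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.2), seed = 12)
  nh <- fit_noise(emb$baf, sim$phased)
  expect_lt(abs(nh$pi0 - 0.5), 0.05)
  expect_lt(abs(nh$sigma - 0.2), 0.04)
  # MLE optimality: fitted likelihood at least that of the true parameters
  expect_gte(attr(nh, "loglik"),
    karyotype_loglik(emb$baf, sim$phased, noise_params(0.5, 0.2)) - 1e-6)
})

test_that("fit_noise requires enough observed sites", {
  g <- toy_grid(60)
  b <- c(rep(0.5, 20), rep(NA_real_, 40))
  expect_error(fit_noise(b, g), "at least 50")
})

test_that("viterbi decoding is available and sensible", {
  sim <- sim_parents(n_snps = 150, contig_len_bp = 3e6, seed = 13)
  emb <- sim_embryo(sim$truth, "monosomy_maternal_loss",
    noise_params(0.5, 0.1), seed = 14)
  fit <- infer_karyotype(emb$baf, sim$phased, noise = noise_params(0.5, 0.1),
    map_rule = "viterbi")
  expect_equal(fit$call, "monosomy_maternal_loss")
  expect_gt(mean(fit$map_class == "monosomy_maternal_loss"), 0.95)
})

test_that("tidy and glance summaries have the documented shape", {
  sim <- sim_parents(n_snps = 150, contig_len_bp = 3e6, seed = 15)
  emb <- sim_embryo(sim$truth, "disomy", noise_params(0.5, 0.1), seed = 16)
  fit <- infer_karyotype(emb$baf, sim$phased, noise = noise_params(0.5, 0.1))
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_named(td, c("embryo_id", "chrom", "class", "posterior"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("call", "posterior_max", "bayes_factor", "pi0_hat",
    "sigma_hat", "posterior_disomy") %in% names(gl)))
})

test_that("embryo-level QC applies the nullisomy and sigma filters", {
  calls <- tibble::tibble(
    embryo_id = rep(c("e1", "e2", "e3"), each = 6),
    call = c(rep("nullisomy", 5), "disomy",
      c(rep("disomy", 5), "nullisomy"),
      rep("disomy", 6)),
    sigma_hat = c(rep(0.2, 6), rep(0.2, 6), rep(0.2, 6))
  )
  qc <- qc_embryos(calls)
  expect_equal(qc$exclude, c(TRUE, FALSE, FALSE))
  expect_equal(qc$reasons[1], "nullisomy_count")
  # a wildly outlying mean sigma excludes (larger cohort for a stable SD)
  calls2 <- tibble::tibble(
    embryo_id = rep(sprintf("e%02d", 1:16), each = 2),
    call = "disomy",
    sigma_hat = c(rep(0.2, 30), rep(0.9, 2))
  )
  qc2 <- qc_embryos(calls2)
  expect_true(qc2$exclude[qc2$embryo_id == "e16"])
  expect_equal(qc2$reasons[qc2$embryo_id == "e16"], "sigma_outlier")
  expect_false(any(qc2$exclude[qc2$embryo_id != "e16"]))
})
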