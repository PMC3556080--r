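test_that("screen simulation is deterministic given the seed and requires one", {
  cfg <- screen_sim_config(n_genes = 10, seed = 99)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  d1 <- simulate_deconvolution(cfg, genes = c("G01", "G02"))
  d2 <- simulate_deconvolution(cfg, genes = c("G01", "G02"))
  expect_identical(d1, d2)
  expect_error(screen_sim_config(n_genes = 5), "seed")
  expect_error(expression_sim_config(n_genes = 5), "seed")
})

test_that("config invariants are enforced", {
  expect_error(screen_sim_config(drugs = c(IM = -0.5), seed = 1), "> 0")
  expect_error(screen_sim_config(knockdown_efficacy = 1.5, seed = 1), "\\[0, 1\\]")
  expect_error(screen_sim_config(n_genes = 3, sensitizers = list(IM = "G09"),
                                 seed = 1), "not in the gene library")
  expect_error(screen_sim_config(sensitizers = list(XX = "G01"), seed = 1),
               "drug labels")
  expect_error(expression_sim_config(planted_down = c(A = -2, A = -1), seed = 1),
               "only once")
  expect_error(expression_sim_config(planted_down = c(A = -Inf), seed = 1),
               "finite")
})

test_that("simulated plates have the configured layout", {
  cfg <- screen_sim_config(n_genes = 7, n_gl2_wells_per_plate = 5,
                           n_replicate_wells = 3, seed = 5)
  m <- simulate_screen(cfg)$measurements
  expect_setequal(unique(m$plate_id), c("IM_vehicle", "IM_drug"))
  gl2 <- tapply(m$gene == "GL2", m$plate_id, sum)
  expect_true(all(gl2 == 5))
  per_gene <- table(m$gene[m$plate_id == "IM_vehicle" & m$gene != "GL2"])
  expect_true(all(per_gene == 3))
  expect_true(all(m$raw_value > 0))
  expect_false(anyDuplicated(m[c("plate_id", "well")]) > 0)
})

test_that("noiseless null screens score SI = 1 for every gene", {
  cfg <- noiseless_cfg(n_genes = 12, seed = 21)
  fit <- score_screen(simulate_screen(cfg)$measurements)
  expect_equal(fit$records$si, rep(1, 12))
  expect_equal(fit$records$p_value, rep(1, 12))
})

test_that("planted effects are recovered exactly without noise", {
  cfg <- noiseless_cfg(n_genes = 6, drugs = c(IM = 0.5),
                       sensitizers = list(IM = "G04"), seed = 8)
  fit <- score_screen(simulate_screen(cfg)$measurements)
  r <- fit$records
  expect_equal(r$si[r$gene == "G04"], 0.5)
  expect_equal(r$si[r$gene != "G04"], rep(1, 5))
  expect_true(r$primary_hit[r$gene == "G04"])
  expect_false(any(r$primary_hit[r$gene != "G04"]))
})

test_that("noiseless deconvolution validation follows planted per-duplex efficacy", {
  # brute-force expectation: a duplex confirms iff its attenuated factor
  # 1 - e (1 - f) < 0.85, i.e. e > 0.15 / (1 - f); validation iff >= 2 confirm
  f <- 0.5
  for (seed in c(2, 7, 13)) {
    set.seed(seed)
    eff <- matrix(runif(5 * 4), 5, 4)
    cfg <- noiseless_cfg(n_genes = 5, drugs = c(IM = f),
                         sensitizers = list(IM = sprintf("G%02d", 1:5)),
                         knockdown_efficacy = eff, seed = seed)
    fit <- score_screen(simulate_deconvolution(cfg)$measurements, by = "sirna")
    val <- validate_hits_deconvolution(fit)
    expected_confirm <- rowSums(eff > 0.15 / (1 - f))
    expect_equal(val$n_confirming_sirnas[order(val$gene)],
                 unname(expected_confirm))
    expect_equal(val$validated_hit[order(val$gene)],
                 unname(expected_confirm >= 2))
  }
})

test_that("expression simulation plants shifts exactly in the noiseless limit", {
  cfg <- expression_sim_config(n_genes = 100,
                               planted_down = c(POSTN = -2.21),
                               planted_up = c(TMCO1 = 1.33),
                               residual_sd = 0, seed = 17)
  sim <- simulate_expression(cfg)
  lfc <- compute_logfc(sim$matrix, sim$controls)
  expect_equal(unname(lfc["POSTN", ]), rep(-2.21, 14))
  expect_equal(unname(lfc["TMCO1", ]), rep(1.33, 14))
  expect_equal(max(abs(lfc[setdiff(rownames(lfc), c("POSTN", "TMCO1")), ])), 0)
})

test_that("null pass count of the all-samples filter matches the closed form", {
  # independent-sample closed form: n_genes * P(|N(0, s*sqrt(1 + 1/n_con))| >= 1)^n_kd,
  # checked with many controls so the shared control-mean term is negligible
  sd <- 1; n_con <- 25; n_kd <- 3; n_genes <- 20000
  cfg <- expression_sim_config(n_genes = n_genes, n_knockdowns = n_kd,
                               n_controls = n_con, residual_sd = sd, seed = 31)
  sim <- simulate_expression(cfg)
  lfc <- compute_logfc(sim$matrix, sim$controls)
  observed <- sum(rowSums(abs(lfc) >= 1) == n_kd)
  p1 <- 2 * pnorm(-1, sd = sd * sqrt(1 + 1 / n_con))
  expected <- n_genes * p1^n_kd
  expect_lt(abs(observed - expected), 5 * sqrt(expected))
})

test_that("a single planted region shift dominates the region report", {
  cfg <- expression_sim_config(n_genes = 2000,
                               region_shift = c("19q13" = 0.4),
                               residual_sd = 0, seed = 23)
  sim <- simulate_expression(cfg)
  ts <- pooled_t_statistics(sim$matrix, sim$controls)
  res <- gene_set_rank_test(stats::setNames(ts$t, ts$gene),
                            region_sets_from_cytoband(sim$annotation))
  expect_identical(res$set[1], "19q13")
  expect_identical(res$direction[1], "up")
  expect_lt(res$p_value[1], min(res$p_value[-1]))
})
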