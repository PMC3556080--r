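# hand-built two-plate experiment exercising the SI formula directly
tiny_experiment <- function(v_drug = 40, gl2_drug = c(60, 70, 80, 90, 100),
                            v_veh = 90, gl2_veh = c(80, 90, 100, 110, 120)) {
  rbind(
    data.frame(plate_id = "veh", well = sprintf("A%02d", seq_along(gl2_veh)),
               gene = "GL2", sirna_id = "GL2", condition = "vehicle",
               drug = "", pair_id = "IM", raw_value = gl2_veh),
    data.frame(plate_id = "veh", well = "B01", gene = "TGT",
               sirna_id = "pooled", condition = "vehicle", drug = "",
               pair_id = "IM", raw_value = v_veh),
    data.frame(plate_id = "drg", well = sprintf("A%02d", seq_along(gl2_drug)),
               gene = "GL2", sirna_id = "GL2", condition = "drug",
               drug = "IM", pair_id = "IM", raw_value = gl2_drug),
    data.frame(plate_id = "drg", well = "B01", gene = "TGT",
               sirna_id = "pooled", condition = "drug", drug = "IM",
               pair_id = "IM", raw_value = v_drug)
  )
}

test_that("GL2 normalization divides by the per-plate control median", {
  m <- tiny_experiment()
  norm <- normalize_to_gl2(m)
  # vehicle plate: GL2 median 100 -> target well 90 normalizes to 0.9
  expect_equal(norm$norm_value[norm$plate_id == "veh" & norm$gene == "TGT"], 0.9)
  # drug plate: GL2 median 80 -> 40 normalizes to 0.5
  expect_equal(norm$norm_value[norm$plate_id == "drg" & norm$gene == "TGT"], 0.5)
  # GL2 wells keep per-plate median 1 by construction
  expect_equal(median(norm$norm_value[norm$is_control & norm$plate_id == "veh"]), 1)
  # a plate of wells all equal to the GL2 median normalizes to all ones
  flat <- m
  flat$raw_value <- 100
  expect_equal(unique(normalize_to_gl2(flat)$norm_value), 1)
})

test_that("the sensitization index is the ratio of normalized arm summaries", {
  si <- compute_si(normalize_to_gl2(tiny_experiment()))
  expect_equal(si$si, 0.5 / 0.9, tolerance = 1e-12)
  expect_equal(si$log2_si, log2(0.5 / 0.9), tolerance = 1e-12)
  # identical arms give SI = 1
  same <- compute_si(normalize_to_gl2(tiny_experiment(v_drug = 50, v_veh = 50,
                                                      gl2_drug = c(80, 90, 100, 110, 120))))
  expect_equal(same$si, 1)
})

test_that("normalization and SI are invariant to per-plate scaling", {
  cfg <- screen_sim_config(n_genes = 10, sensitizers = list(IM = c("G02", "G07")),
                           seed = 12)
  m <- simulate_screen(cfg)$measurements
  fit <- score_screen(m)
  scaled <- m
  scaled$raw_value[scaled$plate_id == "IM_drug"] <-
    scaled$raw_value[scaled$plate_id == "IM_drug"] * 37.5
  fit2 <- score_screen(scaled)
  expect_equal(fit2$records, fit$records, tolerance = 1e-12)
})

test_that("Z'-factor matches direct arithmetic and behaves monotonically", {
  expect_equal(zprime_factor(c(20, 20, 20), c(100, 100, 100)), 1)
  pos <- c(15, 20, 25)        # mean 20, sd 5
  neg <- c(95, 100, 105)      # mean 100, sd 5
  expect_equal(zprime_factor(pos, neg), 1 - 30 / 80)
  wider <- zprime_factor(c(10, 20, 30), neg)  # sd doubled -> smaller Z'
  expect_lt(wider, zprime_factor(pos, neg))
  expect_identical(zprime_factor(c(1, 2), c(1, 2)), -Inf)
})

test_that("the unmoderated drug-effect test equals a pooled-variance t-test", {
  cfg <- screen_sim_config(n_genes = 4, sensitizers = list(IM = "G01"),
                           noise_sd = 0.15, seed = 61)
  norm <- normalize_to_gl2(simulate_screen(cfg)$measurements)
  for (g in c("G01", "G03")) {
    x <- norm[!norm$is_control & norm$gene == g, ]
    ref <- t.test(log2(norm_value) ~ condition, data = x, var.equal = TRUE)
    expect_equal(fit_drug_effect(norm, g), ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  set.seed(202)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit calling applies both criteria with strict inequalities", {
  th <- hit_thresholds()
  rec <- data.frame(si = c(0.80, 0.80, 0.85, 0.90, 0.849),
                    fdr = c(0.10, 0.20, 0.10, 0.10, 0.1499))
  out <- call_primary_hits(rec, th)
  expect_equal(out$primary_hit, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # monotone: lowering SI or FDR never un-calls a hit
  shrunk <- call_primary_hits(transform(rec, si = si * 0.9, fdr = fdr * 0.9), th)
  expect_true(all(shrunk$primary_hit >= out$primary_hit))
})

test_that("deconvolution validation applies the at-least-2-of-4 rule", {
  th <- hit_thresholds()
  rec <- data.frame(
    gene = rep(c("A", "B"), each = 4),
    sirna_id = rep(sprintf("s%d", 1:4), 2),
    drug = "IM",
    si = c(0.7, 0.7, 0.95, 0.95, 0.7, 0.95, 0.95, 0.95),
    fdr = 0.01
  )
  val <- validate_hits_deconvolution(rec, th)
  expect_equal(val$n_confirming_sirnas, c(2L, 1L))
  expect_equal(val$validated_hit, c(TRUE, FALSE))
  expect_equal(val$mean_confirming_si, c(0.7, 0.7))
  short <- rec[rec$sirna_id != "s4", ]
  expect_warning(validate_hits_deconvolution(short, th), "fewer than 4")
})

test_that("best-duplex selection picks the lowest-SI duplexes deterministically", {
  rec <- data.frame(
    gene = rep(c("A", "B"), each = 4),
    sirna_id = rep(sprintf("s%d", 1:4), 2),
    drug = "IM",
    si = c(0.9, 0.6, 0.7, 0.95, 0.8, 0.8, 0.9, 0.7))
  top <- best_sirnas(rec)
  expect_equal(top$sirna_id[top$gene == "A"], c("s2", "s3"))
  # tie at 0.8 for gene B broken by duplex id
  expect_equal(top$sirna_id[top$gene == "B"], c("s4", "s1"))
  expect_equal(top$rank, rep(1:2, 2))
})

test_that("the specificity matrix reproduces planted per-drug truth exactly", {
  genes <- sprintf("G%02d", 1:17)
  sens <- list(sunitinib = genes[1:14], doxorubicin = genes[1:5],
               ifosfamide = character(0))
  cfg <- noiseless_cfg(n_genes = 17,
                       drugs = c(sunitinib = 0.6, doxorubicin = 0.6,
                                 ifosfamide = 0.6),
                       sensitizers = sens, seed = 71)
  fit <- score_screen(simulate_screen(cfg)$measurements)
  spec <- drug_specificity_matrix(fit)
  expect_equal(unname(spec$counts[c("sunitinib", "doxorubicin", "ifosfamide")]),
               c(14, 5, 0))
  expect_equal(dim(spec$si), c(17L, 3L))
  expect_true(all(spec$si[cbind(genes[1:14], "sunitinib")] == 0.6))
})
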