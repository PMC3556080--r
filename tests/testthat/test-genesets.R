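test_that("cytoband labels parse to major bands, ranges and edge cases included", {
  p <- parse_cytoband(c("19q13.1", "19q13.43", "6p25-p24", "Xq22.1", "Yp11",
                        "banana", "7cen"))
  expect_equal(p$major_band,
               c("19q13", "19q13", "6p25", "Xq22", "Yp11", NA, NA))
  # the reference profile's bands, collapsed to major resolution
  prof <- gist_consensus_profile()
  expect_setequal(parse_cytoband(prof$cytoband)$major_band,
                  c("13q13", "2q11", "6p12", "14q24", "1p22", "3q26",
                    "6p25", "1q24"))
})

test_that("region sets group genes by major band, sub-band behind the flag", {
  ann <- data.frame(
    gene = sprintf("g%d", 1:6),
    cytoband = c("19q13.1", "19q13.1", "19q13.1", "19q13.2", "19q13.2", "oops"))
  expect_warning(sets <- region_sets_from_cytoband(ann), "unparseable")
  expect_length(sets, 1)
  expect_length(sets[["19q13"]], 5)
  expect_identical(attr(sets, "unparsed"), "g6")
  suppressWarnings(sub <- region_sets_from_cytoband(ann, granularity = "sub"))
  expect_setequal(names(sub), c("19q13.1", "19q13.2"))
  # all reference-profile genes lie on distinct major bands: singleton sets
  prof <- gist_consensus_profile()
  ref <- region_sets_from_cytoband(prof[, c("gene", "cytoband")])
  expect_length(ref, 8)
  expect_true(all(lengths(ref) == 1))
})

test_that("gene sets round-trip through GMT and pass through generate_gene_sets", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  ann <- data.frame(gene = c("g1", "g2"), cytoband = c("1p11.1", "1p11.2"))
  both <- generate_gene_sets(ann, curated_sets = sets)
  expect_named(both, c("regions", "curated"))
  expect_equal(both$regions[["1p11"]], c("g1", "g2"))
  empty <- generate_gene_sets(ann)
  expect_length(empty$curated, 0)
})

test_that("the rank-sum gene-set p agrees with wilcox.test in both regimes", {
  set.seed(9)
  # exact regime: small tie-free groups
  for (i in 1:10) {
    stats_vec <- stats::setNames(rnorm(40), sprintf("g%d", 1:40))
    members <- sample(names(stats_vec), sample(3:8, 1))
    ours <- wilcoxon_gene_set_test(stats_vec, members)
    ref <- wilcox.test(stats_vec[members], stats_vec[setdiff(names(stats_vec), members)])
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # approximate regime: large complement, ties present
  stats_vec <- stats::setNames(c(rnorm(200), rep(0.5, 30)), sprintf("g%d", 1:230))
  members <- sprintf("g%d", 1:10)
  ours <- wilcoxon_gene_set_test(stats_vec, members)
  ref <- suppressWarnings(
    wilcox.test(stats_vec[members], stats_vec[-(1:10)], exact = FALSE,
                correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("rank-sum p matches exact subset enumeration for small sets", {
  set.seed(15)
  cases <- list(c(N = 20, m = 3), c(N = 30, m = 4), c(N = 40, m = 5))
  for (cs in cases) {
    stats_vec <- stats::setNames(rnorm(cs[["N"]]), sprintf("g%d", seq_len(cs[["N"]])))
    members <- sample(names(stats_vec), cs[["m"]])
    ours <- wilcoxon_gene_set_test(stats_vec, members)
    exact <- wilcox_enum_oracle(stats_vec, names(stats_vec) %in% members)
    expect_equal(ours$p, exact, tolerance = 0.1)
  }
  # extreme tail: the 5 largest statistics among 50
  stats_vec <- stats::setNames(sort(rnorm(50)), sprintf("g%d", 1:50))
  members <- names(stats_vec)[46:50]
  ours <- wilcoxon_gene_set_test(stats_vec, members)
  expect_equal(ours$p, 2 / choose(50, 5), tolerance = 1e-12)
  expect_identical(ours$direction, "up")
})

test_that("degenerate and undersized sets are handled, multi-set agrees with single", {
  stats_vec <- stats::setNames(rnorm(50), sprintf("g%d", 1:50))
  expect_warning(all_genes <- wilcoxon_gene_set_test(stats_vec, names(stats_vec)),
                 "degenerate")
  expect_equal(all_genes$p, 1)
  expect_error(wilcoxon_gene_set_test(stats_vec, c("g1", "g2")), "min_size")

  sets <- list(a = sprintf("g%d", 1:5), b = sprintf("g%d", 10:30),
               tiny = "g1", everything = names(stats_vec))
  res <- gene_set_rank_test(stats_vec, sets)
  expect_setequal(attr(res, "skipped"), c("tiny", "everything"))
  for (nm in c("a", "b")) {
    single <- wilcoxon_gene_set_test(stats_vec, sets[[nm]])
    expect_equal(res$p_value[res$set == nm], single$p)
    expect_equal(res$statistic[res$set == nm], single$statistic)
  }
  expect_equal(res$bonferroni, pmin(1, res$p_value * 2))
})

test_that("Bonferroni adjustment is min(1, p * m)", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1)
  expect_equal(bonferroni_adjust(0.3, m = 1), 0.3)
  p <- runif(20)
  adj <- bonferroni_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bonferroni_adjust(-0.1), "\\[0, 1\\]")
  expect_length(bonferroni_adjust(numeric(0)), 0)
})
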