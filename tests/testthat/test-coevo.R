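# Sign-stratified coevolution: stratification, correlations, median
# splits, signal preference, expression-based sign inference.

test_that("edges stratify by sign with missing rates dropped and counted", {
  e <- data.frame(
    source = c("TF1", "TF1", "TF2", "TF2"),
    target = c("m1", "m2", "m3", "m4"),
    relation_type = "TF-miRNA",
    sign = c("activation", "activation", "repression", "activation"))
  net <- reg_network(e)
  tf_rates <- c(TF1 = 0.1, TF2 = 0.2)
  mir_rates <- c(m1 = 0.1, m2 = 0.2, m3 = 0.3)  # m4 unrated
  groups <- stratify_edges_by_sign(net, "TF-miRNA", tf_rates, mir_rates)
  expect_equal(nrow(groups$activation), 2)
  expect_equal(nrow(groups$repression), 1)
  expect_equal(unname(attr(groups, "dropped")["activation"]), 1)
  expect_warning(stratify_edges_by_sign(net, "miRNA-target", mir_rates, tf_rates),
                 "no edges")
})

test_that("group sizes are conserved across stratification", {
  set.seed(77)
  cfg <- synthetic_config(n_tf = 40, n_mirna = 40, n_gene = 60, n_tf_gene = 80,
                          n_tf_mirna = 120, n_mirna_target = 80, seed = 5)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  groups <- stratify_edges_by_sign(net, "TF-miRNA", rates$protein, rates$mirna)
  n_rated <- sum(!is.na(rates$protein[net$edges$source[net$edges$relation_type == "TF-miRNA"]]) &
                   !is.na(rates$mirna[net$edges$target[net$edges$relation_type == "TF-miRNA"]]))
  expect_equal(sum(vapply(groups, nrow, integer(1))), n_rated)
})

test_that("coevolution correlation is Spearman over edge pairs", {
  g <- tibble::tibble(regulator = c("a", "b", "c"), partner = c("x", "y", "z"),
                      rate_regulator = c(1, 2, 3), rate_partner = c(2, 5, 9))
  expect_equal(coevolution_correlation(g)$rho, 1)
  expect_error(coevolution_correlation(g[1:2, ]), "at least 3")
})

test_that("permuting partner rates destroys the planted correlation", {
  set.seed(15)
  cfg <- synthetic_config(n_tf = 450, n_mirna = 450, n_gene = 20, n_tf_gene = 10,
                          n_tf_mirna = 550, n_mirna_target = 10,
                          p_activation = 1, degree_skew = 0.8,
                          rho_activating = 0.6, rho_mirna_target = 0,
                          rho_tf_gene_activating = 0,
                          cascade_gradient_tf = 0, cascade_gradient_mirna = 0,
                          seed = 20)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  g <- stratify_edges_by_sign(net, "TF-miRNA", rates$protein, rates$mirna)$activation
  expect_gt(coevolution_correlation(g)$rho, 0.4)
  g$rate_partner <- sample(g$rate_partner)
  expect_lt(abs(coevolution_correlation(g)$rho), 0.1)
})

test_that("median split halves by one member and compares the other", {
  g <- tibble::tibble(regulator = letters[1:4], partner = LETTERS[1:4],
                      rate_regulator = c(1, 2, 3, 4),
                      rate_partner = c(0.1, 0.1, 0.9, 0.9))
  m <- median_split_comparison(g, "regulator")
  expect_equal(m$median_a, 0.1)
  expect_equal(m$median_b, 0.9)
  # odd count: middle pair joins the low half
  g5 <- rbind(g, tibble::tibble(regulator = "e", partner = "E",
                                rate_regulator = 2.5, rate_partner = 0.5))
  m5 <- median_split_comparison(g5, "regulator")
  expect_equal(m5$n_a, 3)
  expect_equal(m5$n_b, 2)
  # identical partner rates carry no evidence
  g$rate_partner <- rep(0.3, 4)
  expect_equal(median_split_comparison(g, "regulator")$p_value, 1)
  expect_error(median_split_comparison(g[1:3, ], "regulator"), "at least 4")
})

test_that("planted miRNA-target anti-association shows the expected split direction", {
  cfg <- synthetic_config(n_tf = 20, n_mirna = 300, n_gene = 400,
                          n_tf_gene = 30, n_tf_mirna = 30, n_mirna_target = 450,
                          degree_skew = 0.8, rho_activating = 0,
                          rho_mirna_target = -0.4, rho_tf_gene_activating = 0,
                          cascade_gradient_tf = 0, cascade_gradient_mirna = 0,
                          seed = 31)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  g <- stratify_edges_by_sign(net, "miRNA-target", rates$mirna, rates$protein)$repression
  m <- median_split_comparison(g, "regulator")
  # conserved miRNAs regulate faster-evolving targets
  expect_gt(m$median_a, m$median_b)
})

test_that("signal preference reproduces percentages from known counts", {
  # construct 89 high-half and 114 low-half edges with known signs is
  # equivalent to feeding the counts straight into the table
  r <- fisher_exact_2x2(a = 76, b = 13, c = 82, d = 32)
  expect_equal(round(r$pct_row1, 1), 85.4)
  expect_equal(round(r$pct_row2, 1), 71.9)

  # end-to-end on a small constructed network: 4 edges, high-rate TFs
  # all activate, low-rate TFs all repress
  e <- data.frame(source = paste0("TF", 1:4), target = paste0("m", 1:4),
                  relation_type = "TF-miRNA",
                  sign = c("repression", "repression", "activation", "activation"))
  net <- reg_network(e)
  tf_rates <- c(TF1 = 0.01, TF2 = 0.02, TF3 = 0.5, TF4 = 0.6)
  sp <- signal_preference(net, tf_rates)
  expect_equal(sp$pct_activation_high, 100)
  expect_equal(sp$pct_activation_low, 0)
  expect_equal(unname(sp$table["a"]), 2L)
})

test_that("signal preference handles an all-activation network", {
  e <- data.frame(source = paste0("TF", 1:4), target = paste0("m", 1:4),
                  relation_type = "TF-miRNA", sign = "activation")
  sp <- signal_preference(reg_network(e),
                          c(TF1 = 0.1, TF2 = 0.2, TF3 = 0.3, TF4 = 0.4))
  expect_equal(sp$result$p_value, 1)
  expect_true(is.nan(sp$result$odds_ratio))
})

test_that("signal preference p-values are well calibrated under the null", {
  set.seed(55)
  ps <- vapply(1:100, function(i) {
    n <- 240
    e <- data.frame(source = sprintf("TF%03d", 1:n),
                    target = sprintf("m%03d", 1:n),
                    relation_type = "TF-miRNA",
                    sign = sample(c("activation", "repression"), n, TRUE))
    rates <- setNames(runif(n), sprintf("TF%03d", 1:n))
    signal_preference(reg_network(e), rates)$result$p_value
  }, numeric(1))
  # Fisher's exact p is conservative (discrete), so it dominates the
  # uniform rather than matching it; the calibration that matters is
  # that rejection rates are not inflated and the bulk is spread out
  expect_lt(mean(ps < 0.05), 0.10)
  expect_lt(mean(ps < 0.20), 0.30)
  expect_gt(median(ps), 0.30)
  expect_lt(median(ps), 0.90)
})

test_that("expression sign inference follows the correlation sign", {
  expr <- rbind(TF1 = c(1, 2, 3, 4, 5), g1 = c(2, 4, 6, 8, 10),
                g2 = c(5, 4, 3, 2, 1), g3 = c(1, 1, 1, 1, 1))
  edges <- data.frame(source = "TF1", target = c("g1", "g2", "g3", "g4"))
  out <- infer_sign_from_expression(expr, edges)
  expect_equal(out$sign, c("activation", "repression", "unknown", "unknown"))
  expect_equal(out$flag, c("ok", "ok", "ok", "missing_profile"))
  # antisymmetry: negating one profile flips the call
  expr2 <- expr; expr2["g1", ] <- -expr2["g1", ]
  out2 <- infer_sign_from_expression(expr2, edges[1, , drop = FALSE])
  expect_equal(out2$sign, "repression")
  expect_equal(out2$rho, -out$rho[1])
})

test_that("expression matrices read from TSV keep ids and dimensions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2\ts3", "TF1\t1\t2\t3", "g1\t3\t2\t1"), path)
  m <- read_expression(path)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(rownames(m), c("TF1", "g1"))
  writeLines(c("id\ts1\ts2\ts3", "TF1\t1\t2\tx"), path)
  expect_error(read_expression(path), "non-numeric")
})
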