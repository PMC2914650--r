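# Synthetic-data generator: validity, boundaries, determinism, planted
# structure.

test_that("generated networks pass every structural invariant", {
  cfg <- synthetic_config(n_tf = 10, n_mirna = 5, n_gene = 50,
                          n_tf_gene = 40, n_tf_mirna = 12, n_mirna_target = 20,
                          seed = 1)
  net <- generate_network(cfg)
  expect_s3_class(net, "reg_network")  # constructor re-validates everything
  expect_equal(nrow(net$edges), 72)
  mt <- net$edges[net$edges$relation_type == "miRNA-target", ]
  expect_true(all(mt$sign == "repression"))
  expect_false(any(duplicated(net$edges[c("source", "target", "relation_type")])))
})

test_that("activation probability boundaries and frequencies hold", {
  cfg1 <- synthetic_config(n_tf = 20, n_mirna = 20, n_gene = 40,
                           n_tf_gene = 60, n_tf_mirna = 40, n_mirna_target = 20,
                           p_activation = 1, seed = 2)
  net1 <- generate_network(cfg1)
  tf_edges <- net1$edges[net1$edges$relation_type != "miRNA-target", ]
  expect_true(all(tf_edges$sign == "activation"))

  # observed activation share within 3 sigma of the default 0.79
  cfg <- synthetic_config(n_tf = 100, n_mirna = 80, n_gene = 600,
                          n_tf_gene = 1500, n_tf_mirna = 500,
                          n_mirna_target = 100, seed = 3)
  net <- generate_network(cfg)
  tf_edges <- net$edges[net$edges$relation_type != "miRNA-target", ]
  share <- mean(tf_edges$sign == "activation")
  se <- sqrt(0.79 * 0.21 / nrow(tf_edges))
  expect_lt(abs(share - 0.79), 3 * se)
})

test_that("impossible edge demands are rejected", {
  expect_error(generate_network(
    synthetic_config(n_tf = 2, n_mirna = 2, n_gene = 2, n_tf_gene = 2,
                     n_tf_mirna = 5, n_mirna_target = 2, seed = 1)),
    "exceed")
})

test_that("same seed gives byte-identical bundles, different seeds differ", {
  cfg <- synthetic_config(n_tf = 15, n_mirna = 10, n_gene = 40,
                          n_tf_gene = 50, n_tf_mirna = 20, n_mirna_target = 30,
                          n_pathways = 20, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_bundle(cfg, d1)
  write_synthetic_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  cfg2 <- synthetic_config(n_tf = 15, n_mirna = 10, n_gene = 40,
                           n_tf_gene = 50, n_tf_mirna = 20, n_mirna_target = 30,
                           n_pathways = 20, seed = 6)
  d3 <- withr::local_tempdir()
  write_synthetic_bundle(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "network.tsv")),
                         readLines(file.path(d3, "network.tsv"))))
})

test_that("a null correlation target yields a near-zero measured correlation", {
  cfg <- synthetic_config(n_tf = 400, n_mirna = 450, n_gene = 20,
                          n_tf_gene = 10, n_tf_mirna = 550, n_mirna_target = 10,
                          p_activation = 0.9, degree_skew = 0.8,
                          rho_activating = 0, rho_mirna_target = 0,
                          rho_tf_gene_activating = 0,
                          cascade_gradient_tf = 0, cascade_gradient_mirna = 0,
                          seed = 12)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  g <- stratify_edges_by_sign(net, "TF-miRNA", rates$protein, rates$mirna)$activation
  expect_gte(nrow(g), 450)
  expect_lt(abs(coevolution_correlation(g)$rho), 0.1)
})

test_that("planted cascade gradients produce opposite class directions", {
  cfg <- synthetic_config(n_tf = 80, n_mirna = 60, n_gene = 200,
                          n_tf_gene = 500, n_tf_mirna = 150,
                          n_mirna_target = 250, degree_skew = 1,
                          rho_activating = 0, rho_mirna_target = 0,
                          rho_tf_gene_activating = 0,
                          cascade_gradient_tf = 0.4,
                          cascade_gradient_mirna = -0.4, seed = 9)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  cr <- cascade_report(net, rates$protein, rates$mirna)
  expect_gt(cr$tf$fraction_upstream_lower, 0.5)
  expect_lt(cr$mirna$fraction_upstream_lower, 0.5)
})

test_that("expression profiles match the generated TF-gene edge signs", {
  cfg <- synthetic_config(n_tf = 15, n_mirna = 5, n_gene = 60,
                          n_tf_gene = 80, n_tf_mirna = 8, n_mirna_target = 10,
                          seed = 8)
  net <- generate_network(cfg)
  expr <- generate_expression(net, cfg)
  cls <- setNames(net$nodes$node_class, net$nodes$id)
  # TF targets of TF-gene edges keep independent profiles; the planted
  # sign applies to each gene's first regulator edge
  e <- as.data.frame(net$edges[net$edges$relation_type == "TF-gene" &
                                 net$edges$sign != "unknown", ])
  e <- e[cls[e$target] == "gene", ]
  first <- e[!duplicated(e$target), ]
  out <- infer_sign_from_expression(expr, first)
  expect_true(all(out$sign == first$sign))
})

test_that("rate marginals are positive, right-skewed, and capped for miRNAs", {
  cfg <- synthetic_config(n_tf = 60, n_mirna = 60, n_gene = 200,
                          n_tf_gene = 300, n_tf_mirna = 100,
                          n_mirna_target = 200, seed = 10)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  expect_true(all(rates$protein > 0))
  expect_true(all(rates$mirna >= 0 & rates$mirna <= 1))
  expect_gt(mean(rates$protein), median(rates$protein))  # right skew
  expect_setequal(names(rates$mirna),
                  net$nodes$id[net$nodes$node_class == "miRNA"])
})

test_that("the manifest records the planted parameters", {
  cfg <- synthetic_config(n_tf = 10, n_mirna = 6, n_gene = 20,
                          n_tf_gene = 25, n_tf_mirna = 10, n_mirna_target = 12,
                          rho_activating = 0.42, seed = 77)
  d <- withr::local_tempdir()
  write_synthetic_bundle(cfg, d)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(manifest$rho_activating, 0.42)
  expect_equal(manifest$seed, 77)
})
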