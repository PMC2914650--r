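# One-call orchestration of the full analysis: network in, flat result
# tables and a machine-readable JSON summary out. The numbered scripts
# under analysis/ are thin drivers over this and the module functions.

#' Run the full regulatory-network evolution analysis
#'
#' Stages, in order: network reading and topology summary; miRNA rate
#' computation from alignments (when given) or rate-table loading;
#' expression-based sign inference for TF-gene edges (when an
#' expression matrix is given); sign-stratified coevolution
#' correlations and median splits; signal preference; pathway
#' co-regulation; cascade ordering; link-perturbation sensitivity.
#' Every statistic row carries its stratum and n. One TSV is written
#' per analysis plus `summary.json`. The whole run is a pure function
#' of (inputs, seed).
#'
#' @param config named list or path to a YAML file with entries:
#'   `network` (edge TSV, required), `protein_rates` (TSV, required),
#'   `mirna_rates` (TSV) or both `alignments` (AXT) and `mirna_bed`
#'   (BED6), `pathways` (GMT, optional), `expression` (TSV, optional),
#'   `out_dir` (required), `seed` (default 1), `min_coverage` (default
#'   0.5), `analyses` (logical toggles: `coevolution`, `pathway`,
#'   `cascade`, `sensitivity`), `sensitivity` (list: `remove_frac`,
#'   `add_frac`, `n_reps`).
#' @return list of all result objects, invisibly.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  for (key in c("network", "protein_rates", "out_dir")) {
    if (is.null(cfg[[key]])) stop_fmt("config entry '%s' is required", key)
  }
  toggles <- utils::modifyList(
    list(coevolution = TRUE, pathway = TRUE, cascade = TRUE, sensitivity = TRUE),
    if (is.null(cfg$analyses)) list() else cfg$analyses)
  sens_cfg <- utils::modifyList(list(remove_frac = 0.05, add_frac = 0.05, n_reps = 100),
                                if (is.null(cfg$sensitivity)) list() else cfg$sensitivity)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  min_cov <- if (is.null(cfg$min_coverage)) 0.5 else cfg$min_coverage
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, detail = "") {
    message(sprintf("[%s] %s", name, detail))
  }
  set.seed(seed)

  # --- network -------------------------------------------------------
  net <- read_network(cfg$network)
  stage("network", sprintf("%d nodes, %d edges", nrow(net$nodes), nrow(net$edges)))
  comps <- connected_components(net)
  deg <- degree_summary(net)
  write_tsv_plain(as.data.frame(deg), out_path("degree_summary.tsv"))

  # --- rates ---------------------------------------------------------
  protein_rates <- load_rate_table(cfg$protein_rates)
  divergence_qc <- NULL
  if (!is.null(cfg$alignments) && !is.null(cfg$mirna_bed)) {
    blocks <- read_axt(cfg$alignments)
    intervals <- read_bed6(cfg$mirna_bed)
    divergence_qc <- suppressWarnings(
      divergence_table(blocks, intervals, min_fraction = min_cov))
    usable <- divergence_qc$status == "ok"
    mirna_rates <- stats::setNames(divergence_qc$rate[usable],
                                   divergence_qc$id[usable])
    write_tsv_plain(as.data.frame(divergence_qc), out_path("mirna_divergence_qc.tsv"))
    write_rate_table(mirna_rates, out_path("mirna_rates_computed.tsv"))
    stage("rates", sprintf("%d miRNA divergences computed (%d excluded)",
                           sum(usable), sum(!usable)))
  } else if (!is.null(cfg$mirna_rates)) {
    mirna_rates <- load_rate_table(cfg$mirna_rates)
    stage("rates", sprintf("%d miRNA rates loaded", length(mirna_rates)))
  } else {
    stop_fmt("config needs either 'mirna_rates' or 'alignments' + 'mirna_bed'")
  }
  rates <- list(protein = protein_rates, mirna = mirna_rates)

  # --- expression-based sign inference -------------------------------
  if (!is.null(cfg$expression)) {
    expr <- read_expression(cfg$expression)
    tg_idx <- net$edges$relation_type == "TF-gene"
    inferred <- infer_sign_from_expression(expr, as.data.frame(net$edges[tg_idx, ]))
    stage("sign_inference", sprintf("%d TF-gene edges, %d signed",
                                    nrow(inferred), sum(inferred$sign != "unknown")))
    e2 <- as.data.frame(net$edges)
    e2$sign[tg_idx] <- inferred$sign
    net <- reg_network(e2, nodes = net$nodes)
    write_tsv_plain(as.data.frame(inferred), out_path("tf_gene_signs_inferred.tsv"))
  }

  results <- list()  # flat rows: analysis, stratum, statistic, value, p, n
  add <- function(analysis, stratum, statistic, value, p, n) {
    results[[length(results) + 1]] <<- tibble::tibble(
      analysis = analysis, stratum = stratum, statistic = statistic,
      value = value, p_value = p, n = n)
  }

  # --- coevolution ---------------------------------------------------
  coevo <- NULL
  if (isTRUE(toggles$coevolution)) {
    tm <- suppressWarnings(stratify_edges_by_sign(net, "TF-miRNA",
                                                  rates$protein, rates$mirna))
    for (sgn in names(tm)) {
      g <- tm[[sgn]]
      if (nrow(g) >= 3) {
        r <- coevolution_correlation(g)
        add("coevolution_tf_mirna", sgn, "spearman_rho", r$rho, r$p_value, r$n)
      }
      if (nrow(g) >= 4) {
        m <- median_split_comparison(g, "regulator")
        add("median_split_tf_mirna", sgn, "median_low_half", m$median_a, m$p_value, m$n_a + m$n_b)
        add("median_split_tf_mirna", sgn, "median_high_half", m$median_b, m$p_value, m$n_a + m$n_b)
      }
    }
    tg <- suppressWarnings(stratify_edges_by_sign(net, "TF-gene",
                                                  rates$protein, rates$protein))
    for (sgn in names(tg)) {
      g <- tg[[sgn]]
      if (nrow(g) >= 3) {
        r <- coevolution_correlation(g)
        add("coevolution_tf_gene", sgn, "spearman_rho", r$rho, r$p_value, r$n)
      }
    }
    mt <- suppressWarnings(stratify_edges_by_sign(net, "miRNA-target",
                                                  rates$mirna, rates$protein))
    if (!is.null(mt$repression) && nrow(mt$repression) >= 4) {
      m <- median_split_comparison(mt$repression, "regulator")
      add("median_split_mirna_target", "repression", "median_low_half",
          m$median_a, m$p_value, m$n_a + m$n_b)
      add("median_split_mirna_target", "repression", "median_high_half",
          m$median_b, m$p_value, m$n_a + m$n_b)
    }
    sp <- tryCatch(signal_preference(net, rates$protein), error = function(e) NULL)
    if (!is.null(sp)) {
      add("signal_preference", "high_rate_half", "pct_activation",
          sp$pct_activation_high, sp$result$p_value, sum(sp$table[c("a", "b")]))
      add("signal_preference", "low_rate_half", "pct_activation",
          sp$pct_activation_low, sp$result$p_value, sum(sp$table[c("c", "d")]))
      add("signal_preference", "overall", "odds_ratio",
          sp$result$odds_ratio, sp$result$p_value, sum(sp$table))
    }
    coevo <- list(tf_mirna = tm, tf_gene = tg, mirna_target = mt, signal = sp)
    stage("coevolution", "sign-stratified correlations and median splits done")
  }

  # --- pathway co-regulation ----------------------------------------
  pathways <- NULL; coreg <- NULL
  if (!is.null(cfg$pathways)) pathways <- read_gmt(cfg$pathways)
  if (isTRUE(toggles$pathway) && !is.null(pathways)) {
    coreg <- coregulation_contingency(net, pathways, "pair")
    add("pathway_coregulation", "activating", "pct_common",
        coreg$pct_activating, coreg$result$p_value, sum(coreg$table[c("a", "b")]))
    add("pathway_coregulation", "repressing", "pct_common",
        coreg$pct_repressing, coreg$result$p_value, sum(coreg$table[c("c", "d")]))
    add("pathway_coregulation", "overall", "odds_ratio",
        coreg$result$odds_ratio, coreg$result$p_value, sum(coreg$table))
    stage("pathway", sprintf("OR = %.3f", coreg$result$odds_ratio))
  }

  # --- cascade -------------------------------------------------------
  casc <- NULL
  if (isTRUE(toggles$cascade)) {
    casc <- cascade_report(net, rates$protein, rates$mirna)
    for (s in list(casc$tf, casc$mirna)) {
      add("cascade", s$node_class, "fraction_upstream_lower",
          s$fraction_upstream_lower, NA_real_, s$n_pairs - s$n_ties)
    }
    if (!is.null(casc$comparison)) {
      add("cascade", "TF_vs_miRNA", "odds_ratio",
          casc$comparison$odds_ratio, casc$comparison$p_value,
          (casc$tf$n_pairs - casc$tf$n_ties) + (casc$mirna$n_pairs - casc$mirna$n_ties))
    }
    casc_df <- do.call(rbind, lapply(list(casc$tf, casc$mirna), function(s)
      data.frame(node_class = s$node_class, n_pairs = s$n_pairs,
                 n_ties = s$n_ties, n_upstream_lower = s$n_upstream_lower,
                 fraction_upstream_lower = s$fraction_upstream_lower)))
    write_tsv_plain(casc_df, out_path("cascade.tsv"))
    stage("cascade", sprintf("TF fraction %.3f, miRNA fraction %.3f",
                             casc$tf$fraction_upstream_lower,
                             casc$mirna$fraction_upstream_lower))
  }

  # --- sensitivity ---------------------------------------------------
  sens <- NULL
  if (isTRUE(toggles$sensitivity)) {
    pc <- perturbation_config(sens_cfg$remove_frac, sens_cfg$add_frac,
                              sens_cfg$n_reps, seed)
    sens <- run_sensitivity(net, rates, pathways, pc)
    write_tsv_plain(as.data.frame(sens$summary), out_path("sensitivity.tsv"))
    stage("sensitivity", sprintf("%d replicates done", pc$n_reps))
  }

  flat <- do.call(rbind, results)
  write_tsv_plain(as.data.frame(flat), out_path("statistics.tsv"))

  summary_obj <- list(
    seed = seed,
    network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                   n_components = length(comps),
                   giant_component_share =
                     if (length(comps) > 0) length(comps[[1]]) / nrow(net$nodes) else NA),
    statistics = flat,
    sensitivity = if (!is.null(sens)) sens$summary else NULL)
  jsonlite::write_json(summary_obj, out_path("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")

  invisible(list(network = net, components = comps, degree = deg,
                 rates = rates, divergence_qc = divergence_qc,
                 coevolution = coevo, pathway = coreg, cascade = casc,
                 sensitivity = sens, statistics = flat,
                 summary_path = out_path("summary.json")))
}
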