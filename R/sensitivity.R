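# Link-perturbation sensitivity analysis: robustness of every headline
# statistic to simulated network incompleteness (a fraction of true
# links removed, a fraction of spurious links added).

#' Perturbation configuration
#'
#' @param remove_frac fraction of true links removed per replicate
#'   (default 0.05).
#' @param add_frac fraction of spurious links added per replicate
#'   (default 0.05).
#' @param n_reps replicate count (default 100).
#' @param seed integer seed; replicate r is a pure function of
#'   (seed, r), independent of execution order.
#' @return a validated `perturbation_config`.
#' @export
perturbation_config <- function(remove_frac = 0.05, add_frac = 0.05,
                                n_reps = 100, seed = 1) {
  if (remove_frac < 0 || remove_frac >= 1 || add_frac < 0 || add_frac >= 1) {
    stop_fmt("perturbation fractions must lie in [0, 1)")
  }
  if (n_reps < 1) stop_fmt("n_reps must be >= 1")
  structure(list(remove_frac = remove_frac, add_frac = add_frac,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "perturbation_config")
}

# empirical sign frequencies of a relation type in the original network
sign_freqs <- function(net, relation_type) {
  s <- net$edges$sign[net$edges$relation_type == relation_type]
  if (length(s) == 0) s <- "unknown"
  table(s) / length(s)
}

#' Perturb a network by removing true and adding spurious links
#'
#' Removes `round(remove_frac * |E|)` uniformly chosen edges and adds
#' `round(add_frac * |E|)` edges absent from the original network,
#' sampled uniformly over class-compatible (source, target) pairs and
#' typed by their endpoint classes (rounding is half-up). Added TF-gene
#' and TF-miRNA edges draw their sign from the original network's
#' per-type sign frequencies; added miRNA-target edges are repressive.
#' The node set is never changed. Deterministic given
#' (`cfg$seed`, `rep_index`).
#'
#' @param net a `reg_network`.
#' @param cfg a `perturbation_config`.
#' @param rep_index replicate index (>= 1).
#' @return a `reg_network` with the same node table.
#' @export
perturb_network <- function(net, cfg, rep_index = 1) {
  stopifnot(inherits(net, "reg_network"), inherits(cfg, "perturbation_config"))
  set.seed(child_seed(cfg$seed, rep_index))
  e <- as.data.frame(net$edges)
  n_e <- nrow(e)
  n_rm <- round_half_up(cfg$remove_frac * n_e)
  n_add <- round_half_up(cfg$add_frac * n_e)
  if (n_rm > 0) e_kept <- e[-sample.int(n_e, n_rm), ] else e_kept <- e

  if (n_add > 0) {
    cls <- stats::setNames(net$nodes$node_class, net$nodes$id)
    tfs <- names(cls)[cls == "TF"]
    mirs <- names(cls)[cls == "miRNA"]
    tg_targets <- names(cls)[cls %in% c("gene", "TF")]
    # compatible pair spaces, in fixed order: TF-gene, TF-miRNA, miRNA-target
    sizes <- c(length(tfs) * length(tg_targets),
               length(tfs) * length(mirs),
               length(mirs) * length(tg_targets))
    total <- sum(sizes)
    existing <- paste(net$edges$source, net$edges$target,
                      net$edges$relation_type, sep = "\r")
    if (total - n_e < n_add) {
      stop_fmt("add_frac demands %d edges but only %d compatible non-edges exist",
               n_add, total - n_e)
    }
    decode <- function(ix) {
      if (ix <= sizes[1]) {
        s <- tfs[(ix - 1) %/% length(tg_targets) + 1]
        t <- tg_targets[(ix - 1) %% length(tg_targets) + 1]
        c(s, t, "TF-gene")
      } else if (ix <= sizes[1] + sizes[2]) {
        ix <- ix - sizes[1]
        c(tfs[(ix - 1) %/% length(mirs) + 1],
          mirs[(ix - 1) %% length(mirs) + 1], "TF-miRNA")
      } else {
        ix <- ix - sizes[1] - sizes[2]
        c(mirs[(ix - 1) %/% length(tg_targets) + 1],
          tg_targets[(ix - 1) %% length(tg_targets) + 1], "miRNA-target")
      }
    }
    freqs <- list(`TF-gene` = sign_freqs(net, "TF-gene"),
                  `TF-miRNA` = sign_freqs(net, "TF-miRNA"))
    added <- character(0)
    rows <- list()
    while (length(rows) < n_add) {
      cand <- sample.int(total, 2 * (n_add - length(rows)) + 5, replace = TRUE)
      for (ix in cand) {
        if (length(rows) >= n_add) break
        d <- decode(ix)
        key <- paste(d[1], d[2], d[3], sep = "\r")
        if (key %in% existing || key %in% added) next
        if (d[1] == d[2] && d[3] != "TF-gene") next
        sgn <- if (d[3] == "miRNA-target") "repression" else {
          f <- freqs[[d[3]]]
          sample(names(f), 1, prob = as.numeric(f))
        }
        rows[[length(rows) + 1]] <- data.frame(
          source = d[1], target = d[2], relation_type = d[3], sign = sgn,
          stringsAsFactors = FALSE)
        added <- c(added, key)
      }
    }
    e_kept <- rbind(e_kept, do.call(rbind, rows))
  }
  reg_network(e_kept, nodes = net$nodes)
}

# direction helpers: each statistic gets a sign for stability tracking
stat_row <- function(analysis, value, p, direction) {
  tibble::tibble(analysis = analysis, value = value, p_value = p,
                 direction = direction)
}

na_row <- function(analysis, err = NA_character_) {
  tibble::tibble(analysis = analysis, value = NA_real_, p_value = NA_real_,
                 direction = NA_real_)
}

#' Headline statistics of one network (used by the sensitivity loop)
#'
#' Runs the sign-stratified TF-miRNA and TF-gene coevolution
#' correlations, the miRNA-target median-split comparison, the cascade
#' conservation fractions for both regulator classes (with a two-sided
#' binomial test against 0.5), and, when pathways are given, the
#' pathway co-regulation odds ratio. Failures in a sub-analysis yield
#' NA rows rather than aborting.
#'
#' @param net a `reg_network`.
#' @param rates list with `protein` and `mirna` rate vectors.
#' @param pathways optional pathway list.
#' @return tibble with `analysis`, `value`, `p_value`, `direction`.
#' @export
sensitivity_statistics <- function(net, rates, pathways = NULL) {
  out <- list()
  grab <- function(analysis, expr) {
    res <- tryCatch(expr, error = function(e) NULL)
    out[[length(out) + 1]] <<- if (is.null(res)) na_row(analysis) else res
  }
  corr_row <- function(analysis, groups, sgn) {
    g <- groups[[sgn]]
    if (is.null(g) || nrow(g) < 3) return(na_row(analysis))
    r <- coevolution_correlation(g)
    stat_row(analysis, r$rho, r$p_value, sign(r$rho))
  }
  tm <- suppressWarnings(
    stratify_edges_by_sign(net, "TF-miRNA", rates$protein, rates$mirna))
  grab("coevo_tf_mirna_activating", corr_row("coevo_tf_mirna_activating", tm, "activation"))
  grab("coevo_tf_mirna_repressing", corr_row("coevo_tf_mirna_repressing", tm, "repression"))
  tg <- suppressWarnings(
    stratify_edges_by_sign(net, "TF-gene", rates$protein, rates$protein))
  grab("coevo_tf_gene_activating", corr_row("coevo_tf_gene_activating", tg, "activation"))
  grab("coevo_tf_gene_repressing", corr_row("coevo_tf_gene_repressing", tg, "repression"))
  grab("mirna_target_median_split", {
    mt <- suppressWarnings(
      stratify_edges_by_sign(net, "miRNA-target", rates$mirna, rates$protein))
    cmp <- median_split_comparison(mt$repression, split_on = "regulator")
    stat_row("mirna_target_median_split", cmp$median_a - cmp$median_b,
             cmp$p_value, sign(cmp$median_a - cmp$median_b))
  })
  frac_row <- function(analysis, s) {
    comp <- s$n_pairs - s$n_ties
    if (comp == 0) return(na_row(analysis))
    p <- stats::binom.test(s$n_upstream_lower, comp, 0.5)$p.value
    stat_row(analysis, s$fraction_upstream_lower, p,
             sign(s$fraction_upstream_lower - 0.5))
  }
  grab("cascade_tf_fraction", frac_row("cascade_tf_fraction",
    upstream_conservation_fraction(enumerate_ordered_pairs(net, "TF"),
                                   rates$protein, "TF")))
  grab("cascade_mirna_fraction", frac_row("cascade_mirna_fraction",
    upstream_conservation_fraction(enumerate_ordered_pairs(net, "miRNA"),
                                   rates$mirna, "miRNA")))
  if (!is.null(pathways)) {
    grab("pathway_coregulation_or", {
      cc <- coregulation_contingency(net, pathways, "pair")
      stat_row("pathway_coregulation_or", cc$result$odds_ratio,
               cc$result$p_value, sign(log(cc$result$odds_ratio)))
    })
  }
  do.call(rbind, out)
}

#' Run the link-perturbation sensitivity analysis
#'
#' Re-runs every headline statistic on `cfg$n_reps` independently
#' perturbed copies of the network and summarises, per statistic, the
#' replicate median and the share of replicates preserving the
#' unperturbed direction and the unperturbed significance status at
#' alpha = 0.05.
#'
#' @param net a `reg_network`.
#' @param rates list with `protein` and `mirna` rate vectors.
#' @param pathways optional pathway list.
#' @param cfg a `perturbation_config`.
#' @param alpha significance level for the stability shares.
#' @return A `sensitivity_report`: list with `baseline` (statistics of
#'   the unperturbed network), `replicates` (long tibble with `rep`),
#'   and `summary` (per analysis: baseline value/p, median value, and
#'   the shares `direction_stability`, `significance_stability`,
#'   `preserved`).
#' @export
run_sensitivity <- function(net, rates, pathways = NULL, cfg,
                            alpha = 0.05) {
  stopifnot(inherits(cfg, "perturbation_config"))
  baseline <- sensitivity_statistics(net, rates, pathways)
  reps <- lapply(seq_len(cfg$n_reps), function(r) {
    pn <- suppressWarnings(perturb_network(net, cfg, r))
    st <- sensitivity_statistics(pn, rates, pathways)
    st$rep <- r
    st
  })
  replicates <- do.call(rbind, reps)
  summ <- lapply(seq_len(nrow(baseline)), function(i) {
    an <- baseline$analysis[i]
    rs <- replicates[replicates$analysis == an, ]
    ok <- !is.na(rs$value)
    dir_stab <- mean(rs$direction[ok] == baseline$direction[i])
    sig_stab <- mean((rs$p_value[ok] < alpha) == (baseline$p_value[i] < alpha))
    tibble::tibble(
      analysis = an,
      baseline_value = baseline$value[i], baseline_p = baseline$p_value[i],
      median_value = stats::median(rs$value, na.rm = TRUE),
      n_ok = sum(ok),
      direction_stability = dir_stab,
      significance_stability = sig_stab,
      preserved = mean(ok & rs$direction == baseline$direction[i] &
                         (rs$p_value < alpha) == (baseline$p_value[i] < alpha)))
  })
  structure(list(baseline = baseline, replicates = replicates,
                 summary = do.call(rbind, summ), config = cfg),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d replicates, remove %.0f%% / add %.0f%%\n",
              x$config$n_reps, 100 * x$config$remove_frac,
              100 * x$config$add_frac))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}
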