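# Synthetic-data generator: networks, rates, pathways, expression and
# alignment blocks with planted statistical structure, so every pipeline
# stage can be tested end-to-end without external downloads.
#
# Planting strategy for rates: each node gets a standard-normal latent;
# a partner's latent is blended with the (scaled) sum of its regulators'
# latents (a Gaussian-copula construction), then all latents are pushed
# through a monotone lognormal quantile transform. Spearman correlations
# are invariant under the monotone transform, so the blend weight
# controls the planted rank correlation directly. The per-edge target
# correlation rho_S is converted to the latent Pearson scale via
# rho = 2 sin(pi * rho_S / 6).

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the composition of the curated human network this
#' package's analyses are designed around (425 TFs, 150 miRNAs, ~1700
#' target genes; 2655 TF-gene, 210 TF-miRNA, 1433 miRNA-target edges;
#' roughly four activating TF edges in five) with all planted effects
#' switched on. Tests and experiments run scaled-down copies.
#'
#' @param n_tf,n_mirna,n_gene node counts.
#' @param n_tf_gene,n_tf_mirna,n_mirna_target edge counts per relation
#'   type.
#' @param p_activation Bernoulli activation probability for TF-gene and
#'   TF-miRNA edges.
#' @param degree_skew exponent of the power-law-like regulator
#'   out-degree weights (larger = more hub-dominated).
#' @param tf_target_frac fraction of TF-gene / miRNA-target edges whose
#'   target is a TF rather than a gene (keeps regulator cascades alive).
#' @param rho_activating planted Spearman correlation of TF and miRNA
#'   rates across activating TF-miRNA edges.
#' @param rho_repressing same for repressing TF-miRNA edges.
#' @param rho_mirna_target planted (negative) Spearman association of
#'   miRNA and target rates across miRNA-target edges.
#' @param rho_tf_gene_activating planted Spearman correlation across
#'   activating TF-gene edges.
#' @param cascade_gradient_tf,cascade_gradient_mirna additive latent
#'   shift per unit of cascade depth, where depth is a longest-path
#'   potential from the root regulators that increases along every
#'   edge. A positive gradient makes upstream nodes slower-evolving.
#' @param pathway_or planted odds ratio of common-pathway membership,
#'   activating vs repressing TF-miRNA pairs.
#' @param n_pathways number of pathway sets.
#' @param baseline_common_prob common-pathway probability for repressing
#'   pairs (the OR baseline).
#' @param subst_prob per-site substitution probability for alignment
#'   blocks when no per-miRNA rates are supplied.
#' @param gap_prob per-site probability of a query-gap column.
#' @param interval_width miRNA interval width in bp.
#' @param n_samples expression-matrix sample count.
#' @param rate_meanlog,rate_sdlog lognormal parameters of the marginal
#'   rate distribution (right-skewed, median exp(rate_meanlog)).
#' @param seed integer RNG seed; every generator output is a pure
#'   function of the config including this seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_tf = 425, n_mirna = 150, n_gene = 1700,
                             n_tf_gene = 2655, n_tf_mirna = 210,
                             n_mirna_target = 1433,
                             p_activation = 0.79, degree_skew = 1.5,
                             tf_target_frac = 0.1,
                             rho_activating = 0.25, rho_repressing = 0,
                             rho_mirna_target = -0.2,
                             rho_tf_gene_activating = 0.1,
                             cascade_gradient_tf = 0.12,
                             cascade_gradient_mirna = -0.15,
                             pathway_or = 2.0, n_pathways = 183,
                             baseline_common_prob = 0.12,
                             subst_prob = 0.05, gap_prob = 0.02,
                             interval_width = 80, n_samples = 20,
                             rate_meanlog = log(0.05), rate_sdlog = 0.7,
                             seed = 42) {
  cfg <- as.list(environment())
  probs <- c(p_activation, tf_target_frac, baseline_common_prob,
             subst_prob, gap_prob)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0, 1]")
  rhos <- c(rho_activating, rho_repressing, rho_mirna_target,
            rho_tf_gene_activating)
  if (any(abs(rhos) > 1)) stop_fmt("planted correlations must lie in [-1, 1]")
  counts <- c(n_tf, n_mirna, n_gene, n_tf_gene, n_tf_mirna, n_mirna_target,
              n_pathways, interval_width, n_samples)
  if (any(counts < 1)) stop_fmt("counts must be positive")
  if (pathway_or <= 0) stop_fmt("pathway_or must be positive")
  structure(cfg, class = "synthetic_config")
}

# Spearman target -> latent Pearson scale (bivariate normal relation)
spearman_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)

# sample n distinct (source, target) pairs, sources weighted
sample_edge_pairs <- function(n, sources, src_weights, target_pool,
                              forbid_keys = character(0)) {
  if (n > length(sources) * length(unique(target_pool))) {
    stop_fmt("requested %d edges exceed the number of distinct pairs", n)
  }
  got_src <- character(0); got_tgt <- character(0)
  keys <- forbid_keys
  tries <- 0
  while (length(got_src) < n) {
    tries <- tries + 1
    if (tries > 200) stop_fmt("edge sampling failed to find %d distinct pairs", n)
    m <- 2 * (n - length(got_src)) + 10
    s <- sample(sources, m, replace = TRUE, prob = src_weights)
    t <- sample(target_pool, m, replace = TRUE)
    k <- paste(s, t, sep = "\r")
    ok <- s != t & !k %in% keys & !duplicated(k)
    s <- s[ok]; t <- t[ok]; k <- k[ok]
    take <- seq_len(min(length(s), n - length(got_src)))
    got_src <- c(got_src, s[take]); got_tgt <- c(got_tgt, t[take])
    keys <- c(keys, k[take])
  }
  list(source = got_src, target = got_tgt)
}

#' Generate a synthetic signed regulatory network
#'
#' Tri-partite, directed, signed; regulator out-degrees follow
#' power-law-like weights (exponent `degree_skew`), all miRNA-target
#' edges are repressive, TF-originating edges are activating with
#' probability `p_activation`. A fraction `tf_target_frac` of TF-gene
#' and miRNA-target edges point at TFs so that regulator cascades of
#' depth > 1 exist. Deterministic given `cfg$seed`.
#'
#' @param cfg a `synthetic_config`.
#' @return a `reg_network`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 0))
  tfs <- sprintf("TF%04d", seq_len(cfg$n_tf))
  mirs <- sprintf("mir%04d", seq_len(cfg$n_mirna))
  genes <- sprintf("g%05d", seq_len(cfg$n_gene))
  w_tf <- sample(seq_len(cfg$n_tf)^(-cfg$degree_skew))
  w_mir <- sample(seq_len(cfg$n_mirna)^(-cfg$degree_skew))

  mixed_targets <- function() {
    # pool with TFs over-represented per tf_target_frac
    n_tf_slots <- max(1, round_half_up(cfg$tf_target_frac * length(genes) /
                                         max(1e-9, 1 - cfg$tf_target_frac)))
    c(genes, sample(tfs, min(n_tf_slots, length(tfs))))
  }

  tg <- sample_edge_pairs(cfg$n_tf_gene, tfs, w_tf, mixed_targets())
  tm <- sample_edge_pairs(cfg$n_tf_mirna, tfs, w_tf, mirs)
  mt <- sample_edge_pairs(cfg$n_mirna_target, mirs, w_mir, mixed_targets())

  edges <- rbind(
    data.frame(source = tg$source, target = tg$target,
               relation_type = "TF-gene",
               sign = ifelse(stats::runif(cfg$n_tf_gene) < cfg$p_activation,
                             "activation", "repression"),
               stringsAsFactors = FALSE),
    data.frame(source = tm$source, target = tm$target,
               relation_type = "TF-miRNA",
               sign = ifelse(stats::runif(cfg$n_tf_mirna) < cfg$p_activation,
                             "activation", "repression"),
               stringsAsFactors = FALSE),
    data.frame(source = mt$source, target = mt$target,
               relation_type = "miRNA-target", sign = "repression",
               stringsAsFactors = FALSE))
  reg_network(edges)
}

# cascade depth used when planting rate gradients: a node potential that
# increases along every edge (longest-path relaxation from the roots,
# capped to terminate on the rare directed cycle). A potential of this
# kind is consistent with the reachability ordering -- whenever A is
# upstream of B, depth(A) < depth(B) (outside cycles) -- which a
# min-distance from roots is not, because a downstream node can sit at
# depth 1 via some other root.
node_depths <- function(net) {
  ids <- net$nodes$id
  depth <- stats::setNames(rep(0, length(ids)), ids)
  if (nrow(net$edges) == 0) return(depth)
  g <- as_igraph(net)
  scc <- igraph::components(g, mode = "strong")
  cond <- igraph::contract(g, scc$membership)
  cond <- igraph::simplify(cond)
  # longest-path relaxation in topological order of the condensation DAG
  topo <- as.integer(igraph::topo_sort(cond, mode = "out"))
  cdepth <- rep(0, igraph::vcount(cond))
  el <- igraph::as_edgelist(cond, names = FALSE)
  for (v in topo) {
    outs <- el[el[, 1] == v, 2]
    if (length(outs) > 0) cdepth[outs] <- pmax(cdepth[outs], cdepth[v] + 1)
  }
  depth[ids] <- cdepth[scc$membership[match(ids, igraph::V(g)$name)]]
  depth
}

# regulator lists per planted channel, precomputed once per network
channel_structure <- function(net) {
  e <- net$edges
  cls <- stats::setNames(net$nodes$node_class, net$nodes$id)
  tm <- e[e$relation_type == "TF-miRNA", ]
  tg <- e[e$relation_type == "TF-gene" & e$sign == "activation", ]
  mt <- e[e$relation_type == "miRNA-target", ]
  list(
    tfs = names(cls)[cls == "TF"],
    mirs = names(cls)[cls == "miRNA"],
    genes = names(cls)[cls == "gene"],
    act_regs = split(tm$source[tm$sign == "activation"],
                     tm$target[tm$sign == "activation"]),
    rep_regs = split(tm$source[tm$sign == "repression"],
                     tm$target[tm$sign == "repression"]),
    tg_regs = split(tg$source, tg$target),
    mt_regs = split(mt$source, mt$target),
    edges_act = tm[tm$sign == "activation", c("source", "target")],
    edges_rep = tm[tm$sign == "repression", c("source", "target")],
    edges_tg = tg[, c("source", "target")],
    edges_mt = mt[, c("source", "target")])
}

# one draw of node latents under latent-scale blend coefficients;
# coefs: list(act, rep, tg, mt), each a latent Pearson coefficient
plant_latents <- function(st, coefs) {
  u <- stats::setNames(
    stats::rnorm(length(st$tfs) + length(st$mirs) + length(st$genes)),
    c(st$tfs, st$mirs, st$genes))
  blend <- function(id, channels) {
    # channels: list of list(regs, coef); blends scaled regulator sums
    bs <- numeric(0); zs <- numeric(0)
    for (ch in channels) {
      regs <- ch$regs[[id]]
      if (is.null(regs) || length(regs) == 0 || ch$coef == 0) next
      k <- length(regs)
      bs <- c(bs, min(1, abs(ch$coef) * sqrt(k)) * sign(ch$coef))
      zs <- c(zs, sum(u[regs]) / sqrt(k))
    }
    if (length(bs) == 0) return(u[[id]])
    tot <- sum(bs^2)
    if (tot > 1) { bs <- bs / sqrt(tot); tot <- 1 }
    sum(bs * zs) + sqrt(1 - tot) * u[[id]]
  }
  for (m in st$mirs) {
    u[[m]] <- blend(m, list(list(regs = st$act_regs, coef = coefs$act),
                            list(regs = st$rep_regs, coef = coefs$rep)))
  }
  for (g in st$genes) {
    u[[g]] <- blend(g, list(list(regs = st$tg_regs, coef = coefs$tg),
                            list(regs = st$mt_regs, coef = coefs$mt)))
  }
  u
}

# realized pooled Spearman of one channel's edge list under latents u
channel_spearman <- function(u, edges) {
  if (nrow(edges) < 3) return(NA_real_)
  stats::cor(rank(u[edges$source]), rank(u[edges$target]))
}

# Calibrate latent blend coefficients so the realized pooled Spearman
# per channel matches its target under the realized topology (including
# any cascade-gradient shift). Two effects make the naive coefficient
# miss the target: hub regulators duplicate their latent across many
# edges, attenuating the pooled rank correlation, and gradient shifts
# add depth-structured covariance of their own. The realized
# correlation is monotone in the blend coefficient, so a short
# bisection against a small Monte-Carlo estimate suffices; when even
# the maximal coefficient cannot reach the target the channel is left
# at the cap.
calibrate_coefs <- function(st, targets, shift = 0, n_draws = 8,
                            n_iter = 7) {
  coefs <- lapply(targets, spearman_to_latent)
  edges_of <- list(act = st$edges_act, rep = st$edges_rep,
                   tg = st$edges_tg, mt = st$edges_mt)
  realized <- function(ch) {
    mean(replicate(n_draws, channel_spearman(plant_latents(st, coefs) + shift,
                                             edges_of[[ch]])))
  }
  for (ch in names(coefs)) {
    tgt <- targets[[ch]]
    if (tgt == 0 || nrow(edges_of[[ch]]) < 3) next
    lo <- -0.999; hi <- 0.999
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      coefs[[ch]] <- mid
      r <- realized(ch)
      if (is.na(r)) break
      if (r < tgt) lo <- mid else hi <- mid
    }
    coefs[[ch]] <- (lo + hi) / 2
  }
  coefs
}

#' Generate evolutionary rates with planted structure
#'
#' Rates for TFs and genes play the role of protein dN; rates for
#' miRNAs the role of sequence divergence. Activating TF-miRNA edges
#' carry a planted Spearman correlation `rho_activating` (repressing
#' edges `rho_repressing`), miRNA-target edges a planted
#' `rho_mirna_target` (negative by default), activating TF-gene edges
#' `rho_tf_gene_activating`; cascade depth shifts latents by the
#' per-class gradients. Marginals are lognormal (right-skewed);
#' miRNA rates are capped at 1. Deterministic given `cfg$seed`.
#'
#' @param net a `reg_network` (typically from [generate_network()]).
#' @param cfg the `synthetic_config` used to build it.
#' @return list with named numeric vectors `protein` (TFs and genes)
#'   and `mirna`.
#' @export
generate_rates <- function(net, cfg) {
  stopifnot(inherits(net, "reg_network"), inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 1))
  st <- channel_structure(net)
  tfs <- st$tfs; mirs <- st$mirs; genes <- st$genes

  targets <- list(act = cfg$rho_activating, rep = cfg$rho_repressing,
                  tg = cfg$rho_tf_gene_activating, mt = cfg$rho_mirna_target)
  depth <- node_depths(net)
  shift <- stats::setNames(rep(0, length(depth)), names(depth))
  shift[tfs] <- cfg$cascade_gradient_tf * depth[tfs]
  shift[mirs] <- cfg$cascade_gradient_mirna * depth[mirs]
  # calibrate against the gradient-shifted latents so the requested
  # correlations hold under all planted effects simultaneously
  coefs <- calibrate_coefs(st, targets, shift = shift[c(st$tfs, st$mirs, st$genes)])
  u <- plant_latents(st, coefs) + shift[c(st$tfs, st$mirs, st$genes)]

  to_rate <- function(z) stats::qlnorm(stats::pnorm(scale_robust(z)),
                                       cfg$rate_meanlog, cfg$rate_sdlog)
  prot <- to_rate(u[c(tfs, genes)])
  mir_rate <- to_rate(u[mirs])
  mir_rate[mir_rate > 1] <- 1  # divergence is a proportion
  list(protein = prot, mirna = mir_rate)
}

# center/scale so depth shifts do not push the whole distribution into
# the tails of the quantile transform; monotone, so rank structure kept
scale_robust <- function(z) {
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(z - mean(z))
  (z - mean(z)) / s
}

#' Generate pathway sets with planted co-membership enrichment
#'
#' Every signed TF-miRNA edge independently becomes a common-pathway
#' pair with probability `baseline_common_prob` (repressing) or the
#' probability whose odds are `pathway_or` times larger (activating);
#' common pairs are dropped into one shared pathway, other pairs into
#' two distinct pathways. Random filler genes pad each pathway.
#' Deterministic given `cfg$seed`.
#'
#' @param net a `reg_network`.
#' @param cfg a `synthetic_config`.
#' @return named list of member-id vectors (empty pathways dropped).
#' @export
generate_pathways <- function(net, cfg) {
  stopifnot(inherits(net, "reg_network"), inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 2))
  e <- net$edges[net$edges$relation_type == "TF-miRNA" &
                   net$edges$sign %in% c("activation", "repression"), ]
  odds0 <- cfg$baseline_common_prob / (1 - cfg$baseline_common_prob)
  odds1 <- cfg$pathway_or * odds0
  p_common <- c(activation = odds1 / (1 + odds1),
                repression = cfg$baseline_common_prob)
  sets <- vector("list", cfg$n_pathways)
  names(sets) <- sprintf("pathway_%03d", seq_len(cfg$n_pathways))
  for (i in seq_len(nrow(e))) {
    # only common pairs get a shared placement; non-common pairs get no
    # membership from this edge, so accidental co-memberships (possible
    # through a hub's other placements) stay rare
    if (stats::runif(1) < p_common[[e$sign[i]]]) {
      j <- sample.int(cfg$n_pathways, 1)
      sets[[j]] <- c(sets[[j]], e$source[i], e$target[i])
    }
  }
  genes <- net$nodes$id[net$nodes$node_class == "gene"]
  for (j in seq_len(cfg$n_pathways)) {
    n_fill <- sample(5:15, 1)
    if (length(genes) > 0) {
      sets[[j]] <- c(sets[[j]], sample(genes, min(n_fill, length(genes))))
    }
  }
  sets <- lapply(sets, unique)
  sets[lengths(sets) > 0]
}

#' Generate an expression matrix consistent with TF-gene edge signs
#'
#' TFs get independent standard-normal profiles; each gene with a
#' TF-gene regulator follows its first regulator's profile with the
#' edge's sign (blend weight 0.8), resampled until the Spearman
#' correlation sign matches the edge sign. Deterministic given
#' `cfg$seed`.
#'
#' @param net a `reg_network`.
#' @param cfg a `synthetic_config`.
#' @return numeric matrix, rows = TFs and genes, columns = samples.
#' @export
generate_expression <- function(net, cfg) {
  stopifnot(inherits(net, "reg_network"), inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 3))
  cls <- stats::setNames(net$nodes$node_class, net$nodes$id)
  tfs <- names(cls)[cls == "TF"]
  genes <- names(cls)[cls == "gene"]
  ns <- cfg$n_samples
  expr <- matrix(stats::rnorm(length(tfs) * ns), nrow = length(tfs),
                 dimnames = list(tfs, sprintf("s%02d", seq_len(ns))))
  w <- 0.8
  gm <- matrix(NA_real_, nrow = length(genes), ncol = ns,
               dimnames = list(genes, colnames(expr)))
  e <- net$edges[net$edges$relation_type == "TF-gene" &
                   net$edges$sign %in% c("activation", "repression"), ]
  first_reg <- e[!duplicated(e$target), ]
  reg_of <- stats::setNames(first_reg$source, first_reg$target)
  sign_of <- stats::setNames(ifelse(first_reg$sign == "activation", 1, -1),
                             first_reg$target)
  for (g in genes) {
    if (g %in% names(reg_of)) {
      x <- expr[reg_of[[g]], ]
      s <- sign_of[[g]]
      y <- s * x
      for (try in 1:20) {
        cand <- s * (w * x + sqrt(1 - w^2) * stats::rnorm(ns))
        r <- stats::cor(rank(x), rank(cand))
        if (is.finite(r) && sign(r) == s) { y <- cand; break }
      }
      gm[g, ] <- y
    } else {
      gm[g, ] <- stats::rnorm(ns)
    }
  }
  rbind(expr, gm)
}

#' Genomic intervals for the network's miRNAs
#'
#' Synthetic coordinates: intervals of width `cfg$interval_width`, laid
#' out non-overlapping across five chromosomes on the + strand.
#'
#' @param net a `reg_network`.
#' @param cfg a `synthetic_config`.
#' @return interval tibble (`id`, `chrom`, `start`, `end`, `strand`).
#' @export
generate_mirna_intervals <- function(net, cfg) {
  mirs <- sort(net$nodes$id[net$nodes$node_class == "miRNA"])
  i <- seq_along(mirs)
  start <- 1000L + 1000L * ((i - 1L) %/% 5L)
  tibble::tibble(id = mirs,
                 chrom = sprintf("chr%d", ((i - 1L) %% 5L) + 1L),
                 start = start,
                 end = start + as.integer(cfg$interval_width),
                 strand = "+")
}

#' Generate pairwise alignment blocks over miRNA intervals
#'
#' One block per interval (with 5 bp flanks), i.i.d. per-site
#' substitutions and occasional query-gap columns. When `rates` is
#' supplied, each interval's substitution probability is its planted
#' rate, so downstream divergence estimation recovers the planted rate
#' structure; otherwise the global `cfg$subst_prob` applies.
#' Deterministic given `cfg$seed`.
#'
#' @param intervals interval tibble (see [generate_mirna_intervals()]).
#' @param cfg a `synthetic_config`.
#' @param rates optional named per-interval substitution probabilities.
#' @return alignment-block tibble (see [read_axt()]).
#' @export
generate_alignments <- function(intervals, cfg, rates = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 4))
  bases <- c("A", "C", "G", "T")
  flank <- 5L
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    p <- if (!is.null(rates)) unname(rates[iv$id]) else cfg$subst_prob
    if (is.na(p)) p <- cfg$subst_prob
    p <- min(1, p)
    start <- max(0L, iv$start - flank)
    len <- iv$end + flank - start
    ref <- sample(bases, len, replace = TRUE)
    query <- ref
    sub_at <- stats::runif(len) < p
    query[sub_at] <- vapply(ref[sub_at],
                            function(b) sample(setdiff(bases, b), 1),
                            character(1))
    query[stats::runif(len) < cfg$gap_prob] <- "-"
    tibble::tibble(ref_chrom = iv$chrom, ref_start = start,
                   ref_end = start + len,
                   ref_aln = paste(ref, collapse = ""),
                   query_aln = paste(query, collapse = ""))
  })
  do.call(rbind, rows)
}

#' Generate and write a complete synthetic input bundle
#'
#' Emits exactly the formats the pipeline reads (edge TSV, rate TSVs,
#' BED, AXT, GMT, expression TSV) plus `manifest.json` recording the
#' planted parameters for recovery tests. Same seed, byte-identical
#' files.
#'
#' @param cfg a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly; also the generated
#'   objects in the `objects` element.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(cfg)
  rates <- generate_rates(net, cfg)
  pathways <- generate_pathways(net, cfg)
  expr <- generate_expression(net, cfg)
  intervals <- generate_mirna_intervals(net, cfg)
  blocks <- generate_alignments(intervals, cfg, rates = rates$mirna)

  paths <- list(
    network = file.path(dir, "network.tsv"),
    protein_rates = file.path(dir, "protein_rates.tsv"),
    mirna_rates = file.path(dir, "mirna_rates.tsv"),
    mirna_bed = file.path(dir, "mirna.bed"),
    alignments = file.path(dir, "alignments.axt"),
    pathways = file.path(dir, "pathways.gmt"),
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_network(net, paths$network)
  write_rate_table(rates$protein, paths$protein_rates)
  write_rate_table(rates$mirna, paths$mirna_rates)
  write_bed6(intervals, paths$mirna_bed)
  write_axt(blocks, paths$alignments)
  write_gmt(pathways, paths$pathways)
  expr_df <- data.frame(id = rownames(expr), expr, check.names = FALSE)
  write_tsv_plain(expr_df, paths$expression)
  jsonlite::write_json(unclass(cfg), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(objects = list(
    network = net, rates = rates, pathways = pathways,
    expression = expr, intervals = intervals, alignments = blocks))))
}
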