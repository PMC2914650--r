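# Cascade ordering: shortest paths, upstream/downstream regulator pairs,
# and the upstream-conservation fraction.
#
# "Upstream" means directed reachability over all edge types: A is
# upstream of B when a directed path A => B exists and no return path
# B => A exists. Mutually reachable pairs are excluded rather than
# counted under both orientations (conservative cycle rule). Rate ties
# are excluded from the fraction's denominator because "lower rate" is
# strict.

#' Shortest directed path lengths from one source node
#'
#' Unit edge weights; on an unweighted graph Dijkstra's algorithm
#' reduces to breadth-first search, which is what runs underneath.
#' Unreachable nodes are absent from the result.
#'
#' @param net a `reg_network`.
#' @param source a node id present in the network.
#' @return named numeric vector of path lengths, `source` included with
#'   length 0.
#' @export
shortest_path_lengths <- function(net, source) {
  stopifnot(inherits(net, "reg_network"))
  if (!source %in% net$nodes$id) stop_fmt("unknown source id '%s'", source)
  d <- igraph::distances(as_igraph(net), v = source, mode = "out")[1, ]
  d[is.finite(d)]
}

# reachability matrix among a node subset (finite directed distance)
reachability_among <- function(net, ids) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = ids, to = ids, mode = "out")
  is.finite(d)
}

#' Ordered upstream/downstream pairs within a regulator class
#'
#' Pair (A, B) is emitted iff both nodes are of `node_class`, A != B,
#' a directed path A => B exists, and no directed path B => A exists.
#' Each unordered pair therefore contributes at most one ordered pair.
#'
#' @param net a `reg_network`.
#' @param node_class `"TF"` or `"miRNA"`.
#' @return tibble with columns `upstream`, `downstream`, sorted for
#'   reproducibility.
#' @export
enumerate_ordered_pairs <- function(net, node_class = c("TF", "miRNA")) {
  node_class <- match.arg(node_class)
  ids <- sort(net$nodes$id[net$nodes$node_class == node_class])
  if (length(ids) < 2) {
    return(tibble::tibble(upstream = character(0), downstream = character(0)))
  }
  reach <- reachability_among(net, ids)
  keep <- reach & !t(reach)
  diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(upstream = ids[idx[, 1]], downstream = ids[idx[, 2]])
  out[order(out$upstream, out$downstream), ]
}

#' Fraction of cascade pairs with the lower rate upstream
#'
#' Pairs in which either member lacks a rate are dropped (and counted);
#' pairs with exactly equal rates are counted as ties and excluded from
#' the fraction's denominator.
#'
#' @param pairs tibble from [enumerate_ordered_pairs()].
#' @param rates named numeric rate vector covering (some of) the nodes.
#' @param node_class label carried into the summary (`"TF"`/`"miRNA"`).
#' @return A `cascade_pair_summary`: list with `node_class`, `n_pairs`
#'   (rated pairs), `n_dropped_missing_rate`, `n_upstream_lower`,
#'   `n_ties`, `fraction_upstream_lower` (NA when no comparable pairs).
#' @export
upstream_conservation_fraction <- function(pairs, rates, node_class = "") {
  up <- rates[pairs$upstream]
  dn <- rates[pairs$downstream]
  has <- !is.na(up) & !is.na(dn)
  n_dropped <- sum(!has)
  up <- up[has]; dn <- dn[has]
  n_pairs <- length(up)
  n_ties <- sum(up == dn)
  n_lower <- sum(up < dn)
  comparable <- n_pairs - n_ties
  structure(list(
    node_class = node_class,
    n_pairs = n_pairs,
    n_dropped_missing_rate = n_dropped,
    n_upstream_lower = n_lower,
    n_ties = n_ties,
    fraction_upstream_lower = if (comparable > 0) n_lower / comparable else NA_real_
  ), class = "cascade_pair_summary")
}

#' @export
print.cascade_pair_summary <- function(x, ...) {
  cat(sprintf("Cascade pairs (%s): %d pairs (%d ties, %d dropped); upstream lower in %d (%.1f%%)\n",
              x$node_class, x$n_pairs, x$n_ties, x$n_dropped_missing_rate,
              x$n_upstream_lower, 100 * x$fraction_upstream_lower))
  invisible(x)
}

#' Compare upstream-conservation fractions between TF and miRNA pairs
#'
#' Builds the 2x2 table (class x upstream-lower yes/no), TFs as row 1,
#' and applies Fisher's exact test. Tied pairs are excluded, consistent
#' with the fraction itself.
#'
#' @param tf_summary,mirna_summary `cascade_pair_summary` objects.
#' @return A `contingency_result`.
#' @export
compare_class_fractions <- function(tf_summary, mirna_summary) {
  comp_tf <- tf_summary$n_pairs - tf_summary$n_ties
  comp_mir <- mirna_summary$n_pairs - mirna_summary$n_ties
  if (comp_tf == 0 || comp_mir == 0) {
    stop_fmt("no comparable pairs in one of the classes")
  }
  fisher_exact_2x2(contingency_2x2(
    tf_summary$n_upstream_lower, comp_tf - tf_summary$n_upstream_lower,
    mirna_summary$n_upstream_lower, comp_mir - mirna_summary$n_upstream_lower))
}

#' Cascade report for both regulator classes
#'
#' Convenience wrapper running pair enumeration and the conservation
#' fraction for TFs and miRNAs, plus the between-class Fisher test.
#'
#' @param net a `reg_network`.
#' @param tf_rates,mirna_rates named numeric rate vectors.
#' @return list with `tf`, `mirna` (`cascade_pair_summary`) and
#'   `comparison` (`contingency_result`, NULL when either class has no
#'   comparable pairs).
#' @export
cascade_report <- function(net, tf_rates, mirna_rates) {
  tf_sum <- upstream_conservation_fraction(
    enumerate_ordered_pairs(net, "TF"), tf_rates, "TF")
  mir_sum <- upstream_conservation_fraction(
    enumerate_ordered_pairs(net, "miRNA"), mirna_rates, "miRNA")
  cmp <- NULL
  if ((tf_sum$n_pairs - tf_sum$n_ties) > 0 && (mir_sum$n_pairs - mir_sum$n_ties) > 0) {
    cmp <- compare_class_fractions(tf_sum, mir_sum)
  }
  list(tf = tf_sum, mirna = mir_sum, comparison = cmp)
}
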