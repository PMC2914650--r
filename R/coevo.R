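# Sign-stratified coevolution analyses.
#
# Each EDGE is one observation: a regulator appearing in k edges
# contributes k (regulator rate, partner rate) pairs, matching the
# "pair" language of the underlying analyses. This pseudo-replicates
# hub regulators; the trade-off is documented in the methods vignette.

#' Partition rated edges of one relation type by sign
#'
#' Edges whose regulator or partner lacks a rate are dropped, with a
#' count per sign recorded in the result's `dropped` attribute.
#'
#' @param net a `reg_network`.
#' @param relation_type one of `"TF-gene"`, `"TF-miRNA"`,
#'   `"miRNA-target"`.
#' @param rates_regulator named rates for edge sources.
#' @param rates_partner named rates for edge targets.
#' @return named list (by sign present) of `edge_group` tibbles with
#'   columns `regulator`, `partner`, `rate_regulator`, `rate_partner`;
#'   attribute `dropped` gives per-sign counts of unrated edges.
#' @export
stratify_edges_by_sign <- function(net, relation_type, rates_regulator,
                                   rates_partner) {
  stopifnot(inherits(net, "reg_network"))
  e <- net$edges[net$edges$relation_type == relation_type, ]
  if (nrow(e) == 0) {
    warn_fmt("no edges of type %s in network", relation_type)
    return(structure(list(), dropped = integer(0)))
  }
  rr <- rates_regulator[e$source]
  rp <- rates_partner[e$target]
  rated <- !is.na(rr) & !is.na(rp)
  dropped <- table(e$sign[!rated])
  e <- e[rated, ]; rr <- rr[rated]; rp <- rp[rated]
  groups <- lapply(split(seq_len(nrow(e)), e$sign), function(i) {
    g <- tibble::tibble(regulator = e$source[i], partner = e$target[i],
                        rate_regulator = unname(rr[i]),
                        rate_partner = unname(rp[i]))
    # deterministic ordering for reproducible downstream splits
    g <- g[order(g$regulator, g$partner), ]
    class(g) <- c("edge_group", class(g))
    g
  })
  structure(groups, dropped = dropped)
}

#' Coevolution correlation within an edge group
#'
#' Spearman correlation of regulator and partner evolutionary rates,
#' one observation per edge.
#'
#' @param group an `edge_group` tibble.
#' @return A `correlation_result`.
#' @export
coevolution_correlation <- function(group) {
  if (is.null(group) || nrow(group) < 3) {
    stop_fmt("need at least 3 rated pairs for a correlation")
  }
  spearman_cor(group$rate_regulator, group$rate_partner)
}

# split a group into low/high halves by one member's rate; ties at the
# boundary broken by (regulator, partner) id; odd counts put the middle
# element in the LOW half
median_split_halves <- function(group, split_on = c("regulator", "partner")) {
  split_on <- match.arg(split_on)
  key <- if (split_on == "regulator") group$rate_regulator else group$rate_partner
  ord <- order(key, group$regulator, group$partner)
  n <- length(ord)
  n_low <- ceiling(n / 2)
  list(low = group[ord[seq_len(n_low)], ],
       high = group[ord[seq(n_low + 1, n)], ])
}

#' Median-split comparison of partner rates
#'
#' Pairs are sorted by the `split_on` member's rate and split into a low
#' and a high half (middle pair to the low half on odd counts; boundary
#' ties broken lexicographically by edge id). The OTHER member's rates
#' in the two halves are compared by the Wilcoxon rank-sum test.
#'
#' @param group an `edge_group` tibble with at least 4 pairs.
#' @param split_on which member's rate defines the split.
#' @return A `group_comparison_result` (`median_a` = low half).
#' @export
median_split_comparison <- function(group, split_on = c("regulator", "partner")) {
  split_on <- match.arg(split_on)
  if (is.null(group) || nrow(group) < 4) stop_fmt("need at least 4 pairs for a median split")
  halves <- median_split_halves(group, split_on)
  other <- if (split_on == "regulator") "rate_partner" else "rate_regulator"
  wilcoxon_rank_sum(halves$low[[other]], halves$high[[other]])
}

#' Signal preference of rapidly vs slowly evolving TFs
#'
#' TF-miRNA edges with known sign and a rated TF are split into two
#' halves by TF rate (same convention as [median_split_comparison()]).
#' The 2x2 table counts activation vs repression signals in the
#' high-rate (row 1) and low-rate (row 2) halves; Fisher's exact test
#' is applied.
#'
#' @param net a `reg_network`.
#' @param tf_rates named numeric rates for TFs.
#' @return list with `table` (`contingency_2x2`), `result`
#'   (`contingency_result`), `pct_activation_high`, `pct_activation_low`.
#' @export
signal_preference <- function(net, tf_rates) {
  e <- net$edges[net$edges$relation_type == "TF-miRNA" &
                   net$edges$sign %in% c("activation", "repression"), ]
  rr <- tf_rates[e$source]
  e <- e[!is.na(rr), ]
  if (nrow(e) < 4) stop_fmt("no (or too few) signed TF-miRNA edges with rated TFs")
  g <- tibble::tibble(regulator = e$source, partner = e$target,
                      rate_regulator = unname(tf_rates[e$source]),
                      rate_partner = NA_real_, sign = e$sign)
  halves <- median_split_halves(g, "regulator")
  n_act_high <- sum(halves$high$sign == "activation")
  n_rep_high <- sum(halves$high$sign == "repression")
  n_act_low <- sum(halves$low$sign == "activation")
  n_rep_low <- sum(halves$low$sign == "repression")
  tab <- contingency_2x2(n_act_high, n_rep_high, n_act_low, n_rep_low)
  res <- fisher_exact_2x2(tab)
  list(table = tab, result = res,
       pct_activation_high = res$pct_row1,
       pct_activation_low = res$pct_row2)
}

#' Read an expression matrix from TSV
#'
#' Rows are genes (first column = id), columns are samples; header row
#' required; all rows must have the same number (>= 3) of samples.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = gene ids.
#' @export
read_expression <- function(path) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 4) stop_fmt("expression matrix needs >= 3 sample columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop_fmt("duplicate gene id in expression matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(`mode<-`(m, "numeric"))
  if (anyNA(m)) stop_fmt("non-numeric expression value")
  rownames(m) <- ids
  m
}

#' Infer TF-gene edge signs from expression correlation
#'
#' Per-edge Spearman correlation of the two expression profiles:
#' positive above `min_abs_rho` gives activation, negative below
#' `-min_abs_rho` repression, anything else (including undefined
#' correlations from constant profiles, or endpoints missing from the
#' matrix) stays `unknown`.
#'
#' @param expr numeric expression matrix (rownames = ids).
#' @param edges data frame with `source`, `target` (TF-gene edges).
#' @param min_abs_rho minimum |rho| to call a sign (default 0: the bare
#'   sign of the correlation decides).
#' @return tibble `source`, `target`, `sign`, `rho`, `flag`
#'   (`ok` or `missing_profile`).
#' @export
infer_sign_from_expression <- function(expr, edges, min_abs_rho = 0) {
  n <- nrow(edges)
  rho <- rep(NA_real_, n)
  sign_out <- rep("unknown", n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    s <- edges$source[i]; t <- edges$target[i]
    if (!(s %in% rownames(expr)) || !(t %in% rownames(expr))) {
      flag[i] <- "missing_profile"
      next
    }
    x <- expr[s, ]; y <- expr[t, ]
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    r <- stats::cor(rank(x), rank(y))
    rho[i] <- r
    if (r > min_abs_rho) sign_out[i] <- "activation"
    else if (r < -min_abs_rho) sign_out[i] <- "repression"
  }
  tibble::tibble(source = edges$source, target = edges$target,
                 sign = sign_out, rho = rho, flag = flag)
}
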