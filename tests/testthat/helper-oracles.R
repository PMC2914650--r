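# Brute-force oracles, kept independent of the package implementations
# they check.

# all permutations of 1..n as a matrix (rows = permutations)
perm_matrix <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rec <- function(v) {
      if (length(v) == 1) return(matrix(v, 1, 1))
      out <- NULL
      for (i in seq_along(v)) {
        sub <- rec(v[-i])
        out <- rbind(out, cbind(v[i], sub))
      }
      out
    }
    m <- rec(seq_len(n))
    cache[[key]] <<- m
    m
  }
})

# exact two-sided Spearman p by full permutation enumeration (no ties)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  P <- perm_matrix(n)
  # rho for every permutation of y's ranks against x's ranks
  s_all <- rowSums((matrix(rx[P], nrow(P)) - matrix(ry, nrow(P), n, byrow = TRUE))^2)
  rho_all <- 1 - 6 * s_all / (n * (n^2 - 1))
  r_obs <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  min(1, 2 * min(mean(rho_all <= r_obs + 1e-12), mean(rho_all >= r_obs - 1e-12)))
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cmb <- utils::combn(na + nb, na)
  u_all <- apply(cmb, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-12), mean(u_all >= u_obs - 1e-12)))
}

# two-sided Fisher p by hypergeometric enumeration (probability-mass rule)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# weakly connected components by label propagation to a fixpoint
oracle_components <- function(ids, src, tgt) {
  lab <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(src)) {
      l <- min(lab[[src[i]]], lab[[tgt[i]]])
      if (lab[[src[i]]] != l || lab[[tgt[i]]] != l) {
        lab[[src[i]]] <- l; lab[[tgt[i]]] <- l
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(ids, lab[ids]))
}

# BFS shortest path lengths with unit weights
oracle_bfs <- function(ids, src, tgt, from) {
  adj <- split(tgt, factor(src, levels = ids))
  dist <- stats::setNames(rep(NA_real_, length(ids)), ids)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist[!is.na(dist)]
}

# full transitive closure by Floyd-Warshall style boolean relaxation
oracle_reachability <- function(ids, src, tgt) {
  n <- length(ids)
  reach <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  reach[cbind(src, tgt)] <- TRUE
  for (k in seq_len(n)) {
    reach <- reach | outer(reach[, k], reach[k, ], `&`)
  }
  reach
}

# small random valid edge list for property tests
random_edge_df <- function(n_tf = 6, n_mir = 4, n_gene = 10, n_edges = 20) {
  tfs <- paste0("T", seq_len(n_tf))
  mirs <- paste0("m", seq_len(n_mir))
  genes <- paste0("g", seq_len(n_gene))
  rows <- list()
  keys <- character(0)
  while (length(rows) < n_edges) {
    rt <- sample(c("TF-gene", "TF-miRNA", "miRNA-target"), 1)
    if (rt == "TF-gene") {
      s <- sample(tfs, 1); t <- sample(c(genes, tfs), 1)
    } else if (rt == "TF-miRNA") {
      s <- sample(tfs, 1); t <- sample(mirs, 1)
    } else {
      s <- sample(mirs, 1); t <- sample(genes, 1)
    }
    key <- paste(s, t, rt)
    if (s == t || key %in% keys) next
    keys <- c(keys, key)
    rows[[length(rows) + 1]] <- data.frame(
      source = s, target = t, relation_type = rt,
      sign = if (rt == "miRNA-target") "repression"
             else sample(c("activation", "repression"), 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# hand-built alignment block covering [start, end) on chrom
toy_block <- function(chrom, start, ref, query) {
  tibble::tibble(ref_chrom = chrom, ref_start = start,
                 ref_end = start + nchar(gsub("-", "", ref)),
                 ref_aln = ref, query_aln = query)
}
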