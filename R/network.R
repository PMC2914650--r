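# Signed tri-partite regulatory network: data model, validation, I/O,
# basic topology summaries.
#
# Node classes are inferred from edge context, never declared: sources of
# TF-gene and TF-miRNA edges are TFs; targets of TF-miRNA edges and
# sources of miRNA-target edges are miRNAs; everything else is a gene.
# An id implied to be both TF and miRNA is a hard error, because every
# downstream stratification keys on the class.

RELATION_TYPES <- c("TF-gene", "TF-miRNA", "miRNA-target")
SIGN_TOKENS <- c("activation", "repression", "unknown")

#' Construct a validated signed regulatory network
#'
#' @param edges data frame with columns `source`, `target`,
#'   `relation_type` (one of `"TF-gene"`, `"TF-miRNA"`, `"miRNA-target"`)
#'   and `sign` (`"activation"`, `"repression"`, `"unknown"`).
#'   Every miRNA-target edge must be repressive; duplicate
#'   (source, target, relation_type) triples are rejected, whether or not
#'   their signs agree.
#' @param nodes optional data frame with `id`, `node_class` fixing the
#'   node set (and classes) explicitly; must cover every edge endpoint.
#'   When omitted, classes are inferred from edge context and the node
#'   set is exactly the endpoints.
#' @return A `reg_network`: list with tibbles `nodes` (`id`,
#'   `node_class`) and `edges`.
#' @export
reg_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("source", "target", "relation_type", "sign")
  if (!all(required %in% names(edges))) {
    stop_fmt("edges must have columns: %s", paste(required, collapse = ", "))
  }
  edges <- edges[required]
  for (col in required) edges[[col]] <- as.character(edges[[col]])

  if (nrow(edges) > 0) {
    bad_rel <- !edges$relation_type %in% RELATION_TYPES
    if (any(bad_rel)) {
      stop_fmt("unknown relation_type '%s' (row %d)",
               edges$relation_type[which(bad_rel)[1]], which(bad_rel)[1])
    }
    bad_sign <- !edges$sign %in% SIGN_TOKENS
    if (any(bad_sign)) {
      stop_fmt("unknown sign token '%s' (row %d)",
               edges$sign[which(bad_sign)[1]], which(bad_sign)[1])
    }
    if (any(edges$source == "" | edges$target == "")) {
      stop_fmt("empty node id in edge list")
    }
    key <- paste(edges$source, edges$target, edges$relation_type, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1]
      stop_fmt("duplicate edge (%s -> %s, %s); conflicting or repeated entries are not allowed",
               edges$source[i], edges$target[i], edges$relation_type[i])
    }
    if (any(edges$relation_type == "miRNA-target" & edges$sign != "repression")) {
      i <- which(edges$relation_type == "miRNA-target" & edges$sign != "repression")[1]
      stop_fmt("miRNA-target edge %s -> %s must have sign 'repression'",
               edges$source[i], edges$target[i])
    }
    loops <- edges$source == edges$target
    if (any(loops & edges$relation_type != "TF-gene")) {
      i <- which(loops & edges$relation_type != "TF-gene")[1]
      stop_fmt("self-loop on '%s' only permitted for TF-gene autoregulation",
               edges$source[i])
    }
  }

  if (is.null(nodes)) {
    nodes <- infer_node_classes(edges)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)[c("id", "node_class")]
    if (anyDuplicated(nodes$id)) stop_fmt("duplicate node id in node table")
    if (!all(nodes$node_class %in% c("TF", "miRNA", "gene"))) {
      stop_fmt("node_class must be TF, miRNA or gene")
    }
    missing_ids <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(missing_ids) > 0) {
      stop_fmt("edge endpoint '%s' absent from node table", missing_ids[1])
    }
  }

  # endpoint-class consistency per relation type
  cls <- stats::setNames(nodes$node_class, nodes$id)
  if (nrow(edges) > 0) {
    src_cls <- cls[edges$source]; tgt_cls <- cls[edges$target]
    ok <- (edges$relation_type == "TF-gene" & src_cls == "TF" & tgt_cls %in% c("gene", "TF")) |
      (edges$relation_type == "TF-miRNA" & src_cls == "TF" & tgt_cls == "miRNA") |
      (edges$relation_type == "miRNA-target" & src_cls == "miRNA" & tgt_cls %in% c("gene", "TF"))
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop_fmt("edge %s(%s) -> %s(%s) inconsistent with relation_type %s",
               edges$source[i], src_cls[i], edges$target[i], tgt_cls[i],
               edges$relation_type[i])
    }
  }

  structure(list(nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges)),
            class = "reg_network")
}

infer_node_classes <- function(edges) {
  claim <- list()
  add_claim <- function(claim, ids, class) {
    for (id in unique(ids)) {
      prev <- claim[[id]]
      if (!is.null(prev) && prev != class) {
        stop_fmt("node '%s' implied to be both %s and %s", id, prev, class)
      }
      claim[[id]] <- class
    }
    claim
  }
  if (nrow(edges) > 0) {
    claim <- add_claim(claim, edges$source[edges$relation_type %in% c("TF-gene", "TF-miRNA")], "TF")
    claim <- add_claim(claim, edges$target[edges$relation_type == "TF-miRNA"], "miRNA")
    claim <- add_claim(claim, edges$source[edges$relation_type == "miRNA-target"], "miRNA")
  }
  all_ids <- unique(c(edges$source, edges$target))
  class_of <- vapply(all_ids, function(id) {
    if (is.null(claim[[id]])) "gene" else claim[[id]]
  }, character(1))
  data.frame(id = all_ids, node_class = unname(class_of),
             stringsAsFactors = FALSE)
}

#' Read a signed regulatory network from an edge-list TSV
#'
#' Tab-separated, UTF-8, header row `source target relation_type sign`,
#' lines starting with `#` ignored. Node classes are inferred from edge
#' context; inconsistencies are errors naming the offending edge.
#'
#' @param path path to the TSV file.
#' @return A `reg_network`.
#' @export
read_network <- function(path) {
  df <- tryCatch(read_tsv_plain(path, c("source", "target", "relation_type", "sign")),
                 error = function(e) stop_fmt("parse error in %s: %s", path, conditionMessage(e)))
  reg_network(df)
}

#' Write a network edge list as TSV
#' @param net a `reg_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  write_tsv_plain(as.data.frame(net$edges), path)
}

#' Export a network in SIF format for graph viewers
#'
#' Three columns: source, interaction (`relation_type:sign`), target; no
#' header, tab-separated.
#' @param net a `reg_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  e <- net$edges
  utils::write.table(
    data.frame(e$source, paste(e$relation_type, e$sign, sep = ":"), e$target),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# igraph view of the network (internal); vertex order = nodes$id order
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges[, c("source", "target")]),
    directed = TRUE,
    vertices = as.data.frame(net$nodes[, "id", drop = FALSE]))
}

#' Weakly connected components of the network
#'
#' Edge direction is ignored. Components are returned largest first
#' (size ties broken by smallest member id) as a list of node-id vectors.
#'
#' @param net a `reg_network`.
#' @return list of character vectors partitioning the node ids.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$nodes) == 0) return(list())
  comp <- igraph::components(as_igraph(net), mode = "weak")
  groups <- split(net$nodes$id, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  unname(groups[ord])
}

#' Per-node out-degree split by relation type
#'
#' @param net a `reg_network`.
#' @return tibble with `id`, `node_class`, one out-degree column per
#'   relation type (`out_TF_gene`, `out_TF_miRNA`, `out_miRNA_target`)
#'   and `out_total`. Column sums over the three type columns equal the
#'   edge count.
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  counts <- sapply(RELATION_TYPES, function(rt) {
    src <- net$edges$source[net$edges$relation_type == rt]
    tab <- table(factor(src, levels = net$nodes$id))
    as.integer(tab)
  })
  if (nrow(net$nodes) == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = 3)
  }
  counts <- matrix(counts, ncol = 3,
                   dimnames = list(NULL, gsub("-", "_", paste0("out_", RELATION_TYPES))))
  out <- tibble::tibble(id = net$nodes$id, node_class = net$nodes$node_class)
  out <- cbind(out, tibble::as_tibble(counts))
  out$out_total <- rowSums(counts)
  tibble::as_tibble(out)
}

#' @export
print.reg_network <- function(x, ...) {
  tab <- table(factor(x$nodes$node_class, levels = c("TF", "miRNA", "gene")))
  etab <- table(factor(x$edges$relation_type, levels = RELATION_TYPES))
  cat(sprintf("Signed regulatory network: %d nodes (%d TF, %d miRNA, %d gene), %d edges\n",
              nrow(x$nodes), tab[["TF"]], tab[["miRNA"]], tab[["gene"]],
              nrow(x$edges)))
  cat(sprintf("  edges by type: TF-gene %d, TF-miRNA %d, miRNA-target %d\n",
              etab[["TF-gene"]], etab[["TF-miRNA"]], etab[["miRNA-target"]]))
  invisible(x)
}
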