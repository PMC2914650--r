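# Pathway co-regulation: do activating TF-miRNA pairs share signaling
# pathways more often than repressing pairs?
#
# A regulator "regulates a pathway" when it appears in the pathway's
# member set; pathway membership is an annotation input, not something
# computed here.

#' Read pathway sets from a GMT file
#'
#' @param path GMT path (name, description, members...).
#' @return named list of unique member-id character vectors; empty sets
#'   are rejected.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop_fmt("empty pathway set in %s", path)
  if (anyDuplicated(names(sets))) stop_fmt("duplicate pathway name in %s", path)
  sets
}

#' Write pathway sets as GMT
#' @param pathways named list of member vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Does a TF-miRNA pair share at least one pathway?
#'
#' @param tf,mirna node ids (absent ids simply never co-occur).
#' @param pathways named list of member sets.
#' @return TRUE iff some pathway contains both ids.
#' @export
common_pathway_flag <- function(tf, mirna, pathways) {
  for (set in pathways) {
    if (tf %in% set && mirna %in% set) return(TRUE)
  }
  FALSE
}

# membership index: id -> integer vector of pathway indices
pathway_index <- function(pathways) {
  id <- unlist(pathways, use.names = FALSE)
  idx <- rep(seq_along(pathways), lengths(pathways))
  split(idx, id)
}

#' Pathway co-regulation contingency analysis
#'
#' Rows of the 2x2 table are activating (row 1) vs repressing TF-miRNA
#' pairs. With `counting_unit = "pair"` the columns are
#' common-pathway yes/no per pair; with `"pair_pathway"` every
#' (pair, pathway regulated by either member) combination is one
#' observation and the column is whether the pathway contains both.
#' Fisher's exact test is applied either way.
#'
#' @param net a `reg_network` with signed TF-miRNA edges.
#' @param pathways named list of member sets.
#' @param counting_unit `"pair"` (default) or `"pair_pathway"`.
#' @return list with `table`, `result` (`contingency_result`),
#'   `pct_activating`, `pct_repressing`, `counting_unit`.
#' @export
coregulation_contingency <- function(net, pathways,
                                     counting_unit = c("pair", "pair_pathway")) {
  counting_unit <- match.arg(counting_unit)
  if (length(pathways) == 0) stop_fmt("empty pathway set")
  e <- net$edges[net$edges$relation_type == "TF-miRNA" &
                   net$edges$sign %in% c("activation", "repression"), ]
  if (nrow(e) == 0) stop_fmt("no signed TF-miRNA edges")
  idx <- pathway_index(pathways)
  memb <- function(id) idx[[id]]  # NULL when unannotated

  if (counting_unit == "pair") {
    common <- vapply(seq_len(nrow(e)), function(i) {
      length(intersect(memb(e$source[i]), memb(e$target[i]))) > 0
    }, logical(1))
    act <- e$sign == "activation"
    tab <- contingency_2x2(sum(act & common), sum(act & !common),
                           sum(!act & common), sum(!act & !common))
  } else {
    yes <- c(activation = 0L, repression = 0L)
    no <- c(activation = 0L, repression = 0L)
    for (i in seq_len(nrow(e))) {
      ms <- memb(e$source[i]); mt <- memb(e$target[i])
      both <- length(intersect(ms, mt))
      either <- length(union(ms, mt))
      yes[e$sign[i]] <- yes[e$sign[i]] + both
      no[e$sign[i]] <- no[e$sign[i]] + (either - both)
    }
    tab <- contingency_2x2(yes[["activation"]], no[["activation"]],
                           yes[["repression"]], no[["repression"]])
  }
  res <- fisher_exact_2x2(tab)
  list(table = tab, result = res,
       pct_activating = res$pct_row1, pct_repressing = res$pct_row2,
       counting_unit = counting_unit)
}
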