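#!/usr/bin/env Rscript
# Sign-stratified coevolution: do regulators and their partners evolve
# at correlated rates, and does the regulatory sign matter?

library(mirnetevo)

net <- read_network("results/data/network.tsv")
protein <- load_rate_table("results/data/protein_rates.tsv")
mirna <- load_rate_table("results/mirna_rates.tsv")

rows <- list()
note <- function(...) { message(sprintf(...)) }

# TF -> miRNA, by transcriptional sign
tm <- stratify_edges_by_sign(net, "TF-miRNA", protein, mirna)
for (sgn in names(tm)) {
  g <- tm[[sgn]]
  if (nrow(g) < 4) next
  r <- coevolution_correlation(g)
  m <- median_split_comparison(g, "regulator")
  note("TF-%s-miRNA pairs (n=%d): rho = %.3f (p = %.3g); miRNA medians %.3f vs %.3f by TF-rate half (p = %.3g)",
       sgn, r$n, r$rho, r$p_value, m$median_a, m$median_b, m$p_value)
  rows[[length(rows) + 1]] <- data.frame(
    analysis = "tf_mirna", stratum = sgn, rho = r$rho, p = r$p_value, n = r$n)
}

# TF -> gene, sign inferred from expression profiles
expr <- read_expression("results/data/expression.tsv")
tg_edges <- as.data.frame(net$edges[net$edges$relation_type == "TF-gene", ])
inferred <- infer_sign_from_expression(expr, tg_edges)
tg_edges$sign <- inferred$sign
net2 <- reg_network(rbind(tg_edges,
                          as.data.frame(net$edges[net$edges$relation_type != "TF-gene", ])),
                    nodes = net$nodes)
tg <- stratify_edges_by_sign(net2, "TF-gene", protein, protein)
for (sgn in intersect(c("activation", "repression"), names(tg))) {
  g <- tg[[sgn]]
  if (nrow(g) < 3) next
  r <- coevolution_correlation(g)
  note("TF-%s-gene pairs by expression sign (n=%d): rho = %.3f (p = %.3g)",
       sgn, r$n, r$rho, r$p_value)
  rows[[length(rows) + 1]] <- data.frame(
    analysis = "tf_gene", stratum = sgn, rho = r$rho, p = r$p_value, n = r$n)
}

# miRNA -> target: conserved miRNAs vs their targets' dN
mt <- stratify_edges_by_sign(net, "miRNA-target", mirna, protein)
m <- median_split_comparison(mt$repression, "regulator")
note("miRNA-target pairs (n=%d): target dN medians %.3f (conserved-miRNA half) vs %.3f (fast-miRNA half), p = %.3g",
     m$n_a + m$n_b, m$median_a, m$median_b, m$p_value)

# signal preference of rapidly evolving TFs
sp <- signal_preference(net, protein)
note("Signal preference: %.1f%% activation among high-rate TFs vs %.1f%% among low-rate TFs (OR = %.2f, p = %.3g)",
     sp$pct_activation_high, sp$pct_activation_low,
     sp$result$odds_ratio, sp$result$p_value)

write_tsv_plain(do.call(rbind, rows), "results/coevolution.tsv")
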