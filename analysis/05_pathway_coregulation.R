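#!/usr/bin/env Rscript
# Do activating TF-miRNA pairs co-regulate common signaling pathways
# more often than repressing pairs?

library(mirnetevo)

net <- read_network("results/data/network.tsv")
pathways <- read_gmt("results/data/pathways.gmt")

rows <- list()
for (unit in c("pair", "pair_pathway")) {
  cc <- coregulation_contingency(net, pathways, unit)
  message(sprintf("[%s] %.1f%% of activating vs %.1f%% of repressing pairs share a pathway: OR = %.2f, p = %.3g",
                  unit, cc$pct_activating, cc$pct_repressing,
                  cc$result$odds_ratio, cc$result$p_value))
  rows[[length(rows) + 1]] <- data.frame(
    counting_unit = unit,
    yes_activating = cc$table[["a"]], no_activating = cc$table[["b"]],
    yes_repressing = cc$table[["c"]], no_repressing = cc$table[["d"]],
    pct_activating = cc$pct_activating, pct_repressing = cc$pct_repressing,
    odds_ratio = cc$result$odds_ratio, p = cc$result$p_value)
}
write_tsv_plain(do.call(rbind, rows), "results/pathway_coregulation.tsv")
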