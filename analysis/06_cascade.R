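#!/usr/bin/env Rscript
# Cascade ordering: are upstream regulators more or less conserved than
# the regulators downstream of them?

library(mirnetevo)

net <- read_network("results/data/network.tsv")
protein <- load_rate_table("results/data/protein_rates.tsv")
mirna <- load_rate_table("results/mirna_rates.tsv")

cr <- cascade_report(net, protein, mirna)
print(cr$tf)
print(cr$mirna)
if (!is.null(cr$comparison)) {
  message(sprintf("TF vs miRNA upstream-conservation: OR = %.2f, p = %.3g (opposite cascade polarity of the two regulator classes)",
                  cr$comparison$odds_ratio, cr$comparison$p_value))
}
out <- do.call(rbind, lapply(list(cr$tf, cr$mirna), function(s)
  data.frame(node_class = s$node_class, n_pairs = s$n_pairs, n_ties = s$n_ties,
             n_upstream_lower = s$n_upstream_lower,
             fraction_upstream_lower = s$fraction_upstream_lower)))
write_tsv_plain(out, "results/cascade.tsv")
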