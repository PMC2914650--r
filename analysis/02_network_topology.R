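#!/usr/bin/env Rscript
# Topology of the regulatory network: weakly connected components and
# the skewed regulator out-degree distribution.

library(mirnetevo)

net <- read_network("results/data/network.tsv")
print(net)

comps <- connected_components(net)
giant <- length(comps[[1]]) / nrow(net$nodes)
message(sprintf("%d weakly connected components; giant component holds %.0f%% of nodes",
                length(comps), 100 * giant))

deg <- degree_summary(net)
write_tsv_plain(as.data.frame(deg), "results/degree_summary.tsv")
tf_deg <- deg$out_TF_miRNA[deg$node_class == "TF"]
message(sprintf("TF out-degree to miRNAs: median %d, max %d (most TFs regulate few miRNAs, a few regulate many)",
                median(tf_deg), max(tf_deg)))
write_sif(net, "results/network.sif")
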