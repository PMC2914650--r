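#!/usr/bin/env Rscript
# miRNA evolutionary rates: per-aligned-site sequence divergence over
# each miRNA's genomic interval, from the pairwise alignment blocks.
# Protein-coding rates (dN) are consumed as a table.

library(mirnetevo)

blocks <- read_axt("results/data/alignments.axt")
intervals <- read_bed6("results/data/mirna.bed")
qc <- divergence_table(blocks, intervals)
write_tsv_plain(as.data.frame(qc), "results/mirna_divergence_qc.tsv")

usable <- qc$status == "ok"
rates <- setNames(qc$rate[usable], qc$id[usable])
write_rate_table(rates, "results/mirna_rates.tsv")
message(sprintf("Computed divergence for %d/%d miRNAs (median %.3f); %d excluded for low coverage or no alignment",
                sum(usable), nrow(qc), median(rates), sum(!usable)))

dn <- load_rate_table("results/data/protein_rates.tsv")
message(sprintf("Loaded dN for %d protein-coding genes (median %.3f)",
                length(dn), median(dn)))
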