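#!/usr/bin/env Rscript
# Gene-level differential H3K27 acetylation and the global acetylation
# trend. A gene's acetylation level is the mean signal of the H3K27ac
# peaks within 10 kb of its body; the UV/control fold change (cutoff 2)
# classifies genes up/down/none. The through-origin regression of UV on
# control tag values over merged peak regions summarises the genome-wide
# trend: a slope below 1 is a net loss of H3K27ac.

library(uvomics)

ann <- read_gene_annotation("results/simulated/genes.gff3")
pc <- read_peaks("results/simulated/peaks_control.bed")
pu <- read_peaks("results/simulated/peaks_uv.bed")

dha <- compute_dha(pc, pu, ann, window = 10000, fc_cutoff = 2)
write.table(dha, "results/dha.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- merged_region_signal(pc, pu)
slope <- global_signal_slope(m$tags_a, m$tags_b)

cat("DHA genes:", sum(dha$dha_class != "none"), "of", nrow(dha),
    "(", sum(dha$dha_class == "up"), "up /",
    sum(dha$dha_class == "down"), "down )\n")
cat(sprintf("Global H3K27ac slope over %d merged regions: %.3f (%s)\n",
            nrow(m), slope,
            if (slope < 1) "net loss" else "no net loss"))
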