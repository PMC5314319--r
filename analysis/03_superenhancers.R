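#!/usr/bin/env Rscript
# Super-enhancer landscapes in both samples. Promoter peaks (within
# 2.5 kb of a TSS) are excluded, the remaining constituent enhancers are
# stitched at 12.5 kb, and the rank-ordered signal curve's transition
# point (maximal depth below the diagonal after min-max scaling) sets the
# cutoff: everything strictly above is a super enhancer. SE sets of the
# two samples are compared by interval overlap and associated with genes
# within 25 kb.

library(uvomics)

ann <- read_gene_annotation("results/simulated/genes.gff3")
pc <- read_peaks("results/simulated/peaks_control.bed")
pu <- read_peaks("results/simulated/peaks_uv.bed")

se_c <- call_superenhancers(pc, ann, sample = "control")
se_u <- call_superenhancers(pu, ann, sample = "uv")
print(se_c); print(se_u)

cmp <- compare_se_sets(se_c, se_u)
cat("SE overlap: common", cmp$common_a, "/", cmp$common_b,
    "; unique control", cmp$unique_a, ", unique UV", cmp$unique_b, "\n")

for (s in list(se_c, se_u)) {
  ses <- s$superenhancers
  bed <- data.frame(chrom = GenomicRanges::seqnames(ses),
                    start = GenomicRanges::start(ses) - 1,
                    end = GenomicRanges::end(ses), name = names(ses),
                    total_signal = ses$total_signal)
  write.table(bed, sprintf("results/superenhancers_%s.bed", s$sample),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  assoc <- annotate_se_genes(s, ann, window = 25000)
  write.table(assoc, sprintf("results/se_genes_%s.tsv", s$sample),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(s$sample, ": ", length(ses), " SEs associated with ",
      length(unique(assoc$gene_id)), " genes\n", sep = "")
}
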