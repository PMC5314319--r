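#!/usr/bin/env Rscript
# Somatic SNV profiling and mutation-expression enrichment. Variants from
# the two timepoints are depth-filtered (>= 10 reads), intersected on the
# full allele identity, classified into genomic feature categories
# (exon > UTRs > intron > 1 kb flanks > intergenic) and summarised as a
# strand-collapsed substitution spectrum. Genes carrying intronic common
# variants are then tested for enrichment at the top of the expression
# fold-change ranking (KS statistic, gene-shuffling permutation p).

library(uvomics)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
ann <- read_gene_annotation("results/simulated/genes.gff3")
va <- filter_by_depth(read_variants("results/simulated/variants_4h.vcf"))
vb <- filter_by_depth(read_variants("results/simulated/variants_72h.vcf"))
cat("SNVs after depth filter:", nrow(va), "/", nrow(vb), "\n")

common <- intersect_variant_sets(va, vb)
cls <- classify_variants(common, ann)
write.table(cls, "results/variants_common_classified.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(nrow(common), "common SNVs;",
    sum(cls$category != "intergenic"), "within or near genes\n")
print(table(cls$category))
sp <- mutation_spectrum(common)
print(sp)
cat(sprintf("UV-signature (C>T/G>A) fraction: %.1f%%\n",
            100 * sp[["C>T/G>A"]] / sum(sp)))

dge <- read.delim("results/dge.tsv")
ranked <- dge$gene_id[order(dge$log2fc, decreasing = TRUE)]
intron_genes <- intersect(unique(na.omit(
  cls$gene_id[cls$category == "intron"])), ranked)
if (length(intron_genes) && length(intron_genes) < length(ranked)) {
  enr <- permutation_pvalue(ranked, intron_genes, n_perm = 1000,
                            seed = seed)
  cat(sprintf("Intron-variant genes in the DGE ranking: ES %.3f, p %.4g (%d permutations)\n",
              enr$es, enr$p_perm, enr$n_perm))
  write.table(enr, "results/intron_gene_enrichment.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
} else cat("No intronic common variants near ranked genes; enrichment skipped\n")
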