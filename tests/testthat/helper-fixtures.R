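# shared toy fixtures, built in code

# two-chromosome toy genome with three genes (one minus-strand)
toy_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(2001, 20001, 10001), c(6000, 24000, 12000)),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gB", "gC"))
  features <- GenomicRanges::GRanges(
    c(rep("chr1", 5 + 5), rep("chr2", 4)),
    IRanges::IRanges(
      c(2001, 3501, 5001, 2001, 5601,         # gA exons + UTRs
        20001, 21501, 23001, 23601, 20001,    # gB exons + UTRs
        10001, 11601, 10001, 11901),          # gC exons + UTRs
      c(2600, 4000, 6000, 2240, 6000,
        20600, 22000, 24000, 24000, 20240,
        10400, 12000, 10100, 12000)),
    gene_id = c(rep("gA", 5), rep("gB", 5), rep("gC", 4)),
    type = c("exon", "exon", "exon", "five_prime_UTR", "three_prime_UTR",
             "exon", "exon", "exon", "five_prime_UTR", "three_prime_UTR",
             "exon", "exon", "five_prime_UTR", "three_prime_UTR"))
  genome_annotation(genes, features,
                    c(chr1 = 100000, chr2 = 50000))
}

make_peaks <- function(chrom, start, end, signal,
                       name = sprintf("p%d", seq_along(start))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$name <- name
  gr$signal <- signal
  gr
}

make_variants <- function(chrom, pos, ref = "C", alt = "T", depth = 50) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             ref = rep_len(ref, length(pos)),
             alt = rep_len(alt, length(pos)),
             depth = rep_len(depth, length(pos)),
             stringsAsFactors = FALSE)
}

# independent exhaustive-scan oracle for the transition-point cutoff
se_cutoff_oracle <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  best_i <- NA; best_d <- -Inf
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    y <- (s[i] - s[1]) / (s[n] - s[1])
    if (x - y > best_d) { best_d <- x - y; best_i <- i }
  }
  list(cutoff_index = best_i, cutoff_signal = s[best_i])
}

# independent brute-force double-CDF oracle for the KS enrichment score
ks_oracle <- function(ranked, gene_set) {
  n <- length(ranked); m <- length(gene_set)
  best <- 0
  for (r in seq_len(n)) {
    in_top <- sum(ranked[seq_len(r)] %in% gene_set)
    d <- in_top / m - (r - in_top) / (n - m)
    if (abs(d) > abs(best)) best <- d
  }
  best
}
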