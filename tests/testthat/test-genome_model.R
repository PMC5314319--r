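test_that("GFF3 reading keeps 1-based coordinates and strand-aware TSS", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gplus",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gplus",
    "chr1\tsrc\tgene\t1101\t1200\t.\t-\t.\tID=gminus",
    "chr1\tsrc\texon\t1101\t1200\t.\t-\t.\tParent=gminus"), path)
  ann <- read_gene_annotation(path)
  expect_equal(ann$chrom_lengths, c(chr1 = 10000))
  g <- ann$genes
  expect_equal(GenomicRanges::start(g[g$gene_id == "gplus"]), 101)
  expect_equal(GenomicRanges::end(g[g$gene_id == "gplus"]), 200)
  expect_equal(g$tss[g$gene_id == "gplus"], 101)
  # minus-strand TSS sits at the body end
  expect_equal(g$tss[g$gene_id == "gminus"], 1200)
})

test_that("GFF3 edge cases: empty file, malformed line, bad features", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  ann <- read_gene_annotation(empty)
  expect_length(ann$genes, 0)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t300"), bad)
  expect_error(read_gene_annotation(bad), "line 3")

  # exon outside its gene body fails validation
  out <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 10000",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t150\t250\t.\t+\t.\tParent=g1"), out)
  expect_error(read_gene_annotation(out), "validation")
})

test_that("annotation round-trips through GFF3 unchanged", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(ann, path)
  ann2 <- read_gene_annotation(path)
  expect_equal(ann2$chrom_lengths, ann$chrom_lengths)
  expect_equal(as.data.frame(ann2$genes), as.data.frame(ann$genes))
  ord <- function(f) {
    df <- as.data.frame(f)
    df[order(df$gene_id, df$type, df$start), ]
  }
  expect_equal(ord(ann2$features)$start, ord(ann$features)$start)
  expect_equal(ord(ann2$features)$end, ord(ann$features)$end)
})

test_that("annotation constructor enforces its invariants", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 2000),
                              strand = "+", gene_id = "g1")
  f <- GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                              gene_id = character(0), type = character(0))
  expect_error(genome_annotation(g, f, c(chr1 = 100)), "bounds")
  g2 <- c(g, g)
  expect_error(genome_annotation(g2, f, c(chr1 = 5000)), "duplicated")
})

test_that("BED peaks: parsing, validation, sorting, duplicates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t5000\t5100\tpk2\t7",
               "chr1\t100\t200\tpk1\t5.0",
               "chr1\t100\t200\tpk1b\t5.0"), path)
  expect_message(p <- read_peaks(path), "duplicate")
  # sorted by position, BED half-open converted to 1-based closed
  expect_equal(GenomicRanges::start(p), c(101, 101, 5001))
  expect_equal(GenomicRanges::end(p)[3], 5100)
  expect_equal(p$signal, c(5, 5, 7))

  neg <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpk\t-3", neg)
  expect_error(read_peaks(neg), "negative")

  na <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpk\tNA", na)
  expect_error(read_peaks(na))

  out <- withr::local_tempfile(fileext = ".bed")
  write_peaks(p, out)
  p2 <- read_peaks(out)
  expect_equal(GenomicRanges::start(p2), GenomicRanges::start(p))
  expect_equal(p2$signal, p$signal)
})

test_that("interval distance is a gap distance with overlap at 0", {
  gr <- function(s, e, chrom = "chr1")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  # overlapping, distant, and abutting half-open intervals
  expect_equal(interval_distance(gr(101, 200), gr(151, 300)), 0)
  expect_equal(interval_distance(gr(101, 200), gr(701, 800)), 500)
  expect_equal(interval_distance(gr(101, 200), gr(201, 300)), 0)
  expect_equal(interval_distance(gr(101, 200), gr(101, 200, "chr2")), Inf)
})

test_that("interval distance is symmetric and satisfies the triangle inequality", {
  set.seed(7)
  s <- sample.int(10000, 60)
  ivs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(s, s + sample.int(500, 60)))
  for (k in 1:40) {
    i <- sample.int(60, 3)
    a <- ivs[i[1]]; b <- ivs[i[2]]; c <- ivs[i[3]]
    expect_equal(interval_distance(a, b), interval_distance(b, a))
    expect_lte(interval_distance(a, c),
               interval_distance(a, b) + interval_distance(b, c) +
                 GenomicRanges::width(b))
  }
})

test_that("peak-to-gene assignment respects the distance window", {
  ann <- toy_annotation()
  # gA body starts at 2001: peak ending 500 bp before is assigned,
  # a peak 11 kb away is not
  near <- make_peaks("chr1", 1001, 1500, 3)
  far <- make_peaks("chr1", 32001, 33000, 3)   # ~8 kb past gB end
  asg <- assign_peaks_to_genes(near, ann, window = 10000)
  expect_equal(asg$gene_id, "gA")
  expect_equal(asg$distance, 500)
  asg_far <- assign_peaks_to_genes(far, ann, window = 5000)
  expect_equal(nrow(asg_far), 0)
  # one peak between two genes within the window joins both
  mid <- make_peaks("chr1", 10001, 12000, 2)
  asg_mid <- assign_peaks_to_genes(mid, ann, window = 10000)
  expect_setequal(asg_mid$gene_id, c("gA", "gB"))
})

test_that("window-0 assignment equals a brute-force overlap scan", {
  ann <- toy_annotation()
  set.seed(11)
  s <- sample.int(40000, 100)
  pk <- make_peaks("chr1", s, s + sample.int(800, 100),
                   signal = runif(100))
  asg <- assign_peaks_to_genes(pk, ann, window = 0)
  genes <- ann$genes[as.character(GenomicRanges::seqnames(ann$genes)) ==
                       "chr1"]
  expected <- 0L
  for (i in seq_along(pk)) {
    for (j in seq_along(genes)) {
      if (GenomicRanges::start(pk)[i] <= GenomicRanges::end(genes)[j] &&
          GenomicRanges::end(pk)[i] >= GenomicRanges::start(genes)[j])
        expected <- expected + 1L
    }
  }
  expect_equal(nrow(asg), expected)
})
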