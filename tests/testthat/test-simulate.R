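test_that("generators are deterministic in the seed and sensitive to it", {
  cfg <- simulation_config(seed = 5, n_genes = 40,
                           n_background_enhancers = 100,
                           n_planted_se_clusters = 5,
                           n_dha_up = 5, n_dha_down = 5,
                           n_dge_up = 5, n_dge_down = 5,
                           n_screen_genes = 30, n_essential = 2,
                           n_variants_a = 60, n_variants_b = 50,
                           n_variants_common = 20)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_uv_study(cfg, d1)
  simulate_uv_study(cfg, d2)
  for (f in c("genes.gff3", "peaks_control.bed", "peaks_uv.bed",
              "expression.tsv", "variants_4h.vcf", "screen_ds.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  cfg2 <- simulation_config(seed = 6, n_genes = 40,
                            n_background_enhancers = 100,
                            n_planted_se_clusters = 5,
                            n_dha_up = 5, n_dha_down = 5,
                            n_dge_up = 5, n_dge_down = 5,
                            n_screen_genes = 30, n_essential = 2,
                            n_variants_a = 60, n_variants_b = 50,
                            n_variants_common = 20)
  d3 <- withr::local_tempdir()
  simulate_uv_study(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "peaks_control.bed")),
                         readLines(file.path(d3, "peaks_control.bed"))))
})

test_that("generated annotations are valid and round-trip through GFF3", {
  cfg <- simulation_config(seed = 2, n_genes = 50)
  ann <- generate_annotation(cfg)   # constructor enforces the invariants
  expect_length(ann$genes, 50)
  expect_false(is.unsorted(GenomicRanges::start(
    ann$genes[GenomicRanges::seqnames(ann$genes) == "chr1"])))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(ann, path)
  ann2 <- read_gene_annotation(path)
  expect_equal(as.data.frame(ann2$genes), as.data.frame(ann$genes))
  expect_error(generate_annotation(
    simulation_config(n_genes = 5000,
                      chrom_lengths = c(chr1 = 1e6))), "cannot fit")
})

test_that("a pure global scaling yields exactly the configured slope", {
  cfg <- simulation_config(seed = 3, global_uv_signal_multiplier = 0.5,
                           n_dha_up = 0, n_dha_down = 0,
                           n_se_lost_uv = 0, n_se_gained_uv = 0)
  ann <- generate_annotation(cfg)
  chip <- generate_chipseq_pair(cfg, ann)
  m <- merged_region_signal(chip$peaks_control, chip$peaks_uv)
  expect_equal(global_signal_slope(m$tags_a, m$tags_b), 0.5,
               tolerance = 1e-12)
})

test_that("planted acetylation effects are recovered without false calls", {
  cfg <- simulation_config(seed = 4)
  ann <- generate_annotation(cfg)
  chip <- generate_chipseq_pair(cfg, ann)
  dha <- compute_dha(chip$peaks_control, chip$peaks_uv, ann)
  up <- dha$gene_id[dha$dha_class == "up"]
  down <- dha$gene_id[dha$dha_class == "down"]
  expect_setequal(up, chip$truth$dha_up)
  expect_setequal(down, chip$truth$dha_down)
})

test_that("planted expression effects and coupling drive the integration", {
  cfg <- simulation_config(seed = 1, n_dha_up = 50, n_dha_down = 50)
  ann <- generate_annotation(cfg)
  chip <- generate_chipseq_pair(cfg, ann)
  ex <- generate_expression_pair(cfg, ann, chip$truth)
  dge <- compute_dge(ex$expression)
  # planted strongly-up genes are all recovered
  expect_true(all(ex$truth$dge_up %in% dge$gene_id[dge$dge_class == "up"]))
  # full coupling makes the acetylation-bin expression shift unmistakable
  rec <- integrate_omics(dge, compute_dha(chip$peaks_control,
                                          chip$peaks_uv, ann))
  gs <- group_shift_test(rec)
  expect_lt(gs$p[gs$group == "gt1"], 1e-6)
  expect_lt(gs$p[gs$group == "lt-1"], 1e-6)
  expect_gt(gs$mean_shift[gs$group == "gt1"], 0)

  # with no coupling and no planted effects the shift test is null
  cfg0 <- simulation_config(seed = 2, dge_dha_coupling = 0,
                            n_dge_up = 0, n_dge_down = 0)
  set.seed(100)
  pvals <- vapply(1:50, function(r) {
    cfg_r <- simulation_config(seed = 1000 + r, dge_dha_coupling = 0,
                               n_dge_up = 0, n_dge_down = 0)
    ex_r <- generate_expression_pair(cfg_r, ann, chip$truth)
    rec_r <- integrate_omics(compute_dge(ex_r$expression),
                             compute_dha(chip$peaks_control,
                                         chip$peaks_uv, ann))
    group_shift_test(rec_r)$p[1]
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("variant generation hits sizes, overlap and planted composition", {
  cfg <- simulation_config(seed = 9, n_variants_a = 120, n_variants_b = 90,
                           n_variants_common = 30)
  ann <- generate_annotation(cfg)
  v <- generate_variant_sets(cfg, ann)
  expect_equal(nrow(v$variants_a), 120)
  expect_equal(nrow(v$variants_b), 90)
  common <- intersect_variant_sets(v$variants_a, v$variants_b)
  expect_equal(nrow(common), 30)
  # every planted category is recovered by classification
  cls <- classify_variants(v$variants_a, ann)
  truth <- unlist(v$truth$category[paste(cls$chrom, cls$pos, sep = ":")])
  expect_equal(cls$category, unname(truth))
  expect_error(generate_variant_sets(
    simulation_config(n_variants_a = 10, n_variants_b = 10,
                      n_variants_common = 11), ann), "overlap")
})

test_that("screen generation plants controls at zero and labelled lineages", {
  cfg <- simulation_config(seed = 10, n_screen_genes = 40, n_essential = 3)
  scr <- generate_screen(cfg)
  s <- scr$screen
  expect_equal(dim(s$ds), c(40 * 4 + cfg$n_control_shrnas, 12))
  expect_equal(sum(s$is_negative_control), cfg$n_control_shrnas)
  expect_equal(sum(s$lineage == "skin"), 4)
  expect_length(scr$truth$essential, 3)
  ctrl_med <- median(s$ds[s$is_negative_control, ])
  expect_lt(abs(ctrl_med), 0.3)
  # planted genes really are shifted in skin lines only
  ess_rows <- s$shrna_to_gene %in% scr$truth$essential
  expect_lt(mean(s$ds[ess_rows, s$lineage == "skin"]), -2)
  expect_lt(abs(mean(s$ds[ess_rows, s$lineage == "non-skin"])), 1)
})
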