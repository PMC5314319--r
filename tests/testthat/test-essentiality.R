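test_that("count normalization applies the log2-CPM+1 formula", {
  raw <- matrix(c(1, 999999, 1024, 999998976), 2, 2,
                dimnames = list(c("sh1", "sh2"), c("r1", "r2")))
  # column totals are 1e6 and 1e9: CPM(sh1,r1)=1 -> DS 1;
  # CPM(sh1,r2)=1024/1e9*1e6... use direct cells
  ds <- normalize_shrna(raw)
  expect_equal(ds["sh1", "r1"], log2(1) + 1)
  expect_equal(ds["sh2", "r2"], log2(999998976 / 1e9 * 1e6) + 1)
  raw2 <- matrix(c(1024, 1e6 - 1024), 2, 1,
                 dimnames = list(c("a", "b"), "r"))
  expect_equal(normalize_shrna(raw2)["a", "r"], 11)  # log2(1024)+1

  # doubling every count in a replicate leaves the scores unchanged
  expect_equal(normalize_shrna(raw * 2), ds)

  expect_error(normalize_shrna(matrix(0, 2, 1,
                                      dimnames = list(c("a", "b"), "r"))),
               "zero replicate total")
  rawz <- matrix(c(0, 100), 2, 1, dimnames = list(c("a", "b"), "r"))
  expect_message(normalize_shrna(rawz), "offset")
})

test_that("control centering zeroes the control median and is idempotent", {
  ds <- matrix(c(-1, 0, 1, 5, 2, 2, 2, 7), 4, 2,
               dimnames = list(c("c1", "c2", "c3", "g"), c("s1", "s2")))
  ctrl <- c(TRUE, TRUE, TRUE, FALSE)
  # sample 1 controls {-1,0,1}: median 0, unchanged
  cent <- center_by_controls(ds, ctrl)
  expect_equal(cent[, "s1"], ds[, "s1"])
  # sample 2 controls all 2: everything shifts by -2
  expect_equal(cent[, "s2"], ds[, "s2"] - 2)
  expect_equal(apply(cent[ctrl, ], 2, median), c(s1 = 0, s2 = 0))
  expect_equal(center_by_controls(cent, ctrl), cent)
  expect_error(center_by_controls(ds, rep(FALSE, 4)), "control")
})

test_that("exact rank-sum enumeration reproduces hand counts and wilcox.test", {
  # all four skin scores below all six others: a single extreme split
  p <- rank_sum_test(c(-5, -4, -6, -5), c(0, 0.2, -0.1, 0.1, 0, 0.1),
                     alternative = "less")
  expect_equal(p, 1 / choose(10, 4), tolerance = 1e-12)

  # agreement with wilcox.test exact p on tie-free samples
  set.seed(41)
  for (r in 1:30) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(rank_sum_test(x, y, "less"),
                 wilcox.test(x, y, alternative = "less",
                             exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # beyond the enumeration budget it falls back to the approximation
  x <- rnorm(40); y <- rnorm(40, 1)
  expect_equal(rank_sum_test(x, y, "less"),
               suppressWarnings(wilcox.test(x, y, alternative = "less",
                                            exact = FALSE)$p.value),
               tolerance = 1e-12)
})

test_that("large-sample rank test matches wilcox.test's normal approximation", {
  set.seed(42)
  for (r in 1:20) {
    x <- rnorm(50, -0.2); y <- rnorm(3000)
    expect_equal(uvomics:::mann_whitney_less(x, sort(y)),
                 suppressWarnings(wilcox.test(x, y, alternative = "less",
                                              exact = FALSE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("consistency test favours tight shRNA families and handles boundaries", {
  set.seed(43)
  nr <- 62
  ds <- matrix(rnorm(nr * 6, sd = 2), nr, 6,
               dimnames = list(sprintf("sh%02d", 1:nr),
                               sprintf("l%d", 1:6)))
  map <- c(rep("tight", 3), rep(sprintf("bg%02d", 1:28), each = 2),
           "solo", NA, NA)
  # identical scores for the tight gene's shRNAs in every line
  ds[2, ] <- ds[1, ]; ds[3, ] <- ds[1, ]
  res <- gene_consistency_test(ds, map, seed = 1)
  expect_lt(res$consistency_p[res$gene_id == "tight"], 0.1)
  expect_false("solo" %in% res$gene_id)   # 1-shRNA gene untestable
  expect_true(all(res$n_shrna >= 2))
  # two-shRNA boundary still defined
  expect_true("bg01" %in% res$gene_id)
})

test_that("fully-null consistency behaves as the direct Wilcoxon route predicts", {
  # Under a fully exchangeable screen the within-gene pairwise absolute
  # differences are mutually dependent (6 pairs from 4 shRNAs share
  # values), so the rank-sum approximation is anticonservative: the
  # nominal 0.1 threshold passes ~15-16% of null genes, not 10%. The
  # pass rate is asserted around that simulated level, and the per-gene
  # p-values are cross-checked against stats::wilcox.test on the exact
  # (fully enumerated) null.
  set.seed(44)
  nr <- 620
  ds <- matrix(rnorm(nr * 8), nr, 8,
               dimnames = list(sprintf("s%04d", 1:nr),
                               sprintf("l%d", 1:8)))
  map <- c(rep(sprintf("g%03d", 1:150), each = 4), rep(NA, 20))
  res <- gene_consistency_test(ds, map, alpha = 0.1, seed = 2,
                               max_null_pairs = 2e6)
  expect_lt(abs(mean(res$pass) - 0.155), 0.06)

  ij <- utils::combn(nr, 2)
  null_all <- as.vector(abs(ds[ij[1, ], ] - ds[ij[2, ], ]))
  for (g in sample(res$gene_id, 5)) {
    idx <- which(!is.na(map) & map == g)
    pr <- utils::combn(idx, 2)
    within <- as.vector(abs(ds[pr[1, ], ] - ds[pr[2, ], ]))
    p_ref <- suppressWarnings(
      stats::wilcox.test(within, null_all, alternative = "less",
                         exact = FALSE)$p.value)
    expect_equal(res$consistency_p[res$gene_id == g], p_ref,
                 tolerance = 1e-8)
  }
})

test_that("gene collapse takes the per-line median over shRNAs", {
  ds <- matrix(c(-2, -4, -3, 1, 2, 3), 3, 2,
               dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  g <- collapse_to_gene(ds, rep("gene1", 3), "gene1")
  expect_equal(g["gene1", ], c(l1 = -3, l2 = 2))
  # shRNA order does not matter
  g2 <- collapse_to_gene(ds[c(3, 1, 2), ], rep("gene1", 3), "gene1")
  expect_equal(g2, g)
})

test_that("skin specificity is one-sided with the exact enumeration p", {
  gene_ds <- rbind(hit = c(-5, -4, -6, -5, 0, 0.2, -0.1, 0.1, 0, 0.1),
                   flat = rnorm(10, 0, 0.1),
                   anti = c(3, 4, 3.5, 3, 0, 0, 0.1, -0.1, 0, 0))
  lineage <- c(rep("skin", 4), rep("non-skin", 6))
  res <- skin_specificity_test(gene_ds, lineage)
  hit <- res[res$gene_id == "hit", ]
  expect_equal(hit$specificity_p, 1 / 210, tolerance = 1e-12)
  expect_true(hit$skin_specific)
  # skin scores above non-skin are never flagged, whatever the p
  expect_false(res$skin_specific[res$gene_id == "anti"])
  expect_error(skin_specificity_test(gene_ds, rep("skin", 10)), "lineage")
})

test_that("the pipeline recovers planted genes and ignores ordering", {
  # small enough that the consistency null is enumerated exactly, which
  # makes the whole pipeline order-invariant
  cfg <- simulation_config(seed = 7, n_screen_genes = 20, n_essential = 3,
                           n_control_shrnas = 20)
  scr <- generate_screen(cfg)
  res <- run_essentiality_pipeline(scr$screen, seed = 1)
  hits <- res$gene_id[which(res$skin_specific)]
  expect_true(all(scr$truth$essential %in% hits))

  # permuting shRNAs and cell lines changes nothing
  set.seed(1)
  s <- scr$screen
  rp <- sample(nrow(s$ds)); cp <- sample(ncol(s$ds))
  s2 <- screen_matrix(s$ds[rp, cp], s$shrna_to_gene[rp],
                      s$is_negative_control[rp], s$lineage[cp])
  res2 <- run_essentiality_pipeline(s2, seed = 1)
  strip <- function(x) { attr(x, "gene_ds") <- NULL; x }
  expect_equal(strip(res2), strip(res))

  # lineage degeneracy is an error
  s3 <- s
  s3$lineage <- rep("non-skin", ncol(s$ds))
  expect_error(run_essentiality_pipeline(s3), "skin")
})
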