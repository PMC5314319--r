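#' shRNA screen container
#'
#' Depletion-score matrix (shRNA x cell line) together with the
#' shRNA-to-gene map, negative-control flags and per-line lineage labels.
#' Negative-control shRNAs (non-human targets such as luciferase, GFP,
#' RFP, LacZ) carry no gene and are used to center the scores per sample.
#'
#' @param ds numeric matrix, rows = shRNAs (rownames required), columns =
#'   cell lines (colnames required).
#' @param shrna_to_gene character vector, one gene id per shRNA row
#'   (`NA` for negative controls).
#' @param is_negative_control logical vector per shRNA row.
#' @param lineage character vector per column, `"skin"` or `"non-skin"`.
#' @return object of class `screen_matrix`.
#' @export
screen_matrix <- function(ds, shrna_to_gene, is_negative_control, lineage) {
  stopifnot(is.matrix(ds), !is.null(rownames(ds)), !is.null(colnames(ds)))
  if (length(shrna_to_gene) != nrow(ds) ||
      length(is_negative_control) != nrow(ds))
    stop("per-shRNA vectors must match the number of rows")
  if (length(lineage) != ncol(ds))
    stop("lineage must have one label per cell line")
  if (any(!lineage %in% c("skin", "non-skin")))
    stop("lineage labels must be 'skin' or 'non-skin'")
  if (!any(is_negative_control))
    stop("at least one negative-control shRNA is required")
  if (any(!is_negative_control & is.na(shrna_to_gene)))
    stop("every non-control shRNA must map to exactly one gene")
  structure(list(ds = ds, shrna_to_gene = shrna_to_gene,
                 is_negative_control = is_negative_control,
                 lineage = lineage),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("screen_matrix:", nrow(x$ds), "shRNAs x", ncol(x$ds), "lines (",
      sum(x$lineage == "skin"), "skin ),",
      sum(x$is_negative_control), "negative controls\n")
  invisible(x)
}

#' Normalize raw shRNA read counts to depletion scores
#'
#' Per-cell application of
#' `DS = log2(raw / replicate_total * 1e6) + 1` (counts per million on a
#' log2 scale, offset by 1). Zero counts are replaced by 0.5 before the
#' ratio (flagged with a message); replicate totals are computed from the
#' raw counts and must be positive.
#'
#' @param raw_reads non-negative numeric matrix, shRNA x replicate.
#' @return matrix of depletion scores, same dimensions.
#' @export
normalize_shrna <- function(raw_reads) {
  if (any(raw_reads < 0)) stop("raw read counts must be non-negative")
  totals <- colSums(raw_reads)
  if (any(totals <= 0)) {
    bad <- colnames(raw_reads)[which(totals <= 0)[1]]
    stop("zero replicate total",
         if (!is.null(bad)) paste0(" in sample ", bad))
  }
  n_zero <- sum(raw_reads == 0)
  if (n_zero > 0) {
    message(n_zero, " zero count(s) offset by +0.5 before normalization")
    raw_reads[raw_reads == 0] <- 0.5
  }
  log2(sweep(raw_reads, 2, totals, "/") * 1e6) + 1
}

#' Center depletion scores on the negative controls
#'
#' Subtracts, per sample (column), the median depletion score of the
#' negative-control shRNAs, so the control median of the centered matrix
#' is 0 in every sample. Idempotent.
#'
#' @param ds depletion-score matrix.
#' @param is_negative_control logical per row.
#' @return centered matrix.
#' @export
center_by_controls <- function(ds, is_negative_control) {
  if (!any(is_negative_control)) stop("no negative-control shRNAs")
  ctrl <- ds[is_negative_control, , drop = FALSE]
  med <- apply(ctrl, 2, stats::median)
  if (anyNA(med)) {
    bad <- colnames(ds)[which(is.na(med))[1]]
    stop("no usable controls in sample ", bad)
  }
  sweep(ds, 2, med, "-")
}

#' Exact/approximate one-sided rank-sum test
#'
#' Mann-Whitney test of `x` against `y` using midranks. When the number of
#' group assignments `choose(nx+ny, nx)` is at most `max_exact` the
#' permutation distribution of the rank sum is enumerated exactly (valid
#' under ties); otherwise the normal approximation of
#' [stats::wilcox.test()] is used.
#'
#' @param x,y numeric vectors.
#' @param alternative `"less"` (x shifted below y) or `"greater"`.
#' @param max_exact enumeration budget (default 20000 assignments).
#' @return p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater"),
                          max_exact = 20000) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  n_comb <- choose(nx + ny, nx)
  if (n_comb <= max_exact) {
    sums <- colSums(matrix(r[utils::combn(nx + ny, nx)], nrow = nx))
    if (alternative == "less") mean(sums <= obs) else mean(sums >= obs)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative,
                         exact = FALSE)$p.value)
  }
}

# one-sided (x below y) Mann-Whitney against a large pre-sorted null;
# normal approximation with continuity correction, as stats::wilcox.test
# uses for large samples (tie variance correction omitted: the null is
# effectively continuous). Sorting the null once makes the per-gene cost
# O(nx log ny).
mann_whitney_less <- function(x, y_sorted) {
  nx <- length(x); ny <- length(y_sorted)
  n_le <- findInterval(x, y_sorted)
  n_lt <- findInterval(x, y_sorted, left.open = TRUE)
  u <- sum(n_lt) + 0.5 * sum(n_le - n_lt)
  mu <- nx * ny / 2
  sigma <- sqrt(nx * ny * (nx + ny + 1) / 12)
  stats::pnorm((u - mu + 0.5) / sigma)
}

#' Within-gene consistency of shRNA depletion scores
#'
#' For each gene with at least two shRNAs, the absolute pairwise
#' differences of its shRNAs' depletion scores (within each sample,
#' pooled over samples) are compared to a null of absolute pairwise
#' differences between all shRNAs (random shRNA pairs in random samples,
#' subsampled to at most `max_null_pairs`, seeded). A one-sided rank-sum
#' test asks whether the within-gene differences are smaller, i.e. whether
#' the shRNAs targeting the gene behave consistently. Genes with a single
#' shRNA are untestable and excluded.
#'
#' @param ds centered depletion-score matrix.
#' @param shrna_to_gene gene id per row (`NA` for controls).
#' @param alpha pass threshold on the consistency p-value (default 0.1).
#' @param max_null_pairs null subsample cap (default 1e5); exact
#'   enumeration when the total number of (pair, sample) combinations is
#'   smaller.
#' @param seed integer seed for the null subsample.
#' @param null_type `"diffs"` (absolute pairwise differences, default) or
#'   `"values"` (raw pooled depletion scores as the null sample).
#' @return data.frame with `gene_id`, `n_shrna`, `consistency_p`, `pass`.
#' @export
gene_consistency_test <- function(ds, shrna_to_gene, alpha = 0.1,
                                  max_null_pairs = 1e5, seed = 1,
                                  null_type = c("diffs", "values")) {
  null_type <- match.arg(null_type)
  rows <- which(!is.na(shrna_to_gene))
  genes <- split(rows, shrna_to_gene[rows])
  n_shrna <- lengths(genes)
  testable <- names(genes)[n_shrna >= 2]
  if (!length(testable)) stop("no gene has >= 2 shRNAs")

  nr <- nrow(ds); nc <- ncol(ds)
  if (null_type == "diffs") {
    n_total <- choose(nr, 2) * nc
    if (n_total <= max_null_pairs) {
      ij <- utils::combn(nr, 2)
      null_sample <- as.vector(abs(ds[ij[1, ], , drop = FALSE] -
                                     ds[ij[2, ], , drop = FALSE]))
    } else {
      set.seed(seed)
      i <- sample.int(nr, max_null_pairs, replace = TRUE)
      j <- sample.int(nr - 1, max_null_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1, j)      # distinct row pairs
      cc <- sample.int(nc, max_null_pairs, replace = TRUE)
      null_sample <- abs(ds[cbind(i, cc)] - ds[cbind(j, cc)])
    }
  } else {
    null_sample <- as.vector(ds)
  }

  null_sorted <- sort(null_sample)
  p <- vapply(testable, function(g) {
    idx <- genes[[g]]
    if (null_type == "diffs") {
      ij <- utils::combn(length(idx), 2)
      within <- as.vector(abs(ds[idx[ij[1, ]], , drop = FALSE] -
                                ds[idx[ij[2, ]], , drop = FALSE]))
    } else {
      within <- as.vector(ds[idx, , drop = FALSE])
    }
    mann_whitney_less(within, null_sorted)
  }, 0)

  data.frame(gene_id = testable, n_shrna = unname(n_shrna[testable]),
             consistency_p = unname(p), pass = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Collapse shRNA scores to gene-level scores
#'
#' Per cell line, the gene-level depletion score is the median over the
#' gene's shRNAs. Only the supplied (consistency-passing) genes are
#' collapsed.
#'
#' @param ds depletion-score matrix.
#' @param shrna_to_gene gene id per row.
#' @param genes character vector of genes to collapse.
#' @return gene x line matrix.
#' @export
collapse_to_gene <- function(ds, shrna_to_gene, genes) {
  out <- t(vapply(genes, function(g) {
    apply(ds[which(shrna_to_gene == g), , drop = FALSE], 2, stats::median)
  }, numeric(ncol(ds))))
  rownames(out) <- genes
  out
}

#' Skin-lineage specificity of gene-level depletion
#'
#' One-sided rank-sum test per gene that the depletion score is lower in
#' skin lines than in non-skin lines (stronger depletion = more
#' essential). A gene is flagged skin-specific when p < `alpha` and its
#' median skin score is below its median non-skin score. Exact
#' enumeration (tie-safe) for small line panels.
#'
#' @param gene_ds gene x line matrix.
#' @param lineage `"skin"`/`"non-skin"` per column.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with `gene_id`, `median_skin`, `median_nonskin`,
#'   `specificity_p`, `skin_specific`.
#' @export
skin_specificity_test <- function(gene_ds, lineage, alpha = 0.05) {
  skin <- lineage == "skin"
  if (sum(skin) < 2 || sum(!skin) < 2)
    stop("need at least 2 cell lines per lineage group")
  res <- lapply(rownames(gene_ds), function(g) {
    x <- gene_ds[g, skin]; y <- gene_ds[g, !skin]
    p <- rank_sum_test(x, y, alternative = "less")
    data.frame(gene_id = g,
               median_skin = stats::median(x),
               median_nonskin = stats::median(y),
               specificity_p = p,
               skin_specific = p < alpha &&
                 stats::median(x) < stats::median(y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full depletion-score essentiality pipeline
#'
#' Composition: (optional) count normalization -> negative-control
#' centering -> within-gene consistency filter (p < `consistency_alpha`)
#' -> gene-level median collapse -> skin-lineage specificity test
#' (p < `specificity_alpha`). Deterministic given `seed`. Output order is
#' invariant to shRNA and cell-line ordering of the input.
#'
#' @param screen a [screen_matrix()]; `ds` holds raw counts when
#'   `raw_counts = TRUE`.
#' @param consistency_alpha within-gene consistency threshold (default
#'   0.1).
#' @param specificity_alpha lineage-specificity threshold (default 0.05).
#' @param seed integer seed for the consistency null subsample.
#' @param raw_counts normalize `screen$ds` with [normalize_shrna()] first?
#' @param null_type passed to [gene_consistency_test()].
#' @return data.frame per testable gene: `gene_id`, `n_shrna`,
#'   `consistency_p`, `consistency_pass`, `median_skin`, `median_nonskin`,
#'   `specificity_p`, `skin_specific` (NA for genes failing consistency);
#'   the gene x line matrix of passing genes is attached as attribute
#'   `gene_ds`.
#' @export
run_essentiality_pipeline <- function(screen, consistency_alpha = 0.1,
                                      specificity_alpha = 0.05, seed = 1,
                                      raw_counts = FALSE,
                                      null_type = "diffs") {
  stopifnot(inherits(screen, "screen_matrix"))
  if (!any(screen$lineage == "skin")) stop("screen has no skin lines")
  if (!any(screen$lineage == "non-skin"))
    stop("screen has no non-skin lines")
  ds <- screen$ds
  if (raw_counts) ds <- normalize_shrna(ds)
  ds <- center_by_controls(ds, screen$is_negative_control)

  cons <- gene_consistency_test(ds, screen$shrna_to_gene,
                                alpha = consistency_alpha, seed = seed,
                                null_type = null_type)
  cons <- cons[order(cons$gene_id), ]
  passing <- cons$gene_id[cons$pass]
  out <- data.frame(gene_id = cons$gene_id, n_shrna = cons$n_shrna,
                    consistency_p = cons$consistency_p,
                    consistency_pass = cons$pass,
                    median_skin = NA_real_, median_nonskin = NA_real_,
                    specificity_p = NA_real_, skin_specific = NA,
                    stringsAsFactors = FALSE)
  gene_ds <- NULL
  if (length(passing)) {
    gene_ds <- collapse_to_gene(ds, screen$shrna_to_gene, passing)
    spec <- skin_specificity_test(gene_ds, screen$lineage,
                                  alpha = specificity_alpha)
    idx <- match(spec$gene_id, out$gene_id)
    out$median_skin[idx] <- spec$median_skin
    out$median_nonskin[idx] <- spec$median_nonskin
    out$specificity_p[idx] <- spec$specificity_p
    out$skin_specific[idx] <- spec$skin_specific
  }
  rownames(out) <- NULL
  attr(out, "gene_ds") <- gene_ds
  out
}
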