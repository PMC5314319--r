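#' Differential gene expression from a normalized two-column table
#'
#' `FC = (uv + pseudocount)/(ctrl + pseudocount)`; genes are `up` when
#' `FC > fc_cutoff`, `down` when `FC < 1/fc_cutoff`, else `none`
#' (strict inequalities). Classification is by fold change only; an
#' optional `pvalue` column (externally computed) is carried through
#' untouched for downstream filtering.
#'
#' @param expression data.frame with columns `gene_id`, `expr_control`,
#'   `expr_uv` and optionally `pvalue`.
#' @param pseudocount positive value added to both expression values.
#' @param fc_cutoff fold-change cutoff (> 1); default 2.
#' @return data.frame with `gene_id`, `expr_control`, `expr_uv`, `fc`,
#'   `log2fc`, `dge_class` (+ `pvalue` if supplied).
#' @export
compute_dge <- function(expression, pseudocount = 1, fc_cutoff = 2) {
  req <- c("gene_id", "expr_control", "expr_uv")
  if (!all(req %in% names(expression)))
    stop("expression table needs columns: ", paste(req, collapse = ", "))
  if (any(expression$expr_control < 0) || any(expression$expr_uv < 0))
    stop("negative expression value")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  fc <- (expression$expr_uv + pseudocount) /
        (expression$expr_control + pseudocount)
  out <- data.frame(
    gene_id = expression$gene_id,
    expr_control = expression$expr_control,
    expr_uv = expression$expr_uv,
    fc = fc,
    log2fc = log2(fc),
    dge_class = classify_fc(fc, fc_cutoff),
    stringsAsFactors = FALSE
  )
  if ("pvalue" %in% names(expression)) out$pvalue <- expression$pvalue
  out
}

#' Three-way binning of log2 fold changes
#'
#' Partitions values into `gt1` (log2FC > `edge`), `lt-1`
#' (log2FC < -`edge`) and `mid` otherwise. Values exactly at the edges
#' fall in `mid` (strict inequalities).
#'
#' @param log2fc numeric vector.
#' @param edge bin edge (default 1).
#' @return character vector in `{"gt1","lt-1","mid"}`.
#' @export
bin_by_log2fc <- function(log2fc, edge = 1) {
  ifelse(log2fc > edge, "gt1", ifelse(log2fc < -edge, "lt-1", "mid"))
}

#' Join expression and acetylation calls per gene
#'
#' Builds the per-gene integration record: expression fold change and
#' class, acetylation fold change and class, the three-way acetylation
#' bin, and the concordance call (`positive` when both classes agree and
#' are not `none`; `inverse` for up/down opposition; `none` otherwise).
#'
#' @param dge output of [compute_dge()].
#' @param dha output of [compute_dha()].
#' @param all keep genes present in only one table (missing side gets NA
#'   fold change and class `none`)? Default `FALSE` (intersection).
#' @param edge bin edge passed to [bin_by_log2fc()].
#' @return data.frame with one row per gene.
#' @export
integrate_omics <- function(dge, dha, all = FALSE, edge = 1) {
  m <- merge(
    dge[, c("gene_id", "log2fc", "dge_class")],
    dha[, c("gene_id", "log2fc", "dha_class")],
    by = "gene_id", all = all, suffixes = c("_dge", "_dha"))
  if (all) {
    m$dge_class[is.na(m$dge_class)] <- "none"
    m$dha_class[is.na(m$dha_class)] <- "none"
  }
  m$dha_bin <- bin_by_log2fc(m$log2fc_dha, edge)
  m$dha_bin[is.na(m$log2fc_dha)] <- "mid"
  same <- m$dge_class == m$dha_class & m$dge_class != "none"
  opp <- (m$dge_class == "up" & m$dha_class == "down") |
         (m$dge_class == "down" & m$dha_class == "up")
  m$concordance <- ifelse(same, "positive", ifelse(opp, "inverse", "none"))
  m[order(m$gene_id), ]
}

#' Expression shift across acetylation bins
#'
#' Two-sample t-test of the expression log2FC of the genes in each extreme
#' acetylation bin (`gt1`, `lt-1`) against the genes in the `mid` bin.
#' Student's (equal-variance) test by default, matching the convention of
#' comparing group means of log fold changes; Welch via
#' `var_equal = FALSE`. Groups with fewer than 2 genes are flagged
#' untestable.
#'
#' @param records output of [integrate_omics()] (needs `log2fc_dge` and
#'   `dha_bin`).
#' @param var_equal use the pooled-variance (Student) test? Default TRUE.
#' @return data.frame with one row per extreme bin: `group`, `n`, `n_mid`,
#'   `mean_shift`, `t`, `df`, `p`, `testable`.
#' @export
group_shift_test <- function(records, var_equal = TRUE) {
  mid <- records$log2fc_dge[records$dha_bin == "mid"]
  one <- function(group) {
    x <- records$log2fc_dge[records$dha_bin == group]
    if (length(x) < 2 || length(mid) < 2) {
      return(data.frame(group = group, n = length(x), n_mid = length(mid),
                        mean_shift = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, testable = FALSE))
    }
    tt <- stats::t.test(x, mid, var.equal = var_equal)
    data.frame(group = group, n = length(x), n_mid = length(mid),
               mean_shift = mean(x) - mean(mid),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, testable = TRUE)
  }
  rbind(one("gt1"), one("lt-1"))
}

#' Expression-by-acetylation concordance matrix
#'
#' 3x3 contingency table of expression class against acetylation class.
#' The `(up,up)` and `(down,down)` cells are the positive-correlation
#' genes; `(up,down)` and `(down,up)` the inverse-correlation genes.
#'
#' @param records output of [integrate_omics()].
#' @return a 3x3 table (rows = expression class, cols = acetylation
#'   class), levels ordered up, none, down.
#' @export
concordance_matrix <- function(records) {
  lev <- c("up", "none", "down")
  table(dge = factor(records$dge_class, levels = lev),
        dha = factor(records$dha_class, levels = lev))
}
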