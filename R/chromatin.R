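#' Gene-level differential H3K27 acetylation (DHA)
#'
#' For every gene with at least one assigned peak in either condition, the
#' mean signal of the H3K27ac peaks assigned to it (within `window` bp of
#' the gene body) is compared between UV-irradiated and control samples:
#' `FC = (mean_uv + pseudocount) / (mean_ctrl + pseudocount)`. Genes are
#' classed `up` when `FC > fc_cutoff`, `down` when `FC < 1/fc_cutoff`, and
#' `none` otherwise (strict inequalities: a gene at exactly the cutoff is
#' `none`). The pseudocount defines the fold change when a gene has peaks
#' in only one condition.
#'
#' @param peaks_control,peaks_uv `GRanges` of scored peaks (see
#'   [read_peaks()]).
#' @param annotation a [genome_annotation()] object.
#' @param window peak-to-gene assignment window in bp.
#' @param fc_cutoff fold-change cutoff (> 1); default 2.
#' @param pseudocount positive value added to both means; default 1.
#' @return data.frame with columns `gene_id`, `mean_signal_control`,
#'   `mean_signal_uv`, `fc`, `log2fc`, `dha_class`.
#' @export
compute_dha <- function(peaks_control, peaks_uv, annotation,
                        window = 10000, fc_cutoff = 2, pseudocount = 1) {
  if (!length(annotation$genes)) stop("empty annotation")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (fc_cutoff <= 1) stop("fc_cutoff must be > 1")

  mean_by_gene <- function(peaks) {
    asg <- assign_peaks_to_genes(peaks, annotation, window)
    if (!nrow(asg)) return(numeric(0))
    tapply(asg$signal, asg$gene_id, mean)
  }
  m_ctrl <- mean_by_gene(peaks_control)
  m_uv <- mean_by_gene(peaks_uv)
  genes <- sort(union(names(m_ctrl), names(m_uv)))
  if (!length(genes)) {
    return(data.frame(gene_id = character(0), mean_signal_control = numeric(0),
                      mean_signal_uv = numeric(0), fc = numeric(0),
                      log2fc = numeric(0), dha_class = character(0)))
  }
  mc <- ifelse(genes %in% names(m_ctrl), m_ctrl[genes], 0)
  mu <- ifelse(genes %in% names(m_uv), m_uv[genes], 0)
  fc <- (mu + pseudocount) / (mc + pseudocount)
  data.frame(
    gene_id = genes,
    mean_signal_control = unname(mc),
    mean_signal_uv = unname(mu),
    fc = unname(fc),
    log2fc = unname(log2(fc)),
    dha_class = classify_fc(fc, fc_cutoff),
    stringsAsFactors = FALSE
  )
}

# strict-threshold fold-change classification shared by DHA and DGE
classify_fc <- function(fc, fc_cutoff = 2) {
  ifelse(fc > fc_cutoff, "up", ifelse(fc < 1 / fc_cutoff, "down", "none"))
}

#' Global acetylation trend from paired tag values
#'
#' Least-squares slope through the origin of UV tag values on control tag
#' values, over merged peak regions. A slope below 1 indicates a net
#' genome-wide loss of H3K27ac.
#'
#' @param tags_control,tags_uv equal-length numeric vectors of per-region
#'   tag values (n >= 2).
#' @return the slope `sum(x*y)/sum(x^2)`.
#' @export
global_signal_slope <- function(tags_control, tags_uv) {
  if (length(tags_control) != length(tags_uv))
    stop("paired vectors must have equal length")
  if (length(tags_control) < 2) stop("need at least 2 regions")
  if (all(tags_control == 0)) stop("all-zero control vector")
  sum(tags_control * tags_uv) / sum(tags_control^2)
}

#' Per-region tag values over the merged peak universe
#'
#' Merges the peak intervals of both samples (union, overlap-collapsed) and
#' sums each sample's peak signal within every merged region, producing the
#' paired vectors consumed by [global_signal_slope()].
#'
#' @param peaks_a,peaks_b `GRanges` of scored peaks.
#' @return data.frame with `chrom`, `start`, `end`, `tags_a`, `tags_b`.
#' @export
merged_region_signal <- function(peaks_a, peaks_b) {
  merged <- GenomicRanges::reduce(
    c(GenomicRanges::granges(peaks_a), GenomicRanges::granges(peaks_b)),
    ignore.strand = TRUE)
  sum_in <- function(peaks) {
    hits <- GenomicRanges::findOverlaps(peaks, merged, ignore.strand = TRUE)
    v <- numeric(length(merged))
    s <- tapply(peaks$signal[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
    v[as.integer(names(s))] <- s
    v
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    tags_a = sum_in(peaks_a),
    tags_b = sum_in(peaks_b),
    stringsAsFactors = FALSE
  )
}
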