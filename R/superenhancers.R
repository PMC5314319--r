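#' Remove peaks overlapping promoter windows
#'
#' Drops every peak that overlaps the closed window
#' `[tss - tss_window, tss + tss_window]` of any gene, so that only distal
#' ("constituent enhancer") peaks enter super-enhancer stitching. With
#' `tss_window = 0` only peaks covering the TSS base itself are removed.
#'
#' @param peaks `GRanges` of scored peaks.
#' @param annotation a [genome_annotation()] object.
#' @param tss_window half-width of the promoter window in bp (default 2500).
#' @return the retained peaks.
#' @export
exclude_promoter_peaks <- function(peaks, annotation, tss_window = 2500) {
  stopifnot(tss_window >= 0)
  g <- annotation$genes
  if (!length(g)) return(peaks)
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(pmax(1, g$tss - tss_window), g$tss + tss_window))
  drop <- IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)
  peaks[!drop]
}

#' Stitch constituent enhancers into clusters
#'
#' Transitive closure of the "within `stitch_distance`" relation on a
#' chromosome: consecutive peaks separated by a gap of at most
#' `stitch_distance` bp merge into one stitched enhancer spanning from the
#' first start to the last end; its total signal is the sum of its
#' constituents'.
#'
#' @param peaks `GRanges` of scored peaks.
#' @param stitch_distance maximum gap in bp (default 12500).
#' @return `GRanges` of stitched enhancers with `total_signal`,
#'   `n_constituents` and a `revmap` (`IntegerList` of constituent peak
#'   indices) metadata column.
#' @export
stitch_enhancers <- function(peaks, stitch_distance = 12500) {
  st <- GenomicRanges::reduce(peaks, min.gapwidth = stitch_distance + 1,
                              with.revmap = TRUE, ignore.strand = TRUE)
  st$total_signal <- vapply(st$revmap,
                            function(i) sum(peaks$signal[i]), 0)
  st$n_constituents <- lengths(st$revmap)
  st
}

#' Transition-point cutoff on the rank-ordered signal curve
#'
#' Sorts the stitched-enhancer total signals ascending, min-max scales both
#' rank and signal to the unit square, and places the cutoff at the index
#' maximising the depth below the diagonal, `x - y` (the point where the
#' tangent slope of a convex curve passes 1). Enhancers with signal
#' strictly above the cutoff signal are super enhancers. Ties in depth go
#' to the smallest index; a curve with no point below the diagonal is
#' degenerate and flagged with a warning.
#'
#' @param total_signals numeric vector of stitched-enhancer signals
#'   (length >= 3, not all equal).
#' @return list with `cutoff_signal`, `cutoff_index` (into the ascending
#'   sort), `n`, and `degenerate` flag.
#' @export
se_cutoff <- function(total_signals) {
  n <- length(total_signals)
  if (n < 3) stop("need at least 3 signals")
  s <- sort(total_signals)
  if (s[1] == s[n]) stop("no transition point: constant signal vector")
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  depth <- x - y
  i <- which.max(depth)   # ties resolved to the smallest index
  degenerate <- depth[i] <= 0
  if (degenerate)
    warning("degenerate rank-signal curve: no point below the diagonal")
  list(cutoff_signal = s[i], cutoff_index = i, n = n,
       degenerate = degenerate)
}

#' Call super enhancers from constituent peaks
#'
#' Composition of promoter-peak exclusion, stitching, rank ordering and the
#' transition-point cutoff. Stitched enhancers with total signal strictly
#' above the cutoff are designated super enhancers (so the
#' transition-point enhancer itself is not one).
#'
#' @param peaks `GRanges` of scored peaks.
#' @param annotation a [genome_annotation()] object.
#' @param stitch_distance stitching gap in bp (default 12500).
#' @param tss_window promoter-exclusion half-width in bp (default 2500).
#' @param sample label carried in the result.
#' @return object of class `se_set`: list with `sample`, `stitched`
#'   (`GRanges`, descending `total_signal`, with `rank` and `is_se`),
#'   `superenhancers` (the above-cutoff subset, named `SE_1`, `SE_2`, ...
#'   by rank), `cutoff_signal`, `cutoff_index`.
#' @export
call_superenhancers <- function(peaks, annotation, stitch_distance = 12500,
                                tss_window = 2500, sample = "sample") {
  if (!length(peaks)) stop("no peaks")
  kept <- exclude_promoter_peaks(peaks, annotation, tss_window)
  if (!length(kept)) stop("no peaks left after promoter exclusion")
  st <- stitch_enhancers(kept, stitch_distance)
  if (length(st) < 3) stop("need at least 3 stitched enhancers")
  cut <- se_cutoff(st$total_signal)
  ord <- order(st$total_signal, decreasing = TRUE)
  st <- st[ord]
  st$rank <- seq_along(st)
  st$is_se <- st$total_signal > cut$cutoff_signal
  ses <- st[st$is_se]
  if (length(ses)) names(ses) <- sprintf("SE_%d", ses$rank)
  structure(list(sample = sample, stitched = st, superenhancers = ses,
                 cutoff_signal = cut$cutoff_signal,
                 cutoff_index = cut$cutoff_index,
                 degenerate = cut$degenerate),
            class = "se_set")
}

#' @export
print.se_set <- function(x, ...) {
  cat("se_set [", x$sample, "]: ", length(x$superenhancers), " SEs of ",
      length(x$stitched), " stitched enhancers (cutoff signal ",
      signif(x$cutoff_signal, 4), ")\n", sep = "")
  invisible(x)
}

#' Associate genes with super enhancers
#'
#' A gene is associated with a super enhancer when its body lies within
#' `window` bp of the SE interval (boundary gap distance; a gene inside the
#' SE is at distance 0). Genes may associate with several SEs and vice
#' versa.
#'
#' @param se_set an `se_set` from [call_superenhancers()].
#' @param annotation a [genome_annotation()] object.
#' @param window association window in bp (default 25000).
#' @return data.frame with `se`, `gene_id`, `distance`.
#' @export
annotate_se_genes <- function(se_set, annotation, window = 25000) {
  ses <- se_set$superenhancers
  genes <- annotation$genes
  hits <- GenomicRanges::findOverlaps(ses, genes, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(
    se = names(ses)[qi],
    gene_id = genes$gene_id[si],
    distance = interval_distance(ses[qi], genes[si]),
    stringsAsFactors = FALSE
  )
}

#' Compare two super-enhancer sets
#'
#' An SE of one sample is "common" when it overlaps (by at least
#' `min_overlap_bp`) any SE of the other sample; otherwise it is unique to
#' its sample. Because one SE may span several in the other set, the common
#' counts of the two samples need not agree.
#'
#' @param a,b `se_set` objects on the same genome.
#' @param min_overlap_bp minimum overlap in bp to count as the same SE.
#' @return list with counts `common_a`, `common_b`, `unique_a`, `unique_b`
#'   and logical membership vectors `a_is_common`, `b_is_common`.
#' @export
compare_se_sets <- function(a, b, min_overlap_bp = 1) {
  sa <- a$superenhancers; sb <- b$superenhancers
  a_common <- suppressWarnings(GenomicRanges::countOverlaps(
    sa, sb, minoverlap = min_overlap_bp, ignore.strand = TRUE)) > 0
  b_common <- suppressWarnings(GenomicRanges::countOverlaps(
    sb, sa, minoverlap = min_overlap_bp, ignore.strand = TRUE)) > 0
  list(common_a = sum(a_common), common_b = sum(b_common),
       unique_a = sum(!a_common), unique_b = sum(!b_common),
       a_is_common = a_common, b_is_common = b_common)
}
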