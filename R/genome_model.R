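#' Genome annotation container
#'
#' Bundles gene models (bodies, TSS, strand) with their exon and UTR
#' sub-features and the chromosome lengths they live on. All downstream
#' interval assignment (peak-to-gene annotation, promoter exclusion,
#' super-enhancer/gene association, variant classification) runs against
#' this object.
#'
#' Coordinates are held as `GRanges` (1-based, closed). BED input/output is
#' converted at the boundary; GFF3 and VCF are natively 1-based.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` metadata column
#'   and strand set to `+` or `-`.
#' @param features `GRanges` of sub-features with `gene_id` and `type`
#'   metadata columns; `type` is one of `"exon"`, `"five_prime_UTR"`,
#'   `"three_prime_UTR"`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#'
#' @return An object of class `genome_annotation` with elements `genes`
#'   (carrying a computed `tss` column), `features` and `chrom_lengths`.
#' @export
genome_annotation <- function(genes, features, chrom_lengths) {
  stopifnot(is(genes, "GRanges"), is(features, "GRanges"))
  if (is.null(genes$gene_id)) stop("genes must carry a gene_id column")
  if (anyDuplicated(genes$gene_id))
    stop("validation error: duplicated gene identifiers")
  if (any(!as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop("validation error: gene strand must be + or -")
  if (length(chrom_lengths) &&
      (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))))
    stop("chrom_lengths must be a named vector")

  # genes must lie on known chromosomes, within their lengths
  chr <- as.character(GenomicRanges::seqnames(genes))
  bad <- !(chr %in% names(chrom_lengths))
  if (any(bad))
    stop("validation error: gene on unknown chromosome: ", chr[bad][1])
  if (any(GenomicRanges::start(genes) < 1) ||
      any(GenomicRanges::end(genes) > chrom_lengths[chr]))
    stop("validation error: gene interval outside chromosome bounds")

  # sub-features must lie inside their parent gene body
  if (length(features)) {
    if (is.null(features$gene_id) || is.null(features$type))
      stop("features must carry gene_id and type columns")
    idx <- match(features$gene_id, genes$gene_id)
    if (anyNA(idx))
      stop("validation error: feature refers to unknown gene ",
           features$gene_id[which(is.na(idx))[1]])
    within_ok <-
      as.character(GenomicRanges::seqnames(features)) ==
        as.character(GenomicRanges::seqnames(genes))[idx] &
      GenomicRanges::start(features) >= GenomicRanges::start(genes)[idx] &
      GenomicRanges::end(features) <= GenomicRanges::end(genes)[idx]
    if (!all(within_ok))
      stop("validation error: feature outside gene body for gene ",
           features$gene_id[which(!within_ok)[1]])
  }

  genes$tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                      GenomicRanges::start(genes),
                      GenomicRanges::end(genes))
  obj <- list(genes = genes, features = features,
              chrom_lengths = chrom_lengths)
  class(obj) <- "genome_annotation"
  obj
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$genes), "genes on",
      length(x$chrom_lengths), "chromosomes (",
      format(sum(x$chrom_lengths), big.mark = ","), "bp )\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Accepts `gene`, `exon`, `five_prime_UTR` and `three_prime_UTR` features
#' (1-based inclusive GFF3 coordinates); exons and UTRs are attached to
#' their gene via the `Parent` attribute. Chromosome lengths are taken from
#' `##sequence-region` directives.
#'
#' @param path path to a GFF3 file.
#' @return a [genome_annotation()] object.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body_idx)) {
    nfields <- lengths(strsplit(lines[body_idx], "\t", fixed = TRUE))
    if (any(nfields != 9))
      stop("GFF3 parse error at line ", body_idx[which(nfields != 9)[1]],
           ": expected 9 tab-separated fields")
  }

  sr <- lines[startsWith(lines, "##sequence-region")]
  chrom_lengths <- numeric(0)
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    chrom_lengths <- vapply(parts, function(p) as.numeric(p[4]), 0)
    names(chrom_lengths) <- vapply(parts, function(p) p[2], "")
  }

  if (!length(body_idx)) {
    return(genome_annotation(
      GenomicRanges::GRanges(gene_id = character(0)),
      GenomicRanges::GRanges(gene_id = character(0), type = character(0)),
      chrom_lengths))
  }

  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  gid <- genes$ID
  if (is.null(gid) || anyNA(gid))
    stop("validation error: gene feature without ID attribute")
  gmc <- S4Vectors::DataFrame(gene_id = as.character(gid))
  S4Vectors::mcols(genes) <- gmc

  feats <- gr[gr$type %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  parent <- as.character(S4Vectors::unstrsplit(feats$Parent, sep = ","))
  fmc <- S4Vectors::DataFrame(gene_id = parent,
                              type = as.character(feats$type))
  S4Vectors::mcols(feats) <- fmc

  if (!length(chrom_lengths)) {
    # fall back to observed extents so bounds checks remain meaningful
    ends <- tapply(GenomicRanges::end(gr),
                   as.character(GenomicRanges::seqnames(gr)), max)
    chrom_lengths <- as.numeric(ends)
    names(chrom_lengths) <- names(ends)
  }
  genome_annotation(genes, feats, chrom_lengths)
}

#' Write a genome annotation back to GFF3
#'
#' Inverse of [read_gene_annotation()]: reading the written file recovers
#' the same coordinates, strands, identifiers and chromosome lengths.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  g <- annotation$genes
  f <- annotation$features
  n_g <- length(g); n_f <- length(f)
  all <- c(GenomicRanges::granges(g), GenomicRanges::granges(f))
  all$type <- c(rep("gene", n_g),
                if (n_f) f$type else character(0))
  all$ID <- c(as.character(g$gene_id), rep(NA_character_, n_f))
  all$Parent <- IRanges::CharacterList(
    c(replicate(n_g, character(0), simplify = FALSE),
      if (n_f) as.list(f$gene_id) else list()))
  rtracklayer::export(all, path, format = "gff3")
  # inject sequence-region directives after the version line
  out <- readLines(path)
  sr <- sprintf("##sequence-region %s 1 %d",
                names(annotation$chrom_lengths),
                as.integer(annotation$chrom_lengths))
  writeLines(c(out[1], sr, out[-1]), path)
  invisible(path)
}

#' Read scored peaks from a BED file
#'
#' BED is 0-based half-open on disk; returned peaks are `GRanges` (1-based
#' closed) with the score column renamed to `signal`. Input need not be
#' sorted; output is sorted by (chromosome, start). Duplicate intervals are
#' retained.
#'
#' @param path BED file with at least 5 columns (chrom, start, end, name,
#'   signal).
#' @return `GRanges` with `name` and `signal` metadata columns.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$score) || anyNA(gr$score))
    stop("validation error: peak signal missing or non-numeric")
  if (any(gr$score < 0))
    stop("validation error: negative peak signal")
  gr$signal <- as.numeric(gr$score)
  gr$score <- NULL
  ndup <- sum(duplicated(paste(GenomicRanges::seqnames(gr),
                               GenomicRanges::start(gr),
                               GenomicRanges::end(gr))))
  if (ndup > 0) message(ndup, " duplicate peak interval(s) retained")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write peaks as BED with signal in column 5
#'
#' @param peaks `GRanges` with a `signal` column.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  out <- peaks
  out$score <- out$signal
  out$signal <- NULL
  if (is.null(out$name))
    out$name <- sprintf("peak_%d", seq_along(out))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Gap distance between two intervals
#'
#' Returns 0 when the intervals overlap or abut, otherwise the number of
#' bases strictly between them; intervals on different chromosomes are at
#' infinite distance. Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return numeric vector of distances in bp (`Inf` across chromosomes).
#' @export
interval_distance <- function(a, b) {
  d <- suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
  d <- as.numeric(d)
  d[is.na(d)] <- Inf
  d
}

#' Assign peaks to nearby genes
#'
#' A peak is assigned to every gene whose body lies within `window` bp of
#' it (gap distance; overlap counts as distance 0). Peaks near several
#' genes are assigned to all of them; peaks matching no gene are dropped.
#'
#' @param peaks `GRanges` with a `signal` column.
#' @param annotation a [genome_annotation()] object.
#' @param window maximum gap in bp (default 10000, the standard
#'   peak-to-gene annotation window).
#' @return data.frame with columns `gene_id`, `peak` (index into `peaks`),
#'   `signal`, `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, window = 10000) {
  stopifnot(window >= 0)
  genes <- annotation$genes
  if (!length(genes)) stop("empty annotation")
  hits <- GenomicRanges::findOverlaps(peaks, genes, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(
    gene_id = genes$gene_id[si],
    peak = qi,
    signal = peaks$signal[qi],
    distance = interval_distance(peaks[qi], genes[si]),
    stringsAsFactors = FALSE
  )
}
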