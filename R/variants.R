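#' Read single-nucleotide variants from a VCF or TSV file
#'
#' VCF records are parsed with CHROM, POS (1-based), REF, ALT and depth
#' from the INFO `DP` field; non-SNV records (indels, multi-allelic or
#' symbolic alleles) are skipped with a message giving the count. A TSV
#' alternative needs columns `chrom`, `pos`, `ref`, `alt`, `depth`.
#'
#' @param path input file; treated as VCF when the first line starts with
#'   `##fileformat` or the extension is `.vcf`, TSV otherwise.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `depth`.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1)
  is_vcf <- grepl("\\.vcf$", path) ||
    (length(first) && startsWith(first, "##fileformat"))
  if (is_vcf) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(fx) || nrow(fx) == 0) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        depth = numeric(0)))
    }
    depth <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
    out <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                      ref = fx[, "REF"], alt = fx[, "ALT"],
                      depth = as.numeric(depth),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("chrom", "pos", "ref", "alt", "depth")
    if (!all(req %in% names(out)))
      stop("TSV variant table needs columns: ", paste(req, collapse = ", "))
    out <- out[, req]
  }
  snv <- !is.na(out$ref) & !is.na(out$alt) &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  n_skip <- sum(!snv)
  if (n_skip > 0) message(n_skip, " non-SNV record(s) skipped")
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variants as a minimal VCF
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, `depth`.
#' @param chrom_lengths named vector for the contig header lines.
#' @param path output path.
#' @export
write_variants <- function(variants, path, chrom_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(chrom_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                     as.integer(chrom_lengths)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d",
                  variants$chrom, as.integer(variants$pos), variants$ref,
                  variants$alt, as.integer(variants$depth))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Discard low-depth variants
#'
#' Keeps variants supported by at least `min_depth` reads (a depth of
#' exactly `min_depth` is kept).
#'
#' @param variants variant data.frame.
#' @param min_depth minimum read depth (default 10).
#' @export
filter_by_depth <- function(variants, min_depth = 10) {
  out <- variants[variants$depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants shared between two sets
#'
#' Identity requires exact match of (chrom, pos, ref, alt) — the same
#' position with a different alternate allele is a different variant.
#' Output sorted by (chrom, pos).
#'
#' @param a,b variant data.frames.
#' @return the common variants (rows of `a`).
#' @export
intersect_variant_sets <- function(a, b) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  out <- a[key(a) %in% key(b), , drop = FALSE]
  out <- out[!duplicated(key(out)), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# disjoint genomic feature space of an annotation, in precedence order:
# exon (coding, UTR-free) > utr5 > utr3 > intron > upstream1kb >
# downstream1kb > intergenic
annotation_feature_space <- function(annotation, flank = 1000) {
  g <- annotation$genes
  f <- annotation$features
  gr0 <- function(x) GenomicRanges::granges(x)
  rd <- function(x) GenomicRanges::reduce(x, ignore.strand = TRUE)
  take <- function(type) rd(gr0(f[f$type == type]))
  utr5 <- take("five_prime_UTR")
  utr3 <- take("three_prime_UTR")
  exon_raw <- take("exon")
  utr <- rd(c(utr5, utr3))
  exon <- GenomicRanges::setdiff(exon_raw, utr, ignore.strand = TRUE)
  utr3 <- GenomicRanges::setdiff(utr3, utr5, ignore.strand = TRUE)
  body <- rd(gr0(g))
  intron <- GenomicRanges::setdiff(
    body, rd(c(exon_raw, utr)), ignore.strand = TRUE)
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  up <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(
      ifelse(plus, pmax(1, GenomicRanges::start(g) - flank),
             GenomicRanges::end(g) + 1),
      ifelse(plus, pmax(1, GenomicRanges::start(g) - 1),
             GenomicRanges::end(g) + flank)))
  down <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(
      ifelse(plus, GenomicRanges::end(g) + 1,
             pmax(1, GenomicRanges::start(g) - flank)),
      ifelse(plus, GenomicRanges::end(g) + flank,
             pmax(1, GenomicRanges::start(g) - 1))))
  up <- GenomicRanges::setdiff(rd(up), body, ignore.strand = TRUE)
  down <- GenomicRanges::setdiff(rd(down), body, ignore.strand = TRUE)
  down <- GenomicRanges::setdiff(down, up, ignore.strand = TRUE)
  genome <- GenomicRanges::GRanges(
    names(annotation$chrom_lengths),
    IRanges::IRanges(1, as.integer(annotation$chrom_lengths)))
  intergenic <- GenomicRanges::setdiff(
    genome, rd(c(body, up, down)), ignore.strand = TRUE)
  list(exon = exon, utr5 = utr5, utr3 = utr3, intron = intron,
       upstream1kb = up, downstream1kb = down, intergenic = intergenic)
}

#' Classify variants by genomic feature
#'
#' Assigns each variant exactly one category with precedence
#' exon > utr5 > utr3 > intron > upstream1kb > downstream1kb > intergenic.
#' "exon" means protein-coding exonic sequence outside the UTRs; "intron"
#' is inside a gene body but in no exon; the 1 kb flanks are measured from
#' the gene body ends, strand-aware. `gene_id` is reported for genic and
#' flank categories (the first matching gene when models are close).
#'
#' @param variants variant data.frame (`chrom`, `pos`, ...).
#' @param annotation a [genome_annotation()] object.
#' @param flank flank width in bp (default 1000).
#' @return the input with `category` and `gene_id` columns appended.
#' @export
classify_variants <- function(variants, annotation, flank = 1000) {
  space <- annotation_feature_space(annotation, flank)
  pos <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  category <- rep(NA_character_, nrow(variants))
  for (cat in c("exon", "utr5", "utr3", "intron", "upstream1kb",
                "downstream1kb", "intergenic")) {
    hit <- IRanges::overlapsAny(pos, space[[cat]],
                                      ignore.strand = TRUE)
    category[is.na(category) & hit] <- cat
  }
  category[is.na(category)] <- "intergenic"   # off-annotation positions

  g <- annotation$genes
  near <- GenomicRanges::findOverlaps(pos, g, maxgap = flank,
                                      ignore.strand = TRUE,
                                      select = "first")
  gene_id <- ifelse(category == "intergenic", NA_character_,
                    g$gene_id[near])
  out <- variants
  out$category <- category
  out$gene_id <- gene_id
  out
}

#' Strand-collapsed substitution spectrum
#'
#' Counts substitutions in the six pyrimidine-rooted classes, folding
#' purine-rooted variants onto their reverse complement (so `G>A` counts
#' as `C>T/G>A`, the UV signature class, etc.). Counts sum to the number
#' of variants.
#'
#' @param variants variant data.frame with `ref` and `alt`.
#' @return named integer vector over the six classes.
#' @export
mutation_spectrum <- function(variants) {
  classes <- c("C>T/G>A", "C>A/G>T", "C>G/G>C",
               "T>A/A>T", "T>C/A>G", "T>G/A>C")
  if (!nrow(variants)) {
    out <- integer(length(classes)); names(out) <- classes
    return(out)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- variants$ref; alt <- variants$alt
  flip <- ref %in% c("G", "A")
  ref[flip] <- comp[variants$ref[flip]]
  alt[flip] <- comp[variants$alt[flip]]
  key <- paste0(ref, ">", alt)
  map <- c("C>T" = "C>T/G>A", "C>A" = "C>A/G>T", "C>G" = "C>G/G>C",
           "T>A" = "T>A/A>T", "T>C" = "T>C/A>G", "T>G" = "T>G/A>C")
  tab <- table(factor(map[key], levels = classes))
  out <- as.integer(tab); names(out) <- classes
  out
}
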