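#' Kolmogorov-Smirnov enrichment score of a gene set in a ranked list
#'
#' Classical unweighted KS deviation between the cumulative distribution
#' of the set members' ranks and that of the complement, evaluated down
#' the ranked list. The returned score is the signed deviation of maximal
#' magnitude: positive when the set concentrates at the top of the
#' ranking, negative at the bottom. Depends only on the order of the
#' list, not on the ranking metric itself.
#'
#' @param ranked character vector of unique gene ids, best-ranked first.
#' @param gene_set character vector; must be a proper non-empty subset of
#'   `ranked`.
#' @param weights optional numeric vector aligned to `ranked` (e.g. the
#'   ranking metric): when supplied, the set CDF weights each member by
#'   `abs(weight)` (the running-sum style); the default `NULL` is the
#'   classical unweighted statistic.
#' @return the enrichment score in `[-1, 1]`.
#' @export
ks_enrichment_score <- function(ranked, gene_set, weights = NULL) {
  if (anyDuplicated(ranked)) stop("ranked gene ids must be unique")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% ranked))
    stop("gene_set must be a subset of the ranked genes")
  n <- length(ranked); m <- length(gene_set)
  if (m == 0 || m == n) stop("gene set must be a proper non-empty subset")
  inset <- ranked %in% gene_set
  if (is.null(weights)) {
    f_set <- cumsum(inset) / m
  } else {
    if (length(weights) != n)
      stop("weights must align with the ranked list")
    w <- abs(weights) * inset
    if (sum(w) == 0) stop("all set members have zero weight")
    f_set <- cumsum(w) / sum(w)
  }
  d <- f_set - cumsum(!inset) / (n - m)
  d[which.max(abs(d))]
}

#' Permutation p-value for a KS enrichment score
#'
#' Null distribution by uniformly reshuffling gene labels: the enrichment
#' score is recomputed for `n_perm` random sets of the same size, and
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` (add-one rule, so p is
#' never 0 and is bounded below by `1/(n_perm+1)`). One-sided toward
#' top-of-list enrichment; to test for concentration at the bottom,
#' reverse the ranking.
#'
#' @param ranked character vector of unique gene ids, best-ranked first.
#' @param gene_set proper non-empty subset of `ranked`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; required for reproducibility.
#' @return data.frame with `es`, `p_perm`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(ranked, gene_set, n_perm = 1000, seed) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  es <- ks_enrichment_score(ranked, gene_set)
  n <- length(ranked); m <- length(unique(gene_set))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    inset <- logical(n)
    inset[sample.int(n, m)] <- TRUE
    d <- cumsum(inset) / m - cumsum(!inset) / (n - m)
    d[which.max(abs(d))]
  }, 0)
  data.frame(es = es,
             p_perm = (1 + sum(null_es >= es)) / (n_perm + 1),
             n_perm = n_perm, seed = seed)
}

#' Hypergeometric pathway over-representation with Bonferroni adjustment
#'
#' For each pathway, the upper-tail probability of observing at least the
#' seen overlap between the query set and the pathway under random draws
#' from the universe: `P(X >= k)`, `X ~ Hypergeom(N, K, n)` with `N` the
#' universe size, `K` the pathway size and `n` the query size. Adjusted
#' p is `min(1, p * number of pathways)`.
#'
#' @param query_set character vector of gene ids (subset of `universe`).
#' @param pathway_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all assayed gene ids.
#' @return data.frame with `pathway`, `n_pathway`, `n_overlap`, `p`,
#'   `p_bonferroni`, sorted by `p`.
#' @export
hypergeometric_enrichment <- function(query_set, pathway_sets, universe) {
  universe <- unique(universe)
  query_set <- unique(query_set)
  if (!all(query_set %in% universe))
    stop("query_set must be a subset of the universe")
  if (is.null(names(pathway_sets)))
    names(pathway_sets) <- sprintf("pathway_%d", seq_along(pathway_sets))
  N <- length(universe); nq <- length(query_set)
  res <- lapply(names(pathway_sets), function(nm) {
    pw <- unique(pathway_sets[[nm]])
    if (!all(pw %in% universe))
      stop("pathway '", nm, "' is not a subset of the universe")
    k <- length(intersect(query_set, pw))
    p <- stats::phyper(k - 1, length(pw), N - length(pw), nq,
                       lower.tail = FALSE)
    data.frame(pathway = nm, n_pathway = length(pw), n_overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), ]
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
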