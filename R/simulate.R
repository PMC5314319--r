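#' Simulation configuration with planted ground truth
#'
#' Defaults describe the study conditions the pipeline is designed for: a
#' small multi-chromosome genome with isolated gene models, a
#' heavy-tailed (hockey-stick) enhancer signal landscape with planted
#' super-enhancer clusters, a global UV signal loss with regional gains,
#' planted differential-acetylation and differential-expression genes
#' with configurable coupling, variant sets with controlled overlap,
#' feature-category and substitution-spectrum composition, and an shRNA
#' screen with planted skin-essential genes.
#'
#' Gene models are tiled with inter-gene gaps larger than the 12.5 kb
#' stitch distance and enhancer slots are laid on an 18 kb grid away from
#' gene bodies, so that planted clusters are the only high-aggregate
#' stitched enhancers by construction and recovery tests are exact.
#'
#' @param seed integer master seed; each generator derives its own stream
#'   from it.
#' @param ... overrides for any default listed below.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome / annotation
    chrom_lengths = c(chr1 = 6.5e6, chr2 = 5.5e6, chr3 = 4.5e6),
    n_genes = 200,
    gene_length_range = c(2000, 6000),
    gene_gap_range = c(13000, 18000),
    large_gap_prob = 0.25,
    large_gap_range = c(52000, 70000),
    # H3K27ac peaks
    n_background_enhancers = 500,
    n_planted_se_clusters = 20,
    peaks_per_cluster = 4,
    cluster_signal_multiplier = 50,
    bg_signal_base = 10,
    bg_signal_sdlog = 0.6,
    bg_boost_prob = 0.05,
    bg_boost_range = c(2, 6),
    enhancer_spacing = 18000,
    peak_width_range = c(400, 1200),
    gene_peaks_per_gene = 2,
    global_uv_signal_multiplier = 0.7,
    n_dha_up = 30, n_dha_down = 30, dha_effect = 4,
    n_se_lost_uv = 5, n_se_gained_uv = 2, se_loss_factor = 0.02,
    # expression
    expr_base_meanlog = log(100), expr_base_sdlog = 1,
    n_dge_up = 20, n_dge_down = 20, dge_effect = 8,
    dge_dha_coupling = 1.0, coupling_shift_log2 = 2,
    expr_noise_sdlog2 = 0.5,
    # variants
    n_variants_a = 463, n_variants_b = 417, n_variants_common = 75,
    category_props = c(intron = 0.40, intergenic = 0.28, exon = 0.13,
                       utr5 = 0.07, utr3 = 0.05, upstream1kb = 0.035,
                       downstream1kb = 0.035),
    common_category_counts = NULL,
    spectrum_weights = c("C>T/G>A" = 0.60, "C>A/G>T" = 0.08,
                         "C>G/G>C" = 0.08, "T>A/A>T" = 0.08,
                         "T>C/A>G" = 0.08, "T>G/A>C" = 0.08),
    depth_range = c(10, 100),
    # shRNA screen
    n_screen_genes = 500, shrnas_per_gene = 4, n_control_shrnas = 100,
    n_skin_lines = 4, n_nonskin_lines = 8,
    n_essential = 10, essential_shift = -3,
    shrna_noise_sd = 0.5, gene_baseline_sd = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (abs(sum(cfg$category_props) - 1) > 1e-8)
    stop("category_props must sum to 1")
  if (abs(sum(cfg$spectrum_weights) - 1) > 1e-8)
    stop("spectrum_weights must sum to 1")
  class(cfg) <- "simulation_config"
  cfg
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic genome annotation
#'
#' Tiles non-overlapping gene models (3 exons, terminal UTRs, random
#' strand) along the configured chromosomes, with inter-gene gaps above
#' the stitch distance so genes are interval-isolated.
#'
#' @param config a [simulation_config()].
#' @return a [genome_annotation()] object.
#' @export
generate_annotation <- function(config) {
  stopifnot(config$n_genes >= 1)
  set.seed(config$seed)
  cl <- config$chrom_lengths
  n_per <- pmax(1, round(config$n_genes * cl / sum(cl)))
  # adjust to hit the exact total
  while (sum(n_per) != config$n_genes) {
    i <- if (sum(n_per) > config$n_genes) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(config$n_genes - sum(n_per))
  }

  rows <- list(); feats <- list()
  gi <- 0
  for (ci in seq_along(cl)) {
    chrom <- names(cl)[ci]
    pos <- 1
    for (k in seq_len(n_per[ci])) {
      # occasional large gaps host distal enhancer slots close enough to
      # genes for the 25 kb association window to be exercised
      gap <- if (stats::runif(1) < config$large_gap_prob)
        runif_int(1, config$large_gap_range)
      else runif_int(1, config$gene_gap_range)
      len <- runif_int(1, config$gene_length_range)
      start <- pos + gap
      end <- start + len - 1
      if (end > cl[ci] - config$large_gap_range[2])
        stop("genes cannot fit chromosome ", chrom)
      gi <- gi + 1
      gene_id <- sprintf("gene_%04d", gi)
      strand <- sample(c("+", "-"), 1)
      # segments: exon1, intron1, exon2, intron2, exon3
      cuts <- start - 1 + round(len * c(0.15, 0.35, 0.50, 0.70))
      e1 <- c(start, cuts[1]); e2 <- c(cuts[2] + 1, cuts[3])
      e3 <- c(cuts[4] + 1, end)
      u_w1 <- max(50, round((e1[2] - e1[1] + 1) * 0.4))
      u_w3 <- max(50, round((e3[2] - e3[1] + 1) * 0.4))
      if (strand == "+") {
        utr5 <- c(e1[1], e1[1] + u_w1 - 1)
        utr3 <- c(e3[2] - u_w3 + 1, e3[2])
      } else {
        utr5 <- c(e3[2] - u_w3 + 1, e3[2])
        utr3 <- c(e1[1], e1[1] + u_w1 - 1)
      }
      rows[[gi]] <- data.frame(chrom = chrom, start = start, end = end,
                               strand = strand, gene_id = gene_id)
      feats[[gi]] <- data.frame(
        chrom = chrom,
        start = c(e1[1], e2[1], e3[1], utr5[1], utr3[1]),
        end = c(e1[2], e2[2], e3[2], utr5[2], utr3[2]),
        gene_id = gene_id,
        type = c("exon", "exon", "exon", "five_prime_UTR",
                 "three_prime_UTR"))
      pos <- end
    }
  }
  gdf <- do.call(rbind, rows)
  fdf <- do.call(rbind, feats)
  genes <- GenomicRanges::GRanges(gdf$chrom,
                                  IRanges::IRanges(gdf$start, gdf$end),
                                  strand = gdf$strand, gene_id = gdf$gene_id)
  features <- GenomicRanges::GRanges(fdf$chrom,
                                     IRanges::IRanges(fdf$start, fdf$end),
                                     gene_id = fdf$gene_id, type = fdf$type)
  genome_annotation(genes, features, cl)
}

# lognormal multiplicative noise; exactly 1 when sdlog = 0
signal_noise <- function(n, sdlog) {
  if (sdlog <= 0) rep(1, n) else stats::rlnorm(n, 0, sdlog)
}

#' Generate a paired control/UV H3K27ac peak landscape
#'
#' Control peaks comprise per-gene body peaks, isolated background
#' enhancers with heavy-tailed signal (lognormal with an occasional
#' boosted tail, producing the hockey-stick rank curve), and planted
#' super-enhancer clusters (runs of peaks within the stitch distance at
#' `cluster_signal_multiplier` times background). The UV sample reuses
#' the same intervals with signal scaled by the global multiplier;
#' planted differential-acetylation genes have their gene peaks scaled by
#' `dha_effect`, a configured number of planted clusters collapse
#' (`se_loss_factor`) and a configured number of background-level cluster
#' loci gain cluster-strength signal only after UV.
#'
#' @param config a [simulation_config()].
#' @param annotation the matching [generate_annotation()] output.
#' @return list with `peaks_control`, `peaks_uv` (`GRanges` with `name`,
#'   `signal`) and `truth` (planted gene sets, cluster loci and status,
#'   the global multiplier).
#' @export
generate_chipseq_pair <- function(config, annotation) {
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  cl <- config$chrom_lengths

  # per-gene promoter-proximal peaks (drive the gene-level acetylation
  # calls; they sit inside the TSS exclusion window, so the SE stage
  # never sees them and the DHA and SE plantings stay orthogonal)
  gp <- list()
  for (i in seq_along(genes)) {
    k <- config$gene_peaks_per_gene
    tss <- genes$tss[i]
    centers <- round(tss + seq(-800, 800, length.out = k))
    w <- runif_int(k, config$peak_width_range)
    gp[[i]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes))[i],
      start = pmax(1, centers - w %/% 2), end = centers + w %/% 2,
      gene = genes$gene_id[i])
  }
  gp <- do.call(rbind, gp)
  gene_peaks <- GenomicRanges::GRanges(gp$chrom,
                                       IRanges::IRanges(gp$start, gp$end))
  gene_peaks$gene <- gp$gene
  gene_peaks$signal <- config$bg_signal_base *
    signal_noise(length(gene_peaks), config$bg_signal_sdlog)

  # enhancer slots on a fixed grid, away from gene bodies
  sp <- config$enhancer_spacing
  slots <- suppressWarnings(do.call(c, lapply(names(cl), function(chrom) {
    centers <- seq(sp %/% 2, cl[[chrom]] - sp %/% 2, by = sp)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(centers, centers))
  })))
  # clearance > stitch distance + cluster half-span + promoter-peak reach,
  # so no planted or background enhancer can ever stitch with gene peaks
  near_gene <- IRanges::overlapsAny(slots, genes, maxgap = 17500,
                                    ignore.strand = TRUE)
  slots <- slots[!near_gene]
  n_clusters <- config$n_planted_se_clusters + config$n_se_gained_uv
  n_need <- config$n_background_enhancers + n_clusters
  if (length(slots) < n_need)
    stop("genome too small for the requested enhancer count")
  pick <- sample(seq_along(slots), length(slots))
  # cluster slots must sit two grid steps from one another so that no two
  # planted clusters (or a cluster and its neighbour) can stitch together
  cl_idx <- integer(0)
  for (i in pick) {
    if (length(cl_idx) == n_clusters) break
    cand <- slots[i]
    if (length(cl_idx) == 0 ||
        min(interval_distance(cand, slots[cl_idx])) > 2 * sp - 7000)
      cl_idx <- c(cl_idx, i)
  }
  if (length(cl_idx) < n_clusters)
    stop("genome too small to isolate the requested cluster count")
  bg_idx <- setdiff(pick, cl_idx)[seq_len(config$n_background_enhancers)]
  if (anyNA(bg_idx))
    stop("genome too small for the requested enhancer count")
  bg_slots <- slots[bg_idx]
  cl_slots <- slots[cl_idx]

  # background enhancers: one peak per slot, heavy-tailed signal
  wb <- runif_int(length(bg_slots), config$peak_width_range)
  bg_peaks <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(bg_slots),
    IRanges::IRanges(GenomicRanges::start(bg_slots) - wb %/% 2,
                     GenomicRanges::start(bg_slots) + wb %/% 2))
  sig <- config$bg_signal_base *
    signal_noise(length(bg_peaks), config$bg_signal_sdlog)
  if (config$bg_boost_prob > 0) {
    boost <- stats::runif(length(sig)) < config$bg_boost_prob
    sig[boost] <- sig[boost] *
      stats::runif(sum(boost), config$bg_boost_range[1],
                   config$bg_boost_range[2])
  }
  bg_peaks$gene <- NA_character_
  bg_peaks$signal <- sig

  # planted clusters: runs of peaks within the stitch distance
  cluster_status <- c(
    rep("control", config$n_planted_se_clusters),
    rep("gained", config$n_se_gained_uv))
  if (config$n_se_lost_uv > config$n_planted_se_clusters)
    stop("cannot lose more clusters than are planted")
  lost <- sample(which(cluster_status == "control"),
                 config$n_se_lost_uv)
  cluster_status[lost] <- "lost"
  cp <- list()
  for (j in seq_along(cl_slots)) {
    k <- config$peaks_per_cluster
    center <- GenomicRanges::start(cl_slots)[j]
    offs <- round(seq(-1, 1, length.out = k) * 2500)
    w <- runif_int(k, config$peak_width_range)
    base <- config$bg_signal_base *
      signal_noise(k, config$bg_signal_sdlog)
    ctrl_sig <- if (cluster_status[j] == "gained") base
                else base * config$cluster_signal_multiplier
    cp[[j]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(cl_slots))[j],
      start = center + offs - w %/% 2, end = center + offs + w %/% 2,
      cluster = j, signal = ctrl_sig)
  }
  cp <- do.call(rbind, cp)
  cl_peaks <- GenomicRanges::GRanges(cp$chrom,
                                     IRanges::IRanges(cp$start, cp$end))
  cl_peaks$gene <- NA_character_
  cl_peaks$signal <- cp$signal

  peaks <- c(gene_peaks[, c("gene", "signal")],
             bg_peaks[, c("gene", "signal")],
             cl_peaks[, c("gene", "signal")])
  cluster_of <- c(rep(NA_integer_, length(gene_peaks) + length(bg_peaks)),
                  cp$cluster)

  # planted differential-acetylation genes
  if (config$n_dha_up + config$n_dha_down > length(genes))
    stop("more planted acetylation genes than genes in the annotation")
  dha_pool <- sample(genes$gene_id, config$n_dha_up + config$n_dha_down)
  dha_up <- dha_pool[seq_len(config$n_dha_up)]
  dha_down <- setdiff(dha_pool, dha_up)

  uv_sig <- peaks$signal * config$global_uv_signal_multiplier
  uv_sig[peaks$gene %in% dha_up] <-
    uv_sig[peaks$gene %in% dha_up] * config$dha_effect
  uv_sig[peaks$gene %in% dha_down] <-
    uv_sig[peaks$gene %in% dha_down] / config$dha_effect
  is_lost <- !is.na(cluster_of) & cluster_status[cluster_of] == "lost"
  uv_sig[is_lost] <- uv_sig[is_lost] * config$se_loss_factor
  is_gained <- !is.na(cluster_of) & cluster_status[cluster_of] == "gained"
  uv_sig[is_gained] <- uv_sig[is_gained] * config$cluster_signal_multiplier

  ord <- order(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks))
  peaks <- peaks[ord]; uv_sig <- uv_sig[ord]
  peaks$name <- sprintf("peak_%05d", seq_along(peaks))
  peaks_uv <- peaks
  peaks_uv$signal <- uv_sig

  cluster_loci <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(cl_slots),
    IRanges::IRanges(pmax(1, GenomicRanges::start(cl_slots) - 3500),
                     GenomicRanges::start(cl_slots) + 3500))
  cluster_loci$status <- cluster_status

  list(peaks_control = peaks[, c("name", "signal", "gene")],
       peaks_uv = peaks_uv[, c("name", "signal", "gene")],
       truth = list(dha_up = sort(dha_up), dha_down = sort(dha_down),
                    cluster_loci = cluster_loci,
                    n_se_control = sum(cluster_status != "gained"),
                    n_se_uv = sum(cluster_status == "control") +
                      config$n_se_gained_uv,
                    global_multiplier = config$global_uv_signal_multiplier))
}

#' Generate a paired control/UV expression table
#'
#' Log-normal baseline expression with planted up/down differential
#' genes; a configurable fraction of the planted acetylation genes (when
#' `chip_truth` is supplied) receives a coupled expression shift of
#' `coupling_shift_log2` log2 units in the concordant direction, which is
#' what makes the acetylation-bin expression-shift test significant by
#' construction. Multiplicative log2-normal noise on the UV values.
#'
#' @param config a [simulation_config()].
#' @param annotation the matching annotation.
#' @param chip_truth optional `truth` element of
#'   [generate_chipseq_pair()], used to couple expression to acetylation.
#' @return list with `expression` (data.frame `gene_id`, `expr_control`,
#'   `expr_uv`) and `truth` (planted gene sets, coupled genes).
#' @export
generate_expression_pair <- function(config, annotation,
                                     chip_truth = NULL) {
  set.seed(config$seed + 2L)
  gene_ids <- annotation$genes$gene_id
  n <- length(gene_ids)
  ctrl <- stats::rlnorm(n, config$expr_base_meanlog, config$expr_base_sdlog)
  effect <- rep(1, n); names(effect) <- gene_ids

  excluded <- character(0)
  coupled_up <- coupled_down <- character(0)
  if (!is.null(chip_truth) && config$dge_dha_coupling > 0) {
    pick_frac <- function(x) {
      k <- round(length(x) * config$dge_dha_coupling)
      if (k > 0) sample(x, k) else character(0)
    }
    coupled_up <- pick_frac(chip_truth$dha_up)
    coupled_down <- pick_frac(chip_truth$dha_down)
    effect[coupled_up] <- effect[coupled_up] * 2^config$coupling_shift_log2
    effect[coupled_down] <- effect[coupled_down] / 2^config$coupling_shift_log2
    excluded <- c(chip_truth$dha_up, chip_truth$dha_down)
  }
  free <- setdiff(gene_ids, excluded)
  dge_pool <- sample(free, min(length(free),
                               config$n_dge_up + config$n_dge_down))
  dge_up <- dge_pool[seq_len(config$n_dge_up)]
  dge_down <- setdiff(dge_pool, dge_up)
  effect[dge_up] <- effect[dge_up] * config$dge_effect
  effect[dge_down] <- effect[dge_down] / config$dge_effect

  noise <- if (config$expr_noise_sdlog2 > 0)
    2^stats::rnorm(n, 0, config$expr_noise_sdlog2) else rep(1, n)
  uv <- ctrl * unname(effect[gene_ids]) * noise
  list(
    expression = data.frame(gene_id = gene_ids, expr_control = ctrl,
                            expr_uv = uv, stringsAsFactors = FALSE),
    truth = list(dge_up = sort(dge_up), dge_down = sort(dge_down),
                 coupled_up = sort(coupled_up),
                 coupled_down = sort(coupled_down))
  )
}

# sample k unique positions inside a GRanges space, width-weighted
sample_positions <- function(space, k, taken = character(0)) {
  w <- GenomicRanges::width(space)
  if (sum(w) < k) stop("infeasible category quota for this genome")
  out_chrom <- character(0); out_pos <- integer(0)
  guard <- 0
  while (length(out_pos) < k) {
    need <- k - length(out_pos)
    i <- sample.int(length(space), need, replace = TRUE, prob = w)
    pos <- GenomicRanges::start(space)[i] +
      floor(stats::runif(need) * w[i])
    chrom <- as.character(GenomicRanges::seqnames(space))[i]
    key <- paste(chrom, pos)
    keep <- !(key %in% taken) & !duplicated(key)
    taken <- c(taken, key[keep])
    out_chrom <- c(out_chrom, chrom[keep])
    out_pos <- c(out_pos, pos[keep])
    guard <- guard + 1
    if (guard > 1000) stop("infeasible category quota for this genome")
  }
  list(chrom = out_chrom, pos = out_pos, taken = taken)
}

#' Generate two variant sets with controlled overlap and composition
#'
#' Builds a shared subset of `n_variants_common` variants plus
#' set-specific remainders. Positions are drawn inside the exact genomic
#' feature space of the requested category (so classification recovers
#' the planted category), substitution classes follow the configured
#' spectrum weights (purine/pyrimidine representation chosen at random),
#' and depths are uniform over `depth_range`. The shared-set category
#' composition can be fixed exactly via `common_category_counts`.
#'
#' @param config a [simulation_config()].
#' @param annotation the matching annotation.
#' @return list with `variants_a`, `variants_b` (data.frames) and `truth`
#'   (planted categories keyed by chrom:pos, spectrum classes, overlap).
#' @export
generate_variant_sets <- function(config, annotation) {
  set.seed(config$seed + 3L)
  if (config$n_variants_common > min(config$n_variants_a,
                                     config$n_variants_b))
    stop("overlap cannot exceed either set size")
  space <- annotation_feature_space(annotation)
  cats <- names(config$category_props)

  draw <- function(categories, taken) {
    chrom <- character(0); pos <- integer(0)
    out_cat <- character(0)
    for (cat in unique(categories)) {
      k <- sum(categories == cat)
      s <- sample_positions(space[[cat]], k, taken)
      taken <- s$taken
      chrom <- c(chrom, s$chrom); pos <- c(pos, s$pos)
      out_cat <- c(out_cat, rep(cat, k))
    }
    n <- length(pos)
    cls <- sample(names(config$spectrum_weights), n, replace = TRUE,
                  prob = config$spectrum_weights)
    pyr_ref <- substr(cls, 1, 1); pyr_alt <- substr(cls, 3, 3)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- stats::runif(n) < 0.5
    ref <- ifelse(flip, comp[pyr_ref], pyr_ref)
    alt <- ifelse(flip, comp[pyr_alt], pyr_alt)
    list(df = data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                         alt = unname(alt),
                         depth = runif_int(n, config$depth_range),
                         stringsAsFactors = FALSE),
         category = out_cat, class = cls, taken = taken)
  }

  common_cats <- if (!is.null(config$common_category_counts)) {
    cc <- config$common_category_counts
    if (sum(cc) != config$n_variants_common)
      stop("common_category_counts must sum to the overlap size")
    rep(names(cc), cc)
  } else {
    sample(cats, config$n_variants_common, replace = TRUE,
           prob = config$category_props)
  }
  common <- draw(common_cats, character(0))
  ua <- draw(sample(cats, config$n_variants_a - config$n_variants_common,
                    replace = TRUE, prob = config$category_props),
             common$taken)
  ub <- draw(sample(cats, config$n_variants_b - config$n_variants_common,
                    replace = TRUE, prob = config$category_props),
             ua$taken)

  finish <- function(df) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  key <- function(d) paste(d$df$chrom, d$df$pos, sep = ":")
  truth_cat <- c(common$category, ua$category, ub$category)
  names(truth_cat) <- c(key(common), key(ua), key(ub))
  truth_cls <- c(common$class, ua$class, ub$class)
  names(truth_cls) <- names(truth_cat)

  list(variants_a = finish(rbind(common$df, ua$df)),
       variants_b = finish(rbind(common$df, ub$df)),
       truth = list(category = truth_cat, spectrum_class = truth_cls,
                    n_common = config$n_variants_common))
}

#' Generate an shRNA depletion screen with planted essential genes
#'
#' Depletion scores are built as per-gene baselines (`N(0,
#' gene_baseline_sd)`) plus per-shRNA, per-line noise
#' (`N(0, shrna_noise_sd)`); negative-control shRNAs are noise around 0.
#' Planted skin-essential genes receive `essential_shift` in skin lines
#' only.
#'
#' @param config a [simulation_config()].
#' @return list with `screen` (a [screen_matrix()]) and `truth` (the
#'   planted essential gene ids).
#' @export
generate_screen <- function(config) {
  set.seed(config$seed + 4L)
  genes <- sprintf("sgene_%04d", seq_len(config$n_screen_genes))
  shrnas <- paste0(rep(genes, each = config$shrnas_per_gene), "_sh",
                   seq_len(config$shrnas_per_gene))
  ctrl_names <- sprintf("ctrl_sh%02d", seq_len(config$n_control_shrnas))
  lines <- c(sprintf("SKIN_%d", seq_len(config$n_skin_lines)),
             sprintf("NSKIN_%d", seq_len(config$n_nonskin_lines)))
  lineage <- c(rep("skin", config$n_skin_lines),
               rep("non-skin", config$n_nonskin_lines))

  essential <- sample(genes, config$n_essential)
  baseline <- stats::rnorm(config$n_screen_genes, 0,
                           config$gene_baseline_sd)
  names(baseline) <- genes
  map <- rep(genes, each = config$shrnas_per_gene)

  nr <- length(shrnas); nc <- length(lines)
  ds <- matrix(baseline[map], nr, nc) +
    matrix(stats::rnorm(nr * nc, 0, config$shrna_noise_sd), nr, nc)
  shift <- outer(map %in% essential, lineage == "skin") *
    config$essential_shift
  ds <- ds + shift
  ctrl <- matrix(stats::rnorm(length(ctrl_names) * nc, 0,
                              config$shrna_noise_sd),
                 length(ctrl_names), nc)
  full <- rbind(ds, ctrl)
  rownames(full) <- c(shrnas, ctrl_names)
  colnames(full) <- lines

  scr <- screen_matrix(full,
                       shrna_to_gene = c(map,
                                         rep(NA_character_,
                                             length(ctrl_names))),
                       is_negative_control = c(rep(FALSE, nr),
                                               rep(TRUE,
                                                   length(ctrl_names))),
                       lineage = lineage)
  list(screen = scr, truth = list(essential = sort(essential)))
}

#' Generate a complete synthetic study on disk
#'
#' Runs all generators for one configuration and writes every input the
#' pipeline consumes, plus the planted ground truth and the echoed
#' configuration, to a directory. Deterministic given the configuration.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list of the generated objects and file paths.
#' @export
simulate_uv_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ann <- generate_annotation(config)
  chip <- generate_chipseq_pair(config, ann)
  expr <- generate_expression_pair(config, ann, chip$truth)
  var <- generate_variant_sets(config, ann)
  scr <- generate_screen(config)

  write_gene_annotation(ann, p("genes.gff3"))
  write_peaks(chip$peaks_control, p("peaks_control.bed"))
  write_peaks(chip$peaks_uv, p("peaks_uv.bed"))
  utils::write.table(expr$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_variants(var$variants_a, p("variants_4h.vcf"),
                 config$chrom_lengths)
  write_variants(var$variants_b, p("variants_72h.vcf"),
                 config$chrom_lengths)
  utils::write.table(data.frame(shrna = rownames(scr$screen$ds),
                                scr$screen$ds, check.names = FALSE),
                     p("screen_ds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(shrna = rownames(scr$screen$ds),
               gene = ifelse(is.na(scr$screen$shrna_to_gene), "",
                             scr$screen$shrna_to_gene),
               is_negative_control = scr$screen$is_negative_control),
    p("screen_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(line = colnames(scr$screen$ds),
                                lineage = scr$screen$lineage),
                     p("screen_lineage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- list(
    chipseq = list(
      dha_up = chip$truth$dha_up, dha_down = chip$truth$dha_down,
      cluster_loci = as.data.frame(chip$truth$cluster_loci),
      n_se_control = chip$truth$n_se_control,
      n_se_uv = chip$truth$n_se_uv),
    expression = expr$truth,
    variants = list(category = as.list(var$truth$category),
                    spectrum_class = as.list(var$truth$spectrum_class),
                    n_common = var$truth$n_common),
    screen = scr$truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(annotation = ann, chipseq = chip, expression = expr,
                 variants = var, screen = scr, dir = dir,
                 paths = list(
                   annotation = p("genes.gff3"),
                   peaks_control = p("peaks_control.bed"),
                   peaks_uv = p("peaks_uv.bed"),
                   expression = p("expression.tsv"),
                   variants_a = p("variants_4h.vcf"),
                   variants_b = p("variants_72h.vcf"),
                   screen_ds = p("screen_ds.tsv"),
                   screen_map = p("screen_map.tsv"),
                   screen_lineage = p("screen_lineage.tsv"))))
}
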