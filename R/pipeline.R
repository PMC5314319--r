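#' Pipeline stage parameters
#'
#' All defaults are the analysis' standard values: 10 kb peak-to-gene
#' window, fold-change cutoff 2, 12.5 kb stitch distance, 2.5 kb promoter
#' exclusion, 25 kb SE-gene association window, log2FC bin edges at
#' +/- 1, read depth >= 10, consistency p < 0.1 and lineage-specificity
#' p < 0.05.
#'
#' @param ... overrides for any default.
#' @return named list of parameters.
#' @export
uv_params <- function(...) {
  p <- list(window = 10000, fc_cutoff = 2, pseudocount = 1,
            stitch_distance = 12500, tss_window = 2500,
            se_gene_window = 25000, bin_edge = 1, min_depth = 10,
            n_perm = 1000, consistency_alpha = 0.1,
            specificity_alpha = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

read_screen_files <- function(ds_path, map_path, lineage_path) {
  dsdf <- utils::read.delim(ds_path, check.names = FALSE)
  ds <- as.matrix(dsdf[, -1, drop = FALSE])
  rownames(ds) <- dsdf[[1]]
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  lin <- utils::read.delim(lineage_path, stringsAsFactors = FALSE)
  map <- map[match(rownames(ds), map$shrna), ]
  lin <- lin[match(colnames(ds), lin$line), ]
  gene <- map$gene
  gene[!nzchar(gene) | is.na(gene)] <- NA_character_
  screen_matrix(ds, gene, as.logical(map$is_negative_control),
                lin$lineage)
}

#' Run the integrative UV analysis end-to-end
#'
#' Executes, on whichever inputs are present: gene-level differential
#' acetylation and the global signal trend; super-enhancer calling in
#' both samples with set comparison and gene association; differential
#' expression and its integration with acetylation (bin shift test,
#' concordance matrix); variant depth filtering, timepoint intersection,
#' feature classification and substitution spectrum; enrichment of
#' intron-variant genes in the expression ranking (KS permutation test);
#' and the shRNA essentiality pipeline. Stages whose inputs are absent
#' are skipped with a message. Deterministic given `seed`.
#'
#' @param inputs named list of file paths; recognised names:
#'   `annotation` (GFF3, required), `peaks_control`, `peaks_uv` (BED),
#'   `expression` (TSV), `variants_a`, `variants_b` (VCF/TSV),
#'   `screen_ds`, `screen_map`, `screen_lineage` (TSV), `pathways` (GMT).
#' @param params a [uv_params()] list.
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional directory: stage tables are written as TSV and
#'   the report as JSON.
#' @return object of class `uv_report` with per-stage results and
#'   summary counts.
#' @export
run_uv_pipeline <- function(inputs, params = uv_params(), seed = 1,
                            out_dir = NULL) {
  have <- function(...) {
    keys <- c(...)
    all(keys %in% names(inputs)) &&
      all(vapply(inputs[keys], file.exists, TRUE))
  }
  if (!have("annotation")) stop("stage annotation: input file required")
  report <- list(seed = seed, params = params, stages = character(0))
  res <- list()

  run_stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  ann <- run_stage("annotation", read_gene_annotation(inputs$annotation))
  res$annotation <- ann
  report$n_genes <- length(ann$genes)

  if (have("peaks_control", "peaks_uv")) {
    res$chromatin <- run_stage("chromatin", {
      pc <- read_peaks(inputs$peaks_control)
      pu <- read_peaks(inputs$peaks_uv)
      dha <- compute_dha(pc, pu, ann, window = params$window,
                         fc_cutoff = params$fc_cutoff,
                         pseudocount = params$pseudocount)
      merged <- merged_region_signal(pc, pu)
      list(peaks_control = pc, peaks_uv = pu, dha = dha,
           slope = global_signal_slope(merged$tags_a, merged$tags_b))
    })
    report$stages <- c(report$stages, "chromatin")
    report$dha_counts <- table(res$chromatin$dha$dha_class)
    report$h3k27ac_slope <- res$chromatin$slope

    res$superenhancers <- run_stage("superenhancers", {
      se_c <- call_superenhancers(res$chromatin$peaks_control, ann,
                                  params$stitch_distance,
                                  params$tss_window, sample = "control")
      se_u <- call_superenhancers(res$chromatin$peaks_uv, ann,
                                  params$stitch_distance,
                                  params$tss_window, sample = "uv")
      list(control = se_c, uv = se_u,
           comparison = compare_se_sets(se_c, se_u),
           genes_control = annotate_se_genes(se_c, ann,
                                             params$se_gene_window),
           genes_uv = annotate_se_genes(se_u, ann,
                                        params$se_gene_window))
    })
    report$stages <- c(report$stages, "superenhancers")
    report$se_counts <- c(
      control = length(res$superenhancers$control$superenhancers),
      uv = length(res$superenhancers$uv$superenhancers))
    report$se_venn <- res$superenhancers$comparison[
      c("common_a", "common_b", "unique_a", "unique_b")]
  } else message("[chromatin] skipped: peak inputs absent")

  if (have("expression")) {
    res$expression <- run_stage("expression", {
      tab <- utils::read.delim(inputs$expression,
                               stringsAsFactors = FALSE)
      dge <- compute_dge(tab, pseudocount = params$pseudocount,
                         fc_cutoff = params$fc_cutoff)
      out <- list(dge = dge)
      if (!is.null(res$chromatin)) {
        rec <- integrate_omics(dge, res$chromatin$dha,
                               edge = params$bin_edge)
        out$records <- rec
        out$group_shift <- group_shift_test(rec)
        out$concordance <- concordance_matrix(rec)
      }
      out
    })
    report$stages <- c(report$stages, "expression")
    report$dge_counts <- table(res$expression$dge$dge_class)
    if (!is.null(res$expression$group_shift))
      report$group_shift <- res$expression$group_shift
  } else message("[expression] skipped: expression input absent")

  if (have("variants_a", "variants_b")) {
    res$variants <- run_stage("variants", {
      va <- filter_by_depth(read_variants(inputs$variants_a),
                            params$min_depth)
      vb <- filter_by_depth(read_variants(inputs$variants_b),
                            params$min_depth)
      common <- intersect_variant_sets(va, vb)
      cls <- classify_variants(common, ann)
      list(variants_a = va, variants_b = vb, common = common,
           classified = cls,
           category_counts = table(cls$category),
           spectrum = mutation_spectrum(common))
    })
    report$stages <- c(report$stages, "variants")
    report$n_variants <- c(a = nrow(res$variants$variants_a),
                           b = nrow(res$variants$variants_b),
                           common = nrow(res$variants$common))
    report$variant_categories <- res$variants$category_counts
    report$mutation_spectrum <- res$variants$spectrum

    if (!is.null(res$expression)) {
      res$enrichment <- run_stage("enrichment", {
        dge <- res$expression$dge
        ranked <- dge$gene_id[order(dge$log2fc, decreasing = TRUE)]
        cls <- res$variants$classified
        intron_genes <- unique(stats::na.omit(
          cls$gene_id[cls$category == "intron"]))
        intron_genes <- intersect(intron_genes, ranked)
        if (length(intron_genes) > 0 &&
            length(intron_genes) < length(ranked)) {
          permutation_pvalue(ranked, intron_genes,
                             n_perm = params$n_perm, seed = seed)
        } else NULL
      })
      if (!is.null(res$enrichment)) {
        report$stages <- c(report$stages, "enrichment")
        report$intron_gene_enrichment <- res$enrichment
      }
    }
  } else message("[variants] skipped: variant inputs absent")

  if (have("screen_ds", "screen_map", "screen_lineage")) {
    res$essentiality <- run_stage("essentiality", {
      scr <- read_screen_files(inputs$screen_ds, inputs$screen_map,
                               inputs$screen_lineage)
      run_essentiality_pipeline(
        scr, consistency_alpha = params$consistency_alpha,
        specificity_alpha = params$specificity_alpha, seed = seed)
    })
    report$stages <- c(report$stages, "essentiality")
    ess <- res$essentiality
    report$essentiality_counts <- c(
      tested = nrow(ess), consistent = sum(ess$consistency_pass),
      skin_specific = sum(ess$skin_specific, na.rm = TRUE))
  } else message("[essentiality] skipped: screen inputs absent")

  report$results <- res
  class(report) <- "uv_report"
  if (!is.null(out_dir)) write_uv_report(report, out_dir)
  report
}

#' @export
print.uv_report <- function(x, ...) {
  cat("uv_report (seed ", x$seed, "): stages ",
      paste(x$stages, collapse = ", "), "\n", sep = "")
  if (!is.null(x$dha_counts)) {
    cat("  DHA classes:", paste(names(x$dha_counts), as.integer(x$dha_counts),
                                sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$se_counts))
    cat("  SEs: control=", x$se_counts[["control"]], " uv=",
        x$se_counts[["uv"]], "\n", sep = "")
  if (!is.null(x$dge_counts))
    cat("  DGE classes:", paste(names(x$dge_counts), as.integer(x$dge_counts),
                                sep = "=", collapse = " "), "\n")
  if (!is.null(x$n_variants))
    cat("  SNVs: ", x$n_variants[["a"]], " / ", x$n_variants[["b"]],
        " (", x$n_variants[["common"]], " common)\n", sep = "")
  if (!is.null(x$essentiality_counts))
    cat("  Essentiality:",
        paste(names(x$essentiality_counts),
              as.integer(x$essentiality_counts), sep = "=",
              collapse = " "), "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Stage tables as TSV plus a machine-readable JSON summary. Every number
#' in the summary is re-derivable from the stage tables.
#'
#' @param report a `uv_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_uv_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  res <- report$results
  if (!is.null(res$chromatin)) w(res$chromatin$dha, "dha.tsv")
  if (!is.null(res$superenhancers)) {
    for (s in c("control", "uv")) {
      ses <- res$superenhancers[[s]]$superenhancers
      if (length(ses)) {
        w(data.frame(chrom = GenomicRanges::seqnames(ses),
                     start = GenomicRanges::start(ses) - 1,
                     end = GenomicRanges::end(ses),
                     name = names(ses), total_signal = ses$total_signal),
          paste0("superenhancers_", s, ".bed"))
      }
      w(res$superenhancers[[paste0("genes_", s)]],
        paste0("se_genes_", s, ".tsv"))
    }
  }
  if (!is.null(res$expression)) {
    w(res$expression$dge, "dge.tsv")
    if (!is.null(res$expression$records))
      w(res$expression$records, "integration.tsv")
  }
  if (!is.null(res$variants)) w(res$variants$classified,
                                "variants_common_classified.tsv")
  if (!is.null(res$essentiality)) w(res$essentiality, "essentiality.tsv")

  summ <- report[setdiff(names(report), c("results", "params"))]
  summ$params <- report$params
  for (nm in names(summ))
    if (is.table(summ[[nm]])) summ[[nm]] <- as.list(summ[[nm]])
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
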