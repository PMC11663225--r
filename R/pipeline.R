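## End-to-end orchestration over the synthetic fixture (or user-supplied
## inputs prepared in the same shapes). Stage functions are the exported
## module operations; run_pipeline() chains them, checks the built-in
## invariants, and emits a machine-readable run report with full parameter
## provenance. Deterministic under a fixed root seed.

#' Pipeline configuration
#'
#' Collects every tunable number used by any stage; all of them are echoed
#' into the run report. Defaults mirror the printed analysis constants:
#' padj gate 0.05, signature log2FC gate 1, marker-screen gate 0.3,
#' IC50 sensitivity threshold 2000 pM, 5/7 dendrogram cuts for the
#' sensitive/resistant line, GSEA weight 1. The regulatory-domain extension
#' default here (50 kb) is the 1 Mb default scaled to the synthetic genome
#' (~1000x smaller than a mammalian one).
#'
#' @param seed root seed.
#' @param n_genes fixture size.
#' @param padj_thresh,lfc_thresh DEG gates for signatures.
#' @param marker_lfc_thresh,marker_p_thresh baseline marker-screen gates.
#' @param ic50_threshold molar sensitivity cutoff.
#' @param k_groups named integer vector: dendrogram cut per cell line
#'   (first = sensitive line, 5; second = resistant line, 7).
#' @param basal_up,basal_down,max_extension regulatory-domain parameters (bp).
#' @param gsea_n_perm,gsea_p GSEA permutations and weight exponent.
#' @param n_bins,n_ctrl module-score binning parameters.
#' @param score_fraction motif-scan hit threshold.
#' @param unknown extra arguments are rejected (schema validation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_genes = 2000, padj_thresh = 0.05,
                            lfc_thresh = 1, marker_lfc_thresh = 0.3,
                            marker_p_thresh = 0.05, ic50_threshold = 2000e-12,
                            k_groups = c(M_SENS = 5, M_RES = 7),
                            basal_up = 5000, basal_down = 1000,
                            max_extension = 50000, gsea_n_perm = 999,
                            gsea_p = 1, n_bins = 24, n_ctrl = 100,
                            score_fraction = 0.8) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on the synthetic fixture
#'
#' Chains every stage: fixture generation, per-cell-line NB differential
#' expression for the three treatment contrasts, z-score clustering with the
#' per-line dendrogram cut and selection of double-treatment-high groups,
#' treatment-specific signatures, GSEA of the invasive program against the
#' TGFB1 and double-treatment rankings, consensus peaks and condition-unique
#' peak-gene sets, universe construction and Venn assembly of the apoptosis
#' signature, module scoring of the double-treatment signature on simulated
#' single cells, motif enrichment in double-treatment-unique peak sequences,
#' and 4PL dose-response classification. Ground-truth recovery metrics are
#' included in the report.
#'
#' @param config [pipeline_config()].
#' @param report_path optional path; the report is written there as JSON.
#' @return run report (nested list).
#' @export
run_pipeline <- function(config = pipeline_config(), report_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  truth <- truth_spec(n_genes = config$n_genes, seed = config$seed)
  design <- make_design(truth$cell_lines)
  ann <- make_annotation(truth$n_genes, n_chroms = 3, seed = truth$seed)
  sim <- simulate_counts(truth, design)
  lines <- truth$cell_lines
  contrasts <- setdiff(TREATMENTS, "DMSO")

  ## -- differential expression ------------------------------------------
  de <- lapply(setNames(lines, lines), function(cl) {
    lapply(setNames(contrasts, contrasts), function(trt) {
      de_test(sim$counts, sim$samples, cl, trt)
    })
  })

  ## -- clustering + double-high group selection per line ----------------
  double_high <- lapply(setNames(lines, lines), function(cl) {
    degs <- sort(unique(unlist(lapply(de[[cl]], function(d) {
      d$gene[!is.na(d$padj) & d$padj < config$padj_thresh]
    }))))
    if (length(degs) < max(config$k_groups)) {
      return(character(0))
    }
    sel <- sim$samples$cell_line == cl
    sf <- estimate_size_factors(sim$counts[, sel, drop = FALSE])
    norm <- sweep(sim$counts[degs, sel, drop = FALSE], 2, sf, "/")
    cond_mean <- vapply(TREATMENTS, function(trt) {
      rowMeans(norm[, sim$samples$treatment[sel] == trt, drop = FALSE])
    }, numeric(length(degs)))
    z <- zscore_rows(log2(cond_mean + 1))
    k <- config$k_groups[[cl]] %||% 5
    groups <- cluster_and_cut(z, k = k)
    select_double_high_groups(groups)
  })

  ## -- treatment-specific signatures (per line) -------------------------
  signatures <- lapply(setNames(lines, lines), function(cl) {
    derive_treatment_signatures(de[[cl]], padj_thresh = config$padj_thresh,
                                lfc_thresh = config$lfc_thresh)
  })

  ## -- GSEA of the invasive program -------------------------------------
  sets <- make_gene_sets(truth)
  gsea <- lapply(setNames(c("TGFB1", "TGFB1_MEKI"), c("TGFB1", "TGFB1_MEKI")),
                 function(trt) {
    r <- rank_by_lfc(de[[lines[1]]][[trt]], padj_thresh = config$padj_thresh)
    cand <- sets[c("invasive_program", "mitf_program")]
    cand <- cand[vapply(cand, function(s) any(r$ranked %in% s), logical(1))]
    if (!length(cand)) return(NULL)
    gsea_permutation(r$ranked, r$metric, cand,
                     n_perm = config$gsea_n_perm, seed = config$seed,
                     p = config$gsea_p)
  })

  ## -- CUT&RUN: consensus, unique peak genes ----------------------------
  peaks <- simulate_peaks(truth, ann)
  consensus <- lapply(peaks, function(p) reproducible_peaks(p$rep1, p$rep2))
  domains <- regulatory_domains(ann, basal_up = config$basal_up,
                                basal_down = config$basal_down,
                                max_extension = config$max_extension)
  peak_genes <- lapply(consensus, function(p) peaks_to_genes(p, domains)$genes)
  gene_venn <- venn_partition(peak_genes)
  double_unique_genes <- gene_venn$patterns[["TGFB1_MEKI"]]
  peak_annot <- table(annotate_peak(consensus$TGFB1_MEKI, ann))

  ## -- integration: apoptosis signature ---------------------------------
  apopt <- build_apoptosis_universe(sets$apoptosis, sets$apoptosis_neg_reg)
  parts <- venn_partition(list(DEG_lineA = double_high[[lines[1]]],
                               DEG_lineB = double_high[[lines[2]]],
                               PeakGenes = double_unique_genes,
                               Apoptosis = apopt$members))
  signature <- assemble_apoptosis_signature(parts, deg_a = "DEG_lineA",
                                            deg_b = "DEG_lineB",
                                            peak_genes = "PeakGenes",
                                            apoptosis = "Apoptosis")
  switch_genes <- norm_symbols(truth$gene_blocks$switch_up)
  sens <- mean(switch_genes %in% signature$members)
  contam <- if (length(signature$members)) {
    mean(signature$members %in% norm_symbols(truth$gene_blocks$null))
  } else 0

  ## -- module scores on simulated single cells --------------------------
  sc <- simulate_single_cell(truth)
  double_sig <- signatures[[lines[1]]][["TGFB1_MEKI"]]
  state_scores <- if (length(intersect(double_sig$members,
                                       colnames(sc$expr)))) {
    ms <- module_score(sc$expr, double_sig, n_bins = config$n_bins,
                       n_ctrl = config$n_ctrl, seed = config$seed)
    score_by_state(ms, sc$labels)
  } else NULL

  ## -- motifs ------------------------------------------------------------
  pwms <- list(SMAD_like = pwm("SMAD_like", matrix(c(
    2, 1, 1, 86, 2, 90, 4, 8,
    4, 2, 88, 4, 3, 2, 88, 2,
    88, 3, 5, 4, 88, 3, 3, 2,
    6, 94, 6, 6, 7, 5, 5, 88), nrow = 4, byrow = TRUE)))
  seqs <- simulate_peak_sequences(consensus$TGFB1_MEKI, pwms, truth)
  motifs <- motif_enrichment(seqs$foreground, seqs$background, pwms,
                             score_fraction = config$score_fraction)

  ## -- dose-response ------------------------------------------------------
  dr <- simulate_dose_response(truth)
  fits <- lapply(setNames(unique(dr$cell_line), unique(dr$cell_line)),
                 function(cl) {
    d <- dr[dr$cell_line == cl, ]
    fit_4pl(d$dose_molar, d$response, cell_line = cl, seed = config$seed)
  })
  labels <- classify_threshold(fits, threshold = config$ic50_threshold)

  report <- list(
    version = "1.0",
    seed = config$seed,
    parameters = unclass(config),
    de = lapply(de, function(per_line) {
      lapply(per_line, function(d) {
        list(n_sig = sum(d$padj < config$padj_thresh, na.rm = TRUE),
             n_tested = sum(!is.na(d$pvalue)))
      })
    }),
    double_high_group_sizes = lengths(double_high),
    signature_sizes = lapply(signatures, function(s) {
      lengths(lapply(s, `[[`, "members"))
    }),
    gsea = lapply(gsea, function(g) g[, c("set", "es", "nes", "pvalue",
                                          "padj")]),
    peaks = list(consensus_counts = lengths(consensus),
                 double_unique_genes = length(double_unique_genes),
                 annotation_categories = as.list(peak_annot)),
    apoptosis_signature = list(members = signature$members,
                               provenance = as.list(signature$provenance),
                               size = length(signature$members)),
    truth_recovery = list(switch_sensitivity = sens,
                          null_contamination = contam),
    module_scores = if (!is.null(state_scores)) {
      list(summary = state_scores$summary, argmax = state_scores$argmax)
    },
    motifs = motifs,
    dose_response = list(
      ic50 = vapply(fits, function(f) ifelse(is.na(f$ic50), NA_real_,
                                             f$ic50), numeric(1)),
      flat = vapply(fits, `[[`, logical(1), "flat_flag"),
      labels = as.list(labels)),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(report)
}
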