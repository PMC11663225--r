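## Treatment-specific gene signatures (uniquely significant, strongly
## up-regulated genes per treatment) and expression-bin-matched module scoring
## of signatures on cell-level expression.

#' Construct a gene signature
#'
#' @param name signature name.
#' @param members character vector of gene symbols (normalised, de-duplicated).
#' @param provenance optional named character vector, member -> source tag.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, members, provenance = NULL) {
  members <- unique(norm_symbols(members))
  if (!is.null(provenance)) provenance <- provenance[members]
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$members), " genes\n", sep = "")
  cat(" ", paste(head(x$members, 10), collapse = ", "),
      if (length(x$members) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Derive treatment-specific signatures from DE tables
#'
#' Per treatment, selects genes with `padj < padj_thresh` and
#' `log2fc > lfc_thresh` (one-sided: up-regulated only), builds the binary
#' gene x treatment membership matrix, and keeps for each treatment the genes
#' unique to it. Signatures are pairwise disjoint by construction.
#'
#' @param de_tables named list (treatment -> DE table from [de_test()]).
#' @param padj_thresh adjusted-p gate (default 0.05).
#' @param lfc_thresh log2 fold-change gate (default 1, strict `>`).
#' @return named list of [gene_signature()] objects.
#' @export
derive_treatment_signatures <- function(de_tables, padj_thresh = 0.05,
                                        lfc_thresh = 1) {
  if (length(de_tables) < 2L) stop_invalid("need >= 2 treatments")
  if (any(!vapply(de_tables, nrow, integer(1)))) {
    stop_invalid("empty DE table supplied")
  }
  passing <- lapply(de_tables, function(de) {
    norm_symbols(de$gene[!is.na(de$padj) & de$padj < padj_thresh &
                           !is.na(de$log2fc) & de$log2fc > lfc_thresh])
  })
  all_genes <- sort(unique(unlist(passing)))
  memb <- vapply(passing, function(g) all_genes %in% g,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) {
    memb <- matrix(memb, nrow = 1L, dimnames = list(all_genes, names(passing)))
  }
  n_hits <- rowSums(memb)
  sigs <- lapply(names(de_tables), function(trt) {
    members <- all_genes[n_hits == 1L & memb[, trt]]
    gene_signature(paste0(trt, "_specific"), members,
                   provenance = setNames(rep(paste0("unique_", trt),
                                             length(members)), members))
  })
  names(sigs) <- names(de_tables)
  stopifnot(!anyDuplicated(unlist(lapply(sigs, `[[`, "members"))))
  sigs
}

#' Expression-bin-matched module score
#'
#' Per-cell signature activity: genes are ranked by average expression across
#' cells (ties broken by symbol) and split into `n_bins` near-equal bins; each
#' signature gene draws `n_ctrl` control genes from its own bin (without
#' replacement when the bin is large enough, with replacement otherwise);
#' score(cell) = mean expression of the signature genes minus mean expression
#' of the pooled control draw. Invariant under a global additive shift of the
#' matrix.
#'
#' @param expr numeric matrix, cells x genes, with gene colnames (typically
#'   log-normalised expression).
#' @param signature `gene_signature` or character vector of symbols.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return data.frame `cell, score`.
#' @export
module_score <- function(expr, signature, n_bins = 24, n_ctrl = 100, seed = 1) {
  if (inherits(signature, "gene_signature")) signature <- signature$members
  signature <- norm_symbols(signature)
  genes <- norm_symbols(colnames(expr))
  colnames(expr) <- genes
  if (length(genes) < n_bins) stop_invalid("fewer genes than bins")
  sig <- intersect(signature, genes)
  if (!length(sig)) stop_invalid("no overlap between signature and expressed genes")
  avg <- colMeans(expr)
  o <- order(avg, genes)
  rank <- match(genes, genes[o])
  bin <- ceiling(rank * n_bins / length(genes))
  set.seed(split_seed(seed, 31L))
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- genes[bin == bin[match(g, genes)]]
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
    else sample(pool, n_ctrl, replace = TRUE)
  }))
  score <- rowMeans(expr[, sig, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  data.frame(cell = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             score = unname(score), stringsAsFactors = FALSE)
}

#' Summarise module scores by cell state
#'
#' @param scores data.frame from [module_score()].
#' @param labels character vector of state labels, one per cell (or per row of
#'   `scores`).
#' @return list `summary` (data.frame `state, mean, median, sd, n`), `argmax`
#'   (state with the highest mean; ties broken lexicographically) and `tie`
#'   (logical flag).
#' @export
score_by_state <- function(scores, labels) {
  if (length(labels) != nrow(scores) || anyNA(labels)) {
    stop_invalid("every cell needs a state label")
  }
  st <- sort(unique(as.character(labels)))
  summ <- do.call(rbind, lapply(st, function(s) {
    x <- scores$score[labels == s]
    data.frame(state = s, mean = mean(x), median = median(x),
               sd = sd(x), n = length(x), stringsAsFactors = FALSE)
  }))
  top <- max(summ$mean)
  cand <- summ$state[abs(summ$mean - top) < 1e-12]
  list(summary = summ, argmax = sort(cand)[1], tie = length(cand) > 1L)
}
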