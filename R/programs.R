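## Program-level analysis: row-z-scored hierarchical clustering with fixed-k
## dendrogram cuts, selection of double-treatment-high gene groups, and
## weighted Kolmogorov-Smirnov gene set enrichment on a pre-ranked list.

#' Row z-score a matrix
#'
#' `(x - row mean) / row SD` with the sample SD (ddof = 1). Constant rows are
#' mapped to all zeros and flagged in the `constant` attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape; attribute `constant` is a logical vector.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop_invalid("zscore_rows needs >= 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0 | !is.finite(s)
  z <- (m - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

#' Hierarchical clustering with a fixed-k dendrogram cut
#'
#' Agglomerative clustering of the rows (Euclidean distance; complete linkage
#' by default, the heatmap-package convention) cut into exactly `k` groups.
#' Groups are re-indexed by order of first appearance along the dendrogram
#' leaf order, the order a reader of the heatmap would number them in.
#'
#' @param z row-z-scored matrix (genes x conditions) with gene rownames.
#' @param k number of groups, `2 <= k <= nrow(z)`.
#' @param linkage one of "complete", "average", "ward" (ward.D2).
#' @return list of groups, each `list(index, genes, cond_mean)` where
#'   `cond_mean` is the per-condition mean z of the group.
#' @export
cluster_and_cut <- function(z, k, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  method <- c(complete = "complete", average = "average", ward = "ward.D2")[linkage]
  if (k > nrow(z)) stop_invalid("k exceeds the number of genes")
  hc <- hclust(dist(z), method = method)
  raw <- cutree(hc, k = k)
  ## relabel by dendrogram leaf order
  first <- raw[hc$order]
  lvl <- unique(first)
  lab <- match(raw, lvl)
  lapply(seq_len(k), function(i) {
    ix <- which(lab == i)
    list(index = i,
         genes = rownames(z)[ix],
         cond_mean = colMeans(z[ix, , drop = FALSE]))
  })
}

#' Select gene groups peaking in the double treatment
#'
#' Formalises "higher expression in the double treated samples": a group
#' qualifies when its mean z for the `double_label` condition is both the
#' maximum across conditions and positive. Returns the union of qualifying
#' groups' genes.
#'
#' @param groups output of [cluster_and_cut()] whose `cond_mean` entries carry
#'   condition names.
#' @param double_label condition name of the double treatment.
#' @return character vector of genes (may be empty, with a warning).
#' @export
select_double_high_groups <- function(groups, double_label = "TGFB1_MEKI") {
  sel <- vapply(groups, function(g) {
    cm <- g$cond_mean
    if (!double_label %in% names(cm)) {
      stop_invalid("no condition labeled ", double_label, " in group means")
    }
    cm[double_label] > 0 && cm[double_label] >= max(cm)
  }, logical(1))
  if (!any(sel)) {
    warning("no group peaks in ", double_label, "; returning an empty set")
    return(character(0))
  }
  unique(unlist(lapply(groups[sel], `[[`, "genes")))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked gene list: positions in `gene_set` add
#' `|metric|^p` normalised by the sum of `|metric|^p` over hits; other
#' positions subtract `1/(N - N_hit)`. The enrichment score is the running
#' sum's signed extremum.
#'
#' @param ranked character vector of unique gene symbols sorted by the ranking
#'   metric, descending.
#' @param metric numeric ranking metric aligned with `ranked`.
#' @param gene_set character vector; must intersect `ranked`.
#' @param p weight exponent (0 = classic KS, 1 = weighted, the default).
#' @return list `es`, `running` (length N), `hit_idx`.
#' @export
gsea_score <- function(ranked, metric, gene_set, p = 1) {
  if (anyDuplicated(ranked)) stop_invalid("ranked list must be unique")
  stopifnot(length(ranked) == length(metric))
  hit <- ranked %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop_invalid("no overlap between gene set and ranked list")
  N <- length(ranked)
  w <- abs(metric)^p
  inc <- numeric(N)
  denom_hit <- sum(w[hit])
  inc[hit] <- if (denom_hit > 0) w[hit] / denom_hit else 1 / nh
  if (N > nh) inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hit_idx = which(hit))
}

#' Permutation significance for GSEA enrichment scores
#'
#' Gene-label permutation null (hit positions resampled uniformly, the only
#' scheme available on a pre-ranked list). For each set,
#' `p = (1 + #{|ES_null| >= |ES|}) / (1 + n_perm)` and
#' `NES = ES / mean(|ES_null|)` over null scores of the same sign as ES
#' (NA with a warning if no null score shares the sign). BH adjustment across
#' sets.
#'
#' @inheritParams gsea_score
#' @param gene_sets named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return data.frame `set, size, es, nes, pvalue, padj`, with the running
#'   scores in `attr(, "running")`.
#' @export
gsea_permutation <- function(ranked, metric, gene_sets, n_perm = 999,
                             seed = 1, p = 1) {
  if (n_perm < 100L) stop_invalid("n_perm must be >= 100")
  if (is.null(names(gene_sets))) names(gene_sets) <- seq_along(gene_sets)
  N <- length(ranked)
  res <- lapply(names(gene_sets), function(nm) {
    obs <- gsea_score(ranked, metric, gene_sets[[nm]], p = p)
    nh <- length(obs$hit_idx)
    set.seed(split_seed(seed, match(nm, names(gene_sets))))
    null_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(N, nh)
      gsea_score(ranked, metric, ranked[idx], p = p)$es
    }, numeric(1))
    pval <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    if (is.na(nes)) warning("no same-sign null ES for set ", nm, "; NES is NA")
    list(row = data.frame(set = nm, size = nh, es = obs$es, nes = nes,
                          pvalue = pval, stringsAsFactors = FALSE),
         running = obs$running)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  out$padj <- adjust_bh(out$pvalue)
  attr(out, "running") <- lapply(res, `[[`, "running")
  out
}

#' Build the GSEA ranking from a DE table
#'
#' Sorted log2 fold changes of the significant genes (padj below the gate),
#' descending; ties broken by gene symbol for determinism.
#'
#' @param de data.frame from [de_test()].
#' @param padj_thresh significance gate (default 0.05).
#' @return list `ranked` (gene symbols) and `metric` (log2fc).
#' @export
rank_by_lfc <- function(de, padj_thresh = 0.05) {
  keep <- !is.na(de$padj) & de$padj < padj_thresh & !is.na(de$log2fc)
  d <- de[keep, , drop = FALSE]
  o <- order(-d$log2fc, d$gene)
  list(ranked = d$gene[o], metric = d$log2fc[o])
}
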