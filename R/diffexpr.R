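## Negative binomial differential expression, a documented simplified stand-in
## for the usual DESeq2 fit: median-of-ratios size factors, method-of-moments
## dispersions shrunk toward a mean-dispersion trend, and per-cell-line
## two-group NB contrasts (treatment vs DMSO) tested by Wald z on the log2
## fold change. The NB parameterisation everywhere is var = mu + alpha * mu^2.

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: the median across genes of the ratio of a
#' sample's counts to the per-gene geometric mean, computed over genes that are
#' nonzero in all samples. If no such gene exists, falls back to total-count
#' ratios (scaled to geometric mean 1) with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) {
    stop_invalid("every sample needs at least one nonzero count")
  }
  all_nz <- rowSums(counts == 0) == 0
  if (!any(all_nz)) {
    warning("no gene nonzero in all samples; falling back to total-count ratios")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(counts)))
  }
  sub <- counts[all_nz, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2, function(col) median(col / geo))
  setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments estimate pooled within condition groups on normalised
#' counts, `alpha = max(0, (var - mu) / mu^2)`, then shrunk toward a fitted
#' mean-dispersion trend `alpha_tr(mu) = a0 + a1 / mu` by a weighted average
#' (`shrink_weight` on the trend, default 0.5) and floored at 1e-8.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param groups factor/vector of condition labels per sample; groups with a
#'   single replicate contribute nothing.
#' @param shrink_weight weight of the trend in the weighted average.
#' @return numeric vector of dispersions `alpha_g`.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 shrink_weight = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2L)) {
    stop_invalid("no condition has >= 2 replicates; supply a fixed dispersion ",
                 "to de_test(fixed_dispersion=) instead")
  }
  k <- sweep(counts, 2, size_factors, "/")
  num <- den <- mu_all <- rep(0, nrow(counts))
  wsum <- 0
  for (g in names(tab)[tab >= 2L]) {
    ix <- which(groups == g)
    m <- rowMeans(k[, ix, drop = FALSE])
    v <- apply(k[, ix, drop = FALSE], 1, var)
    w <- length(ix) - 1L
    num <- num + w * (v - m)
    den <- den + w * m^2
    mu_all <- mu_all + w * m
    wsum <- wsum + w
  }
  mu <- mu_all / wsum
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  ## mean-dispersion trend alpha = a0 + a1/mu, least squares on informative genes
  ok <- raw > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[ok]), raw[ok])
    a0 <- max(fit$coefficients[1], 0)
    a1 <- max(fit$coefficients[2], 0)
  } else {
    a0 <- mean(raw[raw > 0])
    if (!is.finite(a0)) a0 <- 0
    a1 <- 0
  }
  trend <- ifelse(mu > 0, a0 + a1 / mu, a0)
  alpha <- (1 - shrink_weight) * raw + shrink_weight * trend
  pmax(alpha, 1e-8)
}

## One-group NB log-mean fit by Fisher scoring, vectorised over genes.
## y: genes x samples counts of one group; sf: size factors; alpha: per gene.
## Returns list(b = log group mean, info = Fisher information for b).
nb_group_fit <- function(y, sf, alpha, max_iter = 50, tol = 1e-8) {
  k <- sweep(y, 2, sf, "/")
  b <- log(pmax(rowMeans(k), 1e-8))
  zero <- rowSums(y) == 0
  step <- rep(0, nrow(y))
  if (all(zero)) {
    mu <- exp(b) %o% sf
    return(list(b = b, info = rowSums(mu / (1 + alpha * mu)), zero = zero,
                converged = rep(TRUE, nrow(y))))
  }
  for (iter in seq_len(max_iter)) {
    mu <- exp(b) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- ifelse(info > 0, score / info, 0)
    step <- pmax(pmin(step, 5), -5)
    b <- b + step
    if (max(abs(step[!zero])) < tol) break
  }
  mu <- exp(b) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  converged <- abs(step) < tol | zero
  list(b = b, info = info, zero = zero, converged = converged)
}

#' Negative binomial Wald differential expression test
#'
#' Fits per-gene NB means for a treatment group and the DMSO reference group
#' within one cell line (log link, Fisher scoring; dispersion shared between
#' groups) and tests `log2fc = 0` by Wald z. Genes with all-zero counts in both
#' groups get NA statistics and are excluded from the BH denominator; genes
#' with all zeros on one side only get a sign-capped `|log2fc| = 10` and NA p.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples sample sheet data.frame (`sample,cell_line,treatment,replicate`),
#'   rows matching `colnames(counts)`.
#' @param cell_line cell line to test.
#' @param treatment treatment group (contrast is `treatment` vs `reference`).
#' @param reference reference treatment, default "DMSO".
#' @param fixed_dispersion optional fixed `alpha` (scalar or per gene) used
#'   instead of [estimate_dispersions()]; required for single-replicate designs.
#' @param shrink_weight passed to [estimate_dispersions()].
#' @param dispersion_from "cell_line" (default) pools the dispersion estimate
#'   over all of the cell line's condition groups, as a full-design NB fit
#'   would; "contrast" uses only the two contrast groups.
#' @param size_factors optional per-sample factors (aligned with
#'   `colnames(counts)`); estimated by median-of-ratios when NULL.
#' @return data.frame `gene, base_mean, log2fc, se, pvalue, padj`.
#' @export
de_test <- function(counts, samples, cell_line, treatment, reference = "DMSO",
                    fixed_dispersion = NULL, shrink_weight = 0.5,
                    dispersion_from = c("cell_line", "contrast"),
                    size_factors = NULL) {
  dispersion_from <- match.arg(dispersion_from)
  counts <- as.matrix(counts)
  if (!treatment %in% samples$treatment) {
    stop_invalid("invalid contrast: unknown treatment label '", treatment, "'")
  }
  sel <- samples$cell_line == cell_line &
    samples$treatment %in% c(reference, treatment)
  if (!any(samples$cell_line == cell_line & samples$treatment == reference)) {
    stop_invalid("invalid design: cell line '", cell_line,
                 "' has no ", reference, " reference samples")
  }
  y <- counts[, sel, drop = FALSE]
  grp <- samples$treatment[sel]
  if (sum(grp == reference) < 2L || sum(grp == treatment) < 2L) {
    stop_invalid("both contrast groups need >= 2 samples for cell line '",
                 cell_line, "'")
  }
  sf <- if (is.null(size_factors)) estimate_size_factors(y) else {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    size_factors[sel]
  }
  alpha <- if (!is.null(fixed_dispersion)) {
    rep_len(fixed_dispersion, nrow(y))
  } else if (dispersion_from == "cell_line") {
    cl <- samples$cell_line == cell_line
    estimate_dispersions(counts[, cl, drop = FALSE],
                         estimate_size_factors(counts[, cl, drop = FALSE]),
                         samples$treatment[cl], shrink_weight = shrink_weight)
  } else {
    estimate_dispersions(y, sf, grp, shrink_weight = shrink_weight)
  }
  alpha <- pmax(alpha, 1e-8)
  ref_ix <- grp == reference
  trt_ix <- grp == treatment
  fr <- nb_group_fit(y[, ref_ix, drop = FALSE], sf[ref_ix], alpha)
  ft <- nb_group_fit(y[, trt_ix, drop = FALSE], sf[trt_ix], alpha)
  log2fc <- (ft$b - fr$b) / log(2)
  se <- sqrt(1 / ft$info + 1 / fr$info) / log(2)
  both_zero <- fr$zero & ft$zero
  one_zero <- xor(fr$zero, ft$zero)
  bad <- !fr$converged | !ft$converged
  if (any(bad & !both_zero & !one_zero)) {
    warning(sum(bad & !both_zero & !one_zero),
            " gene(s) did not converge; statistics set to NA")
  }
  log2fc[one_zero] <- ifelse(ft$zero[one_zero], -10, 10)
  z <- log2fc / se
  pvalue <- 2 * pnorm(-abs(z))
  pvalue[both_zero | one_zero | (bad & !one_zero)] <- NA_real_
  log2fc[both_zero] <- NA_real_
  se[both_zero | one_zero] <- NA_real_
  k <- sweep(y, 2, sf, "/")
  out <- data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(y))),
                    base_mean = rowMeans(k),
                    log2fc = log2fc, se = se, pvalue = pvalue,
                    padj = adjust_bh(pvalue),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0, 1\]; NAs are propagated and excluded
#'   from the number of tests `m`.
#' @return adjusted values, clipped to 1, matched to the input order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m == 0L) return(out)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  out[ok] <- adj
  out
}
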