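#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois rnbinom rlnorm median var sd
#'   pnorm phyper p.adjust hclust cutree dist optim ks.test quantile
#'   setNames complete.cases t.test
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics plot lines abline
NULL

TREATMENTS <- c("DMSO", "TGFB1", "MEKI", "TGFB1_MEKI")

#' Normalise gene symbols
#'
#' Uppercases and strips surrounding whitespace so that symbol sets coming
#' from different sources (GMT files, DE tables, annotation) compare equal.
#'
#' @param x character vector of gene symbols.
#' @return normalised character vector.
#' @export
norm_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

## Deterministic seed splitting: every sub-generator receives
## split_seed(root, k) with a documented, fixed offset k. Keeps all derived
## seeds in the positive 32-bit integer range.
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.integer(seed)) %% 1000003L) * 1009L + 7L * k + 1L) %% 2147483587L
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
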