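# Shared small fixtures, built in code.

small_truth <- function(seed = 7, ...) {
  truth_spec(n_genes = 200,
             block_sizes = c(invasive_up = 15, switch_up = 12, mitf = 8),
             seed = seed, ...)
}

null_effects <- function() {
  list(invasive_up = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 0),
       switch_up = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 0),
       mitf = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 0),
       null = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 0))
}

# a deterministic toy PWM with a strong consensus (GTCTAGAC-like)
toy_pwm <- function() {
  pwm("toy", matrix(c(
    2, 1, 1, 86, 2, 90, 4, 8,
    4, 2, 88, 4, 3, 2, 88, 2,
    88, 3, 5, 4, 88, 3, 3, 2,
    6, 94, 6, 6, 7, 5, 5, 88), nrow = 4, byrow = TRUE))
}

# random peak GRanges on a toy genome (one chromosome, 0-based coords)
random_peaks <- function(n, chrom_len = 10000, max_w = 200, chrom = "chr1") {
  start <- sample.int(chrom_len - max_w, n, replace = TRUE) - 1L
  width <- sample.int(max_w - 1L, n, replace = TRUE)
  switchsig:::bed_to_granges(rep(chrom, n), start, start + width)
}

# per-base indicator of a GRanges on a toy chromosome (index = base0 + 1)
base_indicator <- function(gr, chrom_len = 10000, chrom = "chr1") {
  v <- logical(chrom_len)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(gr)) {
    s0 <- GenomicRanges::start(gr)[i] - 1L
    e0 <- GenomicRanges::end(gr)[i]
    if (e0 > s0) v[(s0 + 1):e0] <- TRUE
  }
  v
}

random_dna <- function(n, len = 60) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
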