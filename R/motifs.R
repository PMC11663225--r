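## Known-motif enrichment in peak sequences: PWM log-odds scanning of both
## strands with a fraction-of-maximum threshold, and sequence-level
## hypergeometric enrichment of foreground vs background hit counts.

revcomp_pwm <- function(pwm_obj) {
  m <- pwm_obj$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm_obj$mat))),
                   drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm_obj$mat <- m
  pwm_obj
}

encode_seq <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (any(!s %in% c("A", "C", "G", "T", "N"))) {
    stop_invalid("invalid character in sequence (alphabet ACGTN)")
  }
  match(s, c("A", "C", "G", "T"))  # N -> NA
}

scan_one_strand <- function(code, lod, threshold) {
  L <- ncol(lod)
  n <- length(code) - L + 1L
  if (n < 1L) return(integer(0))
  sc <- numeric(n)
  nas <- logical(n)
  for (k in seq_len(L)) {
    b <- code[k:(k + n - 1L)]
    nas <- nas | is.na(b)
    v <- lod[cbind(ifelse(is.na(b), 1L, b), k)]
    sc <- sc + v
  }
  which(!nas & sc >= threshold)
}

#' Scan a sequence with a PWM
#'
#' Log-odds scan of both strands. A window is a hit when its score reaches
#' `score_fraction` of the maximum attainable log-odds for the motif. Windows
#' containing N are skipped. Offsets are 1-based window start positions on the
#' forward sequence; minus-strand hits mark windows whose reverse complement
#' matches.
#'
#' @param seq character or `DNAString`/`DNAStringSet` element (alphabet ACGTN).
#' @param pwm `pwm` object.
#' @param score_fraction fraction of the maximal log-odds required (default 0.8).
#' @return data.frame `offset, strand, score`.
#' @export
scan_sequence <- function(seq, pwm, score_fraction = 0.8) {
  code <- encode_seq(seq)
  lod <- log2(pwm$mat / pwm$background)
  L <- ncol(lod)
  if (length(code) < L) stop_invalid("sequence shorter than the PWM")
  max_score <- sum(apply(lod, 2, max))
  threshold <- score_fraction * max_score
  score_at <- function(pos, m) {
    vapply(pos, function(i) {
      sum(m[cbind(code[i:(i + L - 1L)], seq_len(L))])
    }, numeric(1))
  }
  fwd <- scan_one_strand(code, lod, threshold)
  lod_rc <- log2(revcomp_pwm(pwm)$mat / pwm$background)
  rev <- scan_one_strand(code, lod_rc, threshold)
  data.frame(offset = c(fwd, rev),
             strand = rep(c("+", "-"), c(length(fwd), length(rev))),
             score = c(score_at(fwd, lod), score_at(rev, lod_rc)),
             stringsAsFactors = FALSE)
}

count_hit_seqs <- function(seqs, pwm, score_fraction) {
  sum(vapply(as.character(seqs), function(s) {
    nrow(scan_sequence(s, pwm, score_fraction)) > 0L
  }, logical(1)))
}

#' Known-motif enrichment: foreground vs background sequences
#'
#' Counts, per motif, the sequences with at least one hit in the foreground and
#' background sets, computes a one-sided hypergeometric enrichment p-value over
#' the pooled universe (is the foreground over-represented among hit
#' sequences?), an odds ratio (Haldane-corrected when a margin is zero), and BH
#' adjustment across motifs.
#'
#' @param foreground,background `DNAStringSet` or character vectors.
#' @param pwms named list of `pwm` objects.
#' @param score_fraction hit threshold passed to [scan_sequence()].
#' @return data.frame `motif, fg_hits, bg_hits, fg_n, bg_n, odds_ratio,
#'   pvalue, padj`.
#' @export
motif_enrichment <- function(foreground, background, pwms,
                             score_fraction = 0.8) {
  if (!length(foreground) || !length(background)) {
    stop_invalid("foreground and background must both be nonempty")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  }
  n_fg <- length(foreground)
  n_bg <- length(background)
  rows <- lapply(names(pwms), function(nm) {
    fg <- count_hit_seqs(foreground, pwms[[nm]], score_fraction)
    bg <- count_hit_seqs(background, pwms[[nm]], score_fraction)
    ## hypergeometric tail: P(foreground hits >= fg) drawing n_fg sequences
    ## from the pooled universe containing fg + bg hit sequences
    p <- phyper(fg - 1, fg + bg, n_fg + n_bg - fg - bg, n_fg,
                lower.tail = FALSE)
    a <- fg; b <- n_fg - fg; cc <- bg; d <- n_bg - bg
    if (any(c(a, b, cc, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    data.frame(motif = nm, fg_hits = fg, bg_hits = bg, fg_n = n_fg,
               bg_n = n_bg, odds_ratio = (a / b) / (cc / d), pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$pvalue)
  out[order(out$padj, out$pvalue), ]
}
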