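## Peak intervals are handled as GRanges internally. All user-facing
## coordinates (BED files, this package's documented conventions) are 0-based
## half-open; GRanges is 1-based closed, so conversion happens only at the
## read/write boundary: bed [start, end) == GRanges [start + 1, end].

bed_to_granges <- function(chrom, start, end, score = NULL, name = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1L, end = end))
  if (!is.null(score)) gr$score <- score
  if (!is.null(name)) gr$name <- name
  gr
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else ".",
             score = if (!is.null(gr$score)) gr$score else 0,
             strand = ".",
             stringsAsFactors = FALSE)
}

#' Read a BED file of peak intervals
#'
#' Accepts 3- to 6-column BED, 0-based half-open. Malformed lines (fewer than
#' 3 fields, non-numeric or negative coordinates, start >= end) raise an error
#' naming the offending line.
#'
#' @param path BED file.
#' @return `GRanges` with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop_invalid("BED parse error at line ", idx[which(n < 3L)[1]],
                 ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_invalid("BED parse error at line ", idx[bad[1]],
                 ": non-numeric coordinate")
  }
  bad <- which(start < 0 | end < 0)
  if (length(bad)) {
    stop_invalid("BED parse error at line ", idx[bad[1]],
                 ": negative coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop_invalid("BED parse error at line ", idx[bad[1]], ": start >= end")
  }
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                 character(1)), ".")
  score <- suppressWarnings(
    as.numeric(ifelse(n >= 5L,
                      vapply(fields, function(f) f[min(5L, length(f))],
                             character(1)), "0")))
  score[is.na(score)] <- 0
  bed_to_granges(chrom, start, end, score = score, name = name)
}

#' Write peaks to a 6-column BED file
#'
#' @param peaks `GRanges`.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  df <- granges_to_bed(peaks)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Antibody-reproducible consensus peaks
#'
#' Base-pair intersection of two replicate peak sets: every >= 1 bp overlap
#' between the (reduced) replicates is kept, and the result is merged so output
#' intervals are disjoint. This is the strictest reading of "called in both
#' replicates".
#'
#' @param rep_a,rep_b `GRanges` peak sets for the two antibody replicates.
#' @return disjoint `GRanges` covered by both inputs.
#' @export
reproducible_peaks <- function(rep_a, rep_b) {
  GenomicRanges::intersect(GenomicRanges::reduce(rep_a),
                           GenomicRanges::reduce(rep_b),
                           ignore.strand = TRUE)
}

#' Multi-way peak set membership partition
#'
#' Partitions the union of several named peak sets into maximal regions of
#' constant membership (which conditions cover each base), reports per-pattern
#' base-pair and region counts, and extracts condition-unique peak sets.
#'
#' @param peak_sets named list of `GRanges` (>= 2 conditions).
#' @return list with `regions` (`GRanges`, metadata column `pattern` holding
#'   `&`-joined condition names), `counts` (regions per pattern),
#'   `bp` (base pairs per pattern), and `unique` (named list of `GRanges`
#'   covered by exactly one condition).
#' @export
multiway_membership <- function(peak_sets) {
  if (is.null(names(peak_sets)) || length(peak_sets) < 2L) {
    stop_invalid("multiway_membership needs >= 2 named peak sets")
  }
  red <- lapply(peak_sets, GenomicRanges::reduce)
  pooled <- GenomicRanges::reduce(do.call(c, unname(red)))
  d <- GenomicRanges::disjoin(do.call(c, unname(red)))
  memb <- vapply(red, function(s) {
    GenomicRanges::countOverlaps(d, s, ignore.strand = TRUE) > 0L
  }, logical(length(d)))
  if (length(d) == 1L) memb <- matrix(memb, nrow = 1L)
  pattern <- apply(memb, 1L, function(row) {
    paste(names(peak_sets)[row], collapse = "&")
  })
  ## merge adjacent disjoint pieces with identical membership
  ord <- order(as.character(GenomicRanges::seqnames(d)),
               GenomicRanges::start(d))
  d <- d[ord]
  pattern <- pattern[ord]
  memb <- memb[ord, , drop = FALSE]
  keep_new <- c(TRUE, !(as.character(GenomicRanges::seqnames(d)[-1]) ==
                          as.character(GenomicRanges::seqnames(d)[-length(d)]) &
                        GenomicRanges::start(d)[-1] ==
                          GenomicRanges::end(d)[-length(d)] + 1L &
                        pattern[-1] == pattern[-length(d)]))
  grp <- cumsum(keep_new)
  merged <- lapply(split(seq_along(d), grp), function(ix) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(d)[ix[1]],
                           IRanges::IRanges(GenomicRanges::start(d)[ix[1]],
                                            GenomicRanges::end(d)[ix[length(ix)]]))
  })
  regions <- do.call(c, unname(merged))
  regions$pattern <- pattern[keep_new]
  n_memb <- rowSums(memb)[keep_new]
  uniq <- lapply(names(peak_sets), function(nm) {
    GenomicRanges::reduce(regions[regions$pattern == nm & n_memb == 1L])
  })
  names(uniq) <- names(peak_sets)
  list(regions = regions,
       counts = table(regions$pattern),
       bp = tapply(GenomicRanges::width(regions), regions$pattern, sum),
       unique = uniq)
}

#' Annotate peaks by midpoint genomic feature
#'
#' Assigns each peak the category of its midpoint with priority
#' promoter-TSS (TSS +/- `promoter_window`) > exonic > intronic > intergenic.
#' Exon intervals are optional; without them no peak is called exonic and gene
#' bodies count as intronic, which matches annotations that carry only gene
#' spans.
#'
#' @param peaks `GRanges` (0-based half-open at the BED boundary).
#' @param annotation data.frame with columns `symbol,chrom,tss,strand,start,end`
#'   (0-based half-open gene intervals), as produced by [make_annotation()].
#' @param exons optional data.frame `chrom,start,end` of exon intervals.
#' @param promoter_window half-width of the promoter window around the TSS (bp).
#' @return character vector of categories, one per peak.
#' @export
annotate_peak <- function(peaks, annotation, exons = NULL,
                          promoter_window = 1000) {
  if (!all(c("symbol", "chrom", "tss", "start", "end") %in% names(annotation))) {
    stop_invalid("annotation must have columns symbol,chrom,tss,strand,start,end")
  }
  missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(peaks))),
                         unique(annotation$chrom))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from annotation, peaks there are intergenic: ",
            paste(missing_chr, collapse = ", "))
  }
  ## midpoint in 0-based coordinates; as GRanges single-base interval
  mid0 <- floor((GenomicRanges::start(peaks) - 1L + GenomicRanges::end(peaks)) / 2)
  midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                  IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  prom <- bed_to_granges(annotation$chrom,
                         pmax(annotation$tss - promoter_window, 0),
                         annotation$tss + promoter_window + 1L)
  body <- bed_to_granges(annotation$chrom, annotation$start, annotation$end)
  cnt <- function(q, s) {
    ## disjoint seqlevels are expected when a peak chromosome is unannotated
    suppressWarnings(GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE))
  }
  cat <- rep("intergenic", length(peaks))
  in_body <- cnt(midgr, body) > 0L
  cat[in_body] <- "intronic"
  if (!is.null(exons) && nrow(exons)) {
    exgr <- bed_to_granges(exons$chrom, exons$start, exons$end)
    cat[cnt(midgr, exgr) > 0L & in_body] <- "exonic"
  }
  in_prom <- cnt(midgr, prom) > 0L
  cat[in_prom] <- "promoter-TSS"
  cat
}

#' GREAT-style regulatory domains
#'
#' Builds per-gene regulatory domains under the "basal plus extension" rule:
#' the basal domain runs from `basal_up` bp upstream to `basal_down` bp
#' downstream of the TSS (strand-oriented); the extended domain grows from the
#' basal edges in both directions up to `max_extension` bp, stopping early at
#' the nearest other gene's basal domain and clipped at chromosome bounds.
#' Defaults are the cited association tool's defaults (5 kb / 1 kb / 1 Mb).
#'
#' @param annotation data.frame `symbol,chrom,tss,strand,start,end`, optionally
#'   carrying chromosome lengths as `attr(annotation, "chrom_lengths")`
#'   (named vector); without lengths the right edge is unclipped.
#' @param basal_up,basal_down basal domain distances upstream/downstream of the
#'   TSS in bp.
#' @param max_extension maximal extension beyond the basal domain in bp.
#' @return data.frame `symbol, chrom, basal_start, basal_end, ext_start,
#'   ext_end` (0-based half-open).
#' @export
regulatory_domains <- function(annotation, basal_up = 5000, basal_down = 1000,
                               max_extension = 1e6) {
  stopifnot(all(c("symbol", "chrom", "tss", "strand") %in% names(annotation)))
  lens <- attr(annotation, "chrom_lengths")
  up <- ifelse(annotation$strand == "+", basal_up, basal_down)
  dn <- ifelse(annotation$strand == "+", basal_down, basal_up)
  b_start <- pmax(annotation$tss - up, 0)
  b_end <- annotation$tss + dn
  n <- nrow(annotation)
  e_start <- numeric(n)
  e_end <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(annotation$chrom == annotation$chrom[i])
    same <- setdiff(same, i)
    ls <- b_start[i] - max_extension
    rs <- b_end[i] + max_extension
    if (length(same)) {
      left_nb <- b_end[same][b_end[same] <= b_start[i]]
      if (length(left_nb)) ls <- max(ls, max(left_nb))
      right_nb <- b_start[same][b_start[same] >= b_end[i]]
      if (length(right_nb)) rs <- min(rs, min(right_nb))
      ## overlapping neighbour basal domains stop the extension immediately,
      ## but never shrink the gene's own basal domain
      if (any(b_start[same] < b_end[i] & b_end[same] > b_start[i])) {
        ov <- same[b_start[same] < b_end[i] & b_end[same] > b_start[i]]
        if (any(b_end[ov] > b_start[i] & b_start[ov] < b_start[i])) {
          ls <- max(ls, b_start[i])
        }
        if (any(b_start[ov] < b_end[i] & b_end[ov] > b_end[i])) {
          rs <- min(rs, b_end[i])
        }
      }
    }
    e_start[i] <- max(0, min(ls, b_start[i]))
    e_end[i] <- max(rs, b_end[i])
    if (!is.null(lens) && annotation$chrom[i] %in% names(lens)) {
      e_end[i] <- min(e_end[i], lens[[annotation$chrom[i]]])
      b_end[i] <- min(b_end[i], lens[[annotation$chrom[i]]])
    }
  }
  data.frame(symbol = annotation$symbol, chrom = annotation$chrom,
             basal_start = b_start, basal_end = b_end,
             ext_start = e_start, ext_end = pmax(e_end, e_start + 1),
             stringsAsFactors = FALSE)
}

#' Associate peaks with genes via regulatory domains
#'
#' A gene is associated with a peak set if any peak overlaps its extended
#' regulatory domain by >= 1 bp; one peak may associate with several genes.
#'
#' @param peaks `GRanges`.
#' @param domains data.frame from [regulatory_domains()].
#' @return list with `genes` (associated symbol set), `support` (named list of
#'   supporting peak indices per gene) and `unassigned` (indices of peaks that
#'   hit no domain).
#' @export
peaks_to_genes <- function(peaks, domains) {
  dgr <- bed_to_granges(domains$chrom, domains$ext_start, domains$ext_end)
  hits <- GenomicRanges::findOverlaps(peaks, dgr, ignore.strand = TRUE)
  gi <- S4Vectors::subjectHits(hits)
  pi <- S4Vectors::queryHits(hits)
  support <- split(pi, domains$symbol[gi])
  list(genes = sort(unique(domains$symbol[gi])),
       support = support,
       unassigned = setdiff(seq_along(peaks), unique(pi)))
}

#' Length-scaled signal profile over peaks
#'
#' Rescales every peak body to `n_bins_body` bins by mean pooling of per-base
#' coverage, plus flanks of `flank_multiple` x peak width on each side binned
#' at the same fractional resolution (`flank_multiple * n_bins_body` bins per
#' flank), so rows are stackable regardless of peak width. Base `p` (0-based,
#' offset within a stretch of width `w` split into `n` bins) belongs to bin
#' `floor(p * n / w) + 1`. Flank bases beyond chromosome bounds contribute 0
#' and flag the row.
#'
#' @param coverage named list, chromosome -> numeric per-base vector (index 1
#'   is base 0).
#' @param peaks `GRanges`.
#' @param n_bins_body bins across the peak body.
#' @param flank_multiple flank width as a multiple of peak width (default 2,
#'   i.e. -200%..+200% around the body).
#' @return matrix peaks x bins with attribute `clipped` flagging rows that ran
#'   off the chromosome.
#' @export
scaled_signal_profile <- function(coverage, peaks, n_bins_body = 100,
                                  flank_multiple = 2) {
  nb_fl <- n_bins_body * flank_multiple
  out <- matrix(0, nrow = length(peaks), ncol = nb_fl * 2 + n_bins_body)
  clipped <- logical(length(peaks))
  pool <- function(chromcov, from0, width, nbins) {
    ## mean coverage per bin over bases from0 .. from0+width-1 (0-based)
    pos <- from0 + seq_len(width) - 1L
    val <- numeric(width)
    ok <- pos >= 0 & pos < length(chromcov)
    val[ok] <- chromcov[pos[ok] + 1L]
    bin <- floor((seq_len(width) - 1L) * nbins / width) + 1L
    list(means = as.numeric(tapply(val, factor(bin, levels = seq_len(nbins)),
                                   mean)),
         clipped = any(!ok))
  }
  for (i in seq_along(peaks)) {
    chrom <- as.character(GenomicRanges::seqnames(peaks)[i])
    s0 <- GenomicRanges::start(peaks)[i] - 1L
    e0 <- GenomicRanges::end(peaks)[i]
    w <- e0 - s0
    cov <- coverage[[chrom]]
    if (is.null(cov)) cov <- numeric(0)
    fl <- flank_multiple * w
    up <- pool(cov, s0 - fl, fl, nb_fl)
    bd <- pool(cov, s0, w, n_bins_body)
    dn <- pool(cov, e0, fl, nb_fl)
    out[i, ] <- c(up$means, bd$means, dn$means)
    clipped[i] <- up$clipped || bd$clipped || dn$clipped
  }
  out[is.na(out)] <- 0
  colnames(out) <- c(paste0("up", seq_len(nb_fl)),
                     paste0("body", seq_len(n_bins_body)),
                     paste0("down", seq_len(nb_fl)))
  attr(out, "clipped") <- clipped
  out
}
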