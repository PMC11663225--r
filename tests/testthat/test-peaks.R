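gr1 <- function(start, end, chrom = "chr1") {
  switchsig:::bed_to_granges(rep(chrom, length(start)), start, end)
}

test_that("BED round-trip preserves 0-based half-open coordinates", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", tmp)
  gr <- read_bed(tmp)
  expect_equal(GenomicRanges::start(gr), 11L)  # GRanges 1-based closed
  expect_equal(GenomicRanges::end(gr), 20L)

  set.seed(1)
  pk <- random_peaks(25)
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, tmp2)
  rt <- read_bed(tmp2)
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::end(rt), GenomicRanges::end(pk))

  writeLines(c("chr1\t5\t9", "chr1\t20\t10"), tmp)
  expect_error(read_bed(tmp), "line 2.*start >= end")
  writeLines("chr1\t-5\t9", tmp)
  expect_error(read_bed(tmp), "negative")
  writeLines("chr1\tten\t20", tmp)
  expect_error(read_bed(tmp), "non-numeric")
})

test_that("reproducible_peaks equals per-base intersection", {
  a <- gr1(100, 200)
  b <- gr1(150, 250)
  cons <- reproducible_peaks(a, b)
  expect_equal(GenomicRanges::start(cons) - 1L, 150)
  expect_equal(GenomicRanges::end(cons), 200)

  expect_length(reproducible_peaks(gr1(0, 10), gr1(50, 60)), 0L)

  set.seed(11)
  for (i in 1:5) {
    pa <- random_peaks(50)
    pb <- random_peaks(50)
    cons <- reproducible_peaks(pa, pb)
    expect_identical(base_indicator(cons),
                     base_indicator(pa) & base_indicator(pb))
    # output covered by each input
    expect_true(all(base_indicator(cons) <= base_indicator(pa)))
  }
})

test_that("multiway_membership partitions the genome per-base exactly", {
  r <- multiway_membership(list(A = gr1(0, 10), B = gr1(5, 15)))
  pat <- setNames(as.character(r$regions$pattern), NULL)
  df <- data.frame(start = GenomicRanges::start(r$regions) - 1L,
                   end = GenomicRanges::end(r$regions), pattern = pat)
  expect_equal(df[df$pattern == "A", c("start", "end")],
               data.frame(start = 0L, end = 5L), ignore_attr = TRUE)
  expect_equal(df[df$pattern == "A&B", c("start", "end")],
               data.frame(start = 5L, end = 10L), ignore_attr = TRUE)
  expect_equal(df[df$pattern == "B", c("start", "end")],
               data.frame(start = 10L, end = 15L), ignore_attr = TRUE)

  # identical sets: no unique regions, shared class covers all bases
  same <- multiway_membership(list(X = gr1(c(0, 50), c(10, 80)),
                                   Y = gr1(c(0, 50), c(10, 80))))
  expect_true(all(lengths(same$unique) == 0))
  expect_equal(unname(same$bp[["X&Y"]]), 40)

  # 4 random sets vs per-base brute force
  set.seed(12)
  sets <- lapply(setNames(1:4, c("A", "B", "C", "D")),
                 function(i) random_peaks(30))
  mw <- multiway_membership(sets)
  ind <- vapply(sets, base_indicator, logical(10000))
  brute_pattern <- apply(ind, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  got <- character(10000)
  for (i in seq_along(mw$regions)) {
    s0 <- GenomicRanges::start(mw$regions)[i] - 1L
    e0 <- GenomicRanges::end(mw$regions)[i]
    got[(s0 + 1):e0] <- mw$regions$pattern[i]
  }
  expect_identical(got, ifelse(brute_pattern == "", "", brute_pattern))
  # disjoint regions whose union is the union of inputs
  expect_equal(sum(GenomicRanges::width(mw$regions)), sum(rowSums(ind) > 0))
})

test_that("annotate_peak follows the midpoint priority rule", {
  ann <- data.frame(symbol = c("gA", "gB"), chrom = c("chr1", "chr1"),
                    tss = c(5000, 20000), strand = c("+", "+"),
                    start = c(5000, 20000), end = c(12000, 26000))
  exons <- data.frame(chrom = "chr1", start = c(5000, 9000),
                      end = c(5500, 9400))

  # midpoint 100 bp upstream of a TSS -> promoter
  expect_equal(annotate_peak(gr1(4800, 5000), ann), "promoter-TSS")
  # inside gene body, outside exons and promoter windows -> intronic
  expect_equal(annotate_peak(gr1(7500, 7700), ann, exons), "intronic")
  # inside an exon -> exonic
  expect_equal(annotate_peak(gr1(9100, 9300), ann, exons), "exonic")
  # far away -> intergenic
  expect_equal(annotate_peak(gr1(40000, 40100), ann), "intergenic")
  # absent chromosome -> intergenic with a warning
  expect_warning(cat2 <- annotate_peak(gr1(10, 20, "chrX"), ann), "absent")
  expect_equal(cat2, "intergenic")

  # brute-force oracle over 200 random peaks
  set.seed(13)
  ann2 <- make_annotation(40, n_chroms = 2, seed = 3)
  pk <- random_peaks(200, chrom_len = 250000)
  got <- annotate_peak(pk, ann2, promoter_window = 1000)
  mid <- floor((GenomicRanges::start(pk) - 1 + GenomicRanges::end(pk)) / 2)
  brute <- vapply(seq_along(pk), function(i) {
    g <- ann2[ann2$chrom == "chr1", ]
    if (any(abs(mid[i] - g$tss) <= 1000)) return("promoter-TSS")
    if (any(mid[i] >= g$start & mid[i] < g$end)) return("intronic")
    "intergenic"
  }, character(1))
  expect_identical(got, brute)
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  one <- data.frame(symbol = "g", chrom = "chr1", tss = 10000, strand = "+",
                    start = 10000, end = 15000)
  attr(one, "chrom_lengths") <- c(chr1 = 2e6)
  d <- regulatory_domains(one, basal_up = 5000, basal_down = 1000,
                          max_extension = 1e6)
  expect_equal(d$basal_start, 5000)
  expect_equal(d$basal_end, 11000)
  expect_equal(d$ext_start, 0)
  expect_equal(d$ext_end, 1011000)

  # abutting basal domains stop each other's extension exactly
  two <- data.frame(symbol = c("g1", "g2"), chrom = "chr1",
                    tss = c(10000, 16000), strand = c("+", "+"),
                    start = c(10000, 16000), end = c(12000, 18000))
  d2 <- regulatory_domains(two, basal_up = 5000, basal_down = 1000,
                           max_extension = 1e6)
  expect_equal(d2$basal_end[1], 11000)
  expect_equal(d2$basal_start[2], 11000)
  expect_equal(d2$ext_end[1], 11000)   # stopped at g2 basal start
  expect_equal(d2$ext_start[2], 11000) # stopped at g1 basal end

  # invariants on a 500-gene fixture; order independence
  ann <- make_annotation(500, n_chroms = 3, seed = 5)
  dom <- regulatory_domains(ann, max_extension = 50000)
  expect_true(all(dom$ext_start <= dom$basal_start))
  expect_true(all(dom$ext_end >= dom$basal_end))
  expect_true(all(dom$ext_end - dom$ext_start <=
                    dom$basal_end - dom$basal_start + 2 * 50000))
  perm <- sample(nrow(ann))
  ann_p <- ann[perm, ]
  attr(ann_p, "chrom_lengths") <- attr(ann, "chrom_lengths")
  dom_p <- regulatory_domains(ann_p, max_extension = 50000)
  expect_equal(dom_p[order(dom_p$symbol), ], dom[order(dom$symbol), ],
               ignore_attr = TRUE)
})

test_that("peaks_to_genes matches brute-force overlap testing", {
  dom <- data.frame(symbol = c("g1", "g2"), chrom = "chr1",
                    basal_start = c(900, 2000), basal_end = c(1100, 2200),
                    ext_start = c(500, 1500), ext_end = c(1600, 3000))
  single <- peaks_to_genes(gr1(600, 700), dom)
  expect_equal(single$genes, "g1")
  both <- peaks_to_genes(gr1(1550, 1650), dom)
  expect_equal(both$genes, c("g1", "g2"))
  none <- peaks_to_genes(gr1(5000, 5100), dom)
  expect_length(none$genes, 0)
  expect_equal(none$unassigned, 1L)

  set.seed(14)
  ann <- make_annotation(60, n_chroms = 2, seed = 8)
  dom2 <- regulatory_domains(ann, max_extension = 20000)
  pk <- random_peaks(120, chrom_len = 300000)
  got <- peaks_to_genes(pk, dom2)$genes
  s0 <- GenomicRanges::start(pk) - 1L
  e0 <- GenomicRanges::end(pk)
  brute <- sort(unique(unlist(lapply(seq_along(pk), function(i) {
    hit <- dom2$chrom == "chr1" & dom2$ext_start < e0[i] & dom2$ext_end > s0[i]
    dom2$symbol[hit]
  }))))
  expect_equal(got, brute)
})

test_that("scaled signal profiles pool coverage per the bin rule", {
  cov <- list(chr1 = rep(1, 5000))
  pk <- gr1(1000, 1200)
  prof <- scaled_signal_profile(cov, pk, n_bins_body = 10, flank_multiple = 2)
  expect_equal(unname(prof[1, ]), rep(1, 50))

  # indicator of the body: body bins 1, flank bins 0
  cov2 <- list(chr1 = rep(0, 5000))
  cov2$chr1[1001:1200] <- 1
  prof2 <- scaled_signal_profile(cov2, pk, n_bins_body = 10,
                                 flank_multiple = 2)
  expect_equal(unname(prof2[1, 21:30]), rep(1, 10))
  expect_equal(unname(prof2[1, c(1:20, 31:50)]), rep(0, 40))

  # random piecewise coverage vs brute-force per-base assignment
  set.seed(15)
  cov3 <- list(chr1 = rep(runif(50), each = 100))
  pk3 <- gr1(c(700, 2000), c(1000, 2420))
  nb <- 12
  prof3 <- scaled_signal_profile(cov3, pk3, n_bins_body = nb,
                                 flank_multiple = 2)
  brute_bins <- function(v, from0, w, n) {
    out <- numeric(n)
    cnt <- numeric(n)
    for (p in 0:(w - 1)) {
      b <- floor(p * n / w) + 1
      pos <- from0 + p
      val <- if (pos >= 0 && pos < length(v)) v[pos + 1] else 0
      out[b] <- out[b] + val
      cnt[b] <- cnt[b] + 1
    }
    out / cnt
  }
  for (i in 1:2) {
    s0 <- GenomicRanges::start(pk3)[i] - 1L
    e0 <- GenomicRanges::end(pk3)[i]
    w <- e0 - s0
    expected <- c(brute_bins(cov3$chr1, s0 - 2 * w, 2 * w, 2 * nb),
                  brute_bins(cov3$chr1, s0, w, nb),
                  brute_bins(cov3$chr1, e0, 2 * w, 2 * nb))
    expect_equal(unname(prof3[i, ]), expected, tolerance = 1e-12)
  }

  # flank running off the chromosome is zero-padded and flagged
  pk4 <- gr1(100, 300)
  prof4 <- scaled_signal_profile(cov, pk4, n_bins_body = 10,
                                 flank_multiple = 2)
  expect_true(attr(prof4, "clipped")[1])
})
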