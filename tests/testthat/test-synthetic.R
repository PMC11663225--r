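test_that("make_annotation produces valid, deterministic annotations", {
  a2 <- make_annotation(2, n_chroms = 1, seed = 7)
  expect_equal(nrow(a2), 2L)
  expect_true(all(a2$chrom == "chr1"))
  expect_false(anyDuplicated(a2$tss) > 0)
  expect_true(all(a2$strand %in% c("+", "-")))
  expect_true(all(a2$start >= 0 & a2$start < a2$end))
  expect_identical(a2, make_annotation(2, n_chroms = 1, seed = 7))

  a500 <- make_annotation(500, n_chroms = 3, seed = 1)
  expect_equal(sum(table(a500$chrom)), 500L)
  expect_false(anyDuplicated(a500[, c("chrom", "tss")]) > 0)

  expect_error(make_annotation(1), "n_genes >= 2")
})

test_that("simulate_counts matches its NB null model", {
  truth <- truth_spec(n_genes = 1000, effect_sizes = null_effects(),
                      dispersion = 1e-6, lib_size_range = c(1, 1), seed = 3)
  sim <- simulate_counts(truth, make_design(n_reps = 3))
  ratio <- rowMeans(sim$counts) / sim$q
  expect_lt(abs(mean(ratio) - 1), 0.05)

  # determinism
  sim2 <- simulate_counts(truth, make_design(n_reps = 3))
  expect_identical(sim$counts, sim2$counts)

  # missing DMSO reference
  bad <- make_design()
  bad <- bad[bad$treatment != "DMSO" | bad$cell_line != "M_SENS", ]
  expect_error(simulate_counts(truth, bad), "invalid design")
})

test_that("implanted switch block shows the expected double/DMSO mean ratio", {
  # Monte-Carlo over 100 independent simulations of a small fixture
  ratios <- vapply(1:100, function(s) {
    truth <- truth_spec(n_genes = 60,
                        block_sizes = c(invasive_up = 5, switch_up = 20,
                                        mitf = 5),
                        dispersion = 0.05, lib_size_range = c(1, 1), seed = s)
    sim <- simulate_counts(truth, make_design(cell_lines = "M_SENS"))
    sw <- sim$blocks == "switch_up"
    dbl <- sim$samples$treatment == "TGFB1_MEKI"
    ctl <- sim$samples$treatment == "DMSO"
    mean(rowMeans(sim$counts[sw, dbl]) / rowMeans(sim$counts[sw, ctl]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 8), 0.8)
})

test_that("simulate_peaks controls the reproducible fraction", {
  ann <- make_annotation(100, n_chroms = 2, seed = 2)
  t1 <- small_truth(reproducible_fraction = 1)
  p1 <- simulate_peaks(t1, ann, n_backbone = 60, n_specific = 0)
  n_true <- length(attr(p1$DMSO, "true_peaks"))
  expect_equal(length(reproducible_peaks(p1$DMSO$rep1, p1$DMSO$rep2)), n_true)

  t0 <- small_truth(reproducible_fraction = 0)
  p0 <- simulate_peaks(t0, ann, n_backbone = 60, n_specific = 0)
  expect_equal(length(reproducible_peaks(p0$DMSO$rep1, p0$DMSO$rep2)), 0L)

  th <- truth_spec(n_genes = 2000, reproducible_fraction = 0.5, seed = 5)
  ph <- simulate_peaks(th, make_annotation(2000, 3, seed = 5),
                       n_backbone = 200, n_specific = 0)
  n <- length(attr(ph$DMSO, "true_peaks"))
  cons <- length(reproducible_peaks(ph$DMSO$rep1, ph$DMSO$rep2))
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(cons, ci[1])
  expect_lte(cons, ci[2])

  expect_error(simulate_peaks(small_truth(), ann[0, , drop = FALSE]),
               "nonempty")
})

test_that("motif implants appear at the stated rate", {
  ann <- make_annotation(50, seed = 4)
  mot <- toy_pwm()

  t1 <- small_truth(motif_implant_rate = 1)
  pk <- random_peaks(30, chrom_len = 100000, max_w = 80)
  pk <- pk[GenomicRanges::width(pk) >= 20]
  s1 <- simulate_peak_sequences(pk, mot, t1)
  hits <- vapply(as.character(s1$foreground), function(x) {
    nrow(scan_sequence(x, mot, score_fraction = 1.0)) > 0
  }, logical(1))
  expect_true(all(hits))

  t0 <- truth_spec(n_genes = 600, motif_implant_rate = 0, seed = 6)
  pk0 <- switchsig:::bed_to_granges(rep("chr1", 500),
                                    seq(0, by = 200, length.out = 500),
                                    seq(0, by = 200, length.out = 500) + 100)
  s0 <- simulate_peak_sequences(pk0, mot, t0)
  rate <- function(ss) mean(vapply(as.character(ss), function(x) {
    nrow(scan_sequence(x, mot, 0.8)) > 0
  }, logical(1)))
  expect_lt(abs(rate(s0$foreground) - rate(s0$background)), 0.03)

  # determinism
  s1b <- simulate_peak_sequences(pk, mot, t1)
  expect_identical(as.character(s1$foreground), as.character(s1b$foreground))
  expect_identical(as.character(s1$background), as.character(s1b$background))

  # PWM longer than shortest peak
  tiny <- switchsig:::bed_to_granges("chr1", 0, 5)
  expect_error(simulate_peak_sequences(tiny, mot, t1), "PWM longer")
})

test_that("dinucleotide shuffle preserves exact dinucleotide counts", {
  set.seed(1)
  for (s in random_dna(10, len = 80)) {
    sh <- switchsig:::dinuc_shuffle_one(s)
    dinucs <- function(x) {
      v <- strsplit(x, "")[[1]]
      table(paste0(v[-length(v)], v[-1]))
    }
    expect_identical(sort(as.character(strsplit(sh, "")[[1]])),
                     sort(as.character(strsplit(s, "")[[1]])))
    expect_equal(dinucs(sh), dinucs(s))
  }
})

test_that("single-cell simulation places the shift where requested", {
  truth <- small_truth()
  sc0 <- simulate_single_cell(truth, cells_per_state = 60, shift = 0)
  ms0 <- module_score(sc0$expr, truth$gene_blocks$switch_up, n_bins = 10,
                      n_ctrl = 20, seed = 1)
  by0 <- score_by_state(ms0, sc0$labels)
  spread <- diff(range(by0$summary$mean))
  se <- max(by0$summary$sd / sqrt(by0$summary$n))
  expect_lt(spread, 4 * se)  # |delta| small vs SE under the null

  sc1 <- simulate_single_cell(truth, cells_per_state = 60, shift = 1)
  expect_identical(sc1$expr,
                   simulate_single_cell(truth, cells_per_state = 60,
                                        shift = 1)$expr)
  expect_error(simulate_single_cell(truth, states = "one"), ">= 2 states")
})

test_that("dose-response simulation feeds recoverable fits", {
  truth <- truth_spec(seed = 9, fourpl_params = list(
    L1 = list(top = 100, bottom = 5, hill = 1.2, ic50 = 1e-9),
    LF = list(flat = TRUE, level = 95)))
  d0 <- simulate_dose_response(truth, n_reps = 2, noise_sd = 0)
  f <- fit_4pl(d0$dose_molar[d0$cell_line == "L1"],
               d0$response[d0$cell_line == "L1"])
  expect_lt(abs(f$log10_ic50 - log10(1e-9 * 1e6)) / abs(log10(1e-9 * 1e6)),
            1e-6)
  ff <- fit_4pl(d0$dose_molar[d0$cell_line == "LF"],
                d0$response[d0$cell_line == "LF"])
  expect_true(ff$flat_flag)
  expect_true(is.na(ff$ic50))

  expect_identical(simulate_dose_response(truth),
                   simulate_dose_response(truth))
  expect_error(simulate_dose_response(truth, doses = c(1e-9, 2e-9, 4e-9)),
               "4 distinct")
})

test_that("fixture bundle round-trips every format", {
  outdir <- withr::local_tempdir()
  truth <- small_truth()
  bundle <- write_fixture_bundle(truth, outdir)
  expect_true(all(file.exists(unlist(bundle[names(bundle) != "peaks"]))))
  expect_true(all(file.exists(unlist(bundle$peaks))))

  sim <- simulate_counts(truth, make_design(truth$cell_lines))
  expect_identical(read_counts_tsv(bundle$counts_tsv), sim$counts)
  expect_identical(read_counts_mtx(bundle$counts_mtx), sim$counts)
  expect_identical(read_sample_sheet(bundle$sample_sheet)$sample,
                   sim$samples$sample)

  ann <- make_annotation(truth$n_genes, 3, seed = truth$seed)
  peaks <- simulate_peaks(truth, ann)
  rt <- read_bed(bundle$peaks$DMSO_rep1)
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(peaks$DMSO$rep1))
  expect_equal(GenomicRanges::end(rt), GenomicRanges::end(peaks$DMSO$rep1))

  sets <- make_gene_sets(truth)
  expect_equal(read_gmt(bundle$gmt), sets)

  truth2 <- read_truth_json(file.path(outdir, "truth.json"))
  expect_equal(truth2$gene_blocks, truth$gene_blocks)
  expect_equal(truth2$effect_sizes, truth$effect_sizes)
  expect_equal(truth2$dispersion, truth$dispersion)
  expect_equal(truth2$seed, truth$seed)
  expect_equal(truth2$reproducible_fraction, truth$reproducible_fraction)

  pw <- read_jaspar(bundle$pwm)
  expect_equal(length(pw), 1L)
  expect_true(all(abs(colSums(pw[[1]]$mat) - 1) < 1e-6))

  dr <- read_dose_response(bundle$dose_response)
  expect_equal(dr, simulate_dose_response(truth), tolerance = 1e-6)
})

test_that("truth_spec validates its invariants", {
  expect_error(truth_spec(reproducible_fraction = 1.2), "fractions")
  expect_error(truth_spec(dispersion = 0), "dispersion")
  tr <- small_truth()
  expect_false(anyDuplicated(unlist(tr$gene_blocks)) > 0)
})
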