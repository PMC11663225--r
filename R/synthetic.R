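## Synthetic fixture generator with known ground truth. All randomness flows
## from the TruthSpec's root seed, split deterministically per sub-generator
## (split_seed offsets: 1 annotation, 2 counts, 3 peaks, 4 sequences,
## 5 single-cell, 6 dose-response, 7 library sizes). The stated world:
## 4 treatments x 2 cell lines x 3 replicates of NB counts; implanted
## pro-invasive (TGFB1-only up, down in the double treatment), pro-apoptotic
## switch (double-treatment-only up) and MITF (MEKi-responsive) gene blocks;
## two-antibody peak replicates with a controlled reproducible fraction and
## double-treatment-unique peaks at the switch genes; motif implants in
## foreground peak sequences; 4PL viability curves including a flat
## (unfittable) resistant line.

#' Ground-truth specification for the synthetic fixture
#'
#' @param n_genes total genes (gene blocks are carved out of the front).
#' @param block_sizes named integer vector for `invasive_up`, `switch_up`,
#'   `mitf`; the remainder is the `null` block.
#' @param effect_sizes named list block -> named numeric of log2 fold changes
#'   vs DMSO per treatment. Defaults implant the TGFB1-only invasive response
#'   (up 2, down 1 in the double treatment), the double-treatment-only switch
#'   (up 3), and a MEKi response of the MITF block (up 1.5).
#' @param dispersion per-gene NB dispersion `alpha` (scalar recycled);
#'   `var = mu + alpha * mu^2`.
#' @param lib_size_range library-size factors drawn log-uniform in this range.
#' @param reproducible_fraction fraction of peaks present in both antibody
#'   replicates of a condition.
#' @param unique_target_fraction fraction of switch genes given a
#'   double-treatment-unique peak.
#' @param motif_implant_rate per-foreground-sequence probability of one
#'   implanted PWM instance.
#' @param fourpl_params named list cell line -> `list(top, bottom, hill, ic50)`
#'   in molar, or `list(flat = TRUE, level =)` for unfittable lines.
#' @param cell_lines cell line names used by the count design (first = line A,
#'   MEKi-sensitive; second = line B, MEKi-resistant).
#' @param seed root seed.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(n_genes = 2000,
                       block_sizes = c(invasive_up = 60, switch_up = 50,
                                       mitf = 40),
                       effect_sizes = list(
                         invasive_up = c(TGFB1 = 2, MEKI = 0, TGFB1_MEKI = -1),
                         switch_up = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 3),
                         mitf = c(TGFB1 = 0, MEKI = 1.5, TGFB1_MEKI = 0),
                         null = c(TGFB1 = 0, MEKI = 0, TGFB1_MEKI = 0)),
                       dispersion = 0.05,
                       lib_size_range = c(0.7, 1.4),
                       reproducible_fraction = 0.8,
                       unique_target_fraction = 1.0,
                       motif_implant_rate = 0.8,
                       fourpl_params = list(
                         M_SENS = list(top = 100, bottom = 10, hill = 1,
                                       ic50 = 5e-10),
                         M_RES = list(top = 100, bottom = 55, hill = 1,
                                      ic50 = 5e-8),
                         M_FLAT = list(flat = TRUE, level = 100)),
                       cell_lines = c("M_SENS", "M_RES"),
                       seed = 1) {
  stopifnot(n_genes >= sum(block_sizes) + 1, all(block_sizes > 0))
  fr <- c(reproducible_fraction, unique_target_fraction, motif_implant_rate)
  if (any(fr < 0 | fr > 1)) stop_invalid("fractions must lie in [0, 1]")
  if (any(dispersion <= 0)) stop_invalid("dispersion must be > 0")
  if (!all(is.finite(unlist(effect_sizes)))) {
    stop_invalid("effect sizes must be finite")
  }
  symbols <- sprintf("GENE%05d", seq_len(n_genes))
  edges <- cumsum(c(0, block_sizes))
  gene_blocks <- lapply(seq_along(block_sizes), function(i) {
    symbols[(edges[i] + 1):edges[i + 1]]
  })
  names(gene_blocks) <- names(block_sizes)
  gene_blocks$null <- symbols[(edges[length(edges)] + 1):n_genes]
  stopifnot(!anyDuplicated(unlist(gene_blocks)))
  structure(list(gene_blocks = gene_blocks, effect_sizes = effect_sizes,
                 dispersion = rep_len(dispersion, n_genes),
                 lib_size_range = lib_size_range,
                 reproducible_fraction = reproducible_fraction,
                 unique_target_fraction = unique_target_fraction,
                 motif_implant_rate = motif_implant_rate,
                 fourpl_params = fourpl_params, cell_lines = cell_lines,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "truth_spec")
}

block_of <- function(truth) {
  blocks <- rep(NA_character_, truth$n_genes)
  syms <- unlist(truth$gene_blocks, use.names = FALSE)
  labs <- rep(names(truth$gene_blocks), lengths(truth$gene_blocks))
  blocks[match(syms, sprintf("GENE%05d", seq_len(truth$n_genes)))] <- labs
  blocks
}

#' Generate a synthetic gene annotation table
#'
#' Genes are spaced along `n_chroms` chromosomes with distinct TSS coordinates
#' (0-based); strand alternates pseudo-randomly; gene bodies span 5-40 kb
#' downstream of the TSS (strand-oriented). Chromosome lengths are attached as
#' `attr(, "chrom_lengths")`.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_chroms number of chromosomes.
#' @param seed RNG seed; output is byte-identical for a fixed seed.
#' @param spacing mean TSS spacing in bp.
#' @param symbols optional symbol vector (default `GENE00001...`).
#' @return data.frame `symbol, chrom, tss, strand, start, end`.
#' @export
make_annotation <- function(n_genes, n_chroms = 3, seed = 1, spacing = 10000,
                            symbols = NULL) {
  if (n_genes < 2) {
    stop_invalid("make_annotation needs n_genes >= 2 ",
                 "(neighbor-dependent regulatory domains)")
  }
  set.seed(split_seed(seed, 1L))
  symbols <- symbols %||% sprintf("GENE%05d", seq_len(n_genes))
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chroms)), n_genes))
  per <- table(chrom)
  tss <- unlist(lapply(names(per), function(ch) {
    k <- per[[ch]]
    base <- seq_len(k) * spacing
    base + sample.int(floor(spacing / 2), k, replace = TRUE)
  }), use.names = FALSE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  width <- sample(5000:40000, n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(tss - width, 0))
  end <- ifelse(strand == "+", tss + width, tss + 1)
  ann <- data.frame(symbol = symbols, chrom = chrom, tss = tss,
                    strand = strand, start = start, end = end,
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(ann[, c("chrom", "tss")]))
  lens <- tapply(ann$end, ann$chrom, max) + 2 * spacing
  attr(ann, "chrom_lengths") <- setNames(as.numeric(lens), names(lens))
  ann
}

#' Default bulk RNA-seq design
#'
#' @param cell_lines cell line names.
#' @param n_reps replicates per condition (default 3).
#' @return data.frame `sample, cell_line, treatment, replicate`.
#' @export
make_design <- function(cell_lines = c("M_SENS", "M_RES"), n_reps = 3) {
  d <- expand.grid(replicate = seq_len(n_reps), treatment = TREATMENTS,
                   cell_line = cell_lines, stringsAsFactors = FALSE)
  d$sample <- paste(d$cell_line, d$treatment, d$replicate, sep = "_")
  d[, c("sample", "cell_line", "treatment", "replicate")]
}

#' Simulate NB bulk RNA-seq counts
#'
#' Counts are drawn `NB(mean = s_j * q_g * 2^LFC(block(g), treatment_j),
#' var = mu + alpha_g * mu^2)`; baseline means `q_g` are log-normal
#' (median ~200), library sizes log-uniform in `truth$lib_size_range`.
#'
#' @param truth [truth_spec()].
#' @param design data.frame from [make_design()] (every cell line needs DMSO
#'   samples and >= 2 replicates per condition).
#' @return list `counts` (genes x samples integer matrix), `samples` (the
#'   design), `size_factors`, `q` (baseline means), `blocks` (per-gene block
#'   label).
#' @export
simulate_counts <- function(truth, design) {
  for (cl in unique(design$cell_line)) {
    if (!any(design$cell_line == cl & design$treatment == "DMSO")) {
      stop_invalid("invalid design: cell line '", cl, "' lacks DMSO samples")
    }
  }
  tab <- table(design$cell_line, design$treatment)
  if (any(tab > 0 & tab < 2)) {
    stop_invalid("invalid design: every present condition needs >= 2 replicates")
  }
  n_genes <- truth$n_genes
  set.seed(split_seed(truth$seed, 2L))
  q <- rlnorm(n_genes, meanlog = log(200), sdlog = 1.2)
  set.seed(split_seed(truth$seed, 7L))
  s <- exp(runif(nrow(design), log(truth$lib_size_range[1]),
                 log(truth$lib_size_range[2])))
  blocks <- block_of(truth)
  lfc <- matrix(0, n_genes, nrow(design))
  for (j in seq_len(nrow(design))) {
    trt <- design$treatment[j]
    if (trt == "DMSO") next
    for (b in names(truth$effect_sizes)) {
      eff <- truth$effect_sizes[[b]]
      if (trt %in% names(eff) && eff[[trt]] != 0) {
        lfc[blocks == b, j] <- eff[[trt]]
      }
    }
  }
  mu <- (q %o% s) * 2^lfc
  set.seed(split_seed(truth$seed, 2L) + 1L)
  alpha <- truth$dispersion
  counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / alpha,
                                                           ncol(mu))),
                   nrow = n_genes)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("GENE%05d", seq_len(n_genes))
  colnames(counts) <- design$sample
  list(counts = counts, samples = design, size_factors = s, q = q,
       blocks = blocks)
}

#' Simulate per-condition, two-antibody replicate peak sets
#'
#' Each condition carries a shared backbone of peaks at random loci plus
#' condition-specific peaks; the double-treatment condition's specific peaks
#' sit next to the TSS of (a `unique_target_fraction` of) the switch genes, so
#' they are unique to that condition and inside regulatory distance of the
#' designated truth genes. Each peak is present in both antibody replicates
#' with probability `reproducible_fraction` (endpoints jittered by at most
#' width/4, guaranteeing >= 1 bp overlap) and in exactly one replicate
#' otherwise.
#'
#' @param truth [truth_spec()].
#' @param annotation from [make_annotation()].
#' @param n_backbone shared peaks per condition.
#' @param n_specific condition-specific peaks for the non-double conditions.
#' @param peak_width peak width in bp.
#' @return nested list: condition -> list(rep1, rep2) of `GRanges`, with the
#'   per-condition true peak sets in `attr(, "true_peaks")` and the designated
#'   unique target genes in `attr(, "unique_targets")`.
#' @export
simulate_peaks <- function(truth, annotation, n_backbone = 120,
                           n_specific = 25, peak_width = 400) {
  if (!nrow(annotation)) stop_invalid("annotation must be nonempty")
  f <- truth$reproducible_fraction
  if (f < 0 || f > 1) stop_invalid("reproducible_fraction outside [0, 1]")
  set.seed(split_seed(truth$seed, 3L))
  lens <- attr(annotation, "chrom_lengths")
  chroms <- names(lens)
  rand_loci <- function(n, min_gap = 3L * peak_width) {
    ## non-overlapping random peak loci across chromosomes
    ch <- sample(chroms, n, replace = TRUE)
    st <- vapply(ch, function(c0) {
      round(runif(1, peak_width * 5, lens[[c0]] - peak_width * 6))
    }, numeric(1))
    df <- data.frame(chrom = ch, start = st, end = st + peak_width)
    df <- df[order(df$chrom, df$start), ]
    keep <- rep(TRUE, nrow(df))
    if (nrow(df) > 1) {
      for (i in 2:nrow(df)) {
        prev <- max(which(keep[seq_len(i - 1)]))
        keep[i] <- df$chrom[i] != df$chrom[prev] ||
          df$start[i] >= df$end[prev] + min_gap
      }
    }
    df[keep, ]
  }
  backbone <- rand_loci(n_backbone)
  switch_genes <- truth$gene_blocks$switch_up
  n_targets <- round(truth$unique_target_fraction * length(switch_genes))
  targets <- switch_genes[seq_len(n_targets)]
  tgt_ann <- annotation[match(targets, annotation$symbol), , drop = FALSE]
  tgt_ann <- tgt_ann[!is.na(tgt_ann$symbol), , drop = FALSE]
  double_specific <- data.frame(chrom = tgt_ann$chrom,
                                start = tgt_ann$tss + 300,
                                end = tgt_ann$tss + 300 + peak_width)
  out <- list()
  for (cond in TREATMENTS) {
    spec <- if (cond == "TGFB1_MEKI") {
      double_specific
    } else {
      rand_loci(n_specific)
    }
    peaks <- rbind(backbone, spec)
    repro <- runif(nrow(peaks)) < f
    to_rep1 <- repro | (seq_len(nrow(peaks)) %% 2 == 0)
    to_rep2 <- repro | !(seq_len(nrow(peaks)) %% 2 == 0)
    jitter_peaks <- function(df) {
      j <- floor(peak_width / 4)
      s <- df$start + sample(seq(-j, j), nrow(df), replace = TRUE)
      e <- df$end + sample(seq(-j, j), nrow(df), replace = TRUE)
      bed_to_granges(df$chrom, pmax(s, 0), pmax(e, s + 1))
    }
    out[[cond]] <- list(rep1 = jitter_peaks(peaks[to_rep1, , drop = FALSE]),
                        rep2 = jitter_peaks(peaks[to_rep2, , drop = FALSE]))
    attr(out[[cond]], "reproducible") <- repro
    attr(out[[cond]], "true_peaks") <- bed_to_granges(peaks$chrom, peaks$start,
                                                      peaks$end)
  }
  attr(out, "unique_targets") <- tgt_ann$symbol
  out
}

## Altschul-Erickson exact dinucleotide shuffle: random Eulerian walk over the
## dinucleotide multigraph, preserving exact dinucleotide counts.
dinuc_shuffle_one <- function(s) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  if (n < 3) return(s)
  alpha <- unique(v)
  edges <- split(v[-1], factor(v[-n], levels = alpha))
  last <- v[n]
  for (attempt in 1:50) {
    ## pick a random final edge per non-terminal vertex; must reach `last`
    pick <- vapply(alpha, function(a) {
      if (a == last || !length(edges[[a]])) NA_character_
      else sample(edges[[a]], 1)
    }, character(1))
    reaches <- function(a) {
      seen <- character(0)
      while (!is.na(a) && a != last && !(a %in% seen)) {
        seen <- c(seen, a)
        a <- pick[[a]] %||% NA_character_
        if (is.null(a)) a <- NA_character_
      }
      identical(a, last)
    }
    ok <- all(vapply(alpha, function(a) {
      a == last || !length(edges[[a]]) || reaches(a)
    }, logical(1)))
    if (ok) break
  }
  if (!ok) return(paste(sample(v), collapse = ""))  # degenerate fallback
  pools <- lapply(alpha, function(a) {
    e <- edges[[a]]
    if (a != last && length(e)) {
      drop <- match(pick[[a]], e)
      e <- c(sample(e[-drop]), pick[[a]])
    } else {
      e <- sample(e)
    }
    e
  })
  names(pools) <- alpha
  used <- setNames(integer(length(alpha)), alpha)
  res <- character(n)
  res[1] <- v[1]
  cur <- v[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- pools[[cur]][used[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Simulate foreground peak sequences and a shuffled background
#'
#' One random sequence per peak; with probability `truth$motif_implant_rate`
#' the PWM's consensus (max-scoring) word is implanted at a random offset.
#' The background is a per-sequence exact dinucleotide shuffle (the simplest
#' composition-matched null).
#'
#' @param peaks `GRanges` (sequence lengths follow the peak widths).
#' @param pwms list of `pwm` objects; the first is the implanted motif.
#' @param truth [truth_spec()].
#' @param gc background GC content of the random sequences.
#' @return list `foreground`, `background` (`DNAStringSet`) and `implanted`
#'   (logical).
#' @export
simulate_peak_sequences <- function(peaks, pwms, truth, gc = 0.45) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  L <- ncol(pwms[[1]]$mat)
  widths <- GenomicRanges::width(peaks)
  if (any(widths < L)) stop_invalid("PWM longer than the shortest peak")
  consensus <- paste(c("A", "C", "G", "T")[apply(pwms[[1]]$mat, 2,
                                                 which.max)], collapse = "")
  set.seed(split_seed(truth$seed, 4L))
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  fg <- character(length(peaks))
  implanted <- runif(length(peaks)) < truth$motif_implant_rate
  for (i in seq_along(peaks)) {
    w <- widths[i]
    s <- sample(names(pbase), w, replace = TRUE, prob = pbase)
    if (implanted[i]) {
      off <- sample.int(w - L + 1L, 1)
      s[off:(off + L - 1L)] <- strsplit(consensus, "")[[1]]
    }
    fg[i] <- paste(s, collapse = "")
  }
  bg <- vapply(fg, dinuc_shuffle_one, character(1), USE.NAMES = FALSE)
  names(fg) <- names(bg) <- paste0("peak_", seq_along(peaks))
  list(foreground = Biostrings::DNAStringSet(fg),
       background = Biostrings::DNAStringSet(bg),
       implanted = implanted)
}

#' Simulate single-cell expression with melanoma-like states
#'
#' Log-normal expression (log-scale values returned): per-gene baseline means
#' plus Gaussian cell noise; cells of `shifted_state` over-express the
#' `shifted_block` genes by `shift` log units.
#'
#' @param truth [truth_spec()].
#' @param states state names (>= 2; defaults to the four drug-exposure states
#'   of the reference single-cell atlas).
#' @param cells_per_state cells per state.
#' @param shift log-scale over-expression of the designated block.
#' @param shifted_state state receiving the shift.
#' @param shifted_block gene block receiving the shift.
#' @param noise_sd cell-level Gaussian noise SD.
#' @return list `expr` (cells x genes log-scale matrix), `labels`.
#' @export
simulate_single_cell <- function(truth,
                                 states = c("pigmented", "SMC", "NCSC",
                                            "invasive"),
                                 cells_per_state = 200, shift = 1.0,
                                 shifted_state = "NCSC",
                                 shifted_block = "switch_up",
                                 noise_sd = 0.5) {
  if (length(states) < 2L) stop_invalid("need >= 2 states")
  if (!shifted_state %in% states) stop_invalid("unknown shifted_state")
  n_genes <- truth$n_genes
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  set.seed(split_seed(truth$seed, 5L))
  base <- runif(n_genes, 0.1, 4)
  n_cells <- cells_per_state * length(states)
  labels <- rep(states, each = cells_per_state)
  expr <- matrix(rnorm(n_cells * n_genes, sd = noise_sd), n_cells, n_genes)
  expr <- sweep(expr, 2, base, "+")
  block_ix <- genes %in% truth$gene_blocks[[shifted_block]]
  expr[labels == shifted_state, block_ix] <-
    expr[labels == shifted_state, block_ix] + shift
  colnames(expr) <- genes
  rownames(expr) <- paste0("cell_", seq_len(n_cells))
  list(expr = expr, labels = labels)
}

#' Simulate MTT dose-response viability tables
#'
#' Responses follow each cell line's true 4PL curve (or a dose-independent
#' level for flat-flagged resistant lines) plus Gaussian noise. The default
#' dose series is a 5-fold trametinib dilution from 250 nM down to 16 pM plus
#' vehicle wells (dose 0).
#'
#' @param truth [truth_spec()] (uses `fourpl_params`).
#' @param doses molar dose series (>= 4 distinct positive values; a vehicle
#'   row at dose 0 is added if absent).
#' @param n_reps replicates per dose.
#' @param noise_sd Gaussian noise SD in response units (default 2, i.e. 2% of
#'   a 0-100 viability scale).
#' @param vehicle_log10 log10(micromolar) anchor for vehicle wells.
#' @return data.frame `cell_line, dose_molar, replicate, response`.
#' @export
simulate_dose_response <- function(truth,
                                   doses = 250e-9 / 5^(0:6),
                                   n_reps = 3, noise_sd = 2,
                                   vehicle_log10 = -5) {
  if (length(unique(doses[doses > 0])) < 4L) {
    stop_invalid("need >= 4 distinct positive doses (4 free parameters)")
  }
  if (!any(doses == 0)) doses <- c(0, doses)
  set.seed(split_seed(truth$seed, 6L))
  rows <- list()
  for (cl in names(truth$fourpl_params)) {
    p <- truth$fourpl_params[[cl]]
    x <- ifelse(doses == 0, vehicle_log10, log10(doses * 1e6))
    mu <- if (isTRUE(p$flat)) {
      rep(p$level %||% 100, length(doses))
    } else {
      fourpl(x, p$top, p$bottom, p$hill, log10(p$ic50 * 1e6))
    }
    for (r in seq_len(n_reps)) {
      rows[[length(rows) + 1L]] <-
        data.frame(cell_line = cl, dose_molar = doses, replicate = r,
                   response = mu + rnorm(length(doses), sd = noise_sd),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default gene-set fixtures (GMT content)
#'
#' Builds the curated-universe stand-ins used by the pipeline: an invasive
#' program (the implanted invasive block plus decoys), a MITF program, an
#' apoptosis set (switch genes plus decoy null genes) and its
#' negative-regulation counterpart (decoys only).
#'
#' @param truth [truth_spec()].
#' @return named list of character vectors, ready for [write_gmt()].
#' @export
make_gene_sets <- function(truth) {
  set.seed(split_seed(truth$seed, 8L))
  null_pool <- truth$gene_blocks$null
  decoys <- sample(null_pool, 90)
  list(invasive_program = c(truth$gene_blocks$invasive_up, decoys[1:20]),
       mitf_program = c(truth$gene_blocks$mitf, decoys[21:40]),
       apoptosis = c(truth$gene_blocks$switch_up, decoys[41:70]),
       apoptosis_neg_reg = decoys[61:90])
}

#' Write the complete fixture bundle to disk
#'
#' Generates every pipeline input (counts TSV + MTX, sample sheet, annotation,
#' per condition x antibody-replicate BED files, gene-set GMT, PWM file,
#' foreground/background FASTA, dose-response CSV) plus a `truth.json`
#' round-trippable record of the TruthSpec.
#'
#' @param truth [truth_spec()].
#' @param outdir output directory (created if missing).
#' @param design optional design (default [make_design()] on the truth's cell
#'   lines).
#' @return named list of paths (class `fixture_bundle`).
#' @export
write_fixture_bundle <- function(truth, outdir, design = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  design <- design %||% make_design(truth$cell_lines)
  paths <- list()
  ann <- make_annotation(truth$n_genes, n_chroms = 3, seed = truth$seed)
  sim <- simulate_counts(truth, design)
  paths$counts_tsv <- write_counts_tsv(sim$counts,
                                       file.path(outdir, "counts.tsv"))
  paths$counts_mtx <- write_counts_mtx(sim$counts,
                                       file.path(outdir, "counts.mtx"))
  paths$sample_sheet <- write_sample_sheet(sim$samples,
                                           file.path(outdir, "samples.csv"))
  paths$annotation <- file.path(outdir, "annotation.tsv")
  write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  peaks <- simulate_peaks(truth, ann)
  paths$peaks <- list()
  for (cond in names(peaks)) {
    for (rep in c("rep1", "rep2")) {
      p <- file.path(outdir, sprintf("peaks_%s_%s.bed", cond, rep))
      write_bed(peaks[[cond]][[rep]], p)
      paths$peaks[[paste(cond, rep, sep = "_")]] <- p
    }
  }
  sets <- make_gene_sets(truth)
  paths$gmt <- write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  smad_like <- pwm("SMAD_like",
                   counts = matrix(c(  # GTCTAGAC-like palindrome
                     2, 1, 1, 86, 2, 90, 4, 8,
                     4, 2, 88, 4, 3, 2, 88, 2,
                     88, 3, 5, 4, 88, 3, 3, 2,
                     6, 94, 6, 6, 7, 5, 5, 88), nrow = 4, byrow = TRUE))
  paths$pwm <- write_jaspar(list(SMAD_like = smad_like),
                            file.path(outdir, "motifs.jaspar"))
  cons <- reproducible_peaks(peaks$TGFB1_MEKI$rep1, peaks$TGFB1_MEKI$rep2)
  seqs <- simulate_peak_sequences(cons, list(smad_like), truth)
  paths$fasta_fg <- write_fasta(seqs$foreground,
                                file.path(outdir, "peaks_fg.fasta"))
  paths$fasta_bg <- write_fasta(seqs$background,
                                file.path(outdir, "peaks_bg.fasta"))
  dr <- simulate_dose_response(truth)
  paths$dose_response <- write_dose_response(dr,
                                             file.path(outdir,
                                                       "dose_response.csv"))
  paths$truth <- file.path(outdir, "truth.json")
  tr <- unclass(truth)
  tr$effect_sizes <- lapply(tr$effect_sizes, as.list)  # keep names in JSON
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(paths, class = "fixture_bundle")
}

#' Reload a TruthSpec from its JSON record
#'
#' @param path `truth.json` written by [write_fixture_bundle()].
#' @return `truth_spec` object equal to the one written.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gene_blocks <- lapply(x$gene_blocks, as.character)
  x$effect_sizes <- lapply(x$effect_sizes, unlist)
  x$fourpl_params <- lapply(x$fourpl_params, as.list)
  x$seed <- as.integer(x$seed)
  structure(x, class = "truth_spec")
}
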