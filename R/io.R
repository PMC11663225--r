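## File formats used across the pipeline. Counts travel as TSV (gene symbol
## index column + one column per sample) or MatrixMarket MTX with row/col
## sidecars; gene sets as GMT; motifs as JASPAR 2016 text; sequences as FASTA;
## peaks as 6-column BED (see peaks.R); dose-response series as CSV.

#' Write a count matrix as TSV
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param path output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path file written by [write_counts_tsv()].
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix as MatrixMarket MTX plus name sidecars
#'
#' Writes `<path>` (MTX), `<path>.rownames` and `<path>.colnames`.
#'
#' @inheritParams write_counts_tsv
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rownames"))
  writeLines(colnames(counts), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a count matrix from MatrixMarket MTX plus name sidecars
#'
#' @param path MTX file written by [write_counts_mtx()].
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(paste0(path, ".rownames"))
  colnames(m) <- readLines(paste0(path, ".colnames"))
  m
}

#' Read / write the sample sheet
#'
#' CSV with columns `sample,cell_line,treatment,replicate`; `treatment` is one
#' of DMSO, TGFB1, MEKI, TGFB1_MEKI.
#'
#' @param samples data.frame with the four columns above.
#' @param path CSV file.
#' @export
write_sample_sheet <- function(samples, path) {
  stopifnot(all(c("sample", "cell_line", "treatment", "replicate") %in%
                  names(samples)))
  write.table(samples, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  bad <- setdiff(unique(s$treatment), TREATMENTS)
  if (length(bad)) {
    stop_invalid("unknown treatment label(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return named list of character vectors (symbols normalised).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_invalid("malformed GMT line: ", substr(l, 1, 40))
    norm_symbols(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description column content (recycled).
#' @export
write_gmt <- function(sets, path, description = "switchsig") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read position weight matrices from JASPAR 2016 text
#'
#' Parses the plain-text JASPAR format: a `>ID NAME` header followed by four
#' rows `A [ counts... ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional).
#' Counts are converted to per-column probabilities with a pseudocount and
#' clipped below at `pseudo`.
#'
#' @param path JASPAR text file.
#' @param background base frequencies used later for log-odds (default uniform).
#' @param pseudo probability floor applied before log-odds scoring.
#' @return named list of `pwm` objects (fields `name`, `mat` 4 x L probability
#'   matrix with rows A,C,G,T, `background`).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudo = 1e-4) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop_invalid("no JASPAR records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(hdr), function(i) {
    block <- lines[(hdr[i] + 1L):ends[i]]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1L) stop_invalid("missing ", b, " row in JASPAR record")
      toks <- strsplit(gsub("[^0-9eE+. -]", " ", sub("^.", "", ln)),
                       "\\s+")[[1]]
      as.numeric(toks[nzchar(toks)])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L) stop_invalid("ragged JASPAR matrix")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    name <- sub("^>\\s*", "", lines[hdr[i]])
    pwm(name = name, counts = counts, background = background, pseudo = pseudo)
  })
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  pwms
}

#' Construct a PWM object from a count or probability matrix
#'
#' @param name motif name.
#' @param counts 4 x L matrix (rows A,C,G,T) of counts or probabilities.
#' @param background length-4 base frequencies.
#' @param pseudo probability floor.
#' @return object of class `pwm`.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4), pseudo = 1e-4) {
  stopifnot(nrow(counts) == 4L, all(counts >= 0), length(background) == 4L,
            abs(sum(background) - 1) < 1e-6)
  mat <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  mat <- pmax(mat, pseudo)
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  bad <- abs(colSums(mat) - 1) > 1e-6
  if (any(bad)) stop_invalid("PWM columns do not sum to 1")
  structure(list(name = name, mat = mat, background = background),
            class = "pwm")
}

#' Write PWMs in JASPAR 2016 text format
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @param scale probabilities are written as pseudo-counts `round(p * scale)`.
#' @export
write_jaspar <- function(pwms, path, scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(round(p$mat[b, ] * scale), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read / write DNA sequence sets (FASTA)
#'
#' Thin wrappers around Biostrings so the rest of the package trades in
#' `DNAStringSet` objects.
#'
#' @param path FASTA file.
#' @param seqs named `DNAStringSet` or named character vector.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write dose-response viability tables
#'
#' CSV with columns `cell_line,dose_molar,replicate,response`; `dose_molar = 0`
#' marks vehicle (DMSO) wells.
#'
#' @param dr data.frame with those columns.
#' @param path CSV file.
#' @export
write_dose_response <- function(dr, path) {
  stopifnot(all(c("cell_line", "dose_molar", "replicate", "response") %in%
                  names(dr)))
  write.table(dr, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
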