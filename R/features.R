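#' Amino-acid composition (AC) of a sequence
#'
#' The 20-dimensional vector of residue fractions: entry *i* is the count of
#' residue *i* divided by the sequence length.  Entries are ordered by the
#' alphabetical one-letter alphabet ([aa_alphabet()]) and sum to 1.
#'
#' @param residues A validated residue string.
#' @return Named numeric vector of length 20 with attribute `method = "AC"`.
#' @export
#' @examples
#' amino_acid_composition("AAC")[c("A", "C")]  # 2/3, 1/3
amino_acid_composition <- function(residues) {
  if (!nzchar(residues)) stop_pgact("empty sequence")
  ch <- seq_chars(residues)
  v <- as.numeric(table(factor(ch, levels = AA20))) / length(ch)
  structure(stats::setNames(v, AA20), method = "AC")
}

#' Dipeptide composition (DC) of a sequence
#'
#' The 400-dimensional vector of overlapping adjacent residue-pair fractions:
#' entry (a, b) is the count of the pair `ab` among the L-1 adjacent pairs,
#' divided by L-1.  Pairs are ordered row-major alphabetically (AA, AC, ...,
#' AY, CA, ..., YY) and sum to 1.
#'
#' @param residues A validated residue string of length at least 2.
#' @return Named numeric vector of length 400 with attribute `method = "DC"`.
#' @export
#' @examples
#' dipeptide_composition("ACA")[c("AC", "CA")]  # 0.5, 0.5
dipeptide_composition <- function(residues) {
  L <- nchar(residues)
  if (L < 2) stop_pgact("dipeptide composition needs at least 2 residues")
  ch <- seq_chars(residues)
  i1 <- match(ch[-L], AA20)
  i2 <- match(ch[-1], AA20)
  idx <- (i1 - 1L) * 20L + i2
  v <- tabulate(idx, nbins = 400L) / (L - 1L)
  structure(stats::setNames(v, dipeptide_names()), method = "DC")
}

#' Hybrid composition (AC + DC) of a sequence
#'
#' Concatenation of the amino-acid composition (20) and dipeptide composition
#' (400) vectors, giving 420 dimensions.
#'
#' @inheritParams dipeptide_composition
#' @return Named numeric vector of length 420 with attribute `method = "HYBRID"`.
#' @export
hybrid_composition <- function(residues) {
  v <- c(amino_acid_composition(residues), dipeptide_composition(residues))
  structure(v, method = "HYBRID")
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' position holding the position index, the query (consensus) residue and 20
#' integer log-odds columns (the trailing weighted-percentage columns and
#' statistics are ignored).  Columns are reported in PSI-BLAST residue order.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A `pga_pssm` list with `scores` (L x 20 integer matrix, columns
#'   named in PSI-BLAST order) and `consensus` (length-L residue string).
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop_pgact("cannot read PSSM file: ", path)
  lines <- readLines(path, warn = FALSE)
  # the column-header line carries at least 20 single-letter residue fields
  is_header <- vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 20 && all(f %in% c(AA20, "*"))
  }, TRUE, USE.NAMES = FALSE)
  hdr <- which(is_header)[1]
  if (is.na(hdr)) stop_pgact("no PSSM column header found in ", path)
  col_order <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][1:20]
  rows <- list()
  consensus <- character(0)
  for (ln in seq(hdr + 1, length(lines))) {
    l <- trimws(lines[ln])
    if (!nzchar(l)) break
    f <- strsplit(l, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(f[1])))) break  # trailing statistics
    if (length(f) < 22)
      stop_pgact("malformed PSSM row at line ", ln, ": expected at least 22 ",
                 "fields, got ", length(f))
    sc <- suppressWarnings(as.integer(f[3:22]))
    if (anyNA(sc))
      stop_pgact("malformed PSSM row at line ", ln, ": non-integer score")
    rows[[length(rows) + 1]] <- sc
    consensus <- c(consensus, f[2])
  }
  if (length(rows) == 0) stop_pgact("no PSSM rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  structure(list(scores = scores, consensus = paste(consensus, collapse = "")),
            class = "pga_pssm")
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Used to materialise mock or externally computed profiles in the same
#' format [parse_pssm()] reads; round-trips exactly.
#'
#' @param pssm A `pga_pssm` object.
#' @param path Output path.
#' @export
write_pssm <- function(pssm, path) {
  scores <- pssm$scores
  cons <- seq_chars(pssm$consensus)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down,",
                     "information per position, and relative weight of",
                     "gapless real matches to pseudocounts")), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", colnames(scores)), collapse = " ")),
             con)
  for (p in seq_len(nrow(scores)))
    writeLines(paste0(sprintf("%5d %s ", p, cons[p]),
                      paste(sprintf("%3d", scores[p, ]), collapse = " ")), con)
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1340     0.3170"), con)
  invisible(path)
}

#' PSSM-profile composition of a sequence
#'
#' Each log-odds score *s* is squashed to the unit interval with the logistic
#' sigmoid 1/(1+exp(-s)); entry (a, b) of the 400-vector is the sum of the
#' squashed column-*b* scores over all positions whose sequence residue is
#' *a*, divided by the sequence length.  Rows of residues absent from the
#' sequence are exactly zero, and every entry lies in `[0, 1]`.
#'
#' @param pssm A `pga_pssm` whose row count equals the sequence length.
#' @param residues The corresponding residue string.
#' @return Named numeric vector of length 400 (rows and columns alphabetical)
#'   with attribute `method = "PSSM"`.
#' @export
pssm_composition <- function(pssm, residues) {
  L <- nchar(residues)
  if (nrow(pssm$scores) != L)
    stop_pgact("PSSM has ", nrow(pssm$scores), " rows but sequence has ",
               L, " residues")
  sig <- 1 / (1 + exp(-pssm$scores))
  # reorder columns from the file's order to the package alphabet
  sig <- sig[, AA20, drop = FALSE]
  ch <- seq_chars(residues)
  out <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (a in unique(ch)) {
    rows <- which(ch == a)
    out[a, ] <- colSums(sig[rows, , drop = FALSE]) / L
  }
  structure(stats::setNames(as.vector(t(out)), dipeptide_names()),
            method = "PSSM")
}

#' Obtain a PSSM profile for a sequence
#'
#' Three modes:
#' \describe{
#'   \item{mock}{a deterministic, seeded profile needing no external tools:
#'     integer scores uniform in \[-5, 5\] with +4 added to the column of the
#'     position's own residue, so the full PSSM pipeline is testable offline;}
#'   \item{precomputed}{looks up `<id>.pssm` in `dir` and parses it;}
#'   \item{external}{runs PSI-BLAST (`psiblast`, 3 iterations, e-value 0.001)
#'     against the database `db` and parses the resulting ASCII PSSM.}
#' }
#'
#' @param id Sequence identifier.
#' @param residues Residue string.
#' @param mode One of `"mock"`, `"precomputed"`, `"external"`.
#' @param dir Profile directory for `precomputed` mode.
#' @param db BLAST database path for `external` mode.
#' @param seed Integer seed for `mock` mode.
#' @param exe PSI-BLAST executable name/path for `external` mode.
#' @return A `pga_pssm`.
#' @export
pssm_provider <- function(id, residues,
                          mode = c("mock", "precomputed", "external"),
                          dir = NULL, db = NULL, seed = 1,
                          exe = "psiblast") {
  mode <- match.arg(mode)
  if (mode == "mock") return(mock_pssm(residues, seed = seed))
  if (mode == "precomputed") {
    if (is.null(dir))
      stop_pgact("precomputed mode needs a profile directory; pass dir=")
    path <- file.path(dir, paste0(id, ".pssm"))
    if (!file.exists(path))
      stop_pgact("no precomputed profile for '", id, "': expected ", path,
                 " (generate it with psiblast -out_ascii_pssm, or use mock mode)")
    return(parse_pssm(path))
  }
  if (Sys.which(exe) == "")
    stop_pgact("PSI-BLAST executable '", exe, "' not found; install BLAST+ ",
               "or use precomputed/mock mode")
  if (is.null(db))
    stop_pgact("external mode needs a BLAST protein database; pass db= ",
               "(e.g. a local copy of nr)")
  qf <- tempfile(fileext = ".fasta")
  pf <- tempfile(fileext = ".pssm")
  on.exit(unlink(c(qf, pf)))
  writeLines(c(paste0(">", id), residues), qf)
  status <- system2(exe, c("-query", qf, "-db", db,
                           "-num_iterations", "3", "-evalue", "0.001",
                           "-out_ascii_pssm", pf, "-out", tempfile()),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(pf))
    stop_pgact("psiblast failed (exit ", status, ") for sequence '", id, "'")
  parse_pssm(pf)
}

#' @rdname pssm_provider
#' @export
mock_pssm <- function(residues, seed = 1) {
  L <- nchar(residues)
  if (L < 1) stop_pgact("empty sequence")
  ch <- seq_chars(residues)
  scores <- with_seed(seed, {
    m <- matrix(sample(-5:5, L * 20, replace = TRUE), L, 20)
    m
  })
  colnames(scores) <- PSIBLAST_ORDER
  own <- match(ch, PSIBLAST_ORDER)
  scores[cbind(seq_len(L), own)] <- scores[cbind(seq_len(L), own)] + 4L
  structure(list(scores = scores, consensus = residues), class = "pga_pssm")
}

#' Encode a dataset as a feature matrix
#'
#' @param data A `pga_dataset`.
#' @param method One of `"AC"`, `"DC"`, `"PSSM"`, `"HYBRID"`.
#' @param pssm For `method = "PSSM"`: either a named list of `pga_pssm`
#'   objects keyed by sequence id, a directory of precomputed `<id>.pssm`
#'   files, or `"mock"` (the default) for seeded offline profiles.
#' @param seed Seed used when `pssm = "mock"`; each sequence gets a profile
#'   seeded by `seed` plus its rank in the dataset.
#' @return Numeric matrix (sequences x features) with rownames `data$id` and
#'   attribute `method`.
#' @export
feature_matrix <- function(data, method = c("AC", "DC", "PSSM", "HYBRID"),
                           pssm = "mock", seed = 1) {
  method <- match.arg(method)
  enc <- switch(method,
    AC = function(i) amino_acid_composition(data$residues[[i]]),
    DC = function(i) dipeptide_composition(data$residues[[i]]),
    HYBRID = function(i) hybrid_composition(data$residues[[i]]),
    PSSM = function(i) {
      prof <- if (is.list(pssm) && !inherits(pssm, "pga_pssm")) {
        p <- pssm[[data$id[[i]]]]
        if (is.null(p)) stop_pgact("no PSSM profile supplied for '",
                                   data$id[[i]], "'")
        p
      } else if (is.character(pssm) && pssm[1] == "mock") {
        mock_pssm(data$residues[[i]], seed = seed + i)
      } else if (is.character(pssm)) {
        pssm_provider(data$id[[i]], data$residues[[i]], "precomputed",
                      dir = pssm)
      } else stop_pgact("invalid 'pssm' argument")
      pssm_composition(prof, data$residues[[i]])
    })
  rows <- lapply(seq_len(nrow(data)), enc)
  m <- do.call(rbind, rows)
  rownames(m) <- data$id
  attr(m, "method") <- method
  m
}

#' Write a feature matrix as TSV or SVM-light sparse format
#'
#' The TSV layout is one row per sequence: id then the feature values.  The
#' SVM-light layout is `<label> <index>:<value> ...` with 1-based indices and
#' zero entries omitted; labels default to +1.
#'
#' @param x Feature matrix from [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @param labels Numeric labels (+1/-1) per row for the SVM-light file.
#' @export
write_svmlight <- function(x, path, labels = rep(1, nrow(x))) {
  if (length(labels) != nrow(x)) stop_pgact("one label per row required")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    nz <- which(x[i, ] != 0)
    paste(sprintf("%+d", as.integer(labels[i])),
          paste(sprintf("%d:%.10g", nz, x[i, nz]), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
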