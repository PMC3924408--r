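#' Assemble a protein sequence dataset
#'
#' The package represents a set of protein sequences as a plain data frame
#' with columns `id`, `description`, `residues` and (optionally) `label`,
#' carrying class `pga_dataset`.  Labels, when present, must be one of
#' `SAK`, `SK`, `tPA`, `UK` (the four plasminogen-activator subfamilies) or
#' `NEG` (non-activator).
#'
#' @param id Character vector of unique, non-empty sequence identifiers.
#' @param residues Character vector of residue strings over the 20 standard
#'   one-letter codes (see [validate_sequence()]).
#' @param description Optional free-text descriptions (default `""`).
#' @param label Optional label vector, one of `r paste(ALL_LABELS, collapse = ", ")`.
#' @param validate Validation policy passed to [validate_sequence()], or
#'   `NULL` to accept the residues as given (they must already be valid).
#' @return A `pga_dataset` data frame.
#' @export
#' @examples
#' pga_dataset(c("a", "b"), c("ACDE", "MKLV"), label = c("SK", "NEG"))
pga_dataset <- function(id, residues, description = "", label = NULL,
                        validate = "strict") {
  id <- as.character(id)
  residues <- as.character(residues)
  if (length(id) != length(residues))
    stop_pgact("'id' and 'residues' must have the same length")
  if (any(!nzchar(id))) stop_pgact("sequence ids must be non-empty")
  if (anyDuplicated(id))
    stop_pgact("duplicate sequence ids: ",
               paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!is.null(validate))
    residues <- vapply(residues, validate_sequence, "", policy = validate,
                       USE.NAMES = FALSE)
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != length(id))
      stop_pgact("'label' must match the number of sequences")
    bad <- setdiff(unique(label), ALL_LABELS)
    if (length(bad) > 0)
      stop_pgact("unknown labels: ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(ALL_LABELS, collapse = ", "), ")")
    out$label <- label
  }
  class(out) <- c("pga_dataset", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Multi-line record bodies are concatenated; the header token before the
#' first whitespace becomes the id, the remainder the description.  Record
#' order is preserved.
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @param policy Residue validation policy, see [validate_sequence()].
#' @return A `pga_dataset` (no `label` column).
#' @export
read_fasta <- function(path, policy = "map") {
  if (!file.exists(path)) stop_pgact("cannot read FASTA file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_pgact("failed to parse FASTA '",
                                                 path, "': ", conditionMessage(e)))
  if (length(set) == 0)
    return(pga_dataset(character(), character(), validate = NULL))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- as.character(set)
  empty <- !nzchar(residues)
  if (any(empty))
    stop_pgact("FASTA record with empty body: ",
               paste(id[empty], collapse = ", "))
  pga_dataset(id, residues, description, validate = policy)
}

#' Write a dataset to a FASTA file
#'
#' @param data A `pga_dataset` (or data frame with `id` and `residues`).
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60) {
  set <- Biostrings::BStringSet(data$residues)
  names(set) <- ifelse(nzchar(data$description %||% ""),
                       paste(data$id, data$description), data$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and normalise a raw residue string
#'
#' Input is uppercased, then characters outside the 20 standard one-letter
#' codes are handled according to `policy`:
#' \describe{
#'   \item{strict}{any non-standard character is an error;}
#'   \item{drop}{non-standard characters are removed;}
#'   \item{map}{common ambiguity codes are resolved to a representative
#'     residue (B→D, Z→E, U→C, J→L, O→K), X and anything else is dropped.}
#' }
#' Whitespace is always removed before applying the policy.
#'
#' @param raw Raw sequence string.
#' @param policy One of `"strict"`, `"drop"`, `"map"` (default `"strict"`).
#' @return The validated residue string.
#' @export
#' @examples
#' validate_sequence("acde")             # "ACDE"
#' validate_sequence("ACXDE", "drop")    # "ACDE"
#' validate_sequence("ABZ", "map")       # "ADE"
validate_sequence <- function(raw, policy = c("strict", "drop", "map")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw))
    stop_pgact("sequence must be a non-empty string")
  s <- gsub("\\s+", "", toupper(raw))
  ch <- seq_chars(s)
  ok <- ch %in% AA20
  if (policy == "strict") {
    if (any(!ok)) {
      p <- which(!ok)[1]
      stop_pgact("invalid residue '", ch[p], "' at position ", p)
    }
  } else if (policy == "drop") {
    ch <- ch[ok]
  } else {
    map <- c(B = "D", Z = "E", U = "C", J = "L", O = "K")
    amb <- !ok & ch %in% names(map)
    ch[amb] <- map[ch[amb]]
    ch <- ch[ch %in% AA20]
  }
  out <- paste(ch, collapse = "")
  if (!nzchar(out))
    stop_pgact("sequence empty after validation (policy '", policy, "')")
  out
}

#' Pairwise ungapped sequence identity
#'
#' The shorter sequence is slid without gaps along the longer one; identity is
#' the maximal number of matching positions over all offsets, divided by the
#' shorter sequence's length (the CD-HIT convention).
#'
#' @param a,b Residue strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDE")  # 1
#' pairwise_identity("ACD", "XXACDXX")
pairwise_identity <- function(a, b) .ungapped_identity(a, b)

#' Greedy redundancy reduction at an identity threshold
#'
#' Mimics the net effect of CD-HIT: sequences are sorted longest first and
#' each sequence joins the cluster of the first retained representative with
#' pairwise identity strictly above `threshold`, otherwise it becomes a new
#' representative.  Only representatives are returned, in length rank order.
#'
#' @param data A `pga_dataset`.
#' @param threshold Identity fraction in `(0, 1]`; default 0.90, matching the
#'   common curation rule of removing >90\%-identical sequences.
#' @return The filtered `pga_dataset` of cluster representatives.
#' @export
reduce_redundancy <- function(data, threshold = 0.90) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop_pgact("'threshold' must be in (0, 1]")
  n <- nrow(data)
  if (n == 0) return(data)
  ord <- order(-nchar(data$residues))
  reps <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (r in reps) {
      idt <- .ungapped_identity(data$residues[[i]], data$residues[[r]])
      # exact matches always collapse, so threshold 1.0 still removes duplicates
      if (idt > threshold || idt == 1) {
        dup <- TRUE
        break
      }
    }
    if (!dup) reps <- c(reps, i)
  }
  out <- data[reps, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pga_dataset", "data.frame")
  out
}

#' Basic statistics of a protein sequence
#'
#' Molecular weight (sum of average residue masses plus one water, 18.0153
#' Da), residue counts and percentage composition.
#'
#' @param residues A validated residue string.
#' @return A list with `molecular_weight` (daltons), `residue_counts`
#'   (named integer vector over the 20 residues) and `composition_percent`
#'   (named numeric vector summing to 100).
#' @export
#' @examples
#' compute_stats("G")$molecular_weight  # 75.0672
compute_stats <- function(residues) {
  residues <- validate_sequence(residues, "strict")
  ch <- seq_chars(residues)
  counts <- table(factor(ch, levels = AA20))
  counts <- stats::setNames(as.integer(counts), AA20)
  list(molecular_weight = sum(AA_MASS[AA20] * counts) + WATER_MASS,
       residue_counts = counts,
       composition_percent = 100 * counts / length(ch))
}

#' Per-sequence statistics table for a dataset
#'
#' @param data A `pga_dataset`.
#' @return Data frame with one row per sequence: `id`, `length`,
#'   `molecular_weight`, and twenty `pct_<residue>` composition columns.
#' @export
seq_stats <- function(data) {
  cols <- c("id", "length", "molecular_weight", paste0("pct_", AA20))
  if (nrow(data) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(cols) - 1)), cols))
    return(out)
  }
  rows <- lapply(seq_len(nrow(data)), function(i) {
    st <- compute_stats(data$residues[[i]])
    c(list(id = data$id[[i]],
           length = nchar(data$residues[[i]]),
           molecular_weight = st$molecular_weight),
      as.list(stats::setNames(st$composition_percent, paste0("pct_", AA20))))
  })
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Read or write a label manifest
#'
#' The manifest is a two-column tab-separated file (`id`, `label`) with no
#' header, assigning each sequence one of
#' `r paste(ALL_LABELS, collapse = ", ")`.
#'
#' @param path Manifest path.
#' @return `read_labels`: named character vector of labels keyed by id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_pgact("cannot read label manifest: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           col.names = c("id", "label"))
  bad <- setdiff(unique(tab$label), ALL_LABELS)
  if (length(bad) > 0)
    stop_pgact("unknown labels in manifest: ", paste(bad, collapse = ", "))
  stats::setNames(tab$label, tab$id)
}

#' @rdname read_labels
#' @param data A labelled `pga_dataset`.
#' @export
write_labels <- function(data, path) {
  if (is.null(data$label)) stop_pgact("dataset has no labels")
  utils::write.table(data.frame(data$id, data$label), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach manifest labels to a dataset
#'
#' @param data A `pga_dataset`.
#' @param labels Named label vector as returned by [read_labels()].
#' @return The dataset with a `label` column.
#' @export
attach_labels <- function(data, labels) {
  missing <- setdiff(data$id, names(labels))
  if (length(missing) > 0)
    stop_pgact("no label for sequence id(s): ",
               paste(utils::head(missing, 5), collapse = ", "))
  pga_dataset(data$id, data$residues, data$description,
              label = unname(labels[data$id]), validate = NULL)
}

#' @export
print.pga_dataset <- function(x, ...) {
  cat("pga_dataset with", nrow(x), "sequence(s)\n")
  if (!is.null(x$label) && nrow(x) > 0) {
    tab <- table(factor(x$label, levels = ALL_LABELS))
    cat("labels:", paste(names(tab), as.integer(tab), sep = "=", collapse = " "),
        "\n")
  }
  if (nrow(x) > 0) {
    len <- nchar(x$residues)
    cat("length range:", min(len), "-", max(len), "residues\n")
  }
  invisible(x)
}
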