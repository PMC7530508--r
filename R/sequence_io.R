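#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a named character vector of upper-cased
#' sequences. The record id is the description line up to the first
#' whitespace; wrapped sequence lines are concatenated. Records containing
#' characters outside the 20-letter amino-acid alphabet are handled
#' according to `policy`:
#'
#' * `"reject"` (default): the whole record is dropped, with a warning
#'   giving the number of affected records. All four encoders assume the
#'   20-letter alphabet, and silently coercing non-standard residues
#'   (B, J, O, U, X, Z, gaps, stops) would distort composition frequencies.
#' * `"strip"`: invalid characters are removed from the sequence, with a
#'   warning. A record stripped to length zero is dropped.
#'
#' @param path Path to a FASTA file.
#' @param policy Either `"reject"` or `"strip"`; see Details.
#' @return Named character vector of validated sequences (names are record
#'   ids), with class `"protein_records"`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "ACDE", ">p2", "ghik"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, policy = c("reject", "strip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate record id(s) in FASTA: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_records(seqs, policy = policy)
}

#' Validate protein records against the 20-letter alphabet
#'
#' @param records Named character vector of sequences.
#' @param policy `"reject"` drops offending records, `"strip"` removes the
#'   offending characters (see [read_fasta()]).
#' @return Named character vector of valid records, class `"protein_records"`.
#'   Validation is idempotent: already-valid records pass unchanged.
#' @export
validate_records <- function(records, policy = c("reject", "strip")) {
  policy <- match.arg(policy)
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be named by id", call. = FALSE)
  pat <- paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]")
  bad <- grepl(pat, records)
  if (any(bad)) {
    if (policy == "reject") {
      warning(sum(bad), " record(s) rejected for residues outside the ",
              "20-letter alphabet: ", paste(utils::head(names(records)[bad], 5L),
                                            collapse = ", "),
              if (sum(bad) > 5L) ", ..." else "", call. = FALSE)
      records <- records[!bad]
    } else {
      warning(sum(bad), " record(s) had invalid residues stripped",
              call. = FALSE)
      records[bad] <- gsub(pat, "", records[bad])
    }
  }
  empty <- !nzchar(records)
  if (any(empty)) {
    warning(sum(empty), " empty record(s) dropped", call. = FALSE)
    records <- records[!empty]
  }
  if (length(records) == 0L)
    stop("no valid records remain after validation", call. = FALSE)
  structure(records, class = "protein_records")
}

#' Write protein records to a FASTA file
#'
#' @param records Named character vector of sequences (or a
#'   [labeled_dataset]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "labeled_dataset")) records <- records$records
  set <- Biostrings::BStringSet(unclass(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column tab-separated id-to-label map
#'
#' Each row is `id<TAB>label`. Duplicate rows with identical labels collapse
#' to one entry; duplicate ids with conflicting labels are an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping id to family label.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read label file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("label file is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L))
    stop("malformed label row (expected 2 tab-separated fields) at line ",
         which(nfield != 2L)[1L], call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  labs <- vapply(parts, `[[`, "", 2L)
  first <- !duplicated(ids)
  ref <- stats::setNames(labs[first], ids[first])
  conflict <- labs != ref[ids]
  if (any(conflict))
    stop("conflicting labels for id(s): ",
         paste(unique(ids[conflict]), collapse = ", "), call. = FALSE)
  ref
}

#' Write an id-to-label map as a two-column TSV
#'
#' @param labels Named character vector (or a [labeled_dataset]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "labeled_dataset"))
    labels <- stats::setNames(as.character(labels$labels), names(labels$records))
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}

#' Assemble a labeled dataset from records and a label map
#'
#' @param records Named character vector of validated sequences
#'   ([read_fasta()] output).
#' @param label_map Named character vector mapping every record id to its
#'   family label ([read_labels()] output).
#' @return An object of class `"labeled_dataset"`: a list with `records`
#'   (named character vector, order preserved), `labels` (factor, levels =
#'   sorted distinct labels) and `label_set`.
#' @export
build_dataset <- function(records, label_map) {
  if (length(records) == 0L) stop("no records supplied", call. = FALSE)
  ids <- names(records)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  missing <- setdiff(ids, names(label_map))
  if (length(missing) > 0L)
    stop("no label for record id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lab <- as.character(label_map[ids])
  label_set <- sort(unique(lab))
  structure(list(records = structure(as.character(records), names = ids,
                                     class = "protein_records"),
                 labels = factor(lab, levels = label_set),
                 label_set = label_set),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$records), "sequences,",
      length(x$label_set), "families\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records:", length(x), "sequences, lengths",
      min(nchar(x)), "-", max(nchar(x)), "\n")
  invisible(x)
}
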