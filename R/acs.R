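#' Construct an averaged-chemical-shift lookup table
#'
#' An ACS table maps every residue of the 20-letter alphabet to an averaged
#' chemical shift (ppm) for each of the four backbone nuclei 15N, 13Ca, 1Ha
#' and 1HN. It is the per-residue substitution used by the PseACS encoder.
#'
#' @param shifts A numeric matrix or data frame with one row per residue
#'   (rownames = residues) and columns `N15`, `C13a`, `H1a`, `H1N`.
#' @return An object of class `"acs_table"`: a 20 x 4 numeric matrix with
#'   rows in alphabetical residue order and columns in nucleus order.
#' @export
acs_table <- function(shifts) {
  shifts <- as.matrix(shifts)
  if (is.null(rownames(shifts)))
    stop("ACS table needs residue rownames", call. = FALSE)
  missing_res <- setdiff(AA_ALPHABET20, rownames(shifts))
  if (length(missing_res) > 0L)
    stop("ACS table is missing residue(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  missing_nuc <- setdiff(ACS_NUCLEI, colnames(shifts))
  if (length(missing_nuc) > 0L)
    stop("ACS table is missing nucleus column(s): ",
         paste(missing_nuc, collapse = ", "), call. = FALSE)
  m <- shifts[AA_ALPHABET20, ACS_NUCLEI, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("ACS table contains non-finite values", call. = FALSE)
  structure(m, class = c("acs_table", "matrix", "array"))
}

#' Read an averaged-chemical-shift table from TSV
#'
#' Expected format: a header line `residue<TAB>N15<TAB>C13a<TAB>H1a<TAB>H1N`
#' followed by one row per residue; lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return An [acs_table()].
#' @export
read_acs_table <- function(path) {
  if (!file.exists(path)) stop("cannot read ACS table: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"residue" %in% names(df))
    stop("ACS table TSV needs a 'residue' column", call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "residue")])
  rownames(m) <- df$residue
  acs_table(m)
}

#' Write an averaged-chemical-shift table to TSV
#'
#' @param table An [acs_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acs_table <- function(table, path) {
  df <- data.frame(residue = rownames(table), unclass(table)[, ACS_NUCLEI],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled default averaged-chemical-shift table
#'
#' Representative averaged backbone chemical shifts (ppm) per residue for
#' 15N, 13Ca, 1Ha and 1HN, compiled as synthetic stand-in values in the
#' range of public BMRB statistics (see the header of
#' `inst/extdata/acs_table_synthetic_default.tsv` for provenance notes).
#' Override with [read_acs_table()] when a calibrated table is available.
#' PseACS lag features are invariant to any constant offset of the table,
#' so only the between-residue contrasts matter.
#'
#' @return An [acs_table()].
#' @export
default_acs_table <- function() {
  path <- system.file("extdata", "acs_table_synthetic_default.tsv",
                      package = "hspfam", mustWork = TRUE)
  read_acs_table(path)
}

#' Build a toy ACS table with known arithmetic, for tests and examples
#'
#' @param values Either a named numeric vector over the 20 residues (the
#'   same value is used for all four nuclei) or a complete 20 x 4 matrix.
#' @return An [acs_table()].
#' @examples
#' toy_acs_table(setNames(1:20, AA_ALPHABET20))
#' @export
toy_acs_table <- function(values) {
  if (is.matrix(values) || is.data.frame(values)) return(acs_table(values))
  if (is.null(names(values)))
    stop("toy ACS values must be named by residue", call. = FALSE)
  missing_res <- setdiff(AA_ALPHABET20, names(values))
  if (length(missing_res) > 0L)
    stop("toy ACS table is missing residue(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  m <- matrix(rep(as.numeric(values[AA_ALPHABET20]), times = 4L),
              ncol = 4L, dimnames = list(AA_ALPHABET20, ACS_NUCLEI))
  acs_table(m)
}
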