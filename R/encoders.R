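#' Golden-ratio segmentation of a sequence
#'
#' Recursively splits the interval `[0, L)` into N-terminal and C-terminal
#' segments whose length ratio is the golden ratio phi = (1 + sqrt(5)) / 2:
#' a parent of length l splits as `L_N = round(l / phi)` (round half up) and
#' `L_C = l - L_N`. At depth `d` this yields `2^d` contiguous,
#' non-overlapping segments covering the whole sequence, labelled by their
#' N/C path (depth 1: `N`, `C`; depth 2: `NN`, `NC`, `CN`, `CC`; ...).
#'
#' Because the split is uneven, the shortest admissible `L` grows faster
#' than `2^depth` (e.g. depth 3 requires L >= 9, not 8: an L of 8 leaves a
#' depth-2 segment of length 1 that cannot be split further).
#'
#' @param L Sequence length.
#' @param depth Number of recursive split steps (1 gives the plain N/C
#'   split).
#' @return Integer matrix with `2^depth` rows (named by segment label) and
#'   columns `start`, `end`: 0-based half-open coordinates.
#' @examples
#' golden_split(10, 1)  # (0,6) and (6,10)
#' @export
golden_split <- function(L, depth = 1L) {
  L <- as.integer(L)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (L < min_golden_length(depth))
    stop("sequence length ", L, " is too short for golden-ratio depth ",
         depth, "; minimum length is ", min_golden_length(depth),
         call. = FALSE)
  segs <- data.frame(start = 0L, end = L, label = "",
                     stringsAsFactors = FALSE)
  for (d in seq_len(depth)) {
    len <- segs$end - segs$start
    ln <- as.integer(floor(len / PHI + 0.5))
    segs <- data.frame(
      start = as.vector(rbind(segs$start, segs$start + ln)),
      end = as.vector(rbind(segs$start + ln, segs$end)),
      label = as.vector(rbind(paste0(segs$label, "N"),
                              paste0(segs$label, "C"))),
      stringsAsFactors = FALSE)
  }
  out <- cbind(start = segs$start, end = segs$end)
  rownames(out) <- segs$label
  out
}

# smallest L for which every leaf segment at `depth` is non-empty; found by
# direct search (split lengths are monotone in L, so the first success is
# the minimum)
min_golden_length <- function(depth) {
  for (L in seq.int(2L^depth, 4L^depth)) {
    ok <- tryCatch({
      segs <- data.frame(start = 0L, end = L)
      for (d in seq_len(depth)) {
        len <- segs$end - segs$start
        if (any(len < 2L)) stop("short")
        ln <- as.integer(floor(len / PHI + 0.5))
        segs <- data.frame(start = as.vector(rbind(segs$start, segs$start + ln)),
                           end = as.vector(rbind(segs$start + ln, segs$end)))
      }
      all(segs$end - segs$start >= 1L)
    }, error = function(e) FALSE)
    if (ok) return(L)
  }
  stop("no feasible length found for depth ", depth, call. = FALSE)
}

#' Split amino acid composition (SAAC) with golden-ratio segmentation
#'
#' Computes, for every golden-ratio segment of the sequence, the 20 residue
#' frequencies `W_i / L_segment` in alphabetical residue order, and
#' concatenates the segments N-before-C recursively. The feature length is
#' `20 * 2^depth` (40 at the default depth 1).
#'
#' @param sequence Character scalar over the 20-letter alphabet.
#' @param depth Golden-split depth; see [golden_split()].
#' @return Named numeric vector, names `SAAC_<segment>_<residue>`. Each
#'   segment's 20 frequencies sum to 1.
#' @export
encode_saac <- function(sequence, depth = 1L) {
  idx <- seq_to_idx(sequence)
  segs <- golden_split(length(idx), depth)
  out <- numeric(0)
  for (r in seq_len(nrow(segs))) {
    sub <- idx[(segs[r, "start"] + 1L):segs[r, "end"]]
    out <- c(out, tabulate(sub, 20L) / length(sub))
  }
  names(out) <- paste0("SAAC_", rep(rownames(segs), each = 20L), "_",
                       rep(AA_ALPHABET20, times = nrow(segs)))
  out
}

#' Dipeptide composition (DC)
#'
#' Frequencies of the 400 ordered adjacent residue pairs,
#' `f_i = m_i / (L - 1)` where `m_i` counts occurrences of the i-th
#' dipeptide. Pairs are ordered first-residue-major with residues
#' alphabetical (AA, AC, ..., AY, CA, ..., YY).
#'
#' @param sequence Character scalar over the 20-letter alphabet, length >= 2.
#' @return Named numeric vector of length 400 (names `DC_<pair>`), summing
#'   to 1.
#' @export
encode_dc <- function(sequence) {
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L < 2L)
    stop("dipeptide composition needs sequence length >= 2", call. = FALSE)
  pair <- 20L * (idx[-L] - 1L) + idx[-1L]
  out <- tabulate(pair, 400L) / (L - 1L)
  names(out) <- paste0("DC_", rep(AA_ALPHABET20, each = 20L),
                       rep(AA_ALPHABET20, times = 20L))
  out
}

#' Conjoint-triad residue group
#'
#' Maps a residue to its conjoint-triad group (1-7). The 20 residues are
#' partitioned by side-chain dipole moment and volume into
#' \{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\},
#' \{C\}.
#'
#' @param residue Character vector of single-letter residues.
#' @return Integer vector of group indices in 1..7.
#' @examples
#' residue_group(c("A", "K", "C"))  # 1 5 7
#' @export
residue_group <- function(residue) {
  g <- CTF_GROUPS[residue]
  if (anyNA(g))
    stop("unknown residue(s): ",
         paste(unique(residue[is.na(g)]), collapse = ", "), call. = FALSE)
  unname(g)
}

#' Conjoint triad feature (CTF)
#'
#' Maps each residue to its 7-letter group ([residue_group()]) and counts
#' the `L - 2` windows of 3 consecutive residues, giving
#' `x_i = n_i / (L - 2)` over the 343 group triads in lexicographic order.
#'
#' @param sequence Character scalar over the 20-letter alphabet, length >= 3.
#' @return Named numeric vector of length 343 (names `CTF_<g1>_<g2>_<g3>`),
#'   summing to 1.
#' @export
encode_ctf <- function(sequence) {
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L < 3L)
    stop("conjoint triad feature needs sequence length >= 3", call. = FALSE)
  g <- unname(CTF_GROUPS[AA_ALPHABET20])[idx]
  tri <- 49L * (g[1:(L - 2L)] - 1L) + 7L * (g[2:(L - 1L)] - 1L) + g[3:L]
  out <- tabulate(tri, 343L) / (L - 2L)
  i <- seq_len(343L) - 1L
  names(out) <- paste0("CTF_", i %/% 49L + 1L, "_", (i %/% 7L) %% 7L + 1L,
                       "_", i %% 7L + 1L)
  out
}

#' Pseudo-average chemical shift (PseACS)
#'
#' Substitutes every residue by its averaged chemical shift for each
#' backbone nucleus (15N, 13Ca, 1Ha, 1HN in that order) and computes, per
#' nucleus, the lag features
#' `phi(lag) = mean over k of (A_k - A_{k+lag})^2` for `lag = 0 .. lambda`.
#' The block length is `4 * (lambda + 1)` (220 at the default
#' `lambda = 54`).
#'
#' The lag-0 term of the printed formula is identically zero; `tier0`
#' selects whether to emit that literal zero (default) or the mean shift of
#' the sequence, which carries composition information instead of a
#' constant.
#'
#' @param sequence Character scalar over the 20-letter alphabet, length
#'   `> lambda`.
#' @param table An [acs_table()]; defaults to the bundled table.
#' @param lambda Maximum lag (default 54).
#' @param tier0 `"literal"` or `"mean"`; see Details.
#' @return Named numeric vector of length `4 * (lambda + 1)`, names
#'   `PseACS_<nucleus>_lag<lag>`.
#' @export
encode_pseacs <- function(sequence, table = default_acs_table(),
                          lambda = 54L, tier0 = c("literal", "mean")) {
  tier0 <- match.arg(tier0)
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("lambda must be >= 1", call. = FALSE)
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L <= lambda)
    stop("PseACS with lambda = ", lambda, " requires sequence length > ",
         lambda, " (got ", L, ")", call. = FALSE)
  out <- numeric(4L * (lambda + 1L))
  pos <- 0L
  for (nuc in ACS_NUCLEI) {
    A <- unclass(table)[, nuc][idx]
    phi0 <- if (tier0 == "literal") 0 else mean(A)
    lagphi <- vapply(seq_len(lambda), function(l)
      mean((A[1:(L - l)] - A[(1L + l):L])^2), numeric(1))
    out[pos + seq_len(lambda + 1L)] <- c(phi0, lagphi)
    pos <- pos + lambda + 1L
  }
  names(out) <- paste0("PseACS_", rep(ACS_NUCLEI, each = lambda + 1L),
                       "_lag", rep(0:lambda, times = 4L))
  out
}

#' Combined feature encoding of one sequence
#'
#' Concatenates the enabled encoder blocks in the fixed order SAAC, DC,
#' CTF, PseACS. The default full combination has length
#' 40 + 400 + 343 + 220 = 1003.
#'
#' @param sequence Character scalar over the 20-letter alphabet.
#' @param encoders Character vector naming the enabled blocks, a subset of
#'   `c("saac", "dc", "ctf", "pseacs")`.
#' @param acs_table ACS lookup for the PseACS block.
#' @param saac_depth Golden-split depth for the SAAC block.
#' @param lambda,tier0 PseACS parameters; see [encode_pseacs()].
#' @return Named numeric vector with attribute `block_index`: a data frame
#'   with columns `block`, `offset` (0-based), `length`.
#' @export
encode_combined <- function(sequence,
                            encoders = c("saac", "dc", "ctf", "pseacs"),
                            acs_table = default_acs_table(),
                            saac_depth = 1L, lambda = 54L,
                            tier0 = c("literal", "mean")) {
  encoders <- match.arg(encoders, several.ok = TRUE)
  tier0 <- match.arg(tier0)
  order_all <- c("saac", "dc", "ctf", "pseacs")
  enabled <- order_all[order_all %in% encoders]
  vals <- numeric(0)
  blocks <- data.frame(block = character(0), offset = integer(0),
                       length = integer(0), stringsAsFactors = FALSE)
  for (enc in enabled) {
    v <- tryCatch(switch(enc,
      saac = encode_saac(sequence, depth = saac_depth),
      dc = encode_dc(sequence),
      ctf = encode_ctf(sequence),
      pseacs = encode_pseacs(sequence, table = acs_table, lambda = lambda,
                             tier0 = tier0)),
      error = function(e) stop(toupper(enc), ": ", conditionMessage(e),
                               call. = FALSE))
    blocks <- rbind(blocks, data.frame(block = toupper(enc),
                                       offset = length(vals),
                                       length = length(v),
                                       stringsAsFactors = FALSE))
    vals <- c(vals, v)
  }
  attr(vals, "block_index") <- blocks
  vals
}

#' Encode every sequence of a dataset into a feature matrix
#'
#' @param dataset A [build_dataset()] result, or a named character vector of
#'   sequences.
#' @param ... Passed to [encode_combined()].
#' @return Numeric matrix, one row per sequence (rownames = ids, colnames =
#'   feature names), with attribute `block_index` as in [encode_combined()].
#' @export
encode_dataset <- function(dataset, ...) {
  seqs <- if (inherits(dataset, "labeled_dataset")) dataset$records else dataset
  if (length(seqs) == 0L) stop("no sequences to encode", call. = FALSE)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rows[[i]] <- tryCatch(encode_combined(seqs[[i]], ...),
                          error = function(e)
                            stop("record '", names(seqs)[i], "': ",
                                 conditionMessage(e), call. = FALSE))
  }
  X <- do.call(rbind, lapply(rows, as.numeric))
  rownames(X) <- names(seqs)
  colnames(X) <- names(rows[[1L]])
  attr(X, "block_index") <- attr(rows[[1L]], "block_index")
  X
}
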