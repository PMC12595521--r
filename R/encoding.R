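## One-hot encoding of alignments, argmax decoding, and Hamming distance.
## The gap "-" is the 21st symbol everywhere: encoded like a residue and
## counted as a mismatch, so distances do not depend on gap conventions.

#' One-hot encode an alignment
#'
#' Converts an \code{\link{alignedSet}} (or a character matrix / named vector
#' of equal-width gapped sequences) into an \code{n x width x 21} indicator
#' array over \code{\link{rcaAlphabet}}. Every (sequence, column) slice sums
#' to exactly 1. The encoding is the exact inverse of
#' \code{\link{decodeArgmax}} on valid input.
#'
#' @param msa An \code{AlignedSet}, a character residue matrix with rownames,
#'   or a named character vector of equal-width sequences.
#' @return A 3-d numeric array with dimnames \code{(ids, NULL, alphabet)}.
#' @export
#' @examples
#' x <- encodeOneHot(c(s1 = "AC-"))
#' dim(x)
encodeOneHot <- function(msa) {
  m <- as_residue_matrix(msa)
  alpha <- rcaAlphabet()
  idx <- match(m, alpha)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf(
      "alphabet violation: symbol '%s' at sequence '%s', column %d",
      m[bad], rownames(m)[(bad - 1L) %% nrow(m) + 1L],
      (bad - 1L) %/% nrow(m) + 1L))
  }
  n <- nrow(m); L <- ncol(m); K <- length(alpha)
  x <- array(0, dim = c(n, L, K), dimnames = list(rownames(m), NULL, alpha))
  # linear index into the n x L x K array for each (seq, col, symbol) triple
  seqi <- rep.int(seq_len(n), L)
  coli <- rep(seq_len(L), each = n)
  x[cbind(seqi, coli, as.vector(idx))] <- 1
  x
}

#' Decode per-position symbol probabilities to sequences
#'
#' For each sequence and alignment column, emits the symbol with maximal
#' probability; ties are broken deterministically by alphabet order
#' (\code{\link{rcaAlphabet}}). One-hot input decodes to the original
#' sequence exactly.
#'
#' @param probabilities \code{n x width x 21} nonnegative array (rows need
#'   not be normalized), or a single \code{width x 21} matrix.
#' @return Named character vector of gapped sequences.
#' @export
decodeArgmax <- function(probabilities) {
  if (length(dim(probabilities)) == 2L)
    probabilities <- array(probabilities, dim = c(1L, dim(probabilities)),
                           dimnames = c(list(NULL), dimnames(probabilities)))
  stopifnot(length(dim(probabilities)) == 3L,
            dim(probabilities)[3L] == length(rcaAlphabet()))
  if (any(probabilities < 0)) stop("probabilities must be nonnegative")
  n <- dim(probabilities)[1L]; L <- dim(probabilities)[2L]
  flat <- matrix(probabilities, nrow = n * L)  # (seq,col) x symbol
  if (any(rowSums(flat) == 0))
    stop("degenerate distribution: all-zero probability at some position")
  pick <- max.col(flat, ties.method = "first")
  m <- matrix(rcaAlphabet()[pick], nrow = n)
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- dimnames(probabilities)[[1L]]
  out
}

#' Hamming distance between gapped sequences
#'
#' Number of alignment columns at which two equal-width sequences differ.
#' The gap character is an ordinary symbol, so a residue-vs-gap column counts
#' as one difference. Vectorized over \code{a} (recycling \code{b}).
#'
#' @param a,b Gapped sequence strings of equal width (\code{a} may be a
#'   vector, compared element-wise against \code{b}).
#' @return Integer vector of substitution counts.
#' @export
#' @examples
#' hammingDist("ACDE", "ACDF")
hammingDist <- function(a, b) {
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  if (any(nchar(a) != nchar(b)))
    stop("width mismatch: Hamming distance requires equal-width sequences")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1L]] != strsplit(y, "", fixed = TRUE)[[1L]])
  }, a, b, USE.NAMES = FALSE)
}

## internal: coerce the accepted MSA representations to a residue matrix
as_residue_matrix <- function(msa) {
  if (methods::is(msa, "AlignedSet")) return(sequenceMatrix(msa))
  if (is.matrix(msa)) {
    if (is.null(rownames(msa)))
      rownames(msa) <- paste0("seq", seq_len(nrow(msa)))
    return(msa)
  }
  if (is.character(msa)) {
    if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
    w <- unique(nchar(msa))
    if (length(w) != 1L) stop("sequences must have equal width")
    return(matrix(unlist(strsplit(msa, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(msa), byrow = TRUE,
                  dimnames = list(names(msa), NULL)))
  }
  stop("unsupported alignment representation")
}

## internal: fast Hamming of many row-vectors of residues against one sequence
hamming_matrix_to_ref <- function(m, ref_chars) {
  stopifnot(ncol(m) == length(ref_chars))
  rowSums(m != matrix(ref_chars, nrow = nrow(m), ncol = ncol(m), byrow = TRUE))
}
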