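## Dataset refinement for the ortholog set: identity/length filtering against
## the reference, chloroplast transit peptide (cTP) stripping, and
## gap-fraction trimming of the alignment. Positions downstream are 1-based
## in the mature (cTP-removed) protein.

#' Percent identity between two protein sequences
#'
#' For equal-length inputs, the fraction of positions with identical symbols.
#' For unequal lengths, the sequences are globally aligned
#' (Biostrings, BLOSUM62, gap opening 10 / extension 0.5) and identity is
#' matches divided by the alignment length, gaps included in the denominator
#' (\code{method = "alignment"}); \code{method = "shorter"} divides by the
#' shorter sequence length instead. Symmetric in its arguments.
#'
#' @param a,b Non-empty residue strings (no gaps).
#' @param method Denominator convention for unequal lengths.
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' percentIdentity("ACDE", "ACDF")
percentIdentity <- function(a, b, method = c("alignment", "shorter")) {
  method <- match.arg(method)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(b, "", fixed = TRUE)[[1L]]
    return(sum(ca == cb) / length(ca))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  matches <- Biostrings::nmatch(aln)
  denom <- switch(method,
    alignment = nchar(as.character(Biostrings::alignedPattern(aln))),
    shorter = min(nchar(a), nchar(b)))
  matches / denom
}

#' Construct unaligned sequence records
#'
#' A plain data.frame of candidate sequences: one row per record with
#' \code{id}, \code{residues} (20-letter alphabet plus X, no gaps),
#' \code{source} (query / homolog / metagenomic / synthetic) and an optional
#' \code{ctp_length} (count of N-terminal residues predicted to form a
#' chloroplast transit peptide; \code{NA} until predicted).
#'
#' @param id Character identifiers (unique).
#' @param residues Amino-acid strings.
#' @param source Provenance labels, recycled.
#' @param ctp_length Optional predicted transit peptide lengths.
#' @return A data.frame of class \code{"sequence_records"}.
#' @export
sequenceRecords <- function(id, residues, source = "homolog",
                            ctp_length = NA_integer_) {
  stopifnot(length(id) == length(residues), !anyDuplicated(id))
  ok <- grepl(paste0("^[", paste(setdiff(rcaAlphabet(), "-"), collapse = ""), "X]+$"),
              residues)
  if (!all(ok))
    stop("residues must use the amino-acid alphabet plus X, with no gaps (record ",
         id[which(!ok)[1L]], ")")
  bad_ctp <- !is.na(ctp_length) & ctp_length >= nchar(residues)
  if (any(bad_ctp))
    stop("ctp_length must be shorter than the sequence (record ",
         id[which(bad_ctp)[1L]], ")")
  out <- data.frame(id = as.character(id), residues = as.character(residues),
                    source = rep_len(as.character(source), length(id)),
                    ctp_length = rep_len(as.integer(ctp_length), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sequence_records", "data.frame")
  out
}

#' Filter candidate sequences against a reference
#'
#' Applies the two refinement rules of the ortholog-set curation: retain a
#' record iff its identity to the reference exceeds \code{min_identity} (20\%
#' by default) and its length is at least \code{min_length} (140 residues by
#' default). Order-preserving and idempotent. Per-record decisions are
#' attached as the \code{"report"} attribute (id, decision, reason, identity,
#' length) and per-rule rejection counts are messaged.
#'
#' @param records A \code{\link{sequenceRecords}} data.frame.
#' @param reference Reference residue string (or a 1-row records frame).
#' @param min_identity Identity threshold, exclusive.
#' @param min_length Minimum length, inclusive.
#' @param quiet Suppress the summary message.
#' @return The retained subset, with a \code{"report"} attribute.
#' @export
filterCandidates <- function(records, reference, min_identity = 0.20,
                             min_length = 140L, quiet = FALSE) {
  if (is.data.frame(reference)) reference <- reference$residues[1L]
  if (!nzchar(reference)) stop("reference must be non-empty")
  lens <- nchar(records$residues)
  ident <- vapply(records$residues, percentIdentity, numeric(1L),
                  b = reference, USE.NAMES = FALSE)
  keep_len <- lens >= min_length
  keep_id <- ident > min_identity
  keep <- keep_len & keep_id
  reason <- rep("", nrow(records))
  reason[!keep_len] <- "length"
  reason[keep_len & !keep_id] <- "identity"
  report <- data.frame(id = records$id,
                       decision = ifelse(keep, "retained", "rejected"),
                       reason = reason, identity = ident, length = lens,
                       stringsAsFactors = FALSE)
  if (!quiet)
    message(sprintf(
      "filterCandidates: retained %d/%d (rejected %d short, %d low-identity)",
      sum(keep), nrow(records), sum(!keep_len), sum(keep_len & !keep_id)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Predict chloroplast transit peptides (heuristic stub)
#'
#' The campaign's real pipeline delegates cTP prediction to an external
#' predictor; this package ships the adapter surface plus a deterministic
#' heuristic stand-in. The stub flags everything N-terminal of the first
#' occurrence of a conserved anchor motif (by default the first
#' \code{anchor_width} residues of the mature reference) as the transit
#' peptide; no match means no cTP (length 0). Externally predicted lengths
#' can instead be set directly on the \code{ctp_length} column.
#'
#' @param records A \code{\link{sequenceRecords}} data.frame.
#' @param anchor Anchor motif marking the mature N-terminus.
#' @param anchor_width Anchor width when deriving it from \code{reference}.
#' @param reference Mature reference sequence used to derive the anchor.
#' @return The records with \code{ctp_length} populated.
#' @export
predictCtp <- function(records, anchor = NULL, anchor_width = 8L,
                       reference = NULL) {
  if (is.null(anchor)) {
    if (is.null(reference)) stop("supply an anchor motif or a mature reference")
    anchor <- substr(reference, 1L, anchor_width)
  }
  hit <- regexpr(anchor, records$residues, fixed = TRUE)
  records$ctp_length <- ifelse(hit > 0L, as.integer(hit) - 1L, 0L)
  records
}

#' Strip predicted transit peptides
#'
#' Removes the first \code{ctp_length} residues of every record, yielding the
#' mature protein. Identifiers are preserved and the removed prefix length is
#' recorded in a \code{mature_offset} column, so a mature-numbering position
#' \code{p} maps back to \code{p + mature_offset} in the precursor (the
#' campaign's famous position 250 is mature numbering).
#'
#' @param records A \code{\link{sequenceRecords}} data.frame with
#'   \code{ctp_length} populated (see \code{\link{predictCtp}}).
#' @return Records with mature \code{residues}, \code{ctp_length} reset to 0,
#'   and \code{mature_offset} plus \code{ctp_residues} columns.
#' @export
stripCtp <- function(records) {
  if (anyNA(records$ctp_length))
    stop("prediction required: ctp_length missing for record ",
         records$id[which(is.na(records$ctp_length))[1L]])
  off <- records$ctp_length
  records$ctp_residues <- substr(records$residues, 1L, off)
  records$residues <- substr(records$residues, off + 1L, nchar(records$residues))
  records$mature_offset <- off
  records$ctp_length <- 0L
  records
}

#' Trim an alignment by gap fraction
#'
#' Two-pass trim: first drop columns whose gap fraction exceeds
#' \code{max_col_gap_frac}, then drop rows whose gap fraction over the
#' surviving columns exceeds \code{max_row_gap_frac}. The wildtype row is
#' never dropped. Row order is preserved; trimming never adds columns.
#'
#' @param msa An \code{\link{alignedSet}}.
#' @param max_col_gap_frac Maximum tolerated per-column gap fraction.
#' @param max_row_gap_frac Maximum tolerated per-row gap fraction.
#' @return The trimmed \code{AlignedSet}.
#' @export
trimAlignment <- function(msa, max_col_gap_frac = 0.8, max_row_gap_frac = 0.5) {
  stopifnot(max_col_gap_frac >= 0, max_col_gap_frac <= 1,
            max_row_gap_frac >= 0, max_row_gap_frac <= 1)
  m <- sequenceMatrix(msa)
  col_gap <- colMeans(m == "-")
  keep_cols <- col_gap <= max_col_gap_frac
  if (!any(keep_cols)) stop("over-trimmed: no columns survive")
  m2 <- m[, keep_cols, drop = FALSE]
  row_gap <- rowMeans(m2 == "-")
  keep_rows <- row_gap <= max_row_gap_frac | rownames(m2) == wildtypeId(msa)
  if (!any(keep_rows)) stop("over-trimmed: no rows survive")
  alignedSet(m2[keep_rows, , drop = FALSE], wildtype_id = wildtypeId(msa))
}

#' Write a curation report
#'
#' Serializes the per-record report attached by \code{\link{filterCandidates}}
#' (columns id, decision, reason, identity, length) as CSV.
#'
#' @param filtered Output of \code{\link{filterCandidates}}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
writeCurationReport <- function(filtered, path) {
  report <- attr(filtered, "report")
  if (is.null(report)) stop("no report attribute; run filterCandidates first")
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
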