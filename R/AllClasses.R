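#' The 21-letter alignment alphabet
#'
#' Ordered alphabet used throughout the package: the 20 standard amino acids
#' followed by the gap character \code{"-"}. The gap is a first-class symbol:
#' it is one-hot encoded like any residue and it counts as a mismatch in
#' Hamming distances, so sequence distances are reproducible regardless of
#' alignment gappiness.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' rcaAlphabet()
rcaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Default heat-shock temperature ladder
#'
#' The screening ladder used in the thermal challenges: purified protein is
#' held for one hour at each temperature before the ATPase assay. Room
#' temperature (no shock) is handled separately and encoded as
#' \code{rcaRoomTemp()}.
#'
#' @return Numeric vector of ladder temperatures in degrees Celsius.
#' @export
rcaLadder <- function() c(38, 42, 46, 50)

#' @rdname rcaLadder
#' @export
rcaRoomTemp <- function() 25

## ---------------------------------------------------------------------------
## AlignedSet
## ---------------------------------------------------------------------------

#' Fixed-width multiple sequence alignment with a designated wildtype
#'
#' An \code{AlignedSet} holds a gapped protein alignment as a character matrix
#' (one row per sequence, one column per alignment column) together with the
#' identifier of the wildtype reference row. All rows have identical width,
#' identifiers are unique, and every symbol is drawn from the 21-letter
#' alphabet (\code{\link{rcaAlphabet}}) plus the ambiguity code \code{X}
#' (tolerated in curation, rejected at encoding time).
#'
#' @slot seqs Character matrix of single residues; rownames are sequence ids.
#' @slot wildtypeId Identifier of the wildtype row.
#' @aliases AlignedSet-class
#' @exportClass AlignedSet
setClass("AlignedSet",
  representation(seqs = "matrix", wildtypeId = "character"),
  validity = function(object) {
    m <- object@seqs
    if (!is.character(m) || nrow(m) < 1L || ncol(m) < 1L)
      return("seqs must be a non-empty character matrix")
    ids <- rownames(m)
    if (is.null(ids) || anyDuplicated(ids))
      return("sequence ids must be present and unique")
    ok <- m %in% c(rcaAlphabet(), "X")
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      return(sprintf("symbol '%s' outside alphabet at row %d, column %d",
                     m[bad], (bad - 1L) %% nrow(m) + 1L, (bad - 1L) %/% nrow(m) + 1L))
    }
    if (length(object@wildtypeId) != 1L || !(object@wildtypeId %in% ids))
      return("wildtypeId must name exactly one row of the alignment")
    TRUE
  })

#' Construct an AlignedSet
#'
#' @param sequences Named character vector of equal-length gapped sequences,
#'   an \code{AAStringSet}, or a character matrix of residues with rownames.
#' @param wildtype_id Identifier of the wildtype row (must be present).
#' @return An \code{AlignedSet}.
#' @export
#' @examples
#' msa <- alignedSet(c(wt = "ACD-", v1 = "ACDE"), wildtype_id = "wt")
#' alignmentWidth(msa)
alignedSet <- function(sequences, wildtype_id) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences)))
      stop("sequences must be named")
    w <- unique(nchar(sequences))
    if (length(w) != 1L)
      stop("aligned sequences must all have the same width (got widths ",
           paste(w, collapse = ", "), ")")
    m <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = length(sequences), byrow = TRUE,
                dimnames = list(names(sequences), NULL))
  }
  methods::new("AlignedSet", seqs = m, wildtypeId = as.character(wildtype_id))
}

#' @describeIn alignedSet Number of alignment columns.
#' @param x An \code{AlignedSet}.
#' @export
alignmentWidth <- function(x) ncol(x@seqs)

#' @describeIn alignedSet Sequence identifiers (row order preserved).
#' @export
alignmentIds <- function(x) rownames(x@seqs)

#' @describeIn alignedSet Identifier of the wildtype row.
#' @export
wildtypeId <- function(x) x@wildtypeId

#' @describeIn alignedSet The residue matrix (rows = sequences).
#' @export
sequenceMatrix <- function(x) x@seqs

#' @describeIn alignedSet Gapped sequences as a named character vector.
#' @export
alignedSequences <- function(x) {
  stats::setNames(apply(x@seqs, 1L, paste, collapse = ""), rownames(x@seqs))
}

#' @describeIn alignedSet The wildtype row as a single gapped string.
#' @export
wildtypeSequence <- function(x) {
  paste(x@seqs[x@wildtypeId, ], collapse = "")
}

setMethod("show", "AlignedSet", function(object) {
  cat(sprintf("AlignedSet: %d sequences x %d columns (wildtype: %s)\n",
              nrow(object@seqs), ncol(object@seqs), object@wildtypeId))
  gap <- mean(object@seqs == "-")
  cat(sprintf("  gap fraction: %.3f\n", gap))
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Planted genotype-to-thermotolerance map for synthetic campaigns
#'
#' Defines the ground truth used by the synthetic-data generator: a small set
#' of key alignment columns at which a specific stabilizing residue raises the
#' maximum tolerated heat-shock temperature, at the cost of reduced catalytic
#' activity (the stability-activity trade-off). The default plants a single
#' proline-to-glycine swap worth +8 degrees C over a 38 degrees C wildtype
#' baseline, echoing the single-mutation top performer of the screening
#' campaign this package models.
#'
#' @slot keyPositions Integer alignment columns carrying the determinant.
#' @slot stabilizingResidue One residue per key position.
#' @slot baseTmax Wildtype maximum tolerated shock temperature (degrees C).
#' @slot deltaTmax Gain in tolerated temperature per stabilizing substitution.
#' @slot activityScale Multiplicative activity factor in (0, 1] applied once
#'   per stabilizing substitution (trade-off).
#' @slot traceNoiseSd Gaussian observation noise on simulated A340 readings.
#' @slot seed Integer seed controlling everything derived from this truth.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(keyPositions = "integer", stabilizingResidue = "character",
                 baseTmax = "numeric", deltaTmax = "numeric",
                 activityScale = "numeric", traceNoiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    k <- object@keyPositions
    if (length(k) < 1L || anyDuplicated(k) || any(k < 1L))
      return("keyPositions must be distinct positive columns")
    if (length(object@stabilizingResidue) != length(k))
      return("one stabilizing residue per key position required")
    if (!all(object@stabilizingResidue %in% setdiff(rcaAlphabet(), "-")))
      return("stabilizing residues must be amino acids, not gaps")
    if (object@activityScale <= 0 || object@activityScale > 1)
      return("activityScale must lie in (0, 1]")
    if (object@traceNoiseSd < 0)
      return("traceNoiseSd must be nonnegative")
    lad <- rcaLadder()
    reach <- object@baseTmax + seq_along(k) * object@deltaTmax
    if (object@baseTmax < min(rcaRoomTemp(), lad) || object@baseTmax > max(lad))
      return("baseTmax must fall inside the screening range")
    if (!any(reach >= min(lad) & reach <= max(lad)))
      return("baseTmax + k*deltaTmax must reach the ladder for some k >= 1")
    TRUE
  })

#' Construct a GroundTruth
#'
#' @param key_positions Alignment columns carrying the thermotolerance
#'   determinant (default: a single position).
#' @param stabilizing_residue Residue(s) that confer stability at the key
#'   position(s); default \code{"G"}, planting a proline-to-glycine swap.
#' @param base_tmax Wildtype maximum tolerated shock temperature in degrees C.
#' @param delta_tmax Degrees C gained per stabilizing substitution.
#' @param activity_scale Activity retained per stabilizing substitution, in
#'   (0, 1]; values below 1 encode the stability-activity trade-off.
#' @param trace_noise_sd Standard deviation of Gaussian noise added to
#'   simulated absorbance readings (absorbance units).
#' @param seed Integer seed.
#' @return A \code{GroundTruth}.
#' @export
#' @examples
#' truth <- groundTruth(key_positions = 25)
#' truth
groundTruth <- function(key_positions = 25L, stabilizing_residue = "G",
                        base_tmax = 38, delta_tmax = 8, activity_scale = 0.7,
                        trace_noise_sd = 0.01, seed = 1L) {
  if (length(stabilizing_residue) == 1L && length(key_positions) > 1L)
    stabilizing_residue <- rep(stabilizing_residue, length(key_positions))
  methods::new("GroundTruth",
    keyPositions = as.integer(key_positions),
    stabilizingResidue = as.character(stabilizing_residue),
    baseTmax = as.numeric(base_tmax), deltaTmax = as.numeric(delta_tmax),
    activityScale = as.numeric(activity_scale),
    traceNoiseSd = as.numeric(trace_noise_sd), seed = as.integer(seed))
}

#' @describeIn groundTruth Key alignment columns.
#' @param truth A \code{GroundTruth}.
#' @export
keyPositions <- function(truth) truth@keyPositions

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d key position(s) [%s -> %s], base tmax %.0fC, +%.0fC each,\n",
    length(object@keyPositions),
    paste(object@keyPositions, collapse = ","),
    paste(object@stabilizingResidue, collapse = ","),
    object@baseTmax, object@deltaTmax))
  cat(sprintf("  activity scale %.2f per substitution, trace noise sd %.3g AU, seed %d\n",
              object@activityScale, object@traceNoiseSd, object@seed))
})

## ---------------------------------------------------------------------------
## RcaVae
## ---------------------------------------------------------------------------

#' Variational autoencoder over a one-hot encoded alignment
#'
#' Holds the trained encoder/decoder parameters (multilayer perceptrons on the
#' flattened one-hot input), the optional semi-supervised property head on the
#' posterior mean, the training configuration, and the per-epoch loss history.
#' Objects are produced by \code{\link{trainVae}}; use
#' \code{\link{latentEmbedding}}, \code{\link{predictProperty}},
#' \code{\link{proposeVariants}} and \code{\link{vaeElbo}} to work with them.
#'
#' @slot params Named list of weight matrices and bias vectors.
#' @slot config The \code{\link{vaeConfig}} list used for training.
#' @slot history Per-epoch data.frame of loss components.
#' @slot alphabet Alphabet the model was trained over.
#' @slot width Alignment width the model expects.
#' @slot labelStats Mean/sd used to standardize the regression target.
#' @slot supervised Whether a property head was trained.
#' @slot trained Whether training has run.
#' @aliases RcaVae-class
#' @exportClass RcaVae
setClass("RcaVae",
  representation(params = "list", config = "list", history = "data.frame",
                 alphabet = "character", width = "integer",
                 labelStats = "numeric", supervised = "logical",
                 trained = "logical"),
  validity = function(object) {
    if (length(object@trained) != 1L) return("trained must be a single flag")
    TRUE
  })

setMethod("show", "RcaVae", function(object) {
  cfg <- object@config
  cat(sprintf("RcaVae: latent dim %d, %s, alignment width %d\n",
              cfg$latent_dim,
              if (object@supervised) "semi-supervised" else "unsupervised",
              object@width))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final ELBO %.3f (recon %.3f, KL %.3f)\n",
                nrow(object@history), last$elbo, last$reconstruction, last$kl))
  }
})

#' @describeIn trainVae Per-epoch training history.
#' @export
trainingHistory <- function(model) {
  stopifnot(methods::is(model, "RcaVae"))
  model@history
}
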