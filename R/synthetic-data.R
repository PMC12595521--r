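## Synthetic study system: ortholog-like MSAs with a planted thermotolerance
## determinant, and simulated coupled-ATPase assay traces (A340 decay) whose
## initial slope is proportional to residual activity after a heat shock.
## Every downstream stage of the design loop is testable against this truth.

#' Default per-column conservation profile
#'
#' Mixed profile alternating strongly conserved columns (consensus probability
#' 0.95) with variable columns (0.6), loosely imitating the conserved
#' AAA+ core versus variable surface positions of an activase ortholog set.
#'
#' @param length Number of alignment columns.
#' @return Numeric vector in [0, 1], one conservation level per column.
#' @export
defaultConservation <- function(length) {
  rep(c(0.95, 0.6), length.out = length)
}

#' Generate a synthetic ortholog alignment
#'
#' Draws an MSA around a random consensus sequence with subfamily (clade)
#' structure, emulating the correlated variation of a real ortholog set:
#' each non-wildtype sequence belongs to one of \code{n_clades} subfamilies,
#' each subfamily carries its own preferred alternate residue at a fraction
#' of the variable columns (clade-level, correlated variation), and on top
#' of that every column mutates independently to one of three fixed
#' alternates with probability \code{1 - conservation} (residual noise).
#' Row 1 is the designated wildtype and equals the consensus; a fully
#' conserved profile therefore yields an alignment of identical rows. When a
#' \code{\link{groundTruth}} is supplied its key columns are overridden: the
#' wildtype carries proline (the ancestral residue of the planted
#' proline-to-glycine swap) and every other row carries the stabilizing
#' residue with probability \code{key_alt_frac}, so the thermotolerance
#' determinant segregates in the set.
#'
#' @param n_seqs Number of sequences (>= 2).
#' @param length Number of alignment columns (>= 10).
#' @param conservation Per-column consensus probability in [0, 1];
#'   default \code{\link{defaultConservation}}.
#' @param truth Optional \code{GroundTruth} whose key positions are planted.
#' @param key_alt_frac Frequency of the stabilizing residue at key columns
#'   among non-wildtype rows.
#' @param gap_frac Probability that a non-wildtype symbol is replaced by a
#'   gap (default 0; the wildtype row is never gapped).
#' @param n_clades Number of subfamilies.
#' @param clade_divergence Probability that a variable column's subfamily
#'   profile deviates from the consensus (scaled by \code{1 - conservation}).
#' @param seed Integer seed; identical seeds give bit-identical alignments.
#' @param wildtype_id Identifier given to the wildtype row.
#' @return An \code{\link{alignedSet}} whose first row is the wildtype.
#' @export
#' @examples
#' msa <- generateMsa(20, 40, seed = 7)
#' msa
generateMsa <- function(n_seqs, length, conservation = NULL, truth = NULL,
                        key_alt_frac = 0.4, gap_frac = 0, n_clades = 6L,
                        clade_divergence = 0.6, seed = 1L,
                        wildtype_id = "wildtype") {
  if (n_seqs < 2L) stop("n_seqs must be at least 2")
  if (length < 10L) stop("length must be at least 10")
  if (is.null(conservation)) conservation <- defaultConservation(length)
  if (base::length(conservation) != length)
    stop("conservation profile must have one entry per column")
  if (any(conservation < 0 | conservation > 1))
    stop("conservation levels must lie in [0, 1]")
  aa <- setdiff(rcaAlphabet(), "-")
  withr::with_seed(as.integer(seed), {
    consensus <- sample(aa, length, replace = TRUE)
    # three fixed alternates per column, distinct from the consensus
    alternates <- vapply(consensus, function(cs) sample(setdiff(aa, cs), 3L),
                         character(3L))
    if (!is.null(truth)) {
      kp <- truth@keyPositions
      if (any(kp > length))
        stop("key positions exceed alignment width")
      consensus[kp] <- "P"
      for (j in seq_along(kp))
        alternates[, kp[j]] <- c(truth@stabilizingResidue[j],
                                 setdiff(aa, c("P", truth@stabilizingResidue[j]))[1:2])
    }
    ## subfamily profiles: consensus, deviating at variable columns.
    ## clade 1 is the wildtype's own subfamily and stays at the consensus,
    ## so the reference sits inside an occupied region of sequence space.
    profiles <- matrix(rep(consensus, n_clades), nrow = n_clades, byrow = TRUE)
    for (k in seq_len(n_clades)[-1L]) {
      dev <- stats::runif(length) < (1 - conservation) * clade_divergence
      profiles[k, dev] <- alternates[cbind(
        sample.int(3L, sum(dev), replace = TRUE), which(dev))]
    }
    clade <- sample.int(n_clades, n_seqs - 1L, replace = TRUE)
    m <- matrix("", nrow = n_seqs, ncol = length)
    m[1L, ] <- consensus
    for (j in seq_len(length)) {
      take_profile <- stats::runif(n_seqs - 1L) < conservation[j]
      alt <- alternates[sample.int(3L, n_seqs - 1L, replace = TRUE), j]
      m[-1L, j] <- ifelse(take_profile, profiles[clade, j], alt)
    }
    if (!is.null(truth)) {
      for (j in seq_along(truth@keyPositions)) {
        col <- truth@keyPositions[j]
        stab <- stats::runif(n_seqs - 1L) < key_alt_frac
        m[-1L, col] <- ifelse(stab, truth@stabilizingResidue[j], "P")
      }
    }
    if (gap_frac > 0) {
      gapped <- matrix(stats::runif((n_seqs - 1L) * length) < gap_frac,
                       nrow = n_seqs - 1L)
      m[-1L, ][gapped] <- "-"
    }
    rownames(m) <- c(wildtype_id,
                     sprintf("ortho_%04d", seq_len(n_seqs - 1L)))
    alignedSet(m, wildtype_id = wildtype_id)
  })
}

#' True maximum tolerated heat-shock temperature of a sequence
#'
#' Pure function of the planted truth: the wildtype baseline plus
#' \code{delta_tmax} for every key position carrying the stabilizing residue.
#'
#' @param seq Gapped sequence string(s) at the truth's alignment width.
#' @param truth A \code{\link{groundTruth}}.
#' @return Numeric vector of temperatures in degrees C.
#' @export
trueTmax <- function(seq, truth) {
  counts <- count_stabilizing(seq, truth)
  truth@baseTmax + truth@deltaTmax * counts
}

#' @describeIn trueTmax Activity retained relative to wildtype
#'   (\code{activity_scale} once per stabilizing substitution).
#' @export
trueActivityScale <- function(seq, truth) {
  truth@activityScale ^ count_stabilizing(seq, truth)
}

count_stabilizing <- function(seq, truth) {
  kmax <- max(truth@keyPositions)
  vapply(seq, function(s) {
    if (nchar(s) < kmax)
      stop("sequence width does not cover the truth's key positions")
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    sum(chars[truth@keyPositions] == truth@stabilizingResidue)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Simulate a coupled ATPase assay trace
#'
#' Models the NADH-coupled readout: active enzyme hydrolyzes ATP, pyruvate
#' kinase regenerates it from phosphoenolpyruvate, and lactate dehydrogenase
#' oxidizes NADH, read as a linear decrease in absorbance at 340 nm until the
#' substrate is exhausted (a plateau floor). The decay rate is proportional
#' to residual activity: full wildtype-scale activity at or below the
#' sequence's true tolerated temperature, zero above it (binary heat-shock
#' damage), scaled by \code{activity_scale} per stabilizing substitution.
#' Gaussian observation noise with \code{trace_noise_sd} is added on top.
#'
#' @param seq Gapped sequence at the truth's alignment width, or \code{NULL}
#'   for a no-enzyme control well (zero rate).
#' @param shock_temp Heat-shock temperature in degrees C, or \code{"RT"} /
#'   \code{NA} for an unshocked room-temperature well.
#' @param truth A \code{\link{groundTruth}}.
#' @param duration Assay duration in minutes (> 0).
#' @param n_points Number of timepoints (>= 3).
#' @param seed Integer seed for the observation noise.
#' @param a0 Initial absorbance (arbitrary units; amplitudes are
#'   arbitrary-unit by design).
#' @param floor Absorbance floor at substrate exhaustion.
#' @param base_rate Wildtype unshocked decay rate in AU/min.
#' @param sequence_id,well_id Identifiers carried into the output.
#' @param concentration Protein concentration metadata in uM.
#' @param rate Optional decay-rate override in AU/min (e.g. a plate's
#'   positive-control well at full wildtype rate), bypassing the truth.
#' @return Long-format data.frame with columns \code{well_id, sequence_id,
#'   shock_temp_C, time_min, a340} and a \code{concentration} attribute.
#' @export
simulateTrace <- function(seq, shock_temp, truth, duration = 60, n_points = 31,
                          seed = 1L, a0 = 1, floor = 0.1, base_rate = 0.01,
                          sequence_id = "seq", well_id = "A01",
                          concentration = 5, rate = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (n_points < 3L) stop("at least 3 timepoints required")
  is_rt <- is.null(shock_temp) || is.na(shock_temp) ||
    identical(toupper(as.character(shock_temp)), "RT")
  shown_temp <- if (is_rt) "RT" else as.character(shock_temp)
  if (is.null(rate)) {
    if (is.null(seq)) {
      rate <- 0  # no-enzyme control well
    } else {
      tmax <- trueTmax(seq, truth)
      survives <- is_rt || as.numeric(shock_temp) <= tmax
      rate <- if (survives) base_rate * trueActivityScale(seq, truth) else 0
    }
  }
  times <- seq(0, duration, length.out = n_points)
  clean <- pmax(floor, a0 - rate * times)
  noisy <- withr::with_seed(as.integer(seed),
                            clean + stats::rnorm(n_points, 0, truth@traceNoiseSd))
  out <- data.frame(well_id = well_id, sequence_id = sequence_id,
                    shock_temp_C = shown_temp, time_min = times, a340 = noisy,
                    stringsAsFactors = FALSE)
  attr(out, "concentration") <- concentration
  out
}

## ---------------------------------------------------------------------------
## File interchange
## ---------------------------------------------------------------------------

#' Read and write aligned FASTA
#'
#' Gapped FASTA input/output backed by Biostrings; the gap character is
#' \code{"-"}.
#'
#' @param msa An \code{AlignedSet}.
#' @param path File path.
#' @param wildtype_id Wildtype identifier to designate on read (defaults to
#'   the first record).
#' @return \code{readAlignedFasta} returns an \code{AlignedSet};
#'   \code{writeAlignedFasta} returns \code{path} invisibly.
#' @export
writeAlignedFasta <- function(msa, path) {
  seqs <- Biostrings::AAStringSet(alignedSequences(msa))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @rdname writeAlignedFasta
#' @export
readAlignedFasta <- function(path, wildtype_id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  v <- stats::setNames(as.character(seqs), ids)
  if (is.null(wildtype_id)) wildtype_id <- ids[1L]
  alignedSet(v, wildtype_id = wildtype_id)
}

#' Read and write assay trace tables
#'
#' Long-format CSV with columns \code{well_id, sequence_id, shock_temp_C,
#' time_min, a340} (one row per reading), the dialect emitted by
#' \code{\link{simulateTrace}}.
#'
#' @param traces A data.frame of traces (rows from one or more wells).
#' @param path File path.
#' @return \code{readTraceCsv} returns a data.frame; \code{writeTraceCsv}
#'   returns \code{path} invisibly.
#' @export
writeTraceCsv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
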