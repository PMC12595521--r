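## Screening analytics: A340 traces -> initial-rate fits -> activity calls
## -> per-sequence maximum tolerated heat-shock temperature -> round tallies
## and residual-activity percentages.

#' Fit the initial NADH oxidation rate of a trace
#'
#' Least-squares slope of absorbance against time over the initial fraction
#' of points. Active enzyme consumes NADH, so activity shows as a negative
#' slope; the sign is preserved.
#'
#' @param trace data.frame with \code{time_min} and \code{a340} columns (one
#'   well), or a numeric vector of readings with \code{times} supplied.
#' @param window Initial fraction of points used for the fit (at least 3
#'   points are always taken).
#' @param times Timepoints when \code{trace} is a bare numeric vector.
#' @return Slope in delta-A340 per minute.
#' @export
fitRate <- function(trace, window = 0.25, times = NULL) {
  if (is.data.frame(trace)) {
    times <- trace$time_min
    y <- trace$a340
  } else {
    y <- trace
  }
  stopifnot(length(times) == length(y), length(y) >= 3L)
  k <- max(3L, ceiling(window * length(y)))
  t0 <- times[seq_len(k)]; y0 <- y[seq_len(k)]
  if (stats::var(t0) == 0) stop("degenerate time axis: no spread in timepoints")
  unname(stats::coef(stats::lm(y0 ~ t0))[2L])
}

#' Call a well active or inactive
#'
#' Two calling modes. \code{"kinetic"}: a well is active iff its initial
#' rate is more negative than the no-enzyme control mean by more than
#' \code{k} control standard deviations (strict, so a rate equal to control
#' is inactive). \code{"endpoint"} (the default, matching the permissive
#' ~16 h screen in which any residual enzyme completes the reaction): a well
#' is active iff its total absorbance drop strictly exceeds
#' \code{endpoint_frac} of the plate's positive-control drop.
#'
#' @param rate Fitted initial rate of the test well (kinetic mode).
#' @param control_rates Rates of the plate's no-enzyme control wells
#'   (kinetic mode); their mean and sd define the threshold.
#' @param endpoint_drop Total A340 drop of the test well (endpoint mode).
#' @param positive_control_drop Drop of the positive-control well.
#' @param k Control standard deviations below control mean required.
#' @param endpoint_frac Fraction of the positive-control drop required.
#' @param mode Calling mode.
#' @param tol Absolute numerical guard so least-squares round-off on a flat
#'   trace is never called active.
#' @return Logical activity flag.
#' @export
callActive <- function(rate = NULL, control_rates = NULL,
                       endpoint_drop = NULL, positive_control_drop = NULL,
                       k = 3, endpoint_frac = 0.5,
                       mode = c("endpoint", "kinetic"), tol = 1e-12) {
  mode <- match.arg(mode)
  if (mode == "kinetic") {
    if (is.null(rate) || is.null(control_rates) || !length(control_rates))
      stop("uncontrolled plate: kinetic calls need test and control rates")
    mu <- mean(control_rates)
    sd <- if (length(control_rates) > 1L) stats::sd(control_rates) else 0
    return(rate < mu - k * sd - tol)
  }
  if (is.null(endpoint_drop) || is.null(positive_control_drop))
    stop("uncontrolled plate: endpoint calls need test and positive-control drops")
  endpoint_drop > endpoint_frac * positive_control_drop
}

#' Assign the maximum tolerated heat-shock temperature
#'
#' From per-temperature activity flags (the room-temperature call must be
#' present): inactive at RT gives \code{"inactive"}; active at RT but at no
#' shock temperature gives \code{"RT-only"}; otherwise the maximum shock
#' temperature with an active call. Non-monotone patterns (inactive at a
#' lower temperature but active higher) are resolved by taking the maximum,
#' with a warning.
#'
#' @param calls Named logical vector: names \code{"RT"} and ladder
#'   temperatures as characters (e.g. \code{c(RT = TRUE, `38` = TRUE)}).
#' @return Character scalar: \code{"inactive"}, \code{"RT-only"}, or a
#'   temperature such as \code{"46"}.
#' @export
assignTmax <- function(calls) {
  if (!"RT" %in% names(calls)) stop("RT call must be present")
  if (!isTRUE(calls[["RT"]])) return("inactive")
  shocks <- calls[setdiff(names(calls), "RT")]
  if (!length(shocks) || !any(shocks)) return("RT-only")
  temps <- as.numeric(names(shocks))
  active_t <- temps[shocks]
  tmax <- max(active_t)
  if (any(!shocks & temps < tmax))
    warning(sprintf(
      "non-monotone activity pattern (inactive at %s but active at %g); taking the maximum",
      paste(temps[!shocks & temps < tmax], collapse = ","), tmax))
  format(tmax)
}

#' Numeric view of tmax labels
#'
#' Maps screen tmax labels to degrees C for modeling: \code{"inactive"} to
#' \code{NA}, \code{"RT-only"} to room temperature, numeric labels to their
#' value.
#'
#' @param tmax Character vector of tmax labels.
#' @return Numeric vector in degrees C.
#' @export
tmaxNumeric <- function(tmax) {
  out <- suppressWarnings(as.numeric(tmax))
  out[tmax == "RT-only"] <- rcaRoomTemp()
  out[tmax == "inactive"] <- NA_real_
  out
}

#' Tally a screening round
#'
#' Per round: sequences tested, active/inactive at room temperature, the
#' number maintaining activity at each ladder temperature (a sequence with
#' tmax = T counts at every ladder temperature at or below T, so counts are
#' non-increasing along the ladder), and percentages over tested. Exact
#' integer arithmetic; active + inactive = tested always.
#'
#' @param records data.frame with columns \code{sequence_id}, \code{round},
#'   \code{tmax} (labels as from \code{\link{assignTmax}}).
#' @param ladder Shock-temperature ladder.
#' @param above_temp Optional temperature for an "active above" count.
#' @param above_mode \code{">="} (default) counts tmax >= above_temp;
#'   \code{">"} counts strictly greater.
#' @return data.frame, one row per round, plus an \code{"above"} attribute
#'   when \code{above_temp} is given.
#' @export
tallyRound <- function(records, ladder = rcaLadder(), above_temp = NULL,
                       above_mode = c(">=", ">")) {
  above_mode <- match.arg(above_mode)
  stopifnot(all(c("sequence_id", "round", "tmax") %in% names(records)))
  rounds <- unique(records$round)
  tn <- tmaxNumeric(records$tmax)
  out <- do.call(rbind, lapply(rounds, function(r) {
    sel <- records$round == r
    tested <- sum(sel)
    active_rt <- sum(records$tmax[sel] != "inactive")
    row <- data.frame(round = r, tested = tested, active_rt = active_rt,
                      inactive = tested - active_rt,
                      pct_active_rt = 100 * active_rt / tested,
                      stringsAsFactors = FALSE)
    for (temp in ladder) {
      cnt <- sum(sel & !is.na(tn) & tn >= temp)
      row[[paste0("at_", temp)]] <- cnt
      row[[paste0("pct_at_", temp)]] <- 100 * cnt / tested
    }
    row
  }))
  rownames(out) <- NULL
  if (!is.null(above_temp)) {
    cmp <- if (above_mode == ">=") `>=` else `>`
    ab <- vapply(rounds, function(r)
      sum(records$round == r & !is.na(tn) & cmp(tn, above_temp)), numeric(1))
    attr(out, "above") <- stats::setNames(ab, rounds)
    message(sprintf("tallyRound: 'active above %g' counted with tmax %s %g",
                    above_temp, above_mode, above_temp))
  }
  out
}

#' Residual activity after a heat shock
#'
#' Post-shock rate as a percentage of the same sequence's room-temperature
#' rate (same concentration), clipped below at 0. A thermotolerant variant
#' retains ~100% at temperatures it survives; wildtype drops to ~0% above
#' its tolerance.
#'
#' @param rate_post_shock Initial rate after the shock (delta-A340/min).
#' @param rate_rt Room-temperature rate of the same sequence.
#' @return Percent.
#' @export
residualActivity <- function(rate_post_shock, rate_rt) {
  if (any(rate_rt == 0)) stop("no baseline: room-temperature rate is zero")
  pmax(0, 100 * rate_post_shock / rate_rt)
}

#' Concentration normalization to the assay target
#'
#' Wells at or above the 5 uM target are diluted by \code{measured/target};
#' wells below target are run undiluted at the highest possible
#' concentration (factor 1) and flagged.
#'
#' @param measured Measured concentration in uM (>= 0).
#' @param target Target assay concentration in uM.
#' @return data.frame with \code{factor}, \code{undiluted}, \code{no_protein}.
#' @export
normalizeConcentration <- function(measured, target = 5) {
  stopifnot(all(measured >= 0))
  data.frame(measured = measured,
             factor = ifelse(measured >= target, measured / target, 1),
             undiluted = measured < target & measured > 0,
             no_protein = measured == 0)
}

## ---------------------------------------------------------------------------
## simulated plates and screen records
## ---------------------------------------------------------------------------

#' Screen sequences on a simulated plate
#'
#' Runs the full in-silico screen for a set of aligned sequences against a
#' planted \code{\link{groundTruth}}: simulates one well per sequence per
#' condition (room temperature plus each ladder temperature), together with
#' no-enzyme controls and a wildtype-scale positive control, fits initial
#' rates (kinetic mode) or endpoint drops (permissive endpoint mode), calls
#' activity, and assigns each sequence its maximum tolerated temperature.
#'
#' @param sequences Named character vector of gapped sequences.
#' @param truth A \code{\link{groundTruth}}.
#' @param round_label Provenance label for the output records.
#' @param ladder Shock ladder in degrees C.
#' @param mode Activity-calling mode (see \code{\link{callActive}}).
#' @param seed Integer seed for trace noise.
#' @param n_controls Number of no-enzyme control wells per condition.
#' @param duration,n_points Trace length; the endpoint screen defaults to a
#'   long (960 min) incubation so any residual activity completes the
#'   reaction.
#' @return data.frame of screen records: \code{sequence_id, sequence, round,
#'   active_rt, tmax}, plus per-temperature call columns.
#' @export
screenSequences <- function(sequences, truth, round_label = "natural",
                            ladder = rcaLadder(),
                            mode = c("kinetic", "endpoint"), seed = 1L,
                            n_controls = 8L, duration = NULL,
                            n_points = 31L) {
  mode <- match.arg(mode)
  if (is.null(duration)) duration <- if (mode == "endpoint") 960 else 60
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  conds <- c("RT", as.character(ladder))
  seed <- as.integer(seed)

  ## plate controls per condition: no-enzyme wells and a positive control
  ctrl_stats <- lapply(seq_along(conds), function(ci) {
    ctr <- vapply(seq_len(n_controls), function(w) {
      tr <- simulateTrace(NULL, conds[ci], truth, duration = duration,
                          n_points = n_points,
                          seed = seed + 900000L + ci * 1000L + w)
      if (mode == "kinetic") fitRate(tr) else tr$a340[1L] - tr$a340[nrow(tr)]
    }, numeric(1L))
    ## positive control: an unshocked well decaying at full wildtype rate
    pos <- simulateTrace(NULL, "RT", truth, duration = duration,
                         n_points = n_points, seed = seed + 990000L + ci,
                         rate = 0.01)
    list(rates = ctr,
         pos_drop = pos$a340[1L] - pos$a340[nrow(pos)])
  })

  records <- lapply(seq_along(sequences), function(i) {
    calls <- logical(length(conds))
    names(calls) <- conds
    for (ci in seq_along(conds)) {
      tr <- simulateTrace(sequences[[i]], conds[ci], truth,
                          duration = duration, n_points = n_points,
                          seed = seed + i * 100L + ci,
                          sequence_id = ids[i])
      calls[ci] <- if (mode == "kinetic") {
        callActive(rate = fitRate(tr), control_rates = ctrl_stats[[ci]]$rates,
                   mode = "kinetic")
      } else {
        callActive(endpoint_drop = tr$a340[1L] - tr$a340[nrow(tr)],
                   positive_control_drop = ctrl_stats[[ci]]$pos_drop,
                   mode = "endpoint")
      }
    }
    tmax <- suppressWarnings(assignTmax(calls))
    row <- data.frame(sequence_id = ids[i], sequence = sequences[[i]],
                      round = round_label, active_rt = calls[["RT"]],
                      tmax = tmax, stringsAsFactors = FALSE)
    for (temp in ladder) row[[paste0("call_", temp)]] <- calls[[as.character(temp)]]
    row
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## deposited-table interchange
## ---------------------------------------------------------------------------

#' Read a deposited screening table
#'
#' Reads the deposited-dataset dialect: a CSV with one row per tested
#' sequence carrying an identifier, the sequence, a round label, an activity
#' flag, and the highest temperature with retained activity. Header synonyms
#' are mapped through \code{dialect}; activity flags accept yes/no,
#' true/false, 1/0, active/inactive; temperature fields accept ladder
#' values, RT codes, or empty for inactive rows.
#'
#' @param path CSV path.
#' @param dialect Named list mapping canonical names (\code{id},
#'   \code{sequence}, \code{round}, \code{active}, \code{max_temp}) to
#'   acceptable header synonyms.
#' @return data.frame with canonical columns \code{sequence_id},
#'   \code{sequence}, \code{round}, \code{active_rt}, \code{tmax}.
#' @export
readDepositedTable <- function(path, dialect = depositedDialect()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- tolower(trimws(names(raw)))
  pick <- function(canon, required = TRUE) {
    j <- which(hdr %in% dialect[[canon]])
    if (!length(j)) {
      if (required) stop("deposited table lacks a '", canon, "' column")
      return(NULL)
    }
    raw[[j[1L]]]
  }
  active_raw <- tolower(trimws(as.character(pick("active"))))
  active <- active_raw %in% c("yes", "y", "true", "1", "active")
  temp_raw <- trimws(as.character(pick("max_temp")))
  tmax <- ifelse(!active, "inactive",
          ifelse(tolower(temp_raw) %in%
                   c("", "na", "rt", "rt-only", "room temperature"),
                 "RT-only", temp_raw))
  data.frame(sequence_id = as.character(pick("id")),
             sequence = as.character(pick("sequence")),
             round = as.character(pick("round")),
             active_rt = active, tmax = tmax, stringsAsFactors = FALSE)
}

#' @rdname readDepositedTable
#' @export
depositedDialect <- function() {
  list(id = c("id", "sequence_id", "seq_id", "name", "sequence id"),
       sequence = c("sequence", "seq", "residues", "protein_sequence"),
       round = c("round", "screening_round", "design_round", "library"),
       active = c("active", "activity", "is_active", "active_rt"),
       max_temp = c("max_temp", "tmax", "highest_temp", "max_temperature",
                    "highest temperature with retained activity",
                    "max_temp_c"))
}

#' Write screen records
#'
#' @param records Screen-record data.frame.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeScreenRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
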