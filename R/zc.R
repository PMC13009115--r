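#' @include utils.R
NULL

#' Detect the electromechanical zero crossing of a strain trace
#'
#' Local electromechanical activation is the first downward zero crossing of
#' the incremental axial strain trace: the time the myocardium switches from
#' diastolic lengthening (positive) to systolic shortening (negative). The
#' trace is smoothed with a centered moving average, then every downward
#' sign change inside the analysis window is examined; a crossing qualifies
#' only if the smoothed strain stays negative for at least
#' \code{minNegativeMs} after it (transient single-frame dips are rejected).
#' The reported time interpolates linearly between the bracketing frames and
#' is expressed relative to \code{reference}.
#'
#' @param trace numeric strain trace.
#' @param rate frame rate in Hz.
#' @param reference timing reference in ms on the trace clock (QRS onset or
#'   pacing spike); the result is reported relative to it.
#' @param window analysis window c(start, end) in ms on the trace clock;
#'   default reference to reference + 350 ms.
#' @param smoothingMs moving-average width (default 5 ms).
#' @param minNegativeMs required sustained negativity after the crossing
#'   (default 20 ms).
#' @param startMs trace-clock time of the first sample (default 0).
#' @return list with \code{time} (ms relative to reference; NA if none),
#'   \code{quality} ("accepted", "ambiguous" when several crossings qualify
#'   — the first is reported — or "no_crossing"), and
#'   \code{nCandidates}, the number of downward sign changes in the window.
#' @export
detectZeroCrossing <- function(trace, rate, reference = 0,
                               window = c(reference, reference + 350),
                               smoothingMs = 5, minNegativeMs = 20,
                               startMs = 0) {
  stopifnot(minNegativeMs >= 0, rate > 0)
  n <- length(trace)
  dtMs <- 1000 / rate
  times <- startMs + (seq_len(n) - 1) * dtMs
  if (window[1] < times[1] - dtMs / 2 || window[2] > times[n] + dtMs / 2)
    stop("analysis window extends beyond the trace")
  s <- movingAverage(trace, max(1L, round(smoothingMs / dtMs)))

  down <- which(s[-n] > 0 & s[-1] <= 0)         # bracketing indices i, i+1
  tc <- times[down] + dtMs * s[down] / (s[down] - s[down + 1])
  inWin <- tc >= window[1] & tc <= window[2]
  down <- down[inWin]; tc <- tc[inWin]
  nCand <- length(down)
  if (!nCand)
    return(list(time = NA_real_, quality = "no_crossing", nCandidates = 0L))

  # sustained negativity: nothing rises back above zero within the hold
  # window, and the trace does go strictly negative
  kNeg <- ceiling(minNegativeMs / dtMs)
  qualifies <- vapply(down, function(i) {
    j <- (i + 1):min(n, i + 1 + kNeg)
    all(s[j] <= 0) && any(s[j] < 0)
  }, logical(1))
  if (!any(qualifies))
    return(list(time = NA_real_, quality = "no_crossing",
      nCandidates = nCand))
  first <- which(qualifies)[1]
  list(time = tc[first] - reference,
    quality = if (sum(qualifies) > 1L) "ambiguous" else "accepted",
    nCandidates = nCand)
}

#' Annotate zero crossings over the sites of a strain movie
#'
#' Applies \code{\link{detectZeroCrossing}} to every trace of a
#' \linkS4class{StrainMovie}, optionally overriding individual sites with a
#' manual-review table.
#'
#' @param movie a \linkS4class{StrainMovie}.
#' @param reference timing reference in ms on the movie clock; default 0
#'   (acquisition clock; co-registration subtracts the ECG reference later).
#' @param overrides optional data.frame (pixel, at) forcing activation times
#'   at specific sites, emulating manual review.
#' @param ... passed to \code{\link{detectZeroCrossing}}.
#' @return the movie's \code{sites} data.frame with columns \code{at},
#'   \code{quality} and \code{nCandidates} appended.
#' @export
annotateZeroCrossings <- function(movie, reference = 0, overrides = NULL,
                                  ...) {
  res <- lapply(seq_len(ncol(movie@frames)), function(j)
    detectZeroCrossing(movie@frames[, j], movie@frameRate,
      reference = reference, startMs = movie@startMs, ...))
  out <- movie@sites
  out$at <- vapply(res, `[[`, numeric(1), "time")
  out$quality <- vapply(res, `[[`, character(1), "quality")
  out$nCandidates <- vapply(res, `[[`, integer(1), "nCandidates")
  if (!is.null(overrides)) {
    stopifnot(all(c("pixel", "at") %in% names(overrides)))
    hit <- match(overrides$pixel, out$pixel)
    ok <- !is.na(hit)
    out$at[hit[ok]] <- overrides$at[ok]
    out$quality[hit[ok]] <- "accepted"
  }
  out
}
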