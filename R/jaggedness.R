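#' Peak/valley detection parameters
#'
#' The detector confirms an extremum once the signal has moved away from the
#' running candidate by at least `delta` and no value within the next
#' `lookahead` grid points beats the candidate. The defaults (lookahead 1,
#' delta 1e-4 in % reads units) resolve every strict local extremum of a
#' fragment-length histogram, which is what the jagged peak-valley index is
#' defined on.
#'
#' @param lookahead number of grid points scanned ahead before an extremum
#'   is confirmed (>= 1).
#' @param delta minimum amplitude difference, in the histogram's % reads
#'   units, required to confirm an extremum (>= 0).
#' @export
peak_detect_params <- function(lookahead = 1L, delta = 1e-4) {
  stopifnot(length(lookahead) == 1L, lookahead >= 1,
            length(delta) == 1L, delta >= 0)
  structure(list(lookahead = as.integer(lookahead), delta = delta),
            class = "PeakDetectParams")
}

#' Detect peaks and valleys in a size histogram
#'
#' Alternating delta-gated extremum search with lookahead over the % reads
#' histogram exactly as built (no smoothing). Semantics:
#' \itemize{
#'   \item running maxima/minima are tracked; a peak is confirmed at the
#'     current candidate when the signal drops at least `delta` below it and
#'     no value in the next `lookahead` points exceeds it (valleys mirrored);
#'   \item after a confirmation the search alternates, restarting from the
#'     confirming point;
#'   \item a candidate located at the first grid point switches the search
#'     mode but is not reported (boundary artefact);
#'   \item after the scan, a trailing candidate valley to the right of the
#'     last reported peak is reported, so a histogram ending on a descent
#'     contributes its final peak-valley drop.
#' }
#' Each reported peak is paired with the first valley to its right; a
#' trailing peak with no valley to its right enters `peaks` but not `pairs`.
#'
#' @param hist a `SizeHistogram` (or any data.frame with columns `length`,
#'   `percent_reads`).
#' @param params a [peak_detect_params()] object.
#' @return list of class `PeakValleySet` with data.tables `peaks(x, y)`,
#'   `valleys(x, y)` and `pairs(peak_x, peak_y, valley_x, valley_y)`.
#' @export
detect_peaks_valleys <- function(hist, params = peak_detect_params()) {
  x <- hist$length
  y <- hist$percent_reads
  n <- length(y)
  if (n < 3L) stop("histogram must have at least 3 grid points")
  stopifnot(!anyNA(y), !is.unsorted(x))
  la <- params$lookahead
  delta <- params$delta

  peaks_x <- numeric(); peaks_y <- numeric()
  vall_x <- numeric(); vall_y <- numeric()
  mx <- -Inf; mn <- Inf; mxpos <- NA_real_; mnpos <- NA_real_
  mxidx <- NA_integer_; mnidx <- NA_integer_
  mode <- "both"  # which extremum we are looking for

  for (i in seq_len(n)) {
    yi <- y[i]
    if (mode != "min" && yi > mx) { mx <- yi; mxpos <- x[i]; mxidx <- i }
    if (mode != "max" && yi < mn) { mn <- yi; mnpos <- x[i]; mnidx <- i }
    win <- y[i:min(i + la - 1L, n)]

    if (mode != "min" && is.finite(mx) && yi < mx - delta && max(win) < mx) {
      if (mxidx > 1L) { peaks_x <- c(peaks_x, mxpos); peaks_y <- c(peaks_y, mx) }
      mode <- "min"
      mn <- yi; mnpos <- x[i]; mnidx <- i
      mx <- -Inf
      next
    }
    if (mode != "max" && is.finite(mn) && yi > mn + delta && min(win) > mn) {
      if (mnidx > 1L) { vall_x <- c(vall_x, mnpos); vall_y <- c(vall_y, mn) }
      mode <- "max"
      mx <- yi; mxpos <- x[i]; mxidx <- i
      mn <- Inf
    }
  }
  # trailing valley after the last reported peak
  if (mode == "min" && length(peaks_x) &&
      is.finite(mn) && mnpos > peaks_x[length(peaks_x)] &&
      peaks_y[length(peaks_y)] - mn >= delta) {
    vall_x <- c(vall_x, mnpos); vall_y <- c(vall_y, mn)
  }

  peaks <- data.table::data.table(x = peaks_x, y = peaks_y)
  valleys <- data.table::data.table(x = vall_x, y = vall_y)
  pairs <- pair_peaks_valleys(peaks, valleys)
  structure(list(peaks = peaks, valleys = valleys, pairs = pairs),
            class = "PeakValleySet")
}

# Match each peak to the first valley strictly to its right.
pair_peaks_valleys <- function(peaks, valleys) {
  out <- data.table::data.table(peak_x = numeric(), peak_y = numeric(),
                                valley_x = numeric(), valley_y = numeric())
  for (i in seq_len(nrow(peaks))) {
    j <- which(valleys$x > peaks$x[i])
    if (length(j)) {
      j <- j[1L]
      out <- rbind(out, data.table::data.table(
        peak_x = peaks$x[i], peak_y = peaks$y[i],
        valley_x = valleys$x[j], valley_y = valleys$y[j]))
    }
  }
  out
}

#' @export
print.PeakValleySet <- function(x, ...) {
  cat("PeakValleySet:", nrow(x$peaks), "peaks,", nrow(x$valleys),
      "valleys,", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' Jagged peak-valley index
#'
#' The mean drop from each histogram peak to the first valley on its right,
#' `sum(P_i - V_i) / n` over the matched pairs, in % reads units. A
#' histogram with no matched pairs (featureless profile) scores 0.
#'
#' @param pvs a `PeakValleySet` from [detect_peaks_valleys()], or a
#'   `SizeHistogram` (detection is then run with `params`).
#' @param params detection parameters used when `pvs` is a histogram.
#' @return numeric scalar >= 0.
#' @export
jagged_index <- function(pvs, params = peak_detect_params()) {
  if (inherits(pvs, "SizeHistogram") || is.data.frame(pvs))
    pvs <- detect_peaks_valleys(pvs, params)
  stopifnot(inherits(pvs, "PeakValleySet"))
  if (nrow(pvs$pairs) == 0L) return(0)
  mean(pvs$pairs$peak_y - pvs$pairs$valley_y)
}
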