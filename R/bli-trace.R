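#' Construct a biolayer-interferometry trace
#'
#' One sensor's time series of interference shift with per-point phase
#' annotation. Phases must appear as contiguous blocks in the order
#' baseline, association, dissociation (any of the three may be absent).
#'
#' @param time Strictly increasing time points (s).
#' @param signal Interference shift (nm), same length as `time`, finite.
#' @param phase Character or factor per-point labels from
#'   `c("baseline", "association", "dissociation")`.
#' @param analyte_conc Analyte concentration (nM, >= 0).
#' @param sensor_id Sensor identifier string.
#' @param is_reference Logical; `TRUE` for a receptor-free control sensor.
#' @return An object of class `bli_trace`.
#' @export
bli_trace <- function(time, signal, phase, analyte_conc,
                      sensor_id = "S1", is_reference = FALSE) {
  time <- as.numeric(time); signal <- as.numeric(signal)
  phase <- as.character(phase)
  n <- length(time)
  if (length(signal) != n || length(phase) != n) {
    stop("time, signal and phase must have equal length")
  }
  if (n < 2L) stop("a trace needs at least 2 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (!is.numeric(analyte_conc) || analyte_conc < 0) {
    stop("analyte_conc must be >= 0")
  }
  levels <- c("baseline", "association", "dissociation")
  if (!all(phase %in% levels)) {
    stop("unknown phase label(s): ",
         paste(setdiff(unique(phase), levels), collapse = ", "))
  }
  runs <- rle(phase)$values
  if (anyDuplicated(runs)) stop("phase blocks must be contiguous")
  if (is.unsorted(match(runs, levels))) {
    stop("phase blocks must appear in the order baseline, association, dissociation")
  }
  structure(
    list(time = time, signal = signal, phase = phase,
         analyte_conc = as.numeric(analyte_conc),
         sensor_id = as.character(sensor_id),
         is_reference = isTRUE(is_reference)),
    class = "bli_trace"
  )
}

#' @export
print.bli_trace <- function(x, ...) {
  ph <- rle(x$phase)
  cat(sprintf("BLI trace '%s'%s: %d points, analyte %g nM\n", x$sensor_id,
              if (x$is_reference) " (reference)" else "",
              length(x$time), x$analyte_conc))
  for (i in seq_along(ph$values)) {
    cat(sprintf("  %-13s %d points\n", ph$values[i], ph$lengths[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.bli_trace <- function(x, ...) {
  data.frame(sensor_id = x$sensor_id, phase = x$phase, time_s = x$time,
             signal_nm = x$signal, analyte_nM = x$analyte_conc,
             is_reference = x$is_reference, stringsAsFactors = FALSE)
}

# Extract one phase with time re-zeroed at the phase boundary: the last
# point of the preceding phase (where the exponential starts), or the first
# point of the block when nothing precedes it.
.trace_phase <- function(trace, which) {
  idx <- trace$phase == which
  if (!any(idx)) return(NULL)
  first <- which(idx)[1]
  origin <- if (first > 1) trace$time[first - 1] else trace$time[first]
  list(time = trace$time[idx] - origin, signal = trace$signal[idx])
}

#' Preprocess a BLI trace: reference subtraction, smoothing, re-zeroing
#'
#' Standard biosensor trace conditioning: the paired receptor-free reference
#' trace is interpolated onto the sample grid and subtracted, the signal is
#' smoothed with a Savitzky-Golay polynomial filter (applied per phase so
#' that phase boundaries are not smeared), and the baseline mean (over the
#' final seconds of the baseline phase) is subtracted so the baseline sits
#' at zero. Phase labels are preserved.
#'
#' @param trace A [bli_trace()].
#' @param reference Optional receptor-free [bli_trace()] run in parallel;
#'   its time grid must overlap the trace grid (values are interpolated).
#' @param smoothing `NULL` to disable, or a list with elements `window`
#'   (odd number of points, default 11) and `order` (polynomial order,
#'   default 3, must be < window).
#' @param baseline_window Seconds at the end of the baseline phase used for
#'   re-zeroing (default 10).
#' @return A new [bli_trace()].
#' @export
preprocess_trace <- function(trace, reference = NULL,
                             smoothing = list(window = 11, order = 3),
                             baseline_window = 10) {
  stopifnot(inherits(trace, "bli_trace"))
  sig <- trace$signal
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "bli_trace"))
    if (max(reference$time) < min(trace$time) ||
        min(reference$time) > max(trace$time)) {
      stop("reference time grid does not overlap the trace")
    }
    ref <- stats::approx(reference$time, reference$signal, xout = trace$time,
                         rule = 2)$y
    sig <- sig - ref
  }
  if (!is.null(smoothing)) {
    window <- smoothing$window %||% 11
    order <- smoothing$order %||% 3
    if (window %% 2 == 0) stop("smoothing window must be odd")
    if (order >= window) stop("polynomial order must be < window")
    for (ph in unique(trace$phase)) {
      idx <- trace$phase == ph
      if (sum(idx) > window) {
        sig[idx] <- signal::sgolayfilt(sig[idx], p = order, n = window)
      }
    }
  }
  base_idx <- trace$phase == "baseline"
  if (any(base_idx)) {
    bt <- trace$time[base_idx]
    late <- base_idx & trace$time >= max(bt) - baseline_window
    sig <- sig - mean(sig[late])
  }
  bli_trace(trace$time, sig, trace$phase, trace$analyte_conc,
            trace$sensor_id, trace$is_reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
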