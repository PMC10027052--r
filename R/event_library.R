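#' Convert raw fluorescence to dF/F
#'
#' Converts a cells x trials x frames fluorescence tensor into fold change
#' relative to baseline, \eqn{(F - F0)/F0}, where F0 is a per-cell
#' percentile (default the 10th) of that cell's fluorescence pooled across
#' all of its trials and frames.
#'
#' @param raw 3-D numeric array, cells x trials x frames, nonnegative
#'   fluorescence.
#' @param frame_rate Imaging frame rate in Hz, stored as an attribute on the
#'   result.
#' @param f0_percentile Baseline percentile, default 10.
#' @param epsilon Baseline floor; F0 values at or below `epsilon` raise an
#'   error naming the offending cell.
#' @return A cells x trials x frames array of dF/F values with a
#'   `frame_rate` attribute.
#' @examples
#' raw <- array(5, dim = c(1, 2, 10))
#' compute_dfbf(raw)  # constant trace -> dF/F identically 0
#' @export
compute_dfbf <- function(raw, frame_rate = 14.5, f0_percentile = 10,
                         epsilon = 0) {
  check_dfbf(raw)
  n_c <- dim(raw)[1]
  out <- array(0, dim = dim(raw))
  for (ci in seq_len(n_c)) {
    f0 <- as.numeric(quantile(raw[ci, , ], f0_percentile / 100, names = FALSE))
    if (f0 <= epsilon)
      stop(sprintf("cell %d: baseline F0 = %g is not positive", ci, f0))
    out[ci, , ] <- (raw[ci, , ] - f0) / f0
  }
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Detect calcium events in a dF/F trace
#'
#' Marks maximal runs of consecutive frames whose value exceeds
#' mean(trace) + `k_sd` * SD(trace), and keeps runs of at least `min_run`
#' frames. The default `min_run = 5` reads the event criterion "more than
#' four consecutive frames" literally; pass `min_run = 4` for the inclusive
#' reading.
#'
#' @param trace Numeric dF/F vector for one cell-trial.
#' @param k_sd Threshold multiplier on the trace SD, default 2.
#' @param min_run Minimum run length in frames, default 5.
#' @return A data.frame with columns `start` (1-based frame) and `width`
#'   (frames). Zero rows when nothing exceeds threshold (including
#'   zero-variance traces).
#' @export
detect_events <- function(trace, k_sd = 2, min_run = 5) {
  trace <- as.numeric(trace)
  if (length(trace) < min_run)
    stop("trace shorter than `min_run`")
  if (any(!is.finite(trace))) stop("trace must be finite")
  m <- cpp_detect_events(trace, k_sd, as.integer(min_run))
  data.frame(start = m[, 1], width = m[, 2])
}

new_event_library <- function(events, frame_rate = 14.5) {
  if (!length(events)) stop("empty event library")
  widths <- vapply(events, function(e) length(e$trace), integer(1))
  structure(list(events = events, widths = widths, frame_rate = frame_rate),
            class = "tc_event_library")
}

#' Build an event library from a dF/F tensor
#'
#' Runs [detect_events()] on every cell-trial trace and stores each detected
#' event's dF/F snippet together with its start frame, width, source cell
#' and trial.
#'
#' @param dfbf cells x trials x frames dF/F array.
#' @param k_sd,min_run Event detection parameters, see [detect_events()].
#' @param frame_rate Frame rate in Hz; taken from the array attribute when
#'   present.
#' @return A `tc_event_library` object. Errors if no events are found
#'   anywhere in the tensor.
#' @export
build_event_library <- function(dfbf, k_sd = 2, min_run = 5,
                                frame_rate = NULL) {
  check_dfbf(dfbf)
  frame_rate <- frame_rate %||% attr(dfbf, "frame_rate") %||% 14.5
  d <- dim(dfbf)
  events <- list()
  for (ci in seq_len(d[1])) {
    for (tj in seq_len(d[2])) {
      trace <- as.numeric(dfbf[ci, tj, ])
      ev <- detect_events(trace, k_sd, min_run)
      for (k in seq_len(nrow(ev))) {
        idx <- ev$start[k]:(ev$start[k] + ev$width[k] - 1)
        events[[length(events) + 1]] <- list(
          trace = trace[idx], width = ev$width[k],
          source_cell = ci, trial = tj, start = ev$start[k])
      }
    }
  }
  if (!length(events))
    stop("empty event library: no calcium events detected in the tensor")
  new_event_library(events, frame_rate)
}

#' Build an event library directly from snippet traces
#'
#' Convenience constructor for curated or hand-made snippet collections
#' (each snippet becomes one event whose width is its length).
#'
#' @param traces List of numeric dF/F snippet vectors.
#' @param frame_rate Frame rate in Hz.
#' @return A `tc_event_library`.
#' @export
event_library_from_traces <- function(traces, frame_rate = 14.5) {
  events <- lapply(seq_along(traces), function(i) {
    tr <- as.numeric(traces[[i]])
    list(trace = tr, width = length(tr), source_cell = NA_integer_,
         trial = NA_integer_, start = NA_integer_)
  })
  new_event_library(events, frame_rate)
}

#' Summary statistics of event widths in a library
#'
#' @param lib A `tc_event_library`.
#' @return List with `mean`, `sd`, `n`, and `percentile`, a function mapping
#'   a percentile in 0-100 to a width.
#' @export
width_stats <- function(lib) {
  stopifnot(inherits(lib, "tc_event_library"))
  w <- lib$widths
  list(mean = mean(w),
       sd = if (length(w) >= 2) sd(w) else 0,
       n = length(w),
       percentile = function(p) as.numeric(quantile(w, p / 100, names = FALSE)))
}

#' @export
print.tc_event_library <- function(x, ...) {
  ws <- width_stats(x)
  cat(sprintf(
    "Calcium event library: %d events, width %.1f +/- %.1f frames (%.1f Hz)\n",
    ws$n, ws$mean, ws$sd, x$frame_rate))
  invisible(x)
}

#' Generate a synthetic calcium transient template library
#'
#' Download-free stand-in for an experimentally curated event library.
#' Events are discretized double-exponential transients
#' \eqn{A (e^{-t/\tau_d} - e^{-t/\tau_r})}, peak-normalized, scaled by an
#' amplitude drawn uniformly from `amp_range`, and truncated where the
#' decaying tail falls below 5% of the peak. Width diversity comes from an
#' integer jitter on the 5%-cutoff length, realized by time-dilating the
#' kernel so its cutoff lands on the jittered width. The defaults
#' (`tau_rise` 0.07 s, `tau_decay` 0.4 s) are GCaMP6f-like stand-ins.
#'
#' @param n_events Number of events to generate.
#' @param tau_rise,tau_decay Kernel time constants in seconds; requires
#'   `tau_decay > tau_rise > 0`.
#' @param amp_range Length-2 numeric, low and high peak dF/F amplitude.
#' @param width_jitter Maximum absolute integer jitter (frames) on the
#'   kernel's natural cutoff width; 0 gives identical widths.
#' @param frame_rate Frame rate in Hz.
#' @param seed Optional integer; the library is deterministic given the seed.
#' @param shape `"dexp"` for the double-exponential kernel, `"square"` for
#'   flat-top (boxcar) events of the same widths (useful for calibration,
#'   since threshold detection recovers boxcar widths exactly).
#' @return A `tc_event_library`.
#' @export
generate_template_library <- function(n_events = 500, tau_rise = 0.07,
                                      tau_decay = 0.4, amp_range = c(0.5, 2),
                                      width_jitter = 10, frame_rate = 14.5,
                                      seed = NULL,
                                      shape = c("dexp", "square")) {
  shape <- match.arg(shape)
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("require tau_decay > tau_rise > 0")
  if (n_events < 1) stop("n_events must be >= 1")
  dt <- 1 / frame_rate
  kernel <- function(t) exp(-t / tau_decay) - exp(-t / tau_rise)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  k_peak <- kernel(t_peak)
  # natural width: frames 0..L-1 where the last frame still has >= 5% of peak
  f <- ceiling(t_peak / dt)
  while (kernel(f * dt) >= 0.05 * k_peak) f <- f + 1
  base_width <- f  # frames 0 .. f-1
  with_seed(seed, {
    events <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      amp <- runif(1, amp_range[1], amp_range[2])
      j <- if (width_jitter > 0)
        sample.int(2 * width_jitter + 1, 1) - width_jitter - 1 else 0L
      w <- max(5L, base_width + as.integer(j))
      tr <- if (shape == "square") {
        rep(amp, w)
      } else {
        # dilate time so the 5% cutoff lands on the target width
        tt <- (seq_len(w) - 1) * dt * base_width / w
        amp * kernel(tt) / k_peak
      }
      events[[i]] <- list(trace = tr, width = w,
                          source_cell = NA_integer_, trial = NA_integer_,
                          start = NA_integer_)
    }
    new_event_library(events, frame_rate)
  })
}

#' Width-percentile event sampler
#'
#' Selects the subset of library events whose width lies within
#' `n_sd` library-width standard deviations of the width at the requested
#' percentile of the library width histogram, and returns a sampler drawing
#' uniformly from that eligible set.
#'
#' @param lib A `tc_event_library`.
#' @param percentile Target width percentile, 0-100.
#' @param n_sd Nonnegative integer; half-width of the eligibility band in
#'   library-width SDs.
#' @return A function `f(n = 1)` returning `n` event indices into
#'   `lib$events`; its `eligible` attribute holds the eligible index set.
#' @export
select_events_by_width <- function(lib, percentile, n_sd) {
  stopifnot(inherits(lib, "tc_event_library"))
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  ws <- width_stats(lib)
  target <- ws$percentile(percentile)
  band <- n_sd * ws$sd
  eligible <- which(lib$widths >= target - band & lib$widths <= target + band)
  if (!length(eligible))
    stop(sprintf(
      "no events within %g SD of the %g-th width percentile; increase n_sd",
      n_sd, percentile))
  sampler <- function(n = 1) {
    if (length(eligible) == 1) rep(eligible, n)
    else sample(eligible, n, replace = TRUE)
  }
  attr(sampler, "eligible") <- eligible
  attr(sampler, "target_width") <- target
  sampler
}
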