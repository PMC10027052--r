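#' Ridge-to-background area ratio of an averaged trace
#'
#' The ridge is a short window (by default 200 ms, i.e. 3 frames at
#' 14.5 Hz) centered on the peak frame; the ratio is the summed area in the
#' ridge divided by the summed area of all non-ridge frames. Negative dF/F
#' values are clipped at 0 before the sums so the ratio stays nonnegative.
#'
#' @param avg_trace Trial-averaged dF/F vector.
#' @param peak_frame 1-based center of the ridge window (clipped at the
#'   trace edges).
#' @param ridge_halfwidth Half-width of the ridge window in frames;
#'   the window spans `2 * ridge_halfwidth + 1` frames.
#' @return The ratio; `Inf` when all signal lies inside the ridge (zero
#'   background), `NaN` for an all-zero trace.
#' @export
r2b_ratio <- function(avg_trace, peak_frame, ridge_halfwidth = 1) {
  x <- pmax(as.numeric(avg_trace), 0)
  n <- length(x)
  if (peak_frame < 1 || peak_frame > n) stop("peak_frame outside the trace")
  lo <- max(1, peak_frame - ridge_halfwidth)
  hi <- min(n, peak_frame + ridge_halfwidth)
  ridge <- sum(x[lo:hi])
  bg <- sum(x) - ridge
  if (bg > 0) return(ridge / bg)
  if (ridge > 0) Inf else NaN
}

ridge_halfwidth_for <- function(frame_rate, ridge_seconds = 0.2) {
  w <- round(ridge_seconds * frame_rate)
  if (w %% 2 == 0) w <- w + 1  # odd so it can center on the peak
  (w - 1) / 2
}

#' Ridge-to-background scores for one cell
#'
#' Trials are split into two nonoverlapping halves by parity of the trial
#' index. The time of peak response is the argmax of the odd-trial average
#' within the stimulus window; the raw ratio (`r2b_raw`) is computed from
#' the even-trial average at that peak. Controls repeat the identical
#' split-half procedure after giving every trial an independent uniform
#' circular offset (independent peak on the shifted odd-half average,
#' ratio on the shifted even-half average), `n_boot` times, which keeps
#' the null calibrated: label-shuffled cells score near 1. `r2b_mean` is
#' the raw ratio over the mean control ratio; `boot_exceedance` is the
#' fraction of controls below the raw ratio. A second, independent control
#' set provides the null for thresholding the normalized score.
#'
#' @param cell trials x frames dF/F matrix (at least 2 trials).
#' @param stim_window Length-2 frames `(first, last)` searched for the peak.
#' @param n_boot Number of random-offset controls, default 1000.
#' @param frame_rate Hz, used to size the 200 ms ridge window.
#' @return List with `r2b_raw`, `r2b_mean`, `boot_exceedance`,
#'   `peak_frame`, and `mean_threshold` (99th percentile of the independent
#'   normalized control ratios).
#' @export
r2b_scores <- function(cell, stim_window, n_boot = 1000, frame_rate = 14.5) {
  cell <- as.matrix(cell)
  n_t <- nrow(cell); n_f <- ncol(cell)
  if (n_t < 2) stop("need at least 2 trials")
  stim_window <- as.integer(stim_window)
  if (length(stim_window) != 2 || stim_window[1] < 1 ||
      stim_window[2] > n_f || stim_window[1] > stim_window[2])
    stop("invalid (empty) stimulus window")
  hw <- ridge_halfwidth_for(frame_rate)

  odd <- seq(1, n_t, by = 2)
  even <- seq(2, n_t, by = 2)
  avg_a <- pmax(colMeans(cell[odd, , drop = FALSE]), 0)
  avg_b <- pmax(colMeans(cell[even, , drop = FALSE]), 0)
  win <- stim_window[1]:stim_window[2]
  peak <- win[peak_index(avg_a[win])]
  raw <- r2b_ratio(avg_b, peak, hw)

  controls <- cpp_r2b_controls(cell, stim_window[1], stim_window[2],
                               as.integer(hw), as.integer(n_boot))
  controls2 <- cpp_r2b_controls(cell, stim_window[1], stim_window[2],
                                as.integer(hw), as.integer(n_boot))
  ctrl_mean <- mean(controls)
  r2b_mean <- if (is.finite(ctrl_mean) && ctrl_mean > 0 && !is.nan(raw))
    raw / ctrl_mean else NaN
  exceed <- if (is.nan(raw)) 0 else mean(controls < raw, na.rm = TRUE)
  mean_thr <- if (is.finite(ctrl_mean) && ctrl_mean > 0)
    quantile(controls2 / mean(controls2), 0.99, names = FALSE,
             na.rm = TRUE) else NA_real_
  list(r2b_raw = raw, r2b_mean = r2b_mean, boot_exceedance = exceed,
       peak_frame = peak, mean_threshold = mean_thr)
}

#' Ridge-to-background family classification
#'
#' Runs the three r2b algorithms on every cell:
#' \describe{
#'   \item{r2bBoot}{control-exceedance fraction at or above
#'     `threshold_pct`/100 (default the 99th percentile);}
#'   \item{r2bMean}{normalized score `r2b_mean` above the 99th percentile of
#'     an independent set of normalized control ratios;}
#'   \item{r2bBase_O}{Otsu's threshold on the raw ratios across cells.}
#' }
#'
#' @param x A `tc_dataset` or a cells x trials x frames dF/F array.
#' @param stim_window Length-2 frames; defaults to the dataset's configured
#'   stimulus window.
#' @param n_boot Control iterations, default 1000.
#' @param frame_rate Hz (defaults to the dataset's).
#' @param threshold_pct Bootstrap significance percentile, default 99.
#' @param seed Optional RNG seed.
#' @return data.frame with per-cell `score_r2bBase` (raw ratio),
#'   `score_r2bMean`, and Boolean `pred_r2bMean`, `pred_r2bBoot`,
#'   `pred_r2bBase_O`.
#' @export
classify_r2b <- function(x, stim_window = NULL, n_boot = 1000,
                         frame_rate = NULL, threshold_pct = 99,
                         seed = NULL) {
  if (inherits(x, "tc_dataset")) {
    dfbf <- x$dfbf
    stim_window <- stim_window %||% stim_window_of(x$config)
    frame_rate <- frame_rate %||% x$config$frame_rate
  } else dfbf <- x
  check_dfbf(dfbf)
  if (is.null(stim_window)) stop("stim_window is required")
  frame_rate <- frame_rate %||% attr(dfbf, "frame_rate") %||% 14.5
  n_c <- dim(dfbf)[1]
  with_seed(seed, {
    raw <- rmean <- exceed <- numeric(n_c)
    mean_call <- logical(n_c)
    for (ci in seq_len(n_c)) {
      sc <- r2b_scores(cell_matrix(dfbf, ci), stim_window, n_boot,
                       frame_rate)
      raw[ci] <- sc$r2b_raw
      rmean[ci] <- sc$r2b_mean
      exceed[ci] <- sc$boot_exceedance
      mean_call[ci] <- !is.na(sc$mean_threshold) && !is.nan(sc$r2b_mean) &&
        sc$r2b_mean > sc$mean_threshold
    }
    data.frame(
      score_r2bBase = raw, score_r2bMean = rmean,
      pred_r2bMean = mean_call,
      pred_r2bBoot = exceed >= threshold_pct / 100,
      pred_r2bBase_O = otsu_classify(sanitize_scores(raw)))
  })
}
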