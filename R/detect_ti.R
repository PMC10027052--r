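#' Event-rate time histogram for one cell
#'
#' Frames are marked active when they fall inside a detected calcium event
#' (see [detect_events()]); activity is summed into time bins of `bin_size`
#' frames. The per-bin rate is the trial-averaged count of active frames
#' divided by the bin width; occupancy is the fraction of trial frames in
#' the bin (uniform except for a short final bin).
#'
#' @param cell trials x frames dF/F matrix.
#' @param bin_size Bin width in frames, default 3.
#' @param k_sd,min_run Event detection parameters.
#' @return List with `lambda` (per-bin rate), `p` (occupancy, sums to 1),
#'   `lambda_bar` (mean rate, equals `sum(p * lambda)`), `counts` and
#'   `bin_size`.
#' @export
bin_activity <- function(cell, bin_size = 3, k_sd = 2, min_run = 5) {
  cell <- as.matrix(cell)
  n_t <- nrow(cell); n_f <- ncol(cell)
  if (n_f < bin_size) stop("need at least one full bin of frames")
  counts <- cpp_bin_counts(cell, as.integer(bin_size), k_sd,
                           as.integer(min_run))
  n_bins <- length(counts)
  bw <- rep(bin_size, n_bins)
  if (n_f %% bin_size != 0) bw[n_bins] <- n_f %% bin_size
  lambda <- counts / (n_t * bw)
  p <- bw / n_f
  list(lambda = lambda, p = p, lambda_bar = sum(p * lambda),
       counts = counts, bin_size = bin_size)
}

#' Temporal information of a rate histogram
#'
#' Skaggs-form information per event:
#' \deqn{TI = \sum_j p_j \frac{\lambda_j}{\bar\lambda}
#'   \log_2 \frac{\lambda_j}{\bar\lambda}}
#' with \eqn{0 \log 0 := 0}; cells with no activity
#' (\eqn{\bar\lambda = 0}) score 0 bits.
#'
#' @param h Histogram from [bin_activity()].
#' @return Temporal information in bits (nonnegative).
#' @export
temporal_information <- function(h) {
  lb <- h$lambda_bar
  if (lb <= 0) return(0)
  r <- h$lambda / lb
  pos <- r > 0
  sum(h$p[pos] * r[pos] * log2(r[pos]))
}

#' Circularly shuffle each trial of a cell
#'
#' Each trial's trace is circularly shifted by an independent uniform offset
#' in `[0, n_frames)`; the per-trial frame-value multiset (and hence total
#' activity) is conserved exactly.
#'
#' @param cell trials x frames matrix.
#' @return Shuffled matrix of the same shape.
#' @export
circular_shuffle <- function(cell) {
  cell <- as.matrix(cell)
  n_f <- ncol(cell)
  for (t in seq_len(nrow(cell))) {
    o <- sample.int(n_f, 1) - 1L
    if (o > 0) cell[t, ] <- cell[t, c((n_f - o + 1):n_f, 1:(n_f - o))]
  }
  cell
}

#' Temporal-information bootstrap for one cell
#'
#' For each time bin, computes the fraction of circular-shuffle surrogates
#' in which the observed event rate exceeds the surrogate rate. The cell is
#' called positive when that exceedance fraction is above 0.99 in at least
#' two consecutive bins.
#'
#' @param cell trials x frames dF/F matrix.
#' @param n_iter Number of shuffle iterations, default 1000.
#' @param bin_size,k_sd,min_run See [bin_activity()].
#' @param exceedance Per-bin exceedance level, default 0.99.
#' @param min_consecutive Consecutive-bin requirement, default 2.
#' @return List with `exceedance` (per-bin fractions), `positive` (Boolean
#'   call) and `histogram` (the observed [bin_activity()] result).
#' @export
ti_bootstrap <- function(cell, n_iter = 1000, bin_size = 3, k_sd = 2,
                         min_run = 5, exceedance = 0.99,
                         min_consecutive = 2) {
  cell <- as.matrix(cell)
  if (n_iter < 1) stop("n_iter must be >= 1")
  h <- bin_activity(cell, bin_size, k_sd, min_run)
  exc <- cpp_ti_boot(cell, as.integer(bin_size), k_sd, as.integer(min_run),
                     as.integer(n_iter))
  r <- rle(exc > exceedance)
  positive <- any(r$values & r$lengths >= min_consecutive)
  list(exceedance = exc, positive = positive, histogram = h)
}

#' Activity filter and trial-averaged peak score
#'
#' The activity criterion requires detected calcium events in at least 25%
#' of trials. The peak score is the maximum over frames of the
#' trial-averaged dF/F trace (the base score of the tiMean algorithm).
#'
#' @param cell trials x frames dF/F matrix.
#' @param k_sd,min_run Event detection parameters.
#' @param min_fraction Required fraction of trials with activity,
#'   default 0.25.
#' @return List with `active_fraction`, `pass` (Boolean) and `peak_score`.
#' @export
activity_filter <- function(cell, k_sd = 2, min_run = 5,
                            min_fraction = 0.25) {
  cell <- as.matrix(cell)
  has_event <- vapply(seq_len(nrow(cell)), function(t) {
    nrow(cpp_detect_events(cell[t, ], k_sd, as.integer(min_run))) > 0
  }, logical(1))
  frac <- mean(has_event)
  list(active_fraction = frac, pass = frac >= min_fraction,
       peak_score = max(colMeans(cell)))
}

#' Temporal-information family classification
#'
#' Runs the five TI-family algorithms on every cell of a dF/F tensor:
#' \describe{
#'   \item{tiMean}{trial-averaged peak above the 99th percentile of
#'     circular-shuffle surrogate peaks, gated by the 25% activity filter;}
#'   \item{tiBoot}{per-bin rate exceedance above 0.99 in at least two
#'     consecutive bins ([ti_bootstrap()]);}
#'   \item{tiBoth}{logical AND of tiBoot and tiMean;}
#'   \item{tiMean_O, tiBase_O}{Otsu's threshold ([otsu_threshold()]) applied
#'     to the peak-score and temporal-information distributions across the
#'     dataset's cells.}
#' }
#'
#' @param x A `tc_dataset` or a cells x trials x frames dF/F array.
#' @param n_boot Bootstrap iterations, default 1000.
#' @param bin_size,k_sd,min_run Histogram / event detection parameters.
#' @param seed Optional RNG seed.
#' @return data.frame with per-cell columns `score_tiMean`, `score_tiBase`
#'   and Boolean `pred_tiMean`, `pred_tiBoot`, `pred_tiBoth`,
#'   `pred_tiMean_O`, `pred_tiBase_O`.
#' @export
classify_ti <- function(x, n_boot = 1000, bin_size = 3, k_sd = 2,
                        min_run = 5, seed = NULL) {
  dfbf <- if (inherits(x, "tc_dataset")) x$dfbf else x
  check_dfbf(dfbf)
  n_c <- dim(dfbf)[1]
  with_seed(seed, {
    peak <- ti <- numeric(n_c)
    boot <- mean_call <- logical(n_c)
    for (ci in seq_len(n_c)) {
      cell <- cell_matrix(dfbf, ci)
      tb <- ti_bootstrap(cell, n_iter = n_boot, bin_size = bin_size,
                         k_sd = k_sd, min_run = min_run)
      ti[ci] <- temporal_information(tb$histogram)
      boot[ci] <- tb$positive
      af <- activity_filter(cell, k_sd, min_run)
      peak[ci] <- af$peak_score
      null_peaks <- cpp_peak_null(cell, as.integer(n_boot))
      mean_call[ci] <- af$pass &&
        peak[ci] > quantile(null_peaks, 0.99, names = FALSE)
    }
    data.frame(
      score_tiMean = peak, score_tiBase = ti,
      pred_tiMean = mean_call, pred_tiBoot = boot,
      pred_tiBoth = boot & mean_call,
      pred_tiMean_O = otsu_classify(peak),
      pred_tiBase_O = otsu_classify(ti))
  })
}
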