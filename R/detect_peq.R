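#' Estimate time-cell parameters from data alone
#'
#' Data-side counterparts of the generator's control parameters, estimated
#' per cell from detected calcium events:
#' \describe{
#'   \item{htr_est}{fraction of trials containing at least one event whose
#'     peak lies inside the stimulus window;}
#'   \item{ew_mean, ew_sd}{mean and SD of detected event widths (frames);}
#'   \item{imp_sd}{SD of the per-hit-trial peak frames (frames), the
#'     imprecision estimate;}
#'   \item{noise_over_signal}{SD of all non-event frames divided by the
#'     maximum of the trial-averaged trace (0 when there is no signal).}
#' }
#' These estimator definitions are reconstructions: the published method
#' names the four quantities without defining the estimators.
#'
#' @param cell trials x frames dF/F matrix.
#' @param stim_window Length-2 frames `(first, last)`.
#' @param k_sd,min_run Event detection parameters.
#' @return Named list of the five estimates.
#' @export
estimate_cell_parameters <- function(cell, stim_window, k_sd = 2,
                                     min_run = 5) {
  cell <- as.matrix(cell)
  stim_window <- as.integer(stim_window)
  if (length(stim_window) != 2 || stim_window[1] < 1 ||
      stim_window[2] > ncol(cell) || stim_window[1] > stim_window[2])
    stop("invalid stimulus window")
  est <- cpp_peq_estimate(cell, stim_window[1], stim_window[2], k_sd,
                          as.integer(min_run))
  as.list(est)
}

#' Parametric-equation Q score
#'
#' Data-side analog of the reference quality:
#' \deqn{Q = HTR \exp\{-(\alpha N/S + \beta \, sd(EW)/mean(EW) +
#'   \gamma \, sd(Imp)/StimWin)\}}
#' with defaults \eqn{\alpha = 10, \beta = 1, \gamma = 10} (a ten-fold
#' heavier noise weight than the reference score uses).
#'
#' @param est Estimates from [estimate_cell_parameters()].
#' @param stim_win Stimulus window length in frames.
#' @param alpha,beta,gamma Term weights.
#' @return Scalar Q, with `0 <= Q <= htr_est`.
#' @export
compute_peq_score <- function(est, stim_win, alpha = 10, beta = 1,
                              gamma = 10) {
  if (stim_win <= 0) stop("stim_win must be positive")
  term <- alpha * est$noise_over_signal + gamma * est$imp_sd / stim_win
  if (est$ew_mean > 0) term <- term + beta * est$ew_sd / est$ew_mean
  est$htr_est * exp(-term)
}

#' Parametric-equation family classification
#'
#' Computes the Q score for every cell and classifies it two ways:
#' \describe{
#'   \item{peqBase}{Q above the 99th percentile of Q recomputed on
#'     circular-shuffle surrogates of the same cell;}
#'   \item{peqBase_O}{Otsu's threshold on the Q distribution across cells.}
#' }
#'
#' @param x A `tc_dataset` or a cells x trials x frames dF/F array.
#' @param stim_window Length-2 frames; defaults to the dataset's configured
#'   stimulus window.
#' @param n_boot Shuffle iterations, default 1000.
#' @param k_sd,min_run Event detection parameters.
#' @param alpha,beta,gamma Score weights, see [compute_peq_score()].
#' @param seed Optional RNG seed.
#' @return data.frame with per-cell `score_peqBase` plus the four parameter
#'   estimates and Boolean `pred_peqBase`, `pred_peqBase_O`.
#' @export
classify_peq <- function(x, stim_window = NULL, n_boot = 1000, k_sd = 2,
                         min_run = 5, alpha = 10, beta = 1, gamma = 10,
                         seed = NULL) {
  if (inherits(x, "tc_dataset")) {
    dfbf <- x$dfbf
    stim_window <- stim_window %||% stim_window_of(x$config)
  } else dfbf <- x
  check_dfbf(dfbf)
  if (is.null(stim_window)) stop("stim_window is required")
  stim_window <- as.integer(stim_window)
  swl <- stim_window[2] - stim_window[1] + 1
  n_c <- dim(dfbf)[1]
  with_seed(seed, {
    q <- htr <- ns <- ewm <- ews <- imp <- numeric(n_c)
    call <- logical(n_c)
    for (ci in seq_len(n_c)) {
      cell <- cell_matrix(dfbf, ci)
      est <- estimate_cell_parameters(cell, stim_window, k_sd, min_run)
      q[ci] <- compute_peq_score(est, swl, alpha, beta, gamma)
      htr[ci] <- est$htr_est; ns[ci] <- est$noise_over_signal
      ewm[ci] <- est$ew_mean; ews[ci] <- est$ew_sd; imp[ci] <- est$imp_sd
      null_q <- cpp_peq_null(cell, stim_window[1], stim_window[2], k_sd,
                             as.integer(min_run), swl, alpha, beta, gamma,
                             as.integer(n_boot))
      call[ci] <- q[ci] > quantile(null_q, 0.99, names = FALSE)
    }
    data.frame(
      score_peqBase = q, est_htr = htr, est_noise_over_signal = ns,
      est_ew_mean = ewm, est_ew_sd = ews, est_imp_sd = imp,
      pred_peqBase = call, pred_peqBase_O = otsu_classify(q))
  })
}
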