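# Shared fixtures, all generated in code.

# boxcar (flat-top) event library with controlled widths; threshold event
# detection recovers boxcar widths exactly on noiseless traces
square_library <- function(widths = c(6, 8, 10, 12, 14), amp = 1,
                           frame_rate = 14.5) {
  event_library_from_traces(lapply(widths, function(w) rep(amp, w)),
                            frame_rate = frame_rate)
}

# noiseless, imprecision-free, background-free config (overridable)
clean_config <- function(...) {
  defaults <- list(noise_type = "none", noise_percent = 0,
                   imprecision_type = "none", imprecision_fwhm = 0,
                   bg_for_time_cells = FALSE, bg_for_other_cells = FALSE,
                   bg_mean = 0, max_hit_trial_percent = 100,
                   hit_trial_assignment = "fixed")
  do.call(dataset_config, utils::modifyList(defaults, list(...)))
}

# R mirror of the C++ per-trial circular shuffle, consuming the RNG stream
# in the same order (one uniform draw per trial, floor(u * n_frames))
circular_shuffle_matching <- function(cell) {
  n_f <- ncol(cell)
  for (t in seq_len(nrow(cell))) {
    o <- min(floor(runif(1) * n_f), n_f - 1)
    if (o > 0) cell[t, ] <- cell[t, c((n_f - o + 1):n_f, 1:(n_f - o))]
  }
  cell
}

cpp_peq_null_r_wrap <- function(cell, sw, n_iter) {
  timecellbench:::cpp_peq_null(cell, sw[1], sw[2], 2, 5L,
                               sw[2] - sw[1] + 1, 10, 1, 10,
                               as.integer(n_iter))
}

# brute-force oracle for threshold-run event detection
brute_events <- function(trace, k_sd = 2, min_run = 5) {
  thr <- mean(trace) + k_sd * sd(trace)
  above <- trace > thr
  out <- data.frame(start = integer(0), width = integer(0))
  i <- 1
  n <- length(trace)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run)
        out <- rbind(out, data.frame(start = i, width = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# single-cell dF/F tensor from a trials x frames matrix
one_cell_tensor <- function(cell) {
  array(cell, dim = c(1, nrow(cell), ncol(cell)))
}

# a cell matrix with one boxcar event per trial at a fixed (or jittered) frame
aligned_cell <- function(n_trials = 20, n_frames = 246, peak = 100,
                         width = 9, amp = 1, hit_trials = seq_len(n_trials)) {
  cell <- matrix(0, n_trials, n_frames)
  half <- (width - 1) %/% 2
  for (t in hit_trials) {
    idx <- (peak - half):(peak - half + width - 1)
    cell[t, idx] <- amp
  }
  cell
}
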