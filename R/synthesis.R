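#' Synthetic dataset configuration
#'
#' Collects the 17 control parameters of the synthetic data generator plus
#' bookkeeping fields (dimensions, stimulus window, seed). Defaults give a
#' 135-cell, 60-trial, 246-frame session at 14.5 Hz with 50% time cells.
#'
#' @param n_cells,n_trials,n_frames Tensor dimensions.
#' @param frame_rate Frames per second.
#' @param time_cell_percent Percent of cells assigned tuned activity, 0-100.
#' @param cell_order `"basic"` (time cells get the lowest indices) or
#'   `"random"`.
#' @param max_hit_trial_percent Maximum percent of trials with a tuned event.
#' @param hit_trial_assignment `"fixed"` (exactly the maximum) or `"random"`
#'   (integer percent drawn uniformly from half the maximum to the maximum).
#' @param trial_order `"basic"` (hit trials are the lowest-indexed trials) or
#'   `"random"`.
#' @param event_width Length-2 numeric `(percentile, n_sd)` passed to
#'   [select_events_by_width()].
#' @param event_amp_factor Multiplicative amplitude scaling of every inserted
#'   event, default 1.
#' @param event_timing `"sequential"` (peak times tile the
#'   `start_frame:end_frame` window in cell-index order) or `"random"`.
#' @param start_frame,end_frame 1-based window of nominal peak times.
#' @param imprecision_fwhm Trial-pair timing jitter FWHM in frames.
#' @param imprecision_type `"none"`, `"uniform"` or `"normal"`.
#' @param noise_type `"gaussian"` or `"none"`.
#' @param noise_percent Gaussian noise SD as percent of the cell's maximum
#'   signal amplitude, 0-100.
#' @param bg_for_time_cells,bg_for_other_cells Switch background (untuned)
#'   events on for each cell class.
#' @param bg_mean Poisson mean number of background events per trial.
#' @param stim_window Length-2 frames `(first, last)` of the stimulus window
#'   used by the detectors and quality scores; defaults to
#'   `c(start_frame, end_frame)`.
#' @param seed Integer RNG seed; generation is deterministic given
#'   `(config, library, seed)`.
#' @return A validated `tc_config` list.
#' @export
dataset_config <- function(n_cells = 135, n_trials = 60, n_frames = 246,
                           frame_rate = 14.5, time_cell_percent = 50,
                           cell_order = c("basic", "random"),
                           max_hit_trial_percent = 100,
                           hit_trial_assignment = c("fixed", "random"),
                           trial_order = c("random", "basic"),
                           event_width = c(60, 1), event_amp_factor = 1,
                           event_timing = c("sequential", "random"),
                           start_frame = 30, end_frame = 220,
                           imprecision_fwhm = 0,
                           imprecision_type = c("none", "uniform", "normal"),
                           noise_type = c("gaussian", "none"),
                           noise_percent = 10,
                           bg_for_time_cells = FALSE,
                           bg_for_other_cells = FALSE, bg_mean = 0,
                           stim_window = NULL, seed = 1) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_trials = as.integer(n_trials),
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    time_cell_percent = time_cell_percent,
    cell_order = match.arg(cell_order),
    max_hit_trial_percent = max_hit_trial_percent,
    hit_trial_assignment = match.arg(hit_trial_assignment),
    trial_order = match.arg(trial_order),
    event_width = as.numeric(event_width),
    event_amp_factor = event_amp_factor,
    event_timing = match.arg(event_timing),
    start_frame = as.integer(start_frame), end_frame = as.integer(end_frame),
    imprecision_fwhm = imprecision_fwhm,
    imprecision_type = match.arg(imprecision_type),
    noise_type = match.arg(noise_type), noise_percent = noise_percent,
    bg_for_time_cells = isTRUE(bg_for_time_cells),
    bg_for_other_cells = isTRUE(bg_for_other_cells),
    bg_mean = bg_mean,
    stim_window = if (is.null(stim_window)) NULL else as.integer(stim_window),
    seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "tc_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1 || n_trials < 1 || n_frames < 1)
      stop("all dimensions must be >= 1")
    if (frame_rate <= 0) stop("frame_rate must be positive")
    if (time_cell_percent < 0 || time_cell_percent > 100)
      stop("time_cell_percent must be in [0, 100]")
    if (max_hit_trial_percent < 0 || max_hit_trial_percent > 100)
      stop("max_hit_trial_percent must be in [0, 100]")
    if (noise_percent < 0 || noise_percent > 100)
      stop("noise_percent must be in [0, 100]")
    if (!(start_frame >= 1 && start_frame <= end_frame &&
          end_frame <= n_frames))
      stop("require 1 <= start_frame <= end_frame <= n_frames")
    if (length(event_width) != 2 || event_width[2] < 0)
      stop("event_width must be (percentile, n_sd)")
    if (event_amp_factor < 0) stop("event_amp_factor must be >= 0")
    if (imprecision_fwhm < 0) stop("imprecision_fwhm must be >= 0")
    if (bg_mean < 0) stop("bg_mean (Poisson lambda) must be >= 0")
  })
  invisible(cfg)
}

stim_window_of <- function(cfg) {
  cfg$stim_window %||% c(cfg$start_frame, cfg$end_frame)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  fields <- unclass(cfg)
  fields$stim_window <- stim_window_of(cfg)
  writeLines(jsonlite::toJSON(fields[order(names(fields))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

watermark_string <- function(cfg) {
  paste0("SYNTHETIC-TIMECELL-BENCH:", config_hash(cfg))
}

#' Sample trial-pair timing imprecision offsets
#'
#' @param type `"none"` (all zeros), `"uniform"` (integers uniform on
#'   \[-fwhm/2, fwhm/2\]) or `"normal"` (rounded draws from
#'   Normal(0, fwhm / (2 sqrt(2 ln 2)))).
#' @param fwhm Full width at half maximum of the offset distribution, frames.
#' @param n Number of offsets.
#' @return Integer vector of signed frame offsets.
#' @export
sample_imprecision <- function(type = c("none", "uniform", "normal"),
                               fwhm = 0, n = 1) {
  type <- match.arg(type)
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (type == "none" || fwhm == 0) return(integer(n))
  if (type == "uniform") {
    vals <- seq(ceiling(-fwhm / 2), floor(fwhm / 2))
    as.integer(vals[sample.int(length(vals), n, replace = TRUE)])
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    as.integer(round(rnorm(n, 0, sigma)))
  }
}

#' Add Gaussian noise scaled to each cell's maximum signal
#'
#' Adds i.i.d. Gaussian frames with SD equal to `noise_percent`/100 times
#' that cell's maximum (pure-signal) amplitude; cells with no signal use
#' `fallback_max` (e.g. the library's maximum event amplitude).
#'
#' @param x cells x trials x frames signal array (pre-noise).
#' @param noise_percent Percent in 0-100; 0 returns `x` unchanged.
#' @param fallback_max Amplitude used for cells whose maximum signal is not
#'   positive.
#' @return The noisy array.
#' @export
add_noise <- function(x, noise_percent, fallback_max = 1) {
  check_dfbf(x)
  if (noise_percent < 0 || noise_percent > 100)
    stop("noise_percent must be in [0, 100]")
  if (noise_percent == 0) return(x)
  d <- dim(x)
  for (ci in seq_len(d[1])) {
    smax <- max(x[ci, , ])
    if (smax <= 0) smax <- fallback_max
    x[ci, , ] <- x[ci, , ] +
      rnorm(d[2] * d[3], 0, noise_percent / 100 * smax)
  }
  x
}

# Insert Poisson-count untuned events; k ~ Poisson(lambda) events per
# eligible cell-trial, event drawn uniformly from the whole library, start
# frame uniform over the trial, truncated at the trial end, additive.
insert_background <- function(x, eligible, lib, lambda, amp_factor = 1) {
  d <- dim(x)
  counts <- matrix(0L, d[1], d[2])
  if (lambda <= 0 || !any(eligible)) return(list(x = x, counts = counts))
  n_ev <- length(lib$events)
  for (ci in which(eligible)) {
    for (tj in seq_len(d[2])) {
      k <- rpois(1, lambda)
      counts[ci, tj] <- k
      if (k > 0) {
        for (e in seq_len(k)) {
          tr <- lib$events[[sample.int(n_ev, 1)]]$trace * amp_factor
          s0 <- sample.int(d[3], 1)
          idx <- s0:min(d[3], s0 + length(tr) - 1)
          x[ci, tj, idx] <- x[ci, tj, idx] + tr[seq_along(idx)]
        }
      }
    }
  }
  list(x = x, counts = counts)
}

#' Add background (untuned) events to a synthetic dataset
#'
#' @param dataset A `tc_dataset`.
#' @param lib Event library to draw from.
#' @param bg_mean Poisson mean events per trial; defaults to the dataset's
#'   configured value.
#' @param bg_for_time_cells,bg_for_other_cells Eligibility flags; default to
#'   the dataset's configuration.
#' @return The dataset with events superposed additively and
#'   `truth$background_counts` updated.
#' @export
add_background_events <- function(dataset, lib,
                                  bg_mean = dataset$config$bg_mean,
                                  bg_for_time_cells =
                                    dataset$config$bg_for_time_cells,
                                  bg_for_other_cells =
                                    dataset$config$bg_for_other_cells) {
  stopifnot(inherits(dataset, "tc_dataset"),
            inherits(lib, "tc_event_library"))
  if (bg_mean < 0) stop("bg_mean must be >= 0")
  is_tc <- dataset$truth$is_time_cell
  eligible <- (is_tc & bg_for_time_cells) | (!is_tc & bg_for_other_cells)
  res <- insert_background(dataset$dfbf, eligible, lib, bg_mean,
                           dataset$config$event_amp_factor)
  dataset$dfbf <- res$x
  dataset$truth$background_counts <-
    dataset$truth$background_counts + res$counts
  dataset
}

#' Generate a ground-truth-labeled synthetic dF/F dataset
#'
#' Builds a cells x trials x frames dF/F tensor of zeros, assigns time cells
#' and their nominal peak frames, inserts one width-selected,
#' amplitude-scaled calcium event per hit trial at the nominal time plus a
#' per-trial imprecision offset (events extending past the trial edge are
#' truncated), adds Poisson-count background events per the eligibility
#' flags, and finally adds Gaussian noise scaled to each cell's maximum
#' signal. Deterministic given `(config, lib, config$seed)`.
#'
#' @param config A `tc_config` from [dataset_config()].
#' @param lib A nonempty `tc_event_library`.
#' @return A `tc_dataset`: list with `dfbf` (array), `truth` (per-cell
#'   labels, hit-trial mask, assigned peak frames, realized hit-trial
#'   ratios, realized event widths and imprecision offsets, background
#'   counts), `config`, and a `watermark` string tagging the data as
#'   synthetic.
#' @export
generate_dataset <- function(config, lib) {
  stopifnot(inherits(config, "tc_config"), inherits(lib, "tc_event_library"))
  validate_config(config)
  n_c <- config$n_cells; n_t <- config$n_trials; n_f <- config$n_frames
  with_seed(config$seed, {
    n_tc <- round(config$time_cell_percent / 100 * n_c)
    is_tc <- logical(n_c)
    tc_idx <- if (config$cell_order == "basic") seq_len(n_tc)
              else sort(sample.int(n_c, n_tc))
    is_tc[tc_idx] <- TRUE

    nominal <- rep(NA_integer_, n_c)
    if (n_tc > 0) {
      nominal[tc_idx] <- if (config$event_timing == "sequential") {
        as.integer(round(seq(config$start_frame, config$end_frame,
                             length.out = n_tc)))
      } else {
        frames <- config$start_frame:config$end_frame
        as.integer(frames[sample.int(length(frames), n_tc, replace = TRUE)])
      }
    }

    sampler <- select_events_by_width(lib, config$event_width[1],
                                      config$event_width[2])
    x <- array(0, dim = c(n_c, n_t, n_f))
    hit_mask <- matrix(FALSE, n_c, n_t)
    peak_frames <- matrix(NA_integer_, n_c, n_t)
    offsets <- matrix(NA_integer_, n_c, n_t)
    widths <- vector("list", n_c)
    truncated <- 0L

    for (ci in tc_idx) {
      pct <- if (config$hit_trial_assignment == "fixed") {
        config$max_hit_trial_percent
      } else {
        lo <- floor(config$max_hit_trial_percent / 2)
        hi <- floor(config$max_hit_trial_percent)
        if (hi <= lo) lo else sample(lo:hi, 1)
      }
      n_hit <- as.integer(round(pct / 100 * n_t))
      if (n_hit == 0) { widths[[ci]] <- integer(0); next }
      hits <- if (config$trial_order == "basic") seq_len(n_hit)
              else sort(sample.int(n_t, n_hit))
      hit_mask[ci, hits] <- TRUE
      offs <- sample_imprecision(config$imprecision_type,
                                 config$imprecision_fwhm, length(hits))
      ws <- integer(length(hits))
      for (k in seq_along(hits)) {
        tr <- lib$events[[sampler(1)]]$trace * config$event_amp_factor
        pk <- peak_index(tr)
        target <- min(max(nominal[ci] + offs[k], 1L), n_f)
        s0 <- target - pk + 1L
        idx <- s0:(s0 + length(tr) - 1L)
        keep <- idx >= 1L & idx <= n_f
        if (!all(keep)) truncated <- truncated + 1L
        x[ci, hits[k], idx[keep]] <- x[ci, hits[k], idx[keep]] + tr[keep]
        ws[k] <- length(tr)
        peak_frames[ci, hits[k]] <- target
        offsets[ci, hits[k]] <- offs[k]
      }
      widths[[ci]] <- ws
    }

    bg_eligible <- (is_tc & config$bg_for_time_cells) |
      (!is_tc & config$bg_for_other_cells)
    bg <- insert_background(x, bg_eligible, lib, config$bg_mean,
                            config$event_amp_factor)
    x <- bg$x

    if (config$noise_type == "gaussian" && config$noise_percent > 0) {
      lib_max <- max(vapply(lib$events, function(e) max(e$trace),
                            numeric(1))) * config$event_amp_factor
      x <- add_noise(x, config$noise_percent, fallback_max = lib_max)
    }

    attr(x, "frame_rate") <- config$frame_rate
    truth <- list(
      is_time_cell = is_tc,
      hit_trial_mask = hit_mask,
      assigned_peak_frame = peak_frames,
      realized_htr = rowSums(hit_mask) / n_t,
      realized_event_widths = widths,
      realized_imprecision = offsets,
      background_counts = bg$counts,
      nominal_peak_frame = nominal,
      n_truncated_events = truncated)
    structure(list(dfbf = x, truth = truth, config = config,
                   watermark = watermark_string(config)),
              class = "tc_dataset")
  })
}

#' @export
print.tc_dataset <- function(x, ...) {
  d <- dim(x$dfbf)
  cat(sprintf(
    "Synthetic time-cell dataset: %d cells x %d trials x %d frames (%d time cells)\n",
    d[1], d[2], d[3], sum(x$truth$is_time_cell)))
  cat(" watermark:", x$watermark, "\n")
  invisible(x)
}

#' Reference quality score from generator inputs
#'
#' Ground-truth-side quality of a synthetic time cell:
#' \deqn{Q = HTR \exp\{-(\alpha \, MNP/100 \cdot EAF +
#'   \beta \, sd(EW)/mean(EW) + \gamma \, sd(Imp)/StimWin)\}}
#' with defaults \eqn{\alpha = 1, \beta = 1, \gamma = 10}.
#'
#' @param htr Hit trial ratio in \[0, 1\].
#' @param mnp Max noise percent (0-100).
#' @param eaf Event amplification factor.
#' @param ew Vector of inserted event widths, frames (must be nonempty when
#'   `htr > 0`).
#' @param imp Vector of realized imprecision offsets, frames.
#' @param stim_win Stimulus window length in frames (> 0).
#' @param alpha,beta,gamma Term weights.
#' @return Scalar quality in \[0, 1\] (for `mnp`, `eaf` within range).
#' @export
compute_reference_q <- function(htr, mnp, eaf, ew, imp, stim_win,
                                alpha = 1, beta = 1, gamma = 10) {
  if (stim_win <= 0) stop("stim_win must be positive")
  if (htr < 0 || htr > 1) stop("htr must be in [0, 1]")
  if (htr == 0) return(0)
  if (!length(ew)) stop("empty event width list for a time cell")
  if (mean(ew) <= 0) stop("mean event width must be positive")
  spread <- function(v) if (length(v) >= 2) sd(v) else 0
  htr * exp(-(alpha * mnp / 100 * eaf +
              beta * spread(ew) / mean(ew) +
              gamma * spread(imp) / stim_win))
}

#' Per-cell reference quality of a synthetic dataset
#'
#' Applies [compute_reference_q()] to every cell using the generator's
#' realized ground truth; non-time cells (and time cells that realized no
#' hit trials) score 0.
#'
#' @param dataset A `tc_dataset`.
#' @return Numeric vector, one quality value per cell.
#' @export
reference_q <- function(dataset) {
  stopifnot(inherits(dataset, "tc_dataset"))
  cfg <- dataset$config
  tr <- dataset$truth
  sw <- stim_window_of(cfg)
  swl <- sw[2] - sw[1] + 1
  mnp <- if (cfg$noise_type == "gaussian") cfg$noise_percent else 0
  q <- numeric(cfg$n_cells)
  for (ci in which(tr$is_time_cell)) {
    if (tr$realized_htr[ci] == 0) next
    imp <- tr$realized_imprecision[ci, ]
    q[ci] <- compute_reference_q(
      htr = tr$realized_htr[ci], mnp = mnp, eaf = cfg$event_amp_factor,
      ew = tr$realized_event_widths[[ci]], imp = imp[!is.na(imp)],
      stim_win = swl)
  }
  q
}
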