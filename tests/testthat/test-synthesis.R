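test_that("imprecision offsets follow the requested distribution", {
  expect_equal(sample_imprecision("none", 10, 50), integer(50))
  expect_equal(sample_imprecision("uniform", 0, 5), integer(5))

  set.seed(11)
  u <- sample_imprecision("uniform", 10, 5000)
  expect_true(all(u >= -5 & u <= 5))

  # FWHM -> sigma conversion: sigma = fwhm / (2 sqrt(2 ln 2)) ~ 4.2466
  set.seed(12)
  z <- sample_imprecision("normal", 10, 50000)
  expect_equal(sd(z), 10 / (2 * sqrt(2 * log(2))), tolerance = 0.02)

  expect_error(sample_imprecision("uniform", -1, 5), "fwhm")
})

test_that("reference quality evaluates the generator-side equation", {
  # no degradation: q = htr
  expect_equal(compute_reference_q(1, 0, 1, ew = c(8, 8), imp = c(0, 0),
                                   stim_win = 100), 1)
  expect_equal(compute_reference_q(0, 50, 1, ew = 8, imp = 0,
                                   stim_win = 100), 0)
  # htr 0.5, noise 50%, all spreads zero: 0.5 * exp(-0.5)
  expect_equal(compute_reference_q(0.5, 50, 1, ew = c(10, 10), imp = 0,
                                   stim_win = 100), 0.5 * exp(-0.5))
  expect_error(compute_reference_q(0.5, 0, 1, ew = numeric(0), imp = 0,
                                   stim_win = 100), "empty")
})

test_that("generation honors the time-cell fraction and determinism", {
  lib <- square_library()
  cfg <- clean_config(n_cells = 10, n_trials = 8, time_cell_percent = 0,
                      seed = 5)
  ds <- generate_dataset(cfg, lib)
  expect_false(any(ds$truth$is_time_cell))
  expect_true(all(ds$dfbf == 0))

  cfg2 <- clean_config(n_cells = 12, n_trials = 10, seed = 6)
  ds2 <- generate_dataset(cfg2, lib)
  expect_equal(mean(ds2$truth$is_time_cell),
               round(50 / 100 * 12) / 12)
  # non-time cells have no hit trials
  expect_true(all(!ds2$truth$hit_trial_mask[!ds2$truth$is_time_cell, ]))
  # bit-identical regeneration from the same (config, library, seed)
  ds3 <- generate_dataset(cfg2, lib)
  expect_identical(ds2$dfbf, ds3$dfbf)
  expect_identical(ds2$truth, ds3$truth)
  expect_match(ds2$watermark, "^SYNTHETIC-TIMECELL-BENCH:")
})

test_that("imprecision 'none' puts every hit-trial peak at the nominal frame", {
  lib <- square_library(c(9, 9, 9))
  cfg <- clean_config(n_cells = 6, n_trials = 10, seed = 9,
                      event_width = c(50, 1))
  ds <- generate_dataset(cfg, lib)
  tr <- ds$truth
  for (ci in which(tr$is_time_cell)) {
    pk <- tr$assigned_peak_frame[ci, ]
    expect_true(all(pk[!is.na(pk)] == tr$nominal_peak_frame[ci]))
  }
  expect_true(all(tr$realized_imprecision[!is.na(tr$realized_imprecision)]
                  == 0))
})

test_that("noiseless full-HTR datasets are exactly recovered by detection", {
  lib <- square_library(c(9, 11, 13))
  cfg <- clean_config(n_cells = 8, n_trials = 12, seed = 13,
                      event_width = c(50, 2))
  ds <- generate_dataset(cfg, lib)
  tr <- ds$truth
  for (ci in seq_len(cfg$n_cells)) {
    n_ev <- 0
    widths <- integer(0)
    for (tj in seq_len(cfg$n_trials)) {
      ev <- detect_events(ds$dfbf[ci, tj, ])
      n_ev <- n_ev + nrow(ev)
      widths <- c(widths, ev$width)
    }
    if (tr$is_time_cell[ci]) {
      expect_equal(n_ev, cfg$n_trials)  # one event per hit trial
      expect_equal(sort(widths), sort(tr$realized_event_widths[[ci]]))
    } else {
      expect_equal(n_ev, 0)
    }
  }
  # empirical HTR from detected events equals the realized HTR
  has_ev <- vapply(seq_len(cfg$n_trials), function(tj)
    nrow(detect_events(ds$dfbf[1, tj, ])) > 0, logical(1))
  expect_equal(mean(has_ev), tr$realized_htr[1])
})

test_that("noise SD scales with the stated percent of peak signal", {
  lib <- square_library(c(9), amp = 1)
  cfg <- clean_config(n_cells = 2, n_trials = 40, time_cell_percent = 50,
                      noise_type = "gaussian", noise_percent = 10,
                      event_width = c(50, 1), seed = 31)
  ds <- generate_dataset(cfg, lib)
  # non-signal cell: SD of all frames ~ 10% of the library max amplitude
  other <- which(!ds$truth$is_time_cell)[1]
  expect_equal(sd(ds$dfbf[other, , ]), 0.10, tolerance = 0.02)

  # doubling the amplitude doubles the noise on the signal-free cell
  cfg2 <- cfg; cfg2$event_amp_factor <- 2
  ds2 <- generate_dataset(cfg2, lib)
  expect_equal(sd(ds2$dfbf[other, , ]) / sd(ds$dfbf[other, , ]), 2,
               tolerance = 0.1)

  # zero percent leaves the array untouched
  expect_identical(add_noise(ds$dfbf, 0), ds$dfbf)
})

test_that("background insertion follows the Poisson mean and flags", {
  lib <- square_library(c(7))
  cfg <- clean_config(n_cells = 4, n_trials = 60, time_cell_percent = 50,
                      seed = 17)
  ds <- generate_dataset(cfg, lib)

  # flags off: unchanged
  ds0 <- add_background_events(ds, lib, bg_mean = 2,
                               bg_for_time_cells = FALSE,
                               bg_for_other_cells = FALSE)
  expect_identical(ds0$dfbf, ds$dfbf)
  # lambda 0: no events
  set.seed(1)
  dsz <- add_background_events(ds, lib, bg_mean = 0,
                               bg_for_time_cells = TRUE,
                               bg_for_other_cells = TRUE)
  expect_identical(dsz$dfbf, ds$dfbf)

  # lambda 2 over 60 trials: ~120 events per cell on average
  set.seed(2)
  dsb <- add_background_events(ds, lib, bg_mean = 2,
                               bg_for_time_cells = TRUE,
                               bg_for_other_cells = TRUE)
  per_cell <- rowSums(dsb$truth$background_counts)
  expect_equal(mean(per_cell), 120, tolerance = 0.1)
})

test_that("per-cell reference q is bounded and declines with noise", {
  lib <- generate_template_library(n_events = 100, seed = 41)
  qs_by_noise <- sapply(c(10, 40, 70), function(np) {
    mean(sapply(1:10, function(s) {
      cfg <- dataset_config(n_cells = 10, n_trials = 10, noise_percent = np,
                            max_hit_trial_percent = 66,
                            hit_trial_assignment = "random", seed = s)
      ds <- generate_dataset(cfg, lib)
      q <- reference_q(ds)
      expect_true(all(q >= 0 & q <= 1))
      expect_true(all(q <= ds$truth$realized_htr + 1e-12))
      mean(q[ds$truth$is_time_cell])
    }))
  })
  expect_true(all(diff(qs_by_noise) < 0))
})

test_that("the benchmark suite enumerates the published design", {
  configs <- build_benchmark_suite(scale = 1)
  expect_length(configs, 567)
  expect_equal(sum(vapply(configs, `[[`, integer(1), "n_cells")), 76545)
  seeds <- vapply(configs, `[[`, integer(1), "seed")
  expect_equal(anyDuplicated(seeds), 0)
  regimes <- vapply(configs, attr, character(1), "regime")
  expect_equal(unname(table(regimes)[c("unphysiological", "canonical",
                                       "physiological")]),
               c(99L * 3L, 12L * 10L, 15L * 10L),
               ignore_attr = TRUE)
  # 50% time cells except where the fraction itself is modulated
  tcp <- vapply(configs, `[[`, numeric(1), "time_cell_percent")
  mod <- vapply(configs, attr, character(1), "modulated_param")
  expect_true(all(tcp[mod != "time_cell_percent"] == 50))

  # desk-scale reduction: one shuffle per case
  small <- build_benchmark_suite(shuffles_per_case = 1, n_cells = 45,
                                 n_trials = 30)
  expect_length(small, 99 + 12 + 15)
  expect_true(attr(small, "scaled"))
})

test_that("dataset containers round-trip dfbf, truth and watermark", {
  lib <- square_library()
  ds <- generate_dataset(clean_config(n_cells = 5, n_trials = 6, seed = 3),
                         lib)
  path <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_identical(back$dfbf, ds$dfbf)
  expect_identical(back$truth, ds$truth)
  expect_identical(back$watermark, ds$watermark)
})

test_that("results tables round-trip through CSV", {
  lib <- square_library()
  ds <- generate_dataset(clean_config(n_cells = 4, n_trials = 8, seed = 2),
                         lib)
  res <- score_dataset(ds, n_boot = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  back <- read_results(path)
  for (a in tc_algorithms())
    expect_identical(back[[paste0("pred_", a)]], res[[paste0("pred_", a)]])
  expect_equal(back$score_tiBase, res$score_tiBase)
  expect_identical(back$truth, res$truth)
})
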