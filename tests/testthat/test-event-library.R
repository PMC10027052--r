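test_that("dF/F conversion uses the pooled 10th-percentile baseline", {
  # constant fluorescence: F0 equals F, dF/F identically zero
  raw <- array(5, dim = c(1, 2, 10))
  expect_equal(as.numeric(compute_dfbf(raw)), rep(0, 20))

  # 90% of frames at 10, 10% at 20: F0 = 10, peak dF/F = 1
  vals <- c(rep(10, 90), rep(20, 10))
  raw <- array(vals, dim = c(1, 1, 100))
  df <- compute_dfbf(raw)
  expect_equal(max(df), 1.0)
  expect_equal(min(df), 0.0)

  # non-positive baseline is an error naming the cell
  raw <- array(0, dim = c(2, 1, 10))
  raw[2, 1, ] <- 5
  expect_error(compute_dfbf(raw), "cell 1")
})

test_that("dF/F is invariant under positive rescaling of a cell", {
  set.seed(42)
  raw <- array(runif(2 * 3 * 50, 1, 4), dim = c(2, 3, 50))
  scaled <- raw
  scaled[1, , ] <- scaled[1, , ] * 7.3
  expect_equal(compute_dfbf(scaled)[1, , ], compute_dfbf(raw)[1, , ])
})

test_that("event detection finds suprathreshold runs of sufficient length", {
  expect_equal(nrow(detect_events(rep(0, 100))), 0)

  # flat baseline with an 8-frame suprathreshold plateau
  tr <- rep(0, 100)
  tr[21:28] <- 5
  ev <- detect_events(tr)
  expect_equal(ev$start, 21)
  expect_equal(ev$width, 8)

  # a 3-frame blip is below the minimum run length
  tr <- rep(0, 100)
  tr[51:53] <- 5
  expect_equal(nrow(detect_events(tr)), 0)

  expect_error(detect_events(c(1, 2)), "min_run")
})

test_that("event detection matches the brute-force run oracle", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(10:120, 1)
    tr <- rnorm(n)
    if (runif(1) < 0.3) tr[sample(n, min(n, 8))] <- tr[sample(n, 1)] + 4
    min_run <- sample(2:6, 1)
    got <- detect_events(tr, min_run = min_run)
    want <- brute_events(tr, min_run = min_run)
    expect_equal(got$start, want$start)
    expect_equal(got$width, want$width)
    # events never overlap and stay inside the trace
    if (nrow(got) > 1)
      expect_true(all(diff(got$start) >= got$width[-nrow(got)]))
    expect_true(all(got$start >= 1 & got$start + got$width - 1 <= n))
  }
})

test_that("library curation stores snippets and width statistics", {
  expect_error(build_event_library(array(0, dim = c(2, 2, 50))),
               "empty")

  x <- array(0, dim = c(1, 1, 60))
  x[1, 1, 11:19] <- 2
  lib <- build_event_library(x)
  expect_equal(length(lib$events), 1)
  expect_equal(lib$events[[1]]$width, 9)
  expect_equal(lib$events[[1]]$start, 11)
  expect_equal(lib$events[[1]]$trace, rep(2, 9))

  ws <- width_stats(lib)
  expect_equal(ws$mean, mean(lib$widths))
})

test_that("template library width matches the analytic 5% cutoff", {
  tau_r <- 0.07; tau_d <- 0.4; fr <- 14.5
  lib <- generate_template_library(n_events = 1, tau_rise = tau_r,
                                   tau_decay = tau_d, amp_range = c(1, 1),
                                   width_jitter = 0, frame_rate = fr,
                                   seed = 1)
  # closed-form cutoff: last time after the peak with k(t) >= 5% of peak
  k <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
  tp <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  tc <- uniroot(function(t) k(t) - 0.05 * k(tp), c(tp, 10))$root
  expect_equal(lib$widths, floor(tc * fr) + 1)

  # determinism under the same seed
  lib2 <- generate_template_library(n_events = 20, seed = 99)
  lib3 <- generate_template_library(n_events = 20, seed = 99)
  expect_identical(lib2$widths, lib3$widths)
  expect_identical(lib2$events[[5]]$trace, lib3$events[[5]]$trace)

  # vanishing rise time: the peak collapses onto the trace start (frame 1
  # samples t = 0 where the kernel is exactly 0) and the tail decays
  lib4 <- generate_template_library(n_events = 1, tau_rise = 1e-6,
                                    tau_decay = 0.4, amp_range = c(1, 1),
                                    width_jitter = 0, seed = 1)
  tr4 <- lib4$events[[1]]$trace
  expect_lte(which.max(tr4), 2)
  expect_true(all(diff(tr4[which.max(tr4):length(tr4)]) <= 0))

  expect_error(generate_template_library(tau_rise = 0.5, tau_decay = 0.4),
               "tau")
})

test_that("curation recovers template widths up to threshold flooring", {
  lib <- generate_template_library(n_events = 8, width_jitter = 6,
                                   seed = 21)
  # insert each event alone into a noiseless trace and re-detect
  for (e in lib$events) {
    tr <- rep(0, 246)
    tr[40:(40 + e$width - 1)] <- e$trace
    ev <- detect_events(tr)
    expect_equal(nrow(ev), 1)
    expect_lte(ev$width, e$width)     # tails below threshold are clipped
    expect_gte(ev$width, 5)
  }
})

test_that("width-percentile sampler selects the eligible band", {
  # all widths equal: any percentile, zero band still keeps everything
  lib_eq <- square_library(rep(8, 5))
  s <- select_events_by_width(lib_eq, 30, 0)
  expect_equal(sort(attr(s, "eligible")), 1:5)

  lib <- square_library(c(4, 6, 8, 10, 12))
  s50 <- select_events_by_width(lib, 50, 0)
  expect_equal(attr(s50, "eligible"), 3L)  # the median-width event only
  set.seed(1)
  expect_true(all(s50(20) == 3L))

  # a wide band spans the whole library
  sall <- select_events_by_width(lib, 50, 2)
  expect_equal(sort(attr(sall, "eligible")), 1:5)

  # percentile falling between widths with a zero band: nothing eligible
  expect_error(select_events_by_width(lib, 10, 0), "n_sd")
})
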