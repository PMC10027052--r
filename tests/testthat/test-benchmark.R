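test_that("confusion counts enumerate the truth table", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(confusion(truth, truth),
               c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  expect_equal(confusion(!truth, truth),
               c(tp = 0L, fp = 2L, tn = 0L, fn = 2L))
  expect_equal(confusion(c(TRUE, FALSE, TRUE, FALSE), truth),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion(TRUE, truth), "length")
})

test_that("metrics follow their definitions with degenerate guards", {
  m <- tc_metrics(c(tp = 3, fp = 1, tn = 0, fn = 1))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  perfect <- tc_metrics(c(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(perfect[c("recall", "precision", "f1", "accuracy")]),
               c(recall = 1, precision = 1, f1 = 1, accuracy = 1))

  none <- tc_metrics(c(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)
  expect_true(none$flagged)
})

test_that("metrics agree with definitional counting on random cases", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(3:100, 1)
    truth <- runif(n) < runif(1)
    pred <- runif(n) < runif(1)
    cc <- confusion(pred, truth)
    expect_equal(sum(cc), n)
    m <- tc_metrics(cc)
    if (any(pred) && any(truth)) {
      expect_equal(m$precision, sum(pred & truth) / sum(pred))
      expect_equal(m$recall, sum(pred & truth) / sum(truth))
      if (m$precision + m$recall > 0) {
        expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
        expect_lte(m$f1, (m$precision + m$recall) / 2 + 1e-12)
      }
    }
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("Otsu threshold maximizes between-class variance", {
  # perfectly separable scores split strictly between the classes
  th <- otsu_threshold(c(0, 0, 0, 1, 1, 1))
  expect_gt(th, 0)
  expect_lt(th, 1)
  expect_equal(c(0, 0, 0, 1, 1, 1) > th, rep(c(FALSE, TRUE), each = 3))

  # degenerate constant input: sentinel -> all-negative classification
  expect_identical(otsu_threshold(rep(2, 10)), Inf)

  # equivalence with exhaustive search over all candidate bin thresholds,
  # scoring each split by the definitional weighted between-class variance
  brute_otsu <- function(s, n_bins = 256) {
    lo <- min(s); hi <- max(s)
    x <- (s - lo) / (hi - lo)
    idx <- pmin(pmax(ceiling(x * n_bins), 1L), n_bins)
    mids <- (seq_len(n_bins) - 0.5) / n_bins
    v <- mids[idx]
    best <- -Inf; kb <- 1
    for (k in seq_len(n_bins - 1)) {
      g0 <- v[idx <= k]; g1 <- v[idx > k]
      if (!length(g0) || !length(g1)) next
      w0 <- length(g0) / length(v); w1 <- 1 - w0
      sb <- w0 * w1 * (mean(g0) - mean(g1))^2
      if (sb > best + 1e-15) { best <- sb; kb <- k }
    }
    lo + (kb / n_bins) * (hi - lo)
  }
  set.seed(44)
  for (i in 1:50) {
    s <- c(rnorm(sample(5:40, 1)), rnorm(sample(5:40, 1), mean = 3))
    expect_equal(otsu_threshold(s), brute_otsu(s))
  }
})

test_that("score and prediction correlations behave on known inputs", {
  n <- 10000
  set.seed(55)
  a <- rnorm(n)
  res <- data.frame(score_tiMean = a, score_tiBase = a,
                    score_r2bBase = -a, score_peqBase = rnorm(n))
  sc <- score_correlations(res)
  expect_equal(diag(sc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sc["tiMean", "tiBase"], 1)
  expect_equal(sc["tiMean", "r2bBase"], -1)
  expect_lt(abs(sc["tiMean", "peqBase"]), 0.05)

  # independent random Booleans decorrelate at large n
  pred <- as.data.frame(matrix(runif(n * 10) < 0.5, n, 10))
  names(pred) <- paste0("pred_", tc_algorithms())
  pc <- prediction_correlations(pred)
  expect_equal(diag(pc), rep(1, 10), ignore_attr = TRUE)
  expect_lt(max(abs(pc[upper.tri(pc)])), 0.05)
})

test_that("ROC analysis sweeps thresholds and finds the Youden point", {
  truth <- rep(c(FALSE, TRUE), each = 20)
  scores <- c(rnorm(20, 0), rnorm(20, 10))
  r <- roc_and_threshold(scores, truth)
  expect_equal(r$auc, 1)
  # best threshold separates the classes
  expect_equal(scores > r$best_threshold, truth)

  # reversing the score sign flips the AUC
  r2 <- roc_and_threshold(-scores, truth)
  expect_equal(r2$auc, 1 - r$auc)

  # truth-independent scores have AUC near 1/2
  set.seed(66)
  r3 <- roc_and_threshold(rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_equal(r3$auc, 0.5, tolerance = 0.05)

  expect_error(roc_and_threshold(1:5, rep(TRUE, 5)), "class")
})

test_that("concordance counts agreeing algorithms", {
  pred <- matrix(FALSE, 3, 10)
  pred[1, 1:4] <- TRUE   # 4 positives
  pred[2, 1] <- TRUE     # 1 positive
  expect_equal(concordance_classify(pred, 1), c(TRUE, TRUE, FALSE))
  expect_equal(concordance_classify(pred, 10), c(FALSE, FALSE, FALSE))
  expect_equal(concordance_classify(pred, 4), c(TRUE, FALSE, FALSE))
  expect_equal(concordance_classify(pred, 5), c(FALSE, FALSE, FALSE))
  expect_error(concordance_classify(pred, 11), "threshold")

  sweep <- concordance_sweep(pred, truth = c(TRUE, FALSE, FALSE))
  expect_equal(nrow(sweep), 10)
  expect_equal(attr(sweep, "best_threshold"), 2)  # lowest F1-maximizing
})

test_that("sensitivity slopes come from OLS with a slope-zero test", {
  # constant response: zero slope, not significant
  d <- expand.grid(level = c(10, 40, 70), rep = 1:5)
  d$algorithm <- "a"
  d$f1 <- 0.9
  s <- suppressWarnings(parameter_sensitivity(d))  # perfect-fit warning
  expect_equal(s$slope, 0)
  expect_false(s$significant)

  # exact linear response: slope recovered, p ~ 0
  d2 <- d
  d2$f1 <- 1 - 0.005 * d2$level + rnorm(nrow(d2), 0, 1e-6)
  s2 <- parameter_sensitivity(d2)
  expect_equal(s2$slope, -0.005, tolerance = 1e-4)
  expect_lt(s2$p_value, 1e-6)
  expect_true(s2$significant)

  # two levels: slope is the two-point difference quotient
  d3 <- data.frame(level = rep(c(0, 10), each = 3), algorithm = "a")
  d3$f1 <- ifelse(d3$level == 0, 0.8, 0.6)
  expect_equal(suppressWarnings(parameter_sensitivity(d3))$slope,
               (0.6 - 0.8) / 10)

  expect_error(parameter_sensitivity(data.frame(
    level = 1, algorithm = "a", f1 = 1)), "degenerate")
})
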