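#' Confusion counts of a prediction against ground truth
#'
#' @param pred,truth Logical (or 0/1) vectors of equal length.
#' @return Named integer vector `(tp, fp, tn, fn)` summing to the number of
#'   cells.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (any(is.na(pred)) || any(is.na(truth))) stop("NA in predictions/truth")
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Classification metrics from confusion counts
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F1 the harmonic mean of the
#' two, accuracy = (TP+TN)/total. Degenerate denominators yield 0 and set
#' the `flagged` field (so batch tables never carry NaN).
#'
#' @param counts Output of [confusion()].
#' @return List with `recall`, `precision`, `f1`, `accuracy`, `flagged`.
#' @export
tc_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  flagged <- FALSE
  safe <- function(num, den) {
    if (den > 0) return(num / den)
    flagged <<- TRUE
    0
  }
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    flagged <- TRUE
    0
  }
  list(recall = recall, precision = precision, f1 = f1,
       accuracy = safe(tp + tn, tp + fp + tn + fn), flagged = flagged)
}

#' Otsu's threshold
#'
#' Min-max normalizes the scores to \[0, 1\], forms a 256-bin histogram and
#' returns (on the original scale) the threshold maximizing the
#' between-class variance. Ties take the lowest threshold. A zero-variance
#' (or all non-finite) input returns `Inf`, so thresholding classifies
#' every cell as negative.
#'
#' @param scores Numeric vector (at least 2 values).
#' @param n_bins Histogram bins, default 256.
#' @return Threshold on the original score scale; classify with
#'   `score > threshold`.
#' @export
otsu_threshold <- function(scores, n_bins = 256) {
  s <- scores[is.finite(scores)]
  if (length(s) < 2) return(Inf)
  lo <- min(s); hi <- max(s)
  if (hi - lo <= 0) return(Inf)
  x <- (s - lo) / (hi - lo)
  idx <- pmin(pmax(ceiling(x * n_bins), 1L), n_bins)
  p <- tabulate(idx, n_bins) / length(x)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1)
  denom <- w0[k] * (1 - w0[k])
  sigma_b <- ifelse(denom > 0, (mu_t * w0[k] - mu[k])^2 / denom, -Inf)
  lo + (which.max(sigma_b) / n_bins) * (hi - lo)
}

# Boolean classification by Otsu's threshold (degenerate -> all negative)
otsu_classify <- function(scores) {
  s <- sanitize_scores(scores)
  s > otsu_threshold(s)
}

#' Pairwise Pearson correlations of the four base scores
#'
#' Pools cells (time cells and other cells together) and correlates the
#' four analog score distributions. Non-finite scores are sanitized as in
#' Otsu classification; a zero-variance column yields NA entries.
#'
#' @param results Results table from [score_dataset()] / [run_suite()].
#' @return 4 x 4 correlation matrix named by [tc_scores()].
#' @export
score_correlations <- function(results) {
  cols <- paste0("score_", tc_scores())
  m <- vapply(cols, function(cn) sanitize_scores(results[[cn]]),
              numeric(nrow(results)))
  colnames(m) <- tc_scores()
  suppressWarnings(cor(m))
}

#' Pairwise Pearson correlations of the ten Boolean prediction lists
#'
#' @param results Results table from [score_dataset()] / [run_suite()].
#' @return 10 x 10 correlation matrix named by [tc_algorithms()];
#'   zero-variance columns yield NA entries.
#' @export
prediction_correlations <- function(results) {
  cols <- paste0("pred_", tc_algorithms())
  m <- vapply(cols, function(cn) as.numeric(results[[cn]]),
              numeric(nrow(results)))
  colnames(m) <- tc_algorithms()
  suppressWarnings(cor(m))
}

#' ROC curve, AUC and ideal threshold for an analog score
#'
#' Sweeps all distinct score values as thresholds (classification is
#' `score > threshold`), computes TPR and FPR at each, the trapezoid AUC,
#' fits a binomial GLM of the truth on the score, and reports the
#' Youden-optimal threshold (maximizing TPR - FPR).
#'
#' @param scores Numeric vector.
#' @param truth Logical ground-truth labels; both classes must be present.
#' @return List with `roc` (data.frame threshold/tpr/fpr), `auc`, `model`
#'   (the GLM fit) and `best_threshold`.
#' @export
roc_and_threshold <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  if (all(truth) || !any(truth))
    stop("both classes must be present in the truth labels")
  scores <- sanitize_scores(scores)
  ths <- c(-Inf, sort(unique(scores)))
  pos <- sum(truth); neg <- sum(!truth)
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores > ths[i]
    tpr[i] <- sum(pred & truth) / pos
    fpr[i] <- sum(pred & !truth) / neg
  }
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) *
             (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  fit <- suppressWarnings(glm(truth ~ scores, family = binomial()))
  list(roc = data.frame(threshold = ths, tpr = tpr, fpr = fpr),
       auc = auc, model = fit,
       best_threshold = ths[which.max(tpr - fpr)])
}

#' Consensus (concordance) classification
#'
#' A cell is called a time cell when at least `threshold` of the algorithms
#' predict it positive.
#'
#' @param pred Logical matrix or data.frame, cells x algorithms.
#' @param threshold Integer from 1 (union) to the number of algorithms
#'   (intersection).
#' @return Logical vector, one call per cell.
#' @export
concordance_classify <- function(pred, threshold) {
  pred <- as.matrix(pred)
  if (threshold < 1 || threshold > ncol(pred))
    stop("threshold must be in [1, n_algorithms]")
  rowSums(pred) >= threshold
}

#' Sweep concordance thresholds against ground truth
#'
#' @param pred Logical matrix/data.frame, cells x algorithms.
#' @param truth Logical labels.
#' @param thresholds Integer thresholds to evaluate, default all of them.
#' @return data.frame of threshold, confusion counts and metrics, with a
#'   `best_threshold` attribute (lowest threshold maximizing F1).
#' @export
concordance_sweep <- function(pred, truth, thresholds = NULL) {
  pred <- as.matrix(pred)
  thresholds <- thresholds %||% seq_len(ncol(pred))
  rows <- lapply(thresholds, function(th) {
    cc <- confusion(concordance_classify(pred, th), truth)
    m <- tc_metrics(cc)
    data.frame(threshold = th, tp = cc[["tp"]], fp = cc[["fp"]],
               tn = cc[["tn"]], fn = cc[["fn"]], recall = m$recall,
               precision = m$precision, f1 = m$f1, accuracy = m$accuracy)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_threshold") <- out$threshold[which.max(out$f1)]
  out
}

#' Parameter-sensitivity slopes of classification performance
#'
#' Ordinary least squares of a performance score (typically F1) on the
#' modulated parameter level, per algorithm, with a two-sided test of
#' slope = 0.
#'
#' @param data data.frame with one row per (algorithm, level, replicate).
#' @param value,level,algorithm Column names, defaults `"f1"`, `"level"`,
#'   `"algorithm"`.
#' @param sig_level Significance level for the slope test, default 0.01.
#' @return data.frame with per-algorithm `slope`, `p_value`, `rmse` and
#'   `significant`.
#' @export
parameter_sensitivity <- function(data, value = "f1", level = "level",
                                  algorithm = "algorithm",
                                  sig_level = 0.01) {
  if (!all(c(value, level, algorithm) %in% names(data)))
    stop("missing required columns")
  rows <- lapply(split(data, data[[algorithm]]), function(d) {
    x <- d[[level]]; y <- d[[value]]
    if (length(unique(x)) < 2)
      stop("degenerate design: need at least 2 parameter levels")
    if (min(table(x)) < 2)
      stop("degenerate design: need at least 2 replicates per level")
    fit <- lm(y ~ x)
    cf <- summary(fit)$coefficients
    slope <- cf["x", "Estimate"]
    p <- if (nrow(cf) > 1 && !is.nan(cf["x", "Pr(>|t|)"]))
      cf["x", "Pr(>|t|)"] else 1
    data.frame(algorithm = d[[algorithm]][1], slope = slope, p_value = p,
               rmse = sqrt(mean(fit$residuals^2)),
               significant = p < sig_level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-algorithm metrics over a pooled results table
#'
#' Pools all cells in `results`, computes confusion counts of each
#' algorithm's predictions against the truth column, and summarizes them.
#'
#' @param results Results table from [score_dataset()] / [run_suite()] with
#'   a non-NA `truth` column.
#' @param algorithms Algorithm subset, default all ten.
#' @return data.frame with one row per algorithm: counts, recall,
#'   precision, f1, accuracy.
#' @export
suite_metrics <- function(results, algorithms = tc_algorithms()) {
  rows <- lapply(algorithms, function(a) {
    cc <- confusion(results[[paste0("pred_", a)]], results$truth)
    m <- tc_metrics(cc)
    data.frame(algorithm = a, tp = cc[["tp"]], fp = cc[["fp"]],
               tn = cc[["tn"]], fn = cc[["fn"]], recall = m$recall,
               precision = m$precision, f1 = m$f1, accuracy = m$accuracy)
  })
  do.call(rbind, rows)
}
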