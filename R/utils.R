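`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a temporary RNG seed, restoring .Random.seed after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# trials x frames matrix for one cell of a cells x trials x frames array
cell_matrix <- function(dfbf, cell) {
  d <- dim(dfbf)
  matrix(dfbf[cell, , ], nrow = d[2], ncol = d[3])
}

check_dfbf <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3)
    stop("dF/F data must be a 3-D array (cells x trials x frames)")
  if (any(!is.finite(x)))
    stop("dF/F data must be finite")
  invisible(x)
}

# argmax with flat-top plateaus resolving to the plateau center (so boxcar
# events peak at their middle, matching the C++ cores)
peak_index <- function(x) {
  idx <- which(x == max(x))
  idx[ceiling(length(idx) / 2)]
}

# Replace non-finite analog scores so downstream thresholding stays defined:
# NaN (0/0 degenerate traces) -> 0, +Inf (zero-background sentinel) -> largest
# finite score (or 1 if none).
sanitize_scores <- function(s) {
  s[is.nan(s)] <- 0
  if (any(is.infinite(s))) {
    fin <- s[is.finite(s)]
    s[is.infinite(s)] <- if (length(fin)) max(fin) else 1
  }
  s
}
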