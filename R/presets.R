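# Versioned regime presets for the benchmark suite. The three regimes
# modulate one parameter per case:
#  - unphysiological: 99 cases, the non-modulated parameters held at
#    noninterference levels (noise 10%, event width 60th pct +/- 1 SD,
#    imprecision 0, hit trial ratio 100% fixed, no background), 3 shuffles;
#  - canonical: 12 cases (4 parameters x 3 levels) around the baseline
#    physiology preset without background, 10 shuffles;
#  - physiological: the same 12 plus 3 background-activity levels, with
#    background on everywhere, 10 shuffles.
# The published description gives parameter ranges, not full grids; the
# grids below are reconstructions within those ranges.

suite_grid_unphysiological <- function() {
  list(
    noise      = seq(10, 70, by = 5),    # 13
    event_width = seq(5, 95, by = 5),    # 19
    imprecision = seq(0, 50, by = 5),    # 11
    htr        = seq(10, 100, by = 5),   # 19
    background = seq(0.1, 2.0, by = 0.1),# 20
    time_cell_percent = seq(10, 90, by = 5)) # 17  -> total 99
}

suite_grid_canonical <- function() {
  list(noise = c(10, 40, 70),
       event_width = c(30, 60, 90),
       imprecision = c(0, 25, 50),
       htr = c(33, 66, 100))             # 12
}

suite_grid_physiological <- function() {
  c(suite_grid_canonical(), list(background = c(0.5, 1.0, 2.0)))  # 15
}

# apply one modulation to a baseline override list
apply_modulation <- function(ov, param, value) {
  switch(param,
    noise = { ov$noise_percent <- value; ov },
    event_width = { ov$event_width <- c(value, 1); ov },
    imprecision = {
      ov$imprecision_fwhm <- value
      ov$imprecision_type <- if (value > 0) "normal" else "none"
      ov
    },
    htr = { ov$max_hit_trial_percent <- value; ov },
    background = {
      ov$bg_mean <- value
      ov$bg_for_time_cells <- TRUE
      ov$bg_for_other_cells <- TRUE
      ov
    },
    time_cell_percent = { ov$time_cell_percent <- value; ov },
    stop("unknown modulation parameter: ", param))
}

suite_cases <- function() {
  base_unphys <- list(
    time_cell_percent = 50, cell_order = "basic",
    max_hit_trial_percent = 100, hit_trial_assignment = "fixed",
    trial_order = "random", event_width = c(60, 1), event_amp_factor = 1,
    event_timing = "sequential", imprecision_fwhm = 0,
    imprecision_type = "none", noise_type = "gaussian", noise_percent = 10,
    bg_for_time_cells = FALSE, bg_for_other_cells = FALSE, bg_mean = 0)
  # baseline physiology: noise 10%, widths 60th pct +/- 1 SD, imprecision 0,
  # HTR random in 33-66%, 50% time cells
  base_canon <- base_unphys
  base_canon$max_hit_trial_percent <- 66
  base_canon$hit_trial_assignment <- "random"
  base_physio <- base_canon
  base_physio$bg_for_time_cells <- TRUE
  base_physio$bg_for_other_cells <- TRUE
  base_physio$bg_mean <- 1.0

  cases <- list()
  add <- function(regime, base, grids) {
    for (param in names(grids)) {
      for (value in grids[[param]]) {
        ov <- apply_modulation(base, param, value)
        cases[[length(cases) + 1]] <<- list(
          regime = regime, param = param, value = value,
          name = sprintf("%s-%s", param, format(value, trim = TRUE)),
          overrides = ov)
      }
    }
  }
  add("unphysiological", base_unphys, suite_grid_unphysiological())
  add("canonical", base_canon, suite_grid_canonical())
  add("physiological", base_physio, suite_grid_physiological())
  cases
}

#' Enumerate the three-regime benchmark suite
#'
#' Builds the full list of dataset configurations for the benchmark:
#' 99 unphysiological cases x 3 shuffles, 12 canonical cases x 10 shuffles
#' and 15 physiological cases x 10 shuffles — 567 configurations of 135
#' cells, 60 trials and 246 frames at full scale. Every configuration
#' carries a distinct seed. All regimes use 50% time cells except the cases
#' that modulate the time-cell percentage itself.
#'
#' @param scale Fraction in (0, 1\]; values below 1 shrink the per-case
#'   shuffle counts proportionally (never below one shuffle) for desk-scale
#'   runs, and the result is flagged with a `scaled` attribute.
#' @param shuffles_per_case Optional integer overriding the shuffle count of
#'   every case (e.g. 1 for the reduced acceptance suite).
#' @param n_cells,n_trials Optional overrides of the dataset dimensions.
#' @param base_seed Integer; configuration `i` gets seed `base_seed + i`.
#' @return List of `tc_config` objects, each with `dataset_id`, `regime`,
#'   `modulated_param` and `modulated_value` attributes.
#' @export
build_benchmark_suite <- function(scale = 1, shuffles_per_case = NULL,
                                  n_cells = NULL, n_trials = NULL,
                                  base_seed = 20000) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  cases <- suite_cases()
  base_shuffles <- c(unphysiological = 3L, canonical = 10L,
                     physiological = 10L)
  n_shuf <- function(regime) {
    if (!is.null(shuffles_per_case)) return(as.integer(shuffles_per_case))
    max(1L, as.integer(round(scale * base_shuffles[[regime]])))
  }
  configs <- list()
  idx <- 0L
  for (case in cases) {
    for (s in seq_len(n_shuf(case$regime))) {
      idx <- idx + 1L
      ov <- case$overrides
      if (!is.null(n_cells)) ov$n_cells <- n_cells
      if (!is.null(n_trials)) ov$n_trials <- n_trials
      ov$seed <- base_seed + idx
      cfg <- do.call(dataset_config, ov)
      attr(cfg, "dataset_id") <-
        sprintf("%s_%s_shuf%02d", case$regime, case$name, s)
      attr(cfg, "regime") <- case$regime
      attr(cfg, "modulated_param") <- case$param
      attr(cfg, "modulated_value") <- case$value
      configs[[idx]] <- cfg
    }
  }
  scaled <- scale < 1 || !is.null(shuffles_per_case) ||
    !is.null(n_cells) || !is.null(n_trials)
  attr(configs, "scaled") <- scaled
  configs
}
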