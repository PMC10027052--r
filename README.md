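# timecellbench

Synthetic benchmarks and detection algorithms for hippocampal **time
cells** — neurons with reliable, temporally localized calcium activity at a
fixed delay within a trial, tiling the interval between temporally
separated stimuli.

Several published methods detect time cells in two-photon calcium imaging
data (temporal-information bootstraps, ridge-to-background ratios,
peak-significance tests, automatic thresholds), and they do not obviously
agree, nor degrade identically under noise, timing jitter, unreliable
responses or untuned background activity. `timecellbench` addresses this
for experimentalists and methods developers by:

* generating **ground-truth-labeled synthetic dF/F datasets**
  (`cells x trials x frames`) from a library of calcium transient
  templates, under 17 control parameters — time-cell fraction, hit-trial
  ratio, event width selection, trial-pair timing imprecision (FWHM),
  Gaussian noise scaled to peak signal, Poisson background events, and
  more — each dataset watermarked and carrying full per-cell truth;
* implementing **ten detection algorithms** in three families: temporal
  information (`tiMean`, `tiBoot`, `tiBoth`, `tiMean-O`, `tiBase-O`),
  ridge-to-background (`r2bMean`, `r2bBoot`, `r2bBase-O`) and parametric
  equations (`peqBase`, `peqBase-O`), with the bootstrap cores in C++;
* providing a **benchmarking layer**: confusion metrics, score and
  prediction correlation matrices, ROC/GLM threshold analysis,
  consensus ("concordance") classification, and parameter-sensitivity
  slopes.

The generator-side quality of a synthetic time cell is

    Q_ref = HTR * exp{ -( a*MNP/100*EAF + b*sd(EW)/mean(EW) + g*sd(Imp)/StimWin ) },
    a = 1, b = 1, g = 10

(hit-trial ratio, max noise percent, event amplification factor, event
widths, imprecision, stimulus window length); its data-side analog, the
`peq` score, uses the same form with `a = 10` over estimates read out of
the data. The temporal information statistic is the information-per-event
form `TI = sum_j p_j (lambda_j / lambda_bar) log2(lambda_j / lambda_bar)`
(bits) over 3-frame bins.

## Worked example

```r
library(timecellbench)

# 1. A transient template library (double-exponential, GCaMP6f-like)
lib <- generate_template_library(n_events = 100, seed = 7)
lib
#> Calcium event library: 100 events, width 21.6 +/- 5.7 frames (14.5 Hz)

# 2. A labeled synthetic dataset: 20 cells, 50% time cells, 10% noise
cfg <- dataset_config(n_cells = 20, n_trials = 20, noise_percent = 10,
                      max_hit_trial_percent = 100, seed = 3)
ds <- generate_dataset(cfg, lib)
ds
#> Synthetic time-cell dataset: 20 cells x 20 trials x 246 frames (10 time cells)

# 3. Score with all ten algorithms and compare to ground truth
res <- score_dataset(ds, n_boot = 250, seed = 11)
suite_metrics(res)[c(1:3, 7), c("algorithm", "recall", "precision", "f1")]
#>   algorithm recall precision f1
#> 1    tiMean      1         1  1
#> 2    tiBoot      1         1  1
#> 3    tiBoth      1         1  1
#> 7   r2bBoot      1         1  1
```

On this easy dataset (full hit-trial ratio, 10% noise) every bootstrap
algorithm recovers the 10 programmed time cells exactly. The interesting
behavior appears across the benchmark suite, where one parameter at a time
is pushed through unphysiological, canonical and physiological ranges: at
full scale `build_benchmark_suite(scale = 1)` enumerates the complete
567-dataset design (76,545 cells). A desk-scale replica
(one shuffle per case, 45 cells, 30 trials, 250 bootstrap iterations —
126 datasets, a few minutes on one core):

```r
lib <- generate_template_library(n_events = 500, seed = 1001)
configs <- build_benchmark_suite(shuffles_per_case = 1,
                                 n_cells = 45, n_trials = 30, base_seed = 1)
res <- run_suite(configs, lib, n_boot = 250)
suite_metrics(res, tc_bootstrap_algorithms())[, c("algorithm", "recall",
                                                  "precision", "f1",
                                                  "accuracy")]
#>   algorithm recall precision    f1 accuracy
#> 1    tiMean  0.820     0.997 0.900    0.911
#> 2    tiBoot  0.886     0.959 0.921    0.925
#> 3    tiBoth  0.816     0.999 0.898    0.909
#> 4   r2bMean  0.919     0.984 0.950    0.953
#> 5   r2bBoot  0.916     0.991 0.952    0.954
```

All five bootstrap-based algorithms classify with near-perfect precision
and accuracy above 90%; their Boolean prediction lists correlate pairwise
above 0.8 (`prediction_correlations(res)`), and
`concordance_sweep()` shows how consensus among the ten algorithms trades
recall against precision.

The methods vignette (`vignettes/time-cell-benchmarking.Rmd`) documents
the generator's model, every algorithm's decision rule, the regime grids,
numerical conventions, and what the synthetic benchmark does and does not
show about real data. A thin command-line pipeline over the same functions
lives in `inst/cli/tcbench.R` (subcommands `generate`, `suite`, `score`,
`bench`, `sensitivity`).

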