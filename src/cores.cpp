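// Hot loops shared by the detector families: calcium event detection by
// threshold runs, circular-shuffle surrogates for the temporal-information
// and trial-averaged-peak bootstraps, random-offset controls for the
// ridge-to-background ratio, and shuffled re-estimation for the parametric
// equation score. All randomness comes from R's RNG (unif_rand), so results
// are reproducible with set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Run {
  int start;  // 0-based
  int len;
};

double mean_of(const double* x, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  return s / n;
}

double sd_of(const double* x, int n) {
  if (n < 2) return 0.0;
  double m = mean_of(x, n), ss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = x[i] - m;
    ss += d * d;
  }
  return std::sqrt(ss / (n - 1));
}

// detection threshold: trace mean + k_sd * trace SD (circular-shift invariant)
double run_threshold(const double* x, int n, double k_sd) {
  return mean_of(x, n) + k_sd * sd_of(x, n);
}

// maximal runs of x > thr kept iff run length >= min_run
void supra_runs(const double* x, int n, double thr, int min_run,
                std::vector<Run>& out) {
  int i = 0;
  while (i < n) {
    if (x[i] > thr) {
      int j = i + 1;
      while (j < n && x[j] > thr) ++j;
      if (j - i >= min_run) out.push_back({i, j - i});
      i = j;
    } else {
      ++i;
    }
  }
}

int rand_offset(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// argmax over [lo, hi] (0-based inclusive); ties (flat-top plateaus)
// resolve to the center of the maximal plateau
int plateau_argmax(const double* x, int lo, int hi) {
  double best = x[lo];
  for (int f = lo; f <= hi; ++f)
    if (x[f] > best) best = x[f];
  int first = -1, last = -1;
  for (int f = lo; f <= hi; ++f)
    if (x[f] == best) {
      if (first < 0) first = f;
      last = f;
    }
  return first + (last - first) / 2;
}

void copy_trials(const NumericMatrix& cell,
                 std::vector<std::vector<double>>& tr) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  tr.assign(n_t, std::vector<double>(n_f));
  for (int t = 0; t < n_t; ++t)
    for (int f = 0; f < n_f; ++f) tr[t][f] = cell(t, f);
}

}  // namespace

// Event detection on a single dF/F trace. Returns a matrix with columns
// (start, width), start 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_detect_events(NumericVector trace, double k_sd, int min_run) {
  int n = trace.size();
  std::vector<Run> runs;
  double thr = run_threshold(REAL(trace), n, k_sd);
  supra_runs(REAL(trace), n, thr, min_run, runs);
  IntegerMatrix out((int)runs.size(), 2);
  for (size_t i = 0; i < runs.size(); ++i) {
    out((int)i, 0) = runs[i].start + 1;
    out((int)i, 1) = runs[i].len;
  }
  return out;
}

// Active-frame counts per time bin, summed over trials (trials x frames in).
// [[Rcpp::export]]
IntegerVector cpp_bin_counts(NumericMatrix cell, int bin_size, double k_sd,
                             int min_run) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  int n_bins = (n_f + bin_size - 1) / bin_size;
  IntegerVector counts(n_bins);
  std::vector<double> buf(n_f);
  std::vector<Run> runs;
  for (int t = 0; t < n_t; ++t) {
    for (int f = 0; f < n_f; ++f) buf[f] = cell(t, f);
    runs.clear();
    double thr = run_threshold(buf.data(), n_f, k_sd);
    supra_runs(buf.data(), n_f, thr, min_run, runs);
    for (const Run& r : runs)
      for (int f = r.start; f < r.start + r.len; ++f) counts[f / bin_size]++;
  }
  return counts;
}

// Temporal-information bootstrap: fraction of circular-shuffle surrogates in
// which the observed per-bin event rate exceeds the surrogate rate.
// [[Rcpp::export]]
NumericVector cpp_ti_boot(NumericMatrix cell, int bin_size, double k_sd,
                          int min_run, int n_iter) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  int n_bins = (n_f + bin_size - 1) / bin_size;
  std::vector<std::vector<double>> tr;
  copy_trials(cell, tr);
  std::vector<double> thr(n_t);
  for (int t = 0; t < n_t; ++t) thr[t] = run_threshold(tr[t].data(), n_f, k_sd);

  std::vector<int> obs(n_bins, 0), shuf(n_bins, 0), exceed(n_bins, 0);
  std::vector<Run> runs;
  for (int t = 0; t < n_t; ++t) {
    runs.clear();
    supra_runs(tr[t].data(), n_f, thr[t], min_run, runs);
    for (const Run& r : runs)
      for (int f = r.start; f < r.start + r.len; ++f) obs[f / bin_size]++;
  }

  std::vector<double> buf(n_f);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(shuf.begin(), shuf.end(), 0);
    for (int t = 0; t < n_t; ++t) {
      int o = rand_offset(n_f);
      for (int f = 0; f < n_f; ++f) buf[(f + o) % n_f] = tr[t][f];
      runs.clear();
      supra_runs(buf.data(), n_f, thr[t], min_run, runs);
      for (const Run& r : runs)
        for (int f = r.start; f < r.start + r.len; ++f) shuf[f / bin_size]++;
    }
    for (int j = 0; j < n_bins; ++j)
      if (obs[j] > shuf[j]) exceed[j]++;
  }
  NumericVector out(n_bins);
  for (int j = 0; j < n_bins; ++j) out[j] = (double)exceed[j] / n_iter;
  return out;
}

// Null distribution of the trial-averaged peak under per-trial circular
// shifts (used by the tiMean bootstrap).
// [[Rcpp::export]]
NumericVector cpp_peak_null(NumericMatrix cell, int n_iter) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  std::vector<std::vector<double>> tr;
  copy_trials(cell, tr);
  NumericVector out(n_iter);
  std::vector<double> avg(n_f);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(avg.begin(), avg.end(), 0.0);
    for (int t = 0; t < n_t; ++t) {
      int o = rand_offset(n_f);
      for (int f = 0; f < n_f; ++f) avg[(f + o) % n_f] += tr[t][f];
    }
    double mx = avg[0];
    for (int f = 1; f < n_f; ++f) mx = std::max(mx, avg[f]);
    out[it] = mx / n_t;
  }
  return out;
}

namespace {

// ridge/background area ratio of a (clipped, averaged) trace at peak p
double r2b_of_avg(const std::vector<double>& avg, int n_f, int p, int hw) {
  int lo = std::max(0, p - hw), hi = std::min(n_f - 1, p + hw);
  double ridge = 0.0, total = 0.0;
  for (int f = 0; f < n_f; ++f) total += avg[f];
  for (int f = lo; f <= hi; ++f) ridge += avg[f];
  double bg = total - ridge;
  if (bg > 0) return ridge / bg;
  return (ridge > 0) ? R_PosInf : R_NaN;
}

}  // namespace

// Random-offset control ratios for the ridge-to-background score. Each
// iteration circularly shifts every trial, then mirrors the observed
// statistic exactly: the peak is found on the shifted odd-half average
// (within the 1-based inclusive stimulus window) and the ratio computed on
// the shifted even-half average, both clipped at 0. Matching the split-half
// procedure keeps the null centered so label-shuffled cells score near 1.
// [[Rcpp::export]]
NumericVector cpp_r2b_controls(NumericMatrix cell, int stim_lo, int stim_hi,
                               int halfwidth, int n_iter) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  std::vector<std::vector<double>> tr;
  copy_trials(cell, tr);
  int n_a = (n_t + 1) / 2, n_b = n_t / 2;
  NumericVector out(n_iter);
  std::vector<double> avg_a(n_f), avg_b(n_f);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(avg_a.begin(), avg_a.end(), 0.0);
    std::fill(avg_b.begin(), avg_b.end(), 0.0);
    for (int t = 0; t < n_t; ++t) {
      int o = rand_offset(n_f);
      std::vector<double>& dst = (t % 2 == 0) ? avg_a : avg_b;
      for (int f = 0; f < n_f; ++f) dst[(f + o) % n_f] += tr[t][f];
    }
    for (int f = 0; f < n_f; ++f) {
      avg_a[f] = std::max(avg_a[f] / n_a, 0.0);
      avg_b[f] = std::max(avg_b[f] / n_b, 0.0);
    }
    int p = plateau_argmax(avg_a.data(), stim_lo - 1, stim_hi - 1);
    out[it] = r2b_of_avg(avg_b, n_f, p, halfwidth);
  }
  return out;
}

namespace {

// Data-side parameter estimates for the parametric-equation score:
// out5 = (htr, ew_mean, ew_sd, imp_sd, noise_over_signal)
void peq_core(const std::vector<std::vector<double>>& tr, int n_t, int n_f,
              const std::vector<double>& thr, int stim_lo, int stim_hi,
              int min_run, double* out5) {
  std::vector<Run> runs;
  std::vector<double> widths, hit_peaks;
  std::vector<char> inev(n_f);
  std::vector<double> avg(n_f, 0.0);
  double ne_sum = 0.0, ne_ss = 0.0;
  long ne_n = 0;
  int hits = 0;
  for (int t = 0; t < n_t; ++t) {
    const double* x = tr[t].data();
    for (int f = 0; f < n_f; ++f) avg[f] += x[f];
    runs.clear();
    supra_runs(x, n_f, thr[t], min_run, runs);
    std::fill(inev.begin(), inev.end(), 0);
    double best_val = 0.0;
    int best_frame = -1;
    for (const Run& r : runs) {
      widths.push_back((double)r.len);
      for (int f = r.start; f < r.start + r.len; ++f) inev[f] = 1;
      int pk = plateau_argmax(x, r.start, r.start + r.len - 1);
      double pv = x[pk];
      if (pk >= stim_lo - 1 && pk <= stim_hi - 1) {
        if (best_frame < 0 || pv > best_val) {
          best_val = pv;
          best_frame = pk;
        }
      }
    }
    if (best_frame >= 0) {
      hits++;
      hit_peaks.push_back((double)(best_frame + 1));
    }
    for (int f = 0; f < n_f; ++f)
      if (!inev[f]) {
        ne_sum += x[f];
        ne_ss += x[f] * x[f];
        ne_n++;
      }
  }
  double htr = (double)hits / n_t;
  double ew_mean = widths.empty() ? 0.0
                                  : mean_of(widths.data(), (int)widths.size());
  double ew_sd =
      (widths.size() >= 2) ? sd_of(widths.data(), (int)widths.size()) : 0.0;
  double imp_sd = (hit_peaks.size() >= 2)
                      ? sd_of(hit_peaks.data(), (int)hit_peaks.size())
                      : 0.0;
  double sigmax = avg[0];
  for (int f = 1; f < n_f; ++f) sigmax = std::max(sigmax, avg[f]);
  sigmax /= n_t;
  double ns = 0.0;
  if (ne_n >= 2 && sigmax > 0) {
    double m = ne_sum / ne_n;
    double var = (ne_ss - ne_n * m * m) / (ne_n - 1);
    ns = std::sqrt(std::max(var, 0.0)) / sigmax;
  }
  out5[0] = htr;
  out5[1] = ew_mean;
  out5[2] = ew_sd;
  out5[3] = imp_sd;
  out5[4] = ns;
}

double peq_q(const double* e, double stim_win_len, double alpha, double beta,
             double gamma) {
  double term = alpha * e[4] + gamma * e[3] / stim_win_len;
  if (e[1] > 0) term += beta * e[2] / e[1];
  return e[0] * std::exp(-term);
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_peq_estimate(NumericMatrix cell, int stim_lo, int stim_hi,
                               double k_sd, int min_run) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  std::vector<std::vector<double>> tr;
  copy_trials(cell, tr);
  std::vector<double> thr(n_t);
  for (int t = 0; t < n_t; ++t) thr[t] = run_threshold(tr[t].data(), n_f, k_sd);
  NumericVector out(5);
  peq_core(tr, n_t, n_f, thr, stim_lo, stim_hi, min_run, REAL(out));
  out.names() = CharacterVector::create("htr_est", "ew_mean", "ew_sd",
                                        "imp_sd", "noise_over_signal");
  return out;
}

// Null distribution of the parametric-equation Q under per-trial circular
// shifts; the detection threshold is shift-invariant and reused.
// [[Rcpp::export]]
NumericVector cpp_peq_null(NumericMatrix cell, int stim_lo, int stim_hi,
                           double k_sd, int min_run, double stim_win_len,
                           double alpha, double beta, double gamma,
                           int n_iter) {
  int n_t = cell.nrow(), n_f = cell.ncol();
  std::vector<std::vector<double>> tr;
  copy_trials(cell, tr);
  std::vector<double> thr(n_t);
  for (int t = 0; t < n_t; ++t) thr[t] = run_threshold(tr[t].data(), n_f, k_sd);
  std::vector<std::vector<double>> sh(n_t, std::vector<double>(n_f));
  NumericVector out(n_iter);
  double e[5];
  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < n_t; ++t) {
      int o = rand_offset(n_f);
      for (int f = 0; f < n_f; ++f) sh[t][(f + o) % n_f] = tr[t][f];
    }
    peq_core(sh, n_t, n_f, thr, stim_lo, stim_hi, min_run, e);
    out[it] = peq_q(e, stim_win_len, alpha, beta, gamma);
  }
  return out;
}
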