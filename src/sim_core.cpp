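#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Weighted draw over clones by linear scan of cumulative weights.
// `total` is the (maintained) sum of weights; u is clamped to the last
// positive-weight clone so that small drift in the running total is harmless.
static int sample_weighted(const std::vector<double> &w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int last_pos = -1;
  const int m = (int) w.size();
  for (int i = 0; i < m; ++i) {
    if (w[i] > 0.0) {
      acc += w[i];
      last_pos = i;
      if (u < acc) return i;
    }
  }
  return last_pos;
}

// Event-driven core for the tug-of-war Moran models.
//
// model: 0 = A (dying cell fitness-biased), 1 = B (dying cell uniform).
// The replacing cell is fitness-biased in both models; self-replacement is a
// legal no-op event that still advances time. One clone is created per
// mutation event (infinite allele / infinite sites bookkeeping).
//
// Uses R's RNG: results are reproducible under set.seed() at the R level.
// [[Rcpp::export]]
List sim_core(int N, double mu, double p, double s, double d,
              int model, double t_max, double max_events,
              IntegerVector init_alpha, IntegerVector init_beta,
              IntegerVector init_live,
              NumericVector record_grid, NumericVector snapshot_times) {
  const int n0 = init_alpha.size();
  std::vector<int> alpha(init_alpha.begin(), init_alpha.end());
  std::vector<int> beta(init_beta.begin(), init_beta.end());
  std::vector<int> live(init_live.begin(), init_live.end());
  std::vector<int> parent(n0, NA_INTEGER);
  std::vector<int> origin(n0, 0);          // 0 root, 1 driver, 2 passenger
  std::vector<double> birth(n0, 0.0);
  std::vector<double> fit(n0);
  for (int i = 0; i < n0; ++i)
    fit[i] = std::pow(1.0 + s, alpha[i]) * std::pow(1.0 - d, beta[i]);

  double sigma = 0.0;  // total fitness of the N live cells
  for (int i = 0; i < n0; ++i) sigma += live[i] * fit[i];

  double t = 0.0;
  double n_events = 0.0, n_dr = 0.0, n_mut_d = 0.0, n_mut_p = 0.0;
  int since_recompute = 0;
  bool capped = false;

  const int n_grid = record_grid.size();
  NumericVector traj(n_grid);
  int gi = 0;
  const int n_snap = snapshot_times.size();
  std::vector< std::vector<int> > snaps;
  int si = 0;

  std::vector<double> w;  // scratch weight vector for fitness-biased draws

  RNGScope scope;
  while (true) {
    double total = sigma + (double) N * mu;
    double dt = exp_rand() / total;
    double t_new = t + dt;
    if (t_new >= t_max) { t = t_max; break; }
    if (n_events >= max_events) { capped = true; break; }
    // record grid/snapshot points crossed by this waiting time with the
    // current (pre-event) state
    while (gi < n_grid && record_grid[gi] <= t_new) traj[gi++] = sigma / N;
    while (si < n_snap && snapshot_times[si] <= t_new) {
      snaps.push_back(live);
      ++si;
    }
    t = t_new;
    n_events += 1.0;

    if (unif_rand() * total < sigma) {
      // death - replacement
      const int m = (int) live.size();
      w.resize(m);
      for (int i = 0; i < m; ++i) w[i] = live[i] * fit[i];
      int di, rj;
      if (model == 0) {
        di = sample_weighted(w, sigma);
      } else {
        std::vector<double> wu(m);
        for (int i = 0; i < m; ++i) wu[i] = live[i];
        di = sample_weighted(wu, (double) N);
      }
      rj = sample_weighted(w, sigma);
      if (di != rj) {
        --live[di];
        ++live[rj];
        sigma += fit[rj] - fit[di];
      }
      n_dr += 1.0;
    } else {
      // mutation: a uniformly chosen cell founds a new clone
      const int m = (int) live.size();
      std::vector<double> wu(m);
      for (int i = 0; i < m; ++i) wu[i] = live[i];
      int ci = sample_weighted(wu, (double) N);
      bool driver = unif_rand() < p;
      int a = alpha[ci] + (driver ? 1 : 0);
      int b = beta[ci] + (driver ? 0 : 1);
      double f = std::pow(1.0 + s, a) * std::pow(1.0 - d, b);
      alpha.push_back(a);
      beta.push_back(b);
      parent.push_back(ci + 1);  // 1-based ids on the R side
      origin.push_back(driver ? 1 : 2);
      birth.push_back(t);
      fit.push_back(f);
      live.push_back(1);
      --live[ci];
      sigma += f - fit[ci];
      if (driver) n_mut_d += 1.0; else n_mut_p += 1.0;
    }

    // bound floating-point drift of the running total fitness
    if (++since_recompute >= 10000) {
      since_recompute = 0;
      sigma = 0.0;
      for (size_t i = 0; i < live.size(); ++i) sigma += live[i] * fit[i];
    }
  }

  while (gi < n_grid && record_grid[gi] <= t_max) traj[gi++] = sigma / N;
  while (si < n_snap && snapshot_times[si] <= t_max) {
    snaps.push_back(live);
    ++si;
  }

  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i)
    snap_list[i] = IntegerVector(snaps[i].begin(), snaps[i].end());

  return List::create(
    _["time"] = t,
    _["alpha"] = IntegerVector(alpha.begin(), alpha.end()),
    _["beta"] = IntegerVector(beta.begin(), beta.end()),
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["origin"] = IntegerVector(origin.begin(), origin.end()),
    _["birth"] = NumericVector(birth.begin(), birth.end()),
    _["fitness"] = NumericVector(fit.begin(), fit.end()),
    _["live"] = IntegerVector(live.begin(), live.end()),
    _["trajectory"] = traj,
    _["snapshots"] = snap_list,
    _["n_events"] = n_events,
    _["n_death_replacement"] = n_dr,
    _["n_mut_driver"] = n_mut_d,
    _["n_mut_passenger"] = n_mut_p,
    _["capped"] = capped);
}
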