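// Inner simulation loop for the binary E/I network with covariance plasticity
// and two-step synaptic normalisation. Uses R's RNG so that runs are
// reproducible from set.seed() and bit-comparable with the pure-R engine's
// draw order (per step: N_e uniforms for excitatory noise, then N_i for
// inhibitory).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Two-step normalisation: columns to unit sum, then rows to unit sum.
// Zero columns / rows are left untouched (dead synapses stay dead).
static void normalize_block_inplace(arma::mat &w) {
  arma::rowvec cs = arma::sum(w, 0);
  for (arma::uword j = 0; j < w.n_cols; ++j)
    if (cs(j) > 0.0) w.col(j) /= cs(j);
  arma::vec rs = arma::sum(w, 1);
  for (arma::uword i = 0; i < w.n_rows; ++i)
    if (rs(i) > 0.0) w.row(i) /= rs(i);
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(arma::mat ee, const arma::mat &ei, const arma::mat &ie,
                   const arma::mat &ii, const arma::vec &p_e,
                   const arma::vec &p_i, double theta, double eta, int t_steps,
                   bool plasticity, bool spatial, const arma::mat &wmax,
                   int snapshot_every, bool record_raster,
                   const arma::vec &x_e0, const arma::vec &x_i0) {
  const arma::uword ne = ee.n_rows, ni = ii.n_rows;
  arma::vec x_e = x_e0, x_i = x_i0;
  arma::vec mean_e(ne, arma::fill::zeros), mean_i(ni, arma::fill::zeros);
  const double bval = 1.0 + theta;

  IntegerMatrix raster_e(record_raster ? ne : 0, record_raster ? t_steps : 0);
  IntegerMatrix raster_i(record_raster ? ni : 0, record_raster ? t_steps : 0);
  List snapshots;
  std::vector<int> snap_times;

  for (int t = 1; t <= t_steps; ++t) {
    // synchronous threshold update from the previous state
    arma::vec in_e = ee * x_e - ei * x_i;
    arma::vec in_i = ie * x_e - ii * x_i;
    arma::vec nx_e(ne), nx_i(ni);
    for (arma::uword k = 0; k < ne; ++k) {
      double beta = (unif_rand() < p_e(k)) ? bval : 0.0;
      nx_e(k) = (in_e(k) + beta - theta > 0.0) ? 1.0 : 0.0;
    }
    for (arma::uword k = 0; k < ni; ++k) {
      double beta = (unif_rand() < p_i(k)) ? bval : 0.0;
      nx_i(k) = (in_i(k) + beta - theta > 0.0) ? 1.0 : 0.0;
    }
    x_e = nx_e;
    x_i = nx_i;

    // online running means over steps 1..t (inclusive of the current state)
    mean_e = ((t - 1) * mean_e + x_e) / t;
    mean_i = ((t - 1) * mean_i + x_i) / t;

    if (plasticity) {
      arma::vec d = x_e - mean_e;
      ee += eta * (d * d.t());
      ee.diag().zeros();
      ee.transform([](double v) { return v < 0.0 ? 0.0 : v; });
      normalize_block_inplace(ee);
      if (spatial) ee = arma::min(ee, wmax);
    }

    if (record_raster) {
      for (arma::uword k = 0; k < ne; ++k) raster_e(k, t - 1) = (int)x_e(k);
      for (arma::uword k = 0; k < ni; ++k) raster_i(k, t - 1) = (int)x_i(k);
    }
    if (snapshot_every > 0 && t % snapshot_every == 0) {
      snapshots.push_back(wrap(ee));
      snap_times.push_back(t);
    }
    if (t % 20000 == 0) checkUserInterrupt();
  }

  return List::create(
      _["raster_e"] = raster_e, _["raster_i"] = raster_i, _["ee"] = ee,
      _["mean_e"] = mean_e, _["mean_i"] = mean_i, _["x_e"] = x_e,
      _["x_i"] = x_i, _["snapshots"] = snapshots,
      _["snapshot_times"] = wrap(snap_times));
}
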