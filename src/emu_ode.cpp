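#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the EMU labeling ODE
//   d(pool_i * X_i)/dt = (1-dil) * sum_in v * conv(inputs) + dil * vin * e0
//                        - (sum_out v) * X_i
// with the state laid out as concatenated node MIDs. All flux-dependent
// coefficients are prefolded on the R side; this routine only evaluates.
struct EmuModel {
  int n_state;
  std::vector<int> node_start, node_len;
  std::vector<double> node_efflux, node_dil_influx, node_inv_pool;
  std::vector<int> edge_target;
  std::vector<double> edge_val;
  std::vector<int> ops_ptr;             // length nedges+1
  std::vector<int> op_is_state, op_start, op_len;
  std::vector<double> const_data;

  void deriv(const double* y, double* ydot) const {
    std::fill(ydot, ydot + n_state, 0.0);
    double buf[16], tmp[16];
    const size_t ne = edge_target.size();
    for (size_t e = 0; e < ne; ++e) {
      int len = 1;
      buf[0] = edge_val[e];
      for (int k = ops_ptr[e]; k < ops_ptr[e + 1]; ++k) {
        const double* src =
            op_is_state[k] ? y + op_start[k] : const_data.data() + op_start[k];
        int slen = op_len[k];
        int nlen = len + slen - 1;
        for (int i = 0; i < nlen; ++i) tmp[i] = 0.0;
        for (int i = 0; i < len; ++i) {
          const double bi = buf[i];
          if (bi == 0.0) continue;
          for (int j = 0; j < slen; ++j) tmp[i + j] += bi * src[j];
        }
        for (int i = 0; i < nlen; ++i) buf[i] = tmp[i];
        len = nlen;
      }
      double* out = ydot + node_start[edge_target[e]];
      for (int i = 0; i < len; ++i) out[i] += buf[i];
    }
    const size_t nn = node_start.size();
    for (size_t i = 0; i < nn; ++i) {
      double* out = ydot + node_start[i];
      const double* yy = y + node_start[i];
      out[0] += node_dil_influx[i];
      const double eff = node_efflux[i], ip = node_inv_pool[i];
      for (int j = 0; j < node_len[i]; ++j)
        out[j] = (out[j] - eff * yy[j]) * ip;
    }
  }
};

static std::vector<int> as_ivec(IntegerVector v) {
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> as_dvec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}

// Dormand-Prince 5(4) with PI step-size control.
// [[Rcpp::export]]
NumericMatrix emu_integrate_cpp(int n_state, NumericVector y0,
                                NumericVector times,
                                IntegerVector node_start, IntegerVector node_len,
                                NumericVector node_efflux,
                                NumericVector node_dil_influx,
                                NumericVector node_inv_pool,
                                IntegerVector edge_target, NumericVector edge_val,
                                IntegerVector ops_ptr, IntegerVector op_is_state,
                                IntegerVector op_start, IntegerVector op_len,
                                NumericVector const_data,
                                double rtol, double atol) {
  EmuModel m;
  m.n_state = n_state;
  m.node_start = as_ivec(node_start);
  m.node_len = as_ivec(node_len);
  m.node_efflux = as_dvec(node_efflux);
  m.node_dil_influx = as_dvec(node_dil_influx);
  m.node_inv_pool = as_dvec(node_inv_pool);
  m.edge_target = as_ivec(edge_target);
  m.edge_val = as_dvec(edge_val);
  m.ops_ptr = as_ivec(ops_ptr);
  m.op_is_state = as_ivec(op_is_state);
  m.op_start = as_ivec(op_start);
  m.op_len = as_ivec(op_len);
  m.const_data = as_dvec(const_data);

  const int nt = times.size();
  NumericMatrix out(nt, n_state);
  std::vector<double> y(y0.begin(), y0.end());

  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  std::vector<double> k1(n_state), k2(n_state), k3(n_state), k4(n_state),
      k5(n_state), k6(n_state), k7(n_state), yt(n_state), ynew(n_state);

  double t = times[0];
  int it = 0;
  // emit initial point(s) equal to t0
  while (it < nt && times[it] <= t + 1e-14 * std::max(1.0, std::fabs(t))) {
    for (int j = 0; j < n_state; ++j) out(it, j) = y[j];
    ++it;
  }
  if (it >= nt) return out;

  double tend = times[nt - 1];
  double h = (tend - t) * 1e-3;
  if (h <= 0) stop("times must be ascending");
  double errold = 1.0;
  long nstep = 0, maxstep = 2000000;
  m.deriv(y.data(), k1.data());

  while (t < tend) {
    if (++nstep > maxstep)
      stop("labeling ODE integration failed: step limit reached at t=%g", t);
    double tnext = times[it];
    bool hit = false;
    if (t + h >= tnext - 1e-12 * std::max(1.0, std::fabs(tnext))) {
      h = tnext - t;
      hit = true;
    }
    for (int j = 0; j < n_state; ++j) yt[j] = y[j] + h * a21 * k1[j];
    m.deriv(yt.data(), k2.data());
    for (int j = 0; j < n_state; ++j)
      yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    m.deriv(yt.data(), k3.data());
    for (int j = 0; j < n_state; ++j)
      yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    m.deriv(yt.data(), k4.data());
    for (int j = 0; j < n_state; ++j)
      yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    m.deriv(yt.data(), k5.data());
    for (int j = 0; j < n_state; ++j)
      yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                          a64 * k4[j] + a65 * k5[j]);
    m.deriv(yt.data(), k6.data());
    for (int j = 0; j < n_state; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    m.deriv(ynew.data(), k7.data());

    double err = 0.0;
    for (int j = 0; j < n_state; ++j) {
      double ee = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                       e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = ee / sc;
      err += r * r;
    }
    err = std::sqrt(err / n_state);

    if (err <= 1.0) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      if (hit) {
        double teps = 1e-12 * std::max(1.0, std::fabs(t));
        while (it < nt && times[it] <= t + teps) {
          for (int j = 0; j < n_state; ++j) out(it, j) = y[j];
          ++it;
        }
        if (it >= nt) break;
      }
      double fac = 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.7 / 5.0) *
                   std::pow(errold, 0.4 / 5.0);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      errold = err > 1e-4 ? err : 1e-4;
    } else {
      double fac = 0.9 * std::pow(err, -1.0 / 5.0);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14 * std::max(1.0, std::fabs(t)))
        stop("labeling ODE integration failed: step size underflow at t=%g", t);
    }
  }
  return out;
}
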