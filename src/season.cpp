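#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Within-season integrator for the seasonal host-parasite delay system.
//
// State layout (always the resident+mutant system; the resident-only model is
// the special case s_hat_m = 0, which leaves the mutant components identically
// zero without perturbing the resident error control):
//   y[0] = s    susceptible resident juveniles
//   y[1] = a    resident adults
//   y[2] = sm   susceptible mutant juveniles
//   y[3] = am   mutant adults
//   y[4] = v    free-living parasites
//   y[5] = C    cumulative resident infections  int_0^t alpha*s*v du
//   y[6] = Cm   cumulative mutant infections
//
// Method of steps: the mesh contains every non-smooth point (emergence-window
// edges of both types, tau, and all their forward shifts by tau) so no
// Dormand-Prince step straddles a kink, and because consecutive mesh points
// are never more than tau apart every delayed lookup t - tau falls in already
// completed, stored history.  Delayed values come from cubic Hermite
// interpolation of the accepted steps (locally O(h^4), matching the order-5
// integrator at the tolerances used).

namespace {

struct Params {
  double alpha, beta, delta, mus, mua, l, tau, T;
};

struct HistNode {
  double t;
  double y[7];
  double f[7];
};

class SeasonProblem {
public:
  Params p;
  double s_hat, v_hat, s_hat_m;
  double t0, tl, t0m, tlm;
  double burst;  // alpha*beta*exp(-mus*tau)
  std::vector<HistNode> hist;

  // constant per segment (segments never straddle an emergence edge)
  double g_res, g_mut;

  void set_segment_rates(double a, double b) {
    double tm = 0.5 * (a + b);
    g_res = (tm > t0 && tm < t0 + tl) ? 1.0 / tl : 0.0;
    g_mut = (tm > t0m && tm < t0m + tlm) ? 1.0 / tlm : 0.0;
  }

  // Hermite interpolation of component k at time tq (tq within stored history)
  double interp(double tq, int k) const {
    if (tq <= 0.0) return (k == 4) ? v_hat : 0.0;
    size_t n = hist.size();
    // binary search for the step containing tq
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (hist[mid].t <= tq) lo = mid; else hi = mid;
    }
    const HistNode &A = hist[lo], &B = hist[hi];
    double h = B.t - A.t;
    if (h <= 0.0) return A.y[k];
    double th = (tq - A.t) / h;
    double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
    double h10 = th * (1 - th) * (1 - th);
    double h01 = th * th * (3 - 2 * th);
    double h11 = th * th * (th - 1);
    return h00 * A.y[k] + h * h10 * A.f[k] + h01 * B.y[k] + h * h11 * B.f[k];
  }

  void rhs(double t, const double *y, double *f) const {
    double s = y[0], a = y[1], sm = y[2], am = y[3], v = y[4];
    double inf_r = p.alpha * s * v;
    double inf_m = p.alpha * sm * v;
    double delayed = 0.0;
    if (t >= p.tau) {
      double td = t - p.tau;
      double sd = interp(td, 0);
      double smd = interp(td, 2);
      double vd = interp(td, 4);
      if (sd < 0) sd = 0;
      if (smd < 0) smd = 0;
      if (vd < 0) vd = 0;
      delayed = burst * vd * (sd + smd);
    }
    f[0] = s_hat * g_res - p.mus * s - inf_r - p.l * s;
    f[1] = p.l * s - p.mua * a;
    f[2] = s_hat_m * g_mut - p.mus * sm - inf_m - p.l * sm;
    f[3] = p.l * sm - p.mua * am;
    f[4] = delayed - p.delta * v;  // parasite loss to transmission neglected
    f[5] = inf_r;
    f[6] = inf_m;
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th order
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

const int NS = 7;

}  // namespace

// [[Rcpp::export(name = ".season_integrate_cpp")]]
List season_integrate_cpp(double s_hat, double v_hat, double s_hat_m,
                          double t0, double tl, double t0m, double tlm,
                          List params, double rtol, double atol,
                          NumericVector out_times) {
  SeasonProblem pr;
  pr.p.alpha = as<double>(params["alpha"]);
  pr.p.beta = as<double>(params["beta"]);
  pr.p.delta = as<double>(params["delta"]);
  pr.p.mus = as<double>(params["mu_s"]);
  pr.p.mua = as<double>(params["mu_a"]);
  pr.p.l = as<double>(params["l"]);
  pr.p.tau = as<double>(params["tau"]);
  pr.p.T = as<double>(params["T"]);
  pr.s_hat = s_hat;
  pr.v_hat = v_hat;
  pr.s_hat_m = s_hat_m;
  pr.t0 = t0;
  pr.tl = tl;
  pr.t0m = t0m;
  pr.tlm = tlm;
  pr.burst = pr.p.alpha * pr.p.beta * std::exp(-pr.p.mus * pr.p.tau);

  const double T = pr.p.T, tau = pr.p.tau;

  // breakpoint mesh: emergence edges (both types) and all tau-shifts
  std::vector<double> brk;
  {
    std::vector<double> base = {0.0, t0, t0 + tl, t0m, t0m + tlm, T};
    if (tau <= T) base.push_back(tau);
    std::vector<double> q = base;
    while (!q.empty()) {
      double b = q.back();
      q.pop_back();
      if (b >= 0.0 && b <= T) brk.push_back(b);
      if (tau > 0 && b + tau <= T) q.push_back(b + tau);
    }
    std::sort(brk.begin(), brk.end());
    std::vector<double> u;
    for (double b : brk)
      if (u.empty() || b - u.back() > 1e-12) u.push_back(b);
    if (u.back() < T - 1e-12) u.push_back(T);
    brk = u;
  }

  double y[NS] = {0.0, 0.0, 0.0, 0.0, v_hat, 0.0, 0.0};
  double f[NS];
  double ymax[NS];
  for (int i = 0; i < NS; ++i) ymax[i] = std::fabs(y[i]);

  pr.hist.clear();
  pr.hist.reserve(1024);

  double k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS], yt[NS], ynew[NS];
  bool ok = true;
  std::string errmsg;
  long n_steps = 0, n_rej = 0;

  for (size_t seg = 0; ok && seg + 1 < brk.size(); ++seg) {
    double ta = brk[seg], tb = brk[seg + 1];
    pr.set_segment_rates(ta, tb);
    double t = ta;
    pr.rhs(t, y, f);  // segment restart: re-evaluate (g may have jumped)
    {
      HistNode nd;
      nd.t = t;
      for (int i = 0; i < NS; ++i) { nd.y[i] = y[i]; nd.f[i] = f[i]; }
      pr.hist.push_back(nd);
    }
    double h = std::min(tb - ta, 1e-2);
    int guard = 0;
    while (t < tb - 1e-13) {
      if (++guard > 1000000) {
        ok = false;
        errmsg = "step limit exceeded in segment starting at t=" +
                 std::to_string(ta);
        break;
      }
      if (t + h > tb) h = tb - t;
      // DP5 stages (k1 = f, FSAL)
      for (int i = 0; i < NS; ++i) yt[i] = y[i] + h * a21 * f[i];
      pr.rhs(t + c2 * h, yt, k2);
      for (int i = 0; i < NS; ++i)
        yt[i] = y[i] + h * (a31 * f[i] + a32 * k2[i]);
      pr.rhs(t + c3 * h, yt, k3);
      for (int i = 0; i < NS; ++i)
        yt[i] = y[i] + h * (a41 * f[i] + a42 * k2[i] + a43 * k3[i]);
      pr.rhs(t + c4 * h, yt, k4);
      for (int i = 0; i < NS; ++i)
        yt[i] = y[i] +
                h * (a51 * f[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      pr.rhs(t + c5 * h, yt, k5);
      for (int i = 0; i < NS; ++i)
        yt[i] = y[i] + h * (a61 * f[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
      pr.rhs(t + h, yt, k6);
      for (int i = 0; i < NS; ++i)
        ynew[i] = y[i] + h * (b1 * f[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      pr.rhs(t + h, ynew, k7);
      double err = 0.0;
      for (int i = 0; i < NS; ++i) {
        double y4 = y[i] + h * (e1 * f[i] + e3 * k3[i] + e4 * k4[i] +
                                e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        double sc =
            atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double d = (ynew[i] - y4) / sc;
        err += d * d;
      }
      err = std::sqrt(err / NS);
      if (err <= 1.0) {
        t += h;
        for (int i = 0; i < NS; ++i) {
          y[i] = ynew[i];
          // clamp sub-tolerance negative dips (states are nonnegative)
          if (y[i] < 0.0) {
            double tol_i = atol + rtol * ymax[i];
            if (y[i] > -std::sqrt(tol_i) - 1e-8) y[i] = 0.0;
            else {
              ok = false;
              errmsg = "state " + std::to_string(i) +
                       " went negative beyond tolerance at t=" +
                       std::to_string(t);
            }
          }
          if (std::fabs(y[i]) > ymax[i]) ymax[i] = std::fabs(y[i]);
          f[i] = k7[i];
        }
        if (!ok) break;
        HistNode nd;
        nd.t = t;
        for (int i = 0; i < NS; ++i) { nd.y[i] = y[i]; nd.f[i] = f[i]; }
        pr.hist.push_back(nd);
        ++n_steps;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        ++n_rej;
        h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
        if (h < 1e-14) {
          ok = false;
          errmsg = "step size underflow at t=" + std::to_string(t);
          break;
        }
      }
      h = std::min(h, tb - ta);
    }
  }

  NumericVector yT(NS);
  for (int i = 0; i < NS; ++i) yT[i] = y[i];
  yT.names() = CharacterVector::create("s", "a", "s_m", "a_m", "v", "cum_inf",
                                       "cum_inf_m");

  List out = List::create(
      Named("ok") = ok, Named("message") = errmsg, Named("state_T") = yT,
      Named("n_steps") = n_steps, Named("n_rejected") = n_rej,
      Named("breakpoints") = NumericVector(brk.begin(), brk.end()));

  if (out_times.size() > 0 && ok) {
    int m = out_times.size();
    NumericMatrix traj(m, NS + 1);
    for (int j = 0; j < m; ++j) {
      double tq = out_times[j];
      traj(j, 0) = tq;
      for (int k = 0; k < NS; ++k) {
        double val = (tq <= 0.0) ? ((k == 4) ? v_hat : 0.0) : pr.interp(tq, k);
        traj(j, k + 1) = (val < 0 && val > -atol) ? 0.0 : val;
      }
    }
    colnames(traj) = CharacterVector::create("t", "s", "a", "s_m", "a_m", "v",
                                             "cum_inf", "cum_inf_m");
    out["trajectory"] = traj;
  }
  return out;
}
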