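// Fixed-point label propagation: the inner loop of both the forward
// simulator and the fitting objective. Pure Jacobi sweeps: every pool's
// MID for sweep t+1 is assembled from sweep-t MIDs only, in declaration
// order, so results are independent of pool ordering.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Plan {
  int np;
  std::vector<int> ncarb;       // carbons per pool
  std::vector<int> is_source;   // 1 if fixed-MID source pool
  std::vector<std::vector<double> > smids;  // fixed MIDs for sources
  int nr;
  std::vector<int> prod;                       // product pool per reaction
  std::vector<std::vector<int> > subs;         // substrate pool indices
  // per substrate: marginalization matrix (row-major, rows x cols), or
  // empty when all carbons are retained (identity)
  std::vector<std::vector<std::vector<double> > > marg;
  std::vector<std::vector<int> > marg_nrow;
};

Plan unpack(const List& plan) {
  Plan P;
  IntegerVector nc = plan["n_carbons"];
  IntegerVector src = plan["is_source"];
  List sm = plan["source_mids"];
  List rx = plan["reactions"];
  P.np = nc.size();
  P.ncarb.assign(nc.begin(), nc.end());
  P.is_source.assign(src.begin(), src.end());
  P.smids.resize(P.np);
  for (int p = 0; p < P.np; ++p) {
    if (P.is_source[p]) {
      NumericVector v = sm[p];
      P.smids[p].assign(v.begin(), v.end());
    }
  }
  P.nr = rx.size();
  P.prod.resize(P.nr);
  P.subs.resize(P.nr);
  P.marg.resize(P.nr);
  P.marg_nrow.resize(P.nr);
  for (int r = 0; r < P.nr; ++r) {
    List one = rx[r];
    P.prod[r] = as<int>(one["prod"]);
    IntegerVector s = one["subs"];
    P.subs[r].assign(s.begin(), s.end());
    List mg = one["margs"];
    int ns = mg.size();
    P.marg[r].resize(ns);
    P.marg_nrow[r].assign(ns, 0);
    for (int k = 0; k < ns; ++k) {
      RObject o = mg[k];
      if (!o.isNULL()) {
        NumericMatrix M(o);
        P.marg_nrow[r][k] = M.nrow();
        std::vector<double>& flat = P.marg[r][k];
        flat.resize((size_t)M.nrow() * M.ncol());
        for (int i = 0; i < M.nrow(); ++i)
          for (int j = 0; j < M.ncol(); ++j)
            flat[(size_t)i * M.ncol() + j] = M(i, j);
      }
    }
  }
  return P;
}

// convolution acc <- acc * y
void conv_into(std::vector<double>& acc, const std::vector<double>& y) {
  std::vector<double> out(acc.size() + y.size() - 1, 0.0);
  for (size_t i = 0; i < acc.size(); ++i) {
    const double ai = acc[i];
    if (ai == 0.0) continue;
    for (size_t j = 0; j < y.size(); ++j) out[i + j] += ai * y[j];
  }
  acc.swap(out);
}

// Run the fixed-point iteration; returns sweeps used (negative if the
// iteration cap was hit without reaching tol).
int iterate(const Plan& P, const NumericVector& v, double tol, int maxit,
            double damping, std::vector<std::vector<double> >& cur) {
  std::vector<double> den(P.np, 0.0);
  for (int r = 0; r < P.nr; ++r) den[P.prod[r]] += v[r];
  for (int p = 0; p < P.np; ++p)
    if (!P.is_source[p] && den[p] <= 0.0)
      stop("pool with zero total inflow (pool index %d)", p + 1);

  cur.assign(P.np, std::vector<double>());
  for (int p = 0; p < P.np; ++p) {
    if (P.is_source[p]) {
      cur[p] = P.smids[p];
    } else {
      cur[p].assign(P.ncarb[p] + 1, 0.0);
      cur[p][0] = 1.0;  // unlabeled initialization
    }
  }

  std::vector<std::vector<double> > acc(P.np);
  std::vector<double> contrib, y;
  for (int it = 1; it <= maxit; ++it) {
    for (int p = 0; p < P.np; ++p)
      if (!P.is_source[p]) acc[p].assign(P.ncarb[p] + 1, 0.0);

    for (int r = 0; r < P.nr; ++r) {
      const double vr = v[r];
      if (vr == 0.0) continue;
      contrib.assign(1, 1.0);
      const std::vector<int>& ss = P.subs[r];
      for (size_t k = 0; k < ss.size(); ++k) {
        const std::vector<double>& x = cur[ss[k]];
        const int nrow = P.marg_nrow[r][k];
        if (nrow > 0) {
          const std::vector<double>& M = P.marg[r][k];
          const size_t ncol = x.size();
          y.assign(nrow, 0.0);
          for (int i = 0; i < nrow; ++i) {
            double s = 0.0;
            for (size_t j = 0; j < ncol; ++j) s += M[(size_t)i * ncol + j] * x[j];
            y[i] = s;
          }
          conv_into(contrib, y);
        } else {
          conv_into(contrib, x);
        }
      }
      std::vector<double>& a = acc[P.prod[r]];
      const size_t lim = std::min(a.size(), contrib.size());
      for (size_t j = 0; j < lim; ++j) a[j] += vr * contrib[j];
    }

    double resid = 0.0;
    for (int p = 0; p < P.np; ++p) {
      if (P.is_source[p]) continue;
      const double d = den[p];
      std::vector<double>& c = cur[p];
      const std::vector<double>& a = acc[p];
      for (size_t j = 0; j < c.size(); ++j) {
        double nv = damping * (a[j] / d) + (1.0 - damping) * c[j];
        double diff = std::fabs(nv - c[j]);
        if (diff > resid) resid = diff;
        c[j] = nv;
      }
    }
    if (resid < tol) return it;
  }
  return -maxit;
}

}  // namespace

// [[Rcpp::export(name = ".c_compile_plan")]]
SEXP c_compile_plan(List plan) {
  XPtr<Plan> p(new Plan(unpack(plan)), true);
  return p;
}

// [[Rcpp::export(name = ".c_residuals")]]
NumericVector c_residuals(SEXP planPtr, NumericVector v,
                          IntegerVector obs_pool, List obs_mids,
                          double tol, int maxit) {
  XPtr<Plan> P(planPtr);
  std::vector<std::vector<double> > cur;
  int it = iterate(*P, v, tol, maxit, 1.0, cur);
  if (it < 0) stop("label propagation did not converge within the iteration cap");
  int m = 0;
  for (int i = 0; i < obs_mids.size(); ++i)
    m += Rf_length(obs_mids[i]);
  NumericVector out(m);
  int k = 0;
  for (int i = 0; i < obs_pool.size(); ++i) {
    const std::vector<double>& pred = cur[obs_pool[i]];
    NumericVector mm = obs_mids[i];
    for (int j = 0; j < mm.size(); ++j) out[k++] = pred[j] - mm[j];
  }
  return out;
}

// [[Rcpp::export(name = ".c_predict_mids")]]
List c_predict_mids(List plan, NumericVector v, double tol, int maxit,
                    double damping) {
  Plan P = unpack(plan);
  std::vector<std::vector<double> > cur;
  int it = iterate(P, v, tol, maxit, damping, cur);
  List out(P.np);
  for (int p = 0; p < P.np; ++p) out[p] = wrap(cur[p]);
  return List::create(_["mids"] = out,
                      _["iterations"] = std::abs(it),
                      _["converged"] = (it > 0));
}

// [[Rcpp::export(name = ".c_total_loss")]]
double c_total_loss(List plan, NumericVector v, IntegerVector obs_pool,
                    List obs_mids, double tol, int maxit, double damping) {
  Plan P = unpack(plan);
  std::vector<std::vector<double> > cur;
  int it = iterate(P, v, tol, maxit, damping, cur);
  if (it < 0) stop("label propagation did not converge within the iteration cap");
  double L = 0.0;
  for (int i = 0; i < obs_pool.size(); ++i) {
    const std::vector<double>& pred = cur[obs_pool[i]];
    NumericVector m = obs_mids[i];
    for (int j = 0; j < m.size(); ++j) {
      double d = pred[j] - m[j];
      L += d * d;
    }
  }
  return L;
}
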