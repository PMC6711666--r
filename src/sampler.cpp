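// Adaptive Metropolis-within-Gibbs sampler for the hierarchical behavioural
// models: Bernoulli-logit (hit/miss) or Student-t (reaction time) likelihood,
// four fixed effects, correlated 4-dimensional participant and run random
// effects in a non-centred parameterization (z ~ N(0, I), effects =
// diag(sigma) L z), HalfCauchy scale priors, and an LKJ correlation prior
// implemented through the C-vine canonical-partial-correlation transform.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int D = 4;     // coefficients: intercept, task, change, interaction
static const int NC = 6;    // free correlation parameters for a 4x4 matrix

// column index (0-based, C-vine tree level) of the m-th lower-triangular
// element in order (1,0),(2,0),(3,0),(2,1),(3,1),(3,2)
static const int CPC_ROW[NC] = {1, 2, 3, 2, 3, 3};
static const int CPC_COL[NC] = {0, 0, 0, 1, 1, 2};

// Build the Cholesky factor L (lower, unit-diagonal rows normalized) of a
// correlation matrix from unconstrained parameters y via z = tanh(y).
static void buildL(const double *y, double L[D][D]) {
  double z[NC];
  for (int m = 0; m < NC; ++m) z[m] = std::tanh(y[m]);
  for (int i = 0; i < D; ++i)
    for (int j = 0; j < D; ++j) L[i][j] = 0.0;
  L[0][0] = 1.0;
  for (int i = 1; i < D; ++i) {
    double rem = 1.0;
    for (int j = 0; j < i; ++j) {
      // find element index for (i, j)
      int m = 0;
      for (; m < NC; ++m) if (CPC_ROW[m] == i && CPC_COL[m] == j) break;
      L[i][j] = z[m] * std::sqrt(rem);
      rem -= L[i][j] * L[i][j];
      if (rem < 1e-12) rem = 1e-12;
    }
    L[i][i] = std::sqrt(rem);
  }
}

// log prior of the correlation parameters: LKJ(eta) via independent shifted
// Beta densities on the canonical partial correlations, plus the tanh
// Jacobian. Column j (tree level j+1) has shape eta + (D - 2 - j)/2.
static double logPriorCorr(const double *y, double eta) {
  double lp = 0.0;
  for (int m = 0; m < NC; ++m) {
    double z = std::tanh(y[m]);
    double a = eta + 0.5 * (D - 2 - CPC_COL[m]);
    lp += (a - 1.0) * (std::log1p(z) + std::log1p(-z))   // beta((z+1)/2; a, a)
          - R::lbeta(a, a)
          + std::log1p(-z * z) - std::log(2.0);          // d((z+1)/2)/dy
  }
  return lp;
}

// HalfCauchy(scale) prior on exp(ls), with the log Jacobian of exp
static double logPriorHalfCauchy(double ls, double scale) {
  double x = std::exp(ls);
  return std::log(2.0 / (M_PI * scale)) - std::log1p((x / scale) * (x / scale))
         + ls;
}

static double logPriorBetaNormal(const double *b, double sd) {
  double lp = 0.0;
  for (int k = 0; k < D; ++k) lp += -0.5 * (b[k] / sd) * (b[k] / sd);
  return lp;
}

static double logPriorBetaStudent(const double *b, double df, double scale) {
  double lp = 0.0;
  for (int k = 0; k < D; ++k)
    lp += R::dt(b[k] / scale, df, 1) - std::log(scale);
  return lp;
}

struct Model {
  int n, I, J, lik;          // lik: 0 bernoulli-logit, 1 student-t
  const double *X;           // n x D, column-major
  const double *y;
  const int *pid, *rid;      // 0-based
  std::vector<std::vector<int> > byP, byR;
  // cached Student-t normalizing constant (sig and nu are constant within
  // any one proposal evaluation loop)
  mutable double cSig, cNu, cConst;

  double xdot(int t, const double *v) const {
    double s = 0.0;
    for (int k = 0; k < D; ++k) s += X[t + (size_t)n * k] * v[k];
    return s;
  }
  // pointwise log likelihood given linear predictor and residual params
  double llPoint(int t, double eta, double sig, double nu) const {
    if (lik == 0) {
      double e = eta;
      if (e > 0) return y[t] * e - e - std::log1p(std::exp(-e));
      return y[t] * e - std::log1p(std::exp(e));
    }
    if (sig != cSig || nu != cNu) {
      cSig = sig; cNu = nu;
      cConst = R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu) -
               0.5 * std::log(nu * M_PI) - std::log(sig);
    }
    double r = (y[t] - eta) / sig;
    return cConst - 0.5 * (nu + 1.0) * std::log1p(r * r / nu);
  }
};

struct State {
  double beta[D], lsp[D], lsr[D], yp[NC], yr[NC];
  std::vector<double> zp, zr;        // D x I, D x J
  double lsig, lnu;                  // student-t only
  // derived caches
  double Lp[D][D], Lr[D][D];
  std::vector<double> up, vr;        // D x I, D x J random-effect values
  std::vector<double> base, pu, pv;  // per-trial X*beta, X*u, X*v

  void refreshU(const Model &M) {
    buildL(yp, Lp);
    for (int i = 0; i < M.I; ++i)
      for (int k = 0; k < D; ++k) {
        double s = 0.0;
        for (int j = 0; j <= k; ++j) s += Lp[k][j] * zp[j + D * i];
        up[k + D * i] = std::exp(lsp[k]) * s;
      }
  }
  void refreshV(const Model &M) {
    buildL(yr, Lr);
    for (int j = 0; j < M.J; ++j)
      for (int k = 0; k < D; ++k) {
        double s = 0.0;
        for (int m = 0; m <= k; ++m) s += Lr[k][m] * zr[m + D * j];
        vr[k + D * j] = std::exp(lsr[k]) * s;
      }
  }
  void refreshTrialCaches(const Model &M) {
    for (int t = 0; t < M.n; ++t) {
      base[t] = M.xdot(t, beta);
      pu[t] = M.xdot(t, &up[D * M.pid[t]]);
      pv[t] = M.xdot(t, &vr[D * M.rid[t]]);
    }
  }
};

// running covariance-adaptive proposal for a small block (Haario-style)
struct CovAdapt {
  int d, count;
  std::vector<double> mean, cov, chol;
  bool ready;
  void init(int dim) {
    d = dim; count = 0; ready = false;
    mean.assign(d, 0.0);
    cov.assign((size_t)d * d, 0.0);
    chol.assign((size_t)d * d, 0.0);
  }
  void update(const double *x) {
    ++count;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - mean[i];
      mean[i] += dx / count;
      for (int j = 0; j <= i; ++j)
        cov[i * d + j] += dx * (x[j] - mean[j]);
    }
    if (count >= 20 * d && count % 100 == 0) refresh();
  }
  void refresh() {
    // Cholesky of cov/(count-1) + jitter
    std::vector<double> a((size_t)d * d, 0.0);
    for (int i = 0; i < d; ++i)
      for (int j = 0; j <= i; ++j)
        a[i * d + j] = cov[i * d + j] / (count - 1) +
                       (i == j ? 1e-10 : 0.0);
    for (int i = 0; i < d; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = a[i * d + j];
        for (int k = 0; k < j; ++k) s -= chol[i * d + k] * chol[j * d + k];
        if (i == j) {
          if (s <= 0) return;
          chol[i * d + i] = std::sqrt(s);
        } else {
          chol[i * d + j] = s / chol[j * d + j];
        }
      }
    }
    ready = true;
  }
  // proposal displacement scaled by sc
  void propose(double sc, double *dx) const {
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = R::rnorm(0, 1);
    if (ready) {
      for (int i = 0; i < d; ++i) {
        double s = 0.0;
        for (int j = 0; j <= i; ++j) s += chol[i * d + j] * z[j];
        dx[i] = sc * s;
      }
    } else {
      for (int i = 0; i < d; ++i) dx[i] = sc * z[i];
    }
  }
};

// adaptive scale for one proposal block
struct Adapt {
  double lscale;
  int tries, accepts, batch;
  double target;
  Adapt() : lscale(std::log(0.1)), tries(0), accepts(0), batch(0),
            target(0.234) {}
  void init(double s, double tgt) { lscale = std::log(s); target = tgt; }
  void record(bool acc, bool warm) {
    ++tries; if (acc) ++accepts;
    if (warm && tries == 50) {
      ++batch;
      double rate = accepts / 50.0;
      double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
      lscale += (rate > target ? step : -step);
      tries = accepts = 0;
    }
  }
  double scale() const { return std::exp(lscale); }
};

// [[Rcpp::export(name = ".mcmcHier")]]
NumericMatrix mcmcHier(NumericMatrix Xr, NumericVector yr_,
                       IntegerVector pidr, IntegerVector ridr,
                       int likelihood, int nIter, int nWarmup,
                       double betaSd, double betaDf, double betaScale,
                       int betaPriorStudent, double cauchyScale,
                       double lkjEta) {
  Model M;
  M.cSig = -1.0; M.cNu = -1.0; M.cConst = 0.0;
  M.n = Xr.nrow(); M.lik = likelihood;
  M.X = REAL(Xr); M.y = REAL(yr_);
  std::vector<int> pid(M.n), rid(M.n);
  int I = 0, J = 0;
  for (int t = 0; t < M.n; ++t) {
    pid[t] = pidr[t] - 1; rid[t] = ridr[t] - 1;
    if (pid[t] + 1 > I) I = pid[t] + 1;
    if (rid[t] + 1 > J) J = rid[t] + 1;
  }
  M.I = I; M.J = J; M.pid = pid.data(); M.rid = rid.data();
  M.byP.assign(I, std::vector<int>());
  M.byR.assign(J, std::vector<int>());
  for (int t = 0; t < M.n; ++t) {
    M.byP[pid[t]].push_back(t);
    M.byR[rid[t]].push_back(t);
  }

  State S;
  for (int k = 0; k < D; ++k) {
    S.beta[k] = 0.1 * R::rnorm(0, 1);
    S.lsp[k] = std::log(0.3) + 0.1 * R::rnorm(0, 1);
    S.lsr[k] = std::log(0.15) + 0.1 * R::rnorm(0, 1);
  }
  for (int m = 0; m < NC; ++m) {
    S.yp[m] = 0.1 * R::rnorm(0, 1);
    S.yr[m] = 0.1 * R::rnorm(0, 1);
  }
  S.zp.assign((size_t)D * I, 0.0);
  S.zr.assign((size_t)D * J, 0.0);
  for (size_t m = 0; m < S.zp.size(); ++m) S.zp[m] = 0.5 * R::rnorm(0, 1);
  for (size_t m = 0; m < S.zr.size(); ++m) S.zr[m] = 0.5 * R::rnorm(0, 1);
  S.lsig = 0.0; S.lnu = std::log(10.0);
  if (likelihood == 1) {
    double sy = 0, syy = 0;
    for (int t = 0; t < M.n; ++t) { sy += M.y[t]; syy += M.y[t] * M.y[t]; }
    double v = syy / M.n - (sy / M.n) * (sy / M.n);
    S.lsig = 0.5 * std::log(v > 1e-12 ? v : 1.0);
  }
  S.up.assign((size_t)D * I, 0.0);
  S.vr.assign((size_t)D * J, 0.0);
  S.base.assign(M.n, 0.0);
  S.pu.assign(M.n, 0.0);
  S.pv.assign(M.n, 0.0);
  S.refreshU(M); S.refreshV(M); S.refreshTrialCaches(M);

  double sig = std::exp(S.lsig), nu = 2.0 + std::exp(S.lnu);

  // current full log likelihood
  double llCur = 0.0;
  std::vector<double> llPt(M.n), llPtNew(M.n);
  for (int t = 0; t < M.n; ++t) {
    llPt[t] = M.llPoint(t, S.base[t] + S.pu[t] + S.pv[t], sig, nu);
    llCur += llPt[t];
  }

  Adapt aBeta, aLsp, aLsr, aYp, aYr, aSig, aNu;
  aBeta.init(0.05, 0.234); aLsp.init(0.1, 0.234); aLsr.init(0.1, 0.234);
  aYp.init(0.2, 0.234); aYr.init(0.2, 0.234);
  aSig.init(0.05, 0.44); aNu.init(0.3, 0.44);
  std::vector<Adapt> aZp(I), aZr(J);
  for (int i = 0; i < I; ++i) aZp[i].init(0.3, 0.234);
  for (int j = 0; j < J; ++j) aZr[j].init(0.3, 0.234);
  CovAdapt covBeta, covLsp, covYp, covLsr, covYr;
  covBeta.init(D);
  covLsp.init(D); covLsr.init(D);
  covYp.init(NC); covYr.init(NC);
  Adapt aShiftP[D], aShiftR[D], aScaleP[D], aScaleR[D];
  for (int k = 0; k < D; ++k) {
    aShiftP[k].init(0.1, 0.44);
    aShiftR[k].init(0.1, 0.44);
    aScaleP[k].init(0.3, 0.44);
    aScaleR[k].init(0.3, 0.44);
  }

  int nPar = 4 + 4 + 4 + NC + NC + (likelihood == 1 ? 2 : 0);
  int nKeep = nIter - nWarmup;
  NumericMatrix out(nKeep, nPar);

  std::vector<double> etaNew(M.n);

  for (int it = 0; it < nIter; ++it) {
    bool warm = it < nWarmup;
    sig = std::exp(S.lsig); nu = 2.0 + std::exp(S.lnu);

    { // fixed-effect block (covariance-adaptive random walk)
      double prop[D], dx[D];
      double sc = aBeta.scale();
      covBeta.propose(sc, dx);
      for (int k = 0; k < D; ++k) prop[k] = S.beta[k] + dx[k];
      double dPrior = betaPriorStudent
        ? logPriorBetaStudent(prop, betaDf, betaScale) -
          logPriorBetaStudent(S.beta, betaDf, betaScale)
        : logPriorBetaNormal(prop, betaSd) - logPriorBetaNormal(S.beta, betaSd);
      double llNew = 0.0;
      for (int t = 0; t < M.n; ++t) {
        double b = M.xdot(t, prop);
        etaNew[t] = b + S.pu[t] + S.pv[t];
        llPtNew[t] = M.llPoint(t, etaNew[t], sig, nu);
        llNew += llPtNew[t];
      }
      bool acc = std::log(R::runif(0, 1)) < llNew - llCur + dPrior;
      if (acc) {
        for (int k = 0; k < D; ++k) S.beta[k] = prop[k];
        for (int t = 0; t < M.n; ++t) S.base[t] = etaNew[t] - S.pu[t] - S.pv[t];
        llPt.swap(llPtNew);
        llCur = llNew;
      }
      aBeta.record(acc, warm);
    }

    // participant z blocks (non-centred standard-normal coordinates)
    for (int i = 0; i < I; ++i) {
      double zProp[D], uProp[D];
      double sc = aZp[i].scale();
      double dPrior = 0.0;
      for (int k = 0; k < D; ++k) {
        zProp[k] = S.zp[k + D * i] + sc * R::rnorm(0, 1);
        dPrior += -0.5 * (zProp[k] * zProp[k] -
                          S.zp[k + D * i] * S.zp[k + D * i]);
      }
      for (int k = 0; k < D; ++k) {
        double s = 0.0;
        for (int j = 0; j <= k; ++j) s += S.Lp[k][j] * zProp[j];
        uProp[k] = std::exp(S.lsp[k]) * s;
      }
      double dll = 0.0;
      const std::vector<int> &tt = M.byP[i];
      for (size_t q = 0; q < tt.size(); ++q) {
        int t = tt[q];
        double puNew = M.xdot(t, uProp);
        llPtNew[t] = M.llPoint(t, S.base[t] + puNew + S.pv[t], sig, nu);
        dll += llPtNew[t] - llPt[t];
      }
      bool acc = std::log(R::runif(0, 1)) < dll + dPrior;
      if (acc) {
        for (int k = 0; k < D; ++k) {
          S.zp[k + D * i] = zProp[k];
          S.up[k + D * i] = uProp[k];
        }
        for (size_t q = 0; q < tt.size(); ++q) {
          int t = tt[q];
          S.pu[t] = M.xdot(t, &S.up[D * i]);
          llPt[t] = llPtNew[t];
        }
        llCur += dll;
      }
      aZp[i].record(acc, warm);
    }

    // run z blocks
    for (int j = 0; j < J; ++j) {
      double zProp[D], vProp[D];
      double sc = aZr[j].scale();
      double dPrior = 0.0;
      for (int k = 0; k < D; ++k) {
        zProp[k] = S.zr[k + D * j] + sc * R::rnorm(0, 1);
        dPrior += -0.5 * (zProp[k] * zProp[k] -
                          S.zr[k + D * j] * S.zr[k + D * j]);
      }
      for (int k = 0; k < D; ++k) {
        double s = 0.0;
        for (int m = 0; m <= k; ++m) s += S.Lr[k][m] * zProp[m];
        vProp[k] = std::exp(S.lsr[k]) * s;
      }
      double dll = 0.0;
      const std::vector<int> &tt = M.byR[j];
      for (size_t q = 0; q < tt.size(); ++q) {
        int t = tt[q];
        double pvNew = M.xdot(t, vProp);
        llPtNew[t] = M.llPoint(t, S.base[t] + S.pu[t] + pvNew, sig, nu);
        dll += llPtNew[t] - llPt[t];
      }
      bool acc = std::log(R::runif(0, 1)) < dll + dPrior;
      if (acc) {
        for (int k = 0; k < D; ++k) {
          S.zr[k + D * j] = zProp[k];
          S.vr[k + D * j] = vProp[k];
        }
        for (size_t q = 0; q < tt.size(); ++q) {
          int t = tt[q];
          S.pv[t] = M.xdot(t, &S.vr[D * j]);
          llPt[t] = llPtNew[t];
        }
        llCur += dll;
      }
      aZr[j].record(acc, warm);
    }

    // translation moves: shift one fixed effect and compensate the
    // non-centred random effects so the likelihood is untouched; accepted
    // on the prior ratio alone. These decorrelate the fixed effects from
    // the participant/run deviation means (the dominant slow direction of
    // the non-centred posterior).
    for (int level = 0; level < 2; ++level) {
      bool isP = level == 0;
      int G = isP ? I : J;
      double L[D][D];
      for (int a = 0; a < D; ++a)
        for (int b = 0; b < D; ++b)
          L[a][b] = isP ? S.Lp[a][b] : S.Lr[a][b];
      const double *ls = isP ? S.lsp : S.lsr;
      std::vector<double> &z = isP ? S.zp : S.zr;
      for (int k = 0; k < D; ++k) {
        Adapt *ad = isP ? &aShiftP[k] : &aShiftR[k];
        double delta = ad->scale() * R::rnorm(0, 1);
        // solve L dz = -delta exp(-ls_k) e_k (forward substitution)
        double dz[D] = {0, 0, 0, 0};
        double rhs[D] = {0, 0, 0, 0};
        rhs[k] = -delta * std::exp(-ls[k]);
        for (int i2 = k; i2 < D; ++i2) {
          double s = rhs[i2];
          for (int j2 = k; j2 < i2; ++j2) s -= L[i2][j2] * dz[j2];
          dz[i2] = s / L[i2][i2];
        }
        double bOld[D], bNew[D];
        for (int a = 0; a < D; ++a) bOld[a] = bNew[a] = S.beta[a];
        bNew[k] += delta;
        double dPrior = betaPriorStudent
          ? logPriorBetaStudent(bNew, betaDf, betaScale) -
            logPriorBetaStudent(bOld, betaDf, betaScale)
          : logPriorBetaNormal(bNew, betaSd) -
            logPriorBetaNormal(bOld, betaSd);
        for (int m = k; m < D; ++m) {
          double sz = 0.0;
          for (int g = 0; g < G; ++g) sz += z[m + D * g];
          dPrior += -(dz[m] * sz + 0.5 * G * dz[m] * dz[m]);
        }
        bool acc = std::log(R::runif(0, 1)) < dPrior;
        if (acc) {
          S.beta[k] += delta;
          std::vector<double> &re = isP ? S.up : S.vr;
          std::vector<double> &proj = isP ? S.pu : S.pv;
          for (int g = 0; g < G; ++g) {
            for (int m = k; m < D; ++m) z[m + D * g] += dz[m];
            re[k + D * g] -= delta;        // u_k shifts by -delta exactly
          }
          for (int t = 0; t < M.n; ++t) {
            double xk = M.X[t + (size_t)M.n * k];
            S.base[t] += delta * xk;
            proj[t] -= delta * xk;
          }
        }
        ad->record(acc, warm);
      }
    }
    // rescaling moves: change one random-effect scale and rescale the
    // corresponding non-centred coordinates so the effect values (and the
    // likelihood) are untouched; accepted on prior x Jacobian. This breaks
    // the scale/coordinate funnel of the non-centred parameterization.
    for (int level = 0; level < 2; ++level) {
      bool isP = level == 0;
      int G = isP ? I : J;
      double (*L)[D] = isP ? S.Lp : S.Lr;
      double *ls = isP ? S.lsp : S.lsr;
      std::vector<double> &z = isP ? S.zp : S.zr;
      for (int k = 0; k < D; ++k) {
        Adapt *ad = isP ? &aScaleP[k] : &aScaleR[k];
        double delta = ad->scale() * R::rnorm(0, 1);
        double f = std::exp(-delta);
        // per group: w = L z, scale w_k by exp(-delta), re-solve for z
        std::vector<double> zNew((size_t)D * G);
        double dPrior = logPriorHalfCauchy(ls[k] + delta, cauchyScale) -
                        logPriorHalfCauchy(ls[k], cauchyScale) - G * delta;
        for (int g = 0; g < G; ++g) {
          double w[D];
          for (int m = 0; m < D; ++m) {
            double s = 0.0;
            for (int j2 = 0; j2 <= m; ++j2) s += L[m][j2] * z[j2 + D * g];
            w[m] = s;
          }
          w[k] *= f;
          for (int m = 0; m < D; ++m) {
            double s = w[m];
            for (int j2 = 0; j2 < m; ++j2) s -= L[m][j2] * zNew[j2 + D * g];
            zNew[m + D * g] = s / L[m][m];
            dPrior += -0.5 * (zNew[m + D * g] * zNew[m + D * g] -
                              z[m + D * g] * z[m + D * g]);
          }
        }
        bool acc = std::log(R::runif(0, 1)) < dPrior;
        if (acc) {
          ls[k] += delta;
          z = zNew;
        }
        ad->record(acc, warm);
      }
    }
    if (warm) covBeta.update(S.beta);

    // helper lambda-free macro-ish updates for the four global blocks that
    // change u or v wholesale (scales and correlation parameters)
    for (int block = 0; block < 4; ++block) {
      double *par; int len; Adapt *ad; CovAdapt *cv; bool isP;
      switch (block) {
        case 0: par = S.lsp; len = D; ad = &aLsp; cv = &covLsp;
                isP = true; break;
        case 1: par = S.yp; len = NC; ad = &aYp; cv = &covYp;
                isP = true; break;
        case 2: par = S.lsr; len = D; ad = &aLsr; cv = &covLsr;
                isP = false; break;
        default: par = S.yr; len = NC; ad = &aYr; cv = &covYr;
                 isP = false; break;
      }
      double old[NC], dx[NC];
      for (int k = 0; k < len; ++k) old[k] = par[k];
      bool priorRefresh = false;
      if ((block == 1 || block == 3) && R::runif(0, 1) < 0.2) {
        // independence proposal from the LKJ prior itself: the prior terms
        // cancel and acceptance is the bare likelihood ratio
        priorRefresh = true;
        for (int m = 0; m < NC; ++m) {
          double a = lkjEta + 0.5 * (D - 2 - CPC_COL[m]);
          double zp2 = 2.0 * R::rbeta(a, a) - 1.0;
          if (zp2 > 0.999999) zp2 = 0.999999;
          if (zp2 < -0.999999) zp2 = -0.999999;
          par[m] = std::atanh(zp2);
        }
      } else {
        cv->propose(ad->scale(), dx);
        for (int k = 0; k < len; ++k) par[k] = old[k] + dx[k];
      }
      double dPrior = 0.0;
      if (block == 0 || block == 2) {
        for (int k = 0; k < D; ++k)
          dPrior += logPriorHalfCauchy(par[k], cauchyScale) -
                    logPriorHalfCauchy(old[k], cauchyScale);
      } else if (!priorRefresh) {
        dPrior += logPriorCorr(par, lkjEta) - logPriorCorr(old, lkjEta);
      }  // prior-refresh: proposal density cancels the prior ratio
      // recompute the affected random-effect values and the likelihood
      std::vector<double> savedRe = isP ? S.up : S.vr;
      if (isP) S.refreshU(M); else S.refreshV(M);
      double llNew = 0.0;
      for (int t = 0; t < M.n; ++t) {
        double pNew = isP ? M.xdot(t, &S.up[D * M.pid[t]])
                          : M.xdot(t, &S.vr[D * M.rid[t]]);
        etaNew[t] = S.base[t] + (isP ? pNew + S.pv[t] : S.pu[t] + pNew);
        llPtNew[t] = M.llPoint(t, etaNew[t], sig, nu);
        llNew += llPtNew[t];
      }
      bool acc = std::log(R::runif(0, 1)) < llNew - llCur + dPrior;
      if (acc) {
        if (isP) {
          for (int t = 0; t < M.n; ++t)
            S.pu[t] = etaNew[t] - S.base[t] - S.pv[t];
        } else {
          for (int t = 0; t < M.n; ++t)
            S.pv[t] = etaNew[t] - S.base[t] - S.pu[t];
        }
        llPt.swap(llPtNew);
        llCur = llNew;
      } else {
        for (int k = 0; k < len; ++k) par[k] = old[k];
        if (isP) { S.up = savedRe; buildL(S.yp, S.Lp); }
        else { S.vr = savedRe; buildL(S.yr, S.Lr); }
      }
      if (!priorRefresh) ad->record(acc, warm);   // keep RW tuning clean
      if (warm) cv->update(par);
    }

    if (likelihood == 1) {
      // residual scale (HalfCauchy prior) and df (Exponential(0.1) on nu-2)
      for (int which = 0; which < 2; ++which) {
        Adapt *ad = which == 0 ? &aSig : &aNu;
        double old = which == 0 ? S.lsig : S.lnu;
        double prop = old + ad->scale() * R::rnorm(0, 1);
        double sigN = which == 0 ? std::exp(prop) : sig;
        double nuN = which == 1 ? 2.0 + std::exp(prop) : nu;
        double dPrior = which == 0
          ? logPriorHalfCauchy(prop, cauchyScale) -
            logPriorHalfCauchy(old, cauchyScale)
          : (-0.1 * (nuN - 2.0) + prop) - (-0.1 * (nu - 2.0) + old);
        double llNew = 0.0;
        for (int t = 0; t < M.n; ++t) {
          llPtNew[t] = M.llPoint(t, S.base[t] + S.pu[t] + S.pv[t], sigN, nuN);
          llNew += llPtNew[t];
        }
        bool acc = std::log(R::runif(0, 1)) < llNew - llCur + dPrior;
        if (acc) {
          if (which == 0) { S.lsig = prop; sig = sigN; }
          else { S.lnu = prop; nu = nuN; }
          llPt.swap(llPtNew);
          llCur = llNew;
        }
        ad->record(acc, warm);
      }
    }

    if (!warm) {
      int r = it - nWarmup;
      int c = 0;
      for (int k = 0; k < D; ++k) out(r, c++) = S.beta[k];
      for (int k = 0; k < D; ++k) out(r, c++) = std::exp(S.lsp[k]);
      for (int k = 0; k < D; ++k) out(r, c++) = std::exp(S.lsr[k]);
      double L[D][D];
      buildL(S.yp, L);
      // correlations R = L L' lower off-diagonals in (2,1),(3,1),(4,1),
      // (3,2),(4,2),(4,3) order
      for (int m = 0; m < NC; ++m) {
        int i = CPC_ROW[m], j = CPC_COL[m];
        double s = 0.0;
        for (int k = 0; k <= (i < j ? i : j); ++k) s += L[i][k] * L[j][k];
        out(r, c++) = s;
      }
      buildL(S.yr, L);
      for (int m = 0; m < NC; ++m) {
        int i = CPC_ROW[m], j = CPC_COL[m];
        double s = 0.0;
        for (int k = 0; k <= (i < j ? i : j); ++k) s += L[i][k] * L[j][k];
        out(r, c++) = s;
      }
      if (likelihood == 1) {
        out(r, c++) = std::exp(S.lsig);
        out(r, c++) = 2.0 + std::exp(S.lnu);
      }
    }
  }
  return out;
}
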