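#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the animal model
//   y = Xb + Za + Wc + e,  a ~ N(0, A (x) G0),  c ~ N(0, I (x) C0),
//   e ~ N(0, I (x) R0)
// for k = 1 or 2 traits, each linear or threshold-binary. Threshold traits
// carry a latent liability (threshold fixed at 0); identifiability is
// restored after every residual draw by rescaling the trait so its residual
// variance is exactly 1 (parameter-expansion / rescaling scheme).
//
// Covariance full conditionals are inverse-Wishart with scale a'A^{-1}a
// (genetic), c'c (pen) and e'e (residual) plus prior scale, and degrees of
// freedom q + nu0, npen + nu0, n + nu0; the default nu0 = -(k+1), scale 0
// corresponds to a flat prior on the covariance matrix.
//
// Performance notes: indicator columns of X are stored as row-index lists;
// u = A^{-1} a is maintained incrementally per trait (one sparse-row scan
// per animal update) and refreshed from scratch periodically to stop
// floating-point drift, so both the effect updates and the genetic
// quadratic form a'A^{-1}a are O(nnz) per sweep.

static const int KMAX = 2;

static void inv_k(int k, const double S[KMAX][KMAX], double out[KMAX][KMAX],
                  int iter, const char *what) {
  if (k == 1) {
    if (S[0][0] <= 0.0)
      stop("non-positive %s variance at iteration %d", what, iter);
    out[0][0] = 1.0 / S[0][0];
    return;
  }
  double det = S[0][0] * S[1][1] - S[0][1] * S[1][0];
  if (det <= 0.0 || S[0][0] <= 0.0)
    stop("non-positive-definite %s covariance at iteration %d", what, iter);
  out[0][0] = S[1][1] / det;
  out[1][1] = S[0][0] / det;
  out[0][1] = out[1][0] = -S[0][1] / det;
}

// Draw from inverse-Wishart(S, df) for k <= 2 via the Bartlett decomposition
// of a Wishart(df, S^{-1}) draw.
static void riwish_k(int k, double S[KMAX][KMAX], double df,
                     double out[KMAX][KMAX], int iter, const char *what) {
  // Jitter S towards SPD if a near-degenerate scale matrix appears.
  if (k == 2) {
    double det = S[0][0] * S[1][1] - S[0][1] * S[1][0];
    double tr = S[0][0] + S[1][1];
    if (det <= 1e-12 * tr * tr) {
      double eps = 1e-8 * (tr > 0 ? tr : 1.0);
      S[0][0] += eps; S[1][1] += eps;
    }
  }
  if (df <= k - 1)
    stop("degrees of freedom too small for %s covariance draw (iteration %d)",
         what, iter);
  double V[KMAX][KMAX];
  inv_k(k, S, V, iter, what);
  if (k == 1) {
    double w = R::rchisq(df) * V[0][0];
    out[0][0] = 1.0 / w;
    return;
  }
  double l11 = std::sqrt(V[0][0]);
  double l21 = V[1][0] / l11;
  double arg = V[1][1] - l21 * l21;
  double l22 = std::sqrt(arg > 1e-300 ? arg : 1e-300);
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  double w11 = l11 * a11;
  double w21 = l21 * a11 + l22 * a21;
  double w22 = l22 * a22;
  double W[KMAX][KMAX];
  W[0][0] = w11 * w11;
  W[0][1] = W[1][0] = w11 * w21;
  W[1][1] = w21 * w21 + w22 * w22;
  inv_k(k, W, out, iter, what);
}

// Truncated-normal draw by inversion; positive = TRUE truncates to (0, inf).
static double rtnorm0(double mean, double sd, bool positive) {
  double p0 = R::pnorm(0.0, mean, sd, 1, 0);  // P(X < 0)
  double u = positive ? p0 + unif_rand() * (1.0 - p0) : unif_rand() * p0;
  if (u < 1e-16) u = 1e-16;
  if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
  double z = R::qnorm(u, mean, sd, 1, 0);
  if (positive && z <= 0.0) z = 1e-8;
  if (!positive && z >= 0.0) z = -1e-8;
  return z;
}

// Exposed for testing the truncated-normal inversion sampler.
// [[Rcpp::export]]
NumericVector rtnorm_cpp(int n, double mean, double sd, bool positive) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm0(mean, sd, positive);
  return out;
}

// [[Rcpp::export]]
List gibbs_animal_cpp(NumericMatrix y, NumericMatrix X,
                      IntegerVector zid, IntegerVector wid,
                      int q, int npen,
                      IntegerVector ap, IntegerVector ai, NumericVector ax,
                      LogicalVector thr,
                      int n_iter, int burn_in, int thin,
                      double nu0_g, NumericMatrix S0g,
                      double nu0_c, NumericMatrix S0c,
                      double nu0_e, NumericMatrix S0e,
                      NumericMatrix Gs, NumericMatrix Cs, NumericMatrix Rs) {
  const int n = y.nrow(), k = y.ncol(), p = X.ncol();
  if (k > KMAX) stop("at most two traits are supported");
  int n_thr = 0;
  for (int t = 0; t < k; ++t) if (thr[t]) ++n_thr;

  // ---- index records by animal and by pen (counting sort) ----
  std::vector<int> zptr(q + 1, 0), wptr(npen + 1, 0), zrec(n), wrec(n);
  for (int i = 0; i < n; ++i) { zptr[zid[i] + 1]++; wptr[wid[i] + 1]++; }
  for (int i = 0; i < q; ++i) zptr[i + 1] += zptr[i];
  for (int i = 0; i < npen; ++i) wptr[i + 1] += wptr[i];
  {
    std::vector<int> zc(zptr.begin(), zptr.end()), wc(wptr.begin(), wptr.end());
    for (int i = 0; i < n; ++i) {
      zrec[zc[zid[i]]++] = i;
      wrec[wc[wid[i]]++] = i;
    }
  }

  // ---- sparse view of X: indicator columns as row lists ----
  std::vector<double> xx(p, 0.0);
  std::vector<bool> is_ind(p, false);
  std::vector<std::vector<int> > xrows(p);
  std::vector<std::vector<double> > xvals(p);
  for (int j = 0; j < p; ++j) {
    bool ind = true;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v != 0.0 && v != 1.0) { ind = false; break; }
    }
    is_ind[j] = ind;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v == 0.0) continue;
      xrows[j].push_back(i);
      if (!ind) xvals[j].push_back(v);
      xx[j] += v * v;
    }
  }

  // ---- state ----
  std::vector<double> L(n * k), e(n * k);          // column-major [t*n + i]
  std::vector<double> b(p * k, 0.0), a(q * k, 0.0), c(npen * k, 0.0);
  std::vector<double> u(q * k, 0.0);               // u_t = A^{-1} a_t
  double G[KMAX][KMAX] = {{0}}, C[KMAX][KMAX] = {{0}}, R[KMAX][KMAX] = {{0}};
  double Ginv[KMAX][KMAX], Cinv[KMAX][KMAX], Rinv[KMAX][KMAX];
  for (int s = 0; s < k; ++s)
    for (int t = 0; t < k; ++t) {
      G[s][t] = Gs(s, t); C[s][t] = Cs(s, t); R[s][t] = Rs(s, t);
    }
  std::vector<double> adiag(q, 0.0);               // diagonal of A^{-1}
  for (int i = 0; i < q; ++i)
    for (int idx = ap[i]; idx < ap[i + 1]; ++idx)
      if (ai[idx] == i) adiag[i] = ax[idx];
  for (int t = 0; t < k; ++t)
    for (int i = 0; i < n; ++i) {
      double v = y(i, t);
      if (thr[t]) v = (v > 0.5) ? 0.5 : -0.5;      // crude liability start
      L[t * n + i] = v;
      e[t * n + i] = v;                            // all effects start at zero
    }

  // ---- storage ----
  const int m = k * (k + 1) / 2;
  const int n_stored = (n_iter - burn_in) / thin;
  NumericMatrix chains(n_stored, 3 * m + p * k);
  std::vector<double> a_sum(q * k, 0.0), a_ss(q * k, 0.0);
  int stored = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
    inv_k(k, G, Ginv, iter, "genetic");
    inv_k(k, C, Cinv, iter, "pen");
    inv_k(k, R, Rinv, iter, "residual");

    // refresh u = A^{-1} a from scratch periodically (drift control)
    if (iter == 1 || iter % 500 == 0) {
      std::fill(u.begin(), u.end(), 0.0);
      for (int t = 0; t < k; ++t) {
        const double *at = &a[t * q];
        double *ut = &u[t * q];
        for (int i = 0; i < q; ++i) {
          double acc = 0.0;
          for (int idx = ap[i]; idx < ap[i + 1]; ++idx)
            acc += ax[idx] * at[ai[idx]];
          ut[i] = acc;
        }
      }
    }

    // ---- liability augmentation for threshold traits ----
    for (int t = 0; t < k; ++t) {
      if (!thr[t]) continue;
      int o = 1 - t;
      double beta = 0.0, cvar = R[t][t];
      if (k == 2) {
        beta = R[t][o] / R[o][o];
        cvar = R[t][t] - R[t][o] * R[t][o] / R[o][o];
        if (cvar < 1e-10) cvar = 1e-10;
      }
      double csd = std::sqrt(cvar);
      double *Lt = &L[t * n], *et = &e[t * n];
      const double *eo = (k == 2) ? &e[o * n] : NULL;
      for (int i = 0; i < n; ++i) {
        double fitted = Lt[i] - et[i];
        double cm = fitted + (eo ? beta * eo[i] : 0.0);
        double l = rtnorm0(cm, csd, y(i, t) > 0.5);
        Lt[i] = l;
        et[i] = l - fitted;
      }
    }

    // ---- fixed effects (flat prior) ----
    for (int t = 0; t < k; ++t) {
      int o = 1 - t;
      double *et = &e[t * n];
      const double *eo = (k == 2) ? &e[o * n] : NULL;
      const double rtt = Rinv[t][t], rto = (k == 2) ? Rinv[t][o] : 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] <= 0.0) continue;
        const std::vector<int> &rows = xrows[j];
        const size_t nr = rows.size();
        double sum_re = 0.0;
        if (is_ind[j]) {
          for (size_t ii = 0; ii < nr; ++ii) {
            int i = rows[ii];
            sum_re += rtt * et[i] + (eo ? rto * eo[i] : 0.0);
          }
        } else {
          const std::vector<double> &vals = xvals[j];
          for (size_t ii = 0; ii < nr; ++ii) {
            int i = rows[ii];
            sum_re += vals[ii] * (rtt * et[i] + (eo ? rto * eo[i] : 0.0));
          }
        }
        double prec = xx[j] * rtt;
        double mean = (sum_re + prec * b[t * p + j]) / prec;
        double bnew = mean + norm_rand() / std::sqrt(prec);
        double delta = bnew - b[t * p + j];
        b[t * p + j] = bnew;
        if (is_ind[j]) {
          for (size_t ii = 0; ii < nr; ++ii) et[rows[ii]] -= delta;
        } else {
          for (size_t ii = 0; ii < nr; ++ii)
            et[rows[ii]] -= xvals[j][ii] * delta;
        }
      }
    }

    // ---- additive genetic effects ----
    for (int t = 0; t < k; ++t) {
      int o = 1 - t;
      double *et = &e[t * n];
      const double *eo = (k == 2) ? &e[o * n] : NULL;
      double *at = &a[t * q], *ut = &u[t * q];
      const double *uo = (k == 2) ? &u[o * q] : NULL;
      const double rtt = Rinv[t][t], rto = (k == 2) ? Rinv[t][o] : 0.0;
      const double gtt = Ginv[t][t], gto = (k == 2) ? Ginv[t][o] : 0.0;
      for (int i = 0; i < q; ++i) {
        double cross = ut[i] - adiag[i] * at[i];
        double prior_rhs = -gtt * cross - (uo ? gto * uo[i] : 0.0);
        double sum_re = 0.0;
        const int ni = zptr[i + 1] - zptr[i];
        for (int idx = zptr[i]; idx < zptr[i + 1]; ++idx) {
          int r = zrec[idx];
          sum_re += rtt * et[r] + (eo ? rto * eo[r] : 0.0);
        }
        double prec = ni * rtt + gtt * adiag[i];
        double rhs = sum_re + ni * rtt * at[i] + prior_rhs;
        double anew = rhs / prec + norm_rand() / std::sqrt(prec);
        double delta = anew - at[i];
        if (delta != 0.0) {
          at[i] = anew;
          for (int idx = zptr[i]; idx < zptr[i + 1]; ++idx)
            et[zrec[idx]] -= delta;
          for (int idx = ap[i]; idx < ap[i + 1]; ++idx)
            ut[ai[idx]] += ax[idx] * delta;
        }
      }
    }

    // ---- pen effects ----
    for (int t = 0; t < k; ++t) {
      int o = 1 - t;
      double *et = &e[t * n];
      const double *eo = (k == 2) ? &e[o * n] : NULL;
      double *ct = &c[t * npen];
      const double *co = (k == 2) ? &c[o * npen] : NULL;
      const double rtt = Rinv[t][t], rto = (k == 2) ? Rinv[t][o] : 0.0;
      for (int j = 0; j < npen; ++j) {
        const int nj = wptr[j + 1] - wptr[j];
        double sum_re = 0.0;
        for (int idx = wptr[j]; idx < wptr[j + 1]; ++idx) {
          int r = wrec[idx];
          sum_re += rtt * et[r] + (eo ? rto * eo[r] : 0.0);
        }
        double prec = nj * rtt + Cinv[t][t];
        double rhs = sum_re + nj * rtt * ct[j];
        if (co) rhs -= Cinv[t][o] * co[j];
        double cnew = rhs / prec + norm_rand() / std::sqrt(prec);
        double delta = cnew - ct[j];
        ct[j] = cnew;
        for (int idx = wptr[j]; idx < wptr[j + 1]; ++idx)
          et[wrec[idx]] -= delta;
      }
    }

    // ---- covariance components ----
    double S[KMAX][KMAX];
    for (int s = 0; s < k; ++s)
      for (int t = 0; t < k; ++t) S[s][t] = S0g(s, t);
    for (int s = 0; s < k; ++s)
      for (int t = 0; t < k; ++t) {
        const double *as = &a[s * q], *vt = &u[t * q];
        double acc = 0.0;
        for (int i = 0; i < q; ++i) acc += as[i] * vt[i];
        S[s][t] += acc;
      }
    // symmetrise against incremental-update rounding
    if (k == 2) S[0][1] = S[1][0] = 0.5 * (S[0][1] + S[1][0]);
    riwish_k(k, S, q + nu0_g, G, iter, "genetic");

    for (int s = 0; s < k; ++s)
      for (int t = 0; t < k; ++t) S[s][t] = S0c(s, t);
    for (int j = 0; j < npen; ++j)
      for (int s = 0; s < k; ++s)
        for (int t = 0; t < k; ++t) S[s][t] += c[s * npen + j] * c[t * npen + j];
    riwish_k(k, S, npen + nu0_c, C, iter, "pen");

    // ---- residual covariance ----
    // Threshold traits have residual variance fixed at 1 for
    // identifiability, so the residual step depends on the trait kinds.
    if (n_thr == 0) {
      for (int s = 0; s < k; ++s)
        for (int t = 0; t < k; ++t) S[s][t] = S0e(s, t);
      for (int i = 0; i < n; ++i)
        for (int s = 0; s < k; ++s)
          for (int t = 0; t < k; ++t) S[s][t] += e[s * n + i] * e[t * n + i];
      riwish_k(k, S, n + nu0_e, R, iter, "residual");
    } else if (k == 2 && n_thr == 1) {
      // linear trait 'lo', threshold trait 'lt': decompose
      //   e_lin | e_thr ~ N(beta * e_thr, psi),  var(e_thr) = 1,
      // and Gibbs-sample (beta, psi) with flat priors, which keeps the
      // restriction R[lt][lt] = 1 exact.
      const int lt = thr[0] ? 0 : 1, lo = 1 - lt;
      const double *el = &e[lo * n], *et2 = &e[lt * n];
      double sxx = 0.0, sxy = 0.0, syy = 0.0;
      for (int i = 0; i < n; ++i) {
        sxx += et2[i] * et2[i];
        sxy += et2[i] * el[i];
        syy += el[i] * el[i];
      }
      double psi = R[lo][lo] - R[lo][lt] * R[lo][lt];
      double beta = sxy / sxx + norm_rand() * std::sqrt(psi / sxx);
      double sse = syy - 2.0 * beta * sxy + beta * beta * sxx;
      psi = sse / R::rchisq(n - 2.0);
      R[lt][lt] = 1.0;
      R[lo][lt] = R[lt][lo] = beta;
      R[lo][lo] = psi + beta * beta;
    } else if (k == 2 && n_thr == 2) {
      // both residual variances fixed at 1: random-walk Metropolis on the
      // residual correlation with a flat prior on (-1, 1)
      double s11 = 0.0, s22 = 0.0, s12 = 0.0;
      const double *e1 = &e[0], *e2 = &e[n];
      for (int i = 0; i < n; ++i) {
        s11 += e1[i] * e1[i];
        s22 += e2[i] * e2[i];
        s12 += e1[i] * e2[i];
      }
      double rho = R[0][1];
      double logpost = [&](double r) {
        double om = 1.0 - r * r;
        return -0.5 * n * std::log(om) - (s11 + s22 - 2.0 * r * s12) / (2.0 * om);
      }(rho);
      double prop = rho + 0.05 * norm_rand();
      if (prop > -0.999 && prop < 0.999) {
        double om = 1.0 - prop * prop;
        double lp = -0.5 * n * std::log(om) -
          (s11 + s22 - 2.0 * prop * s12) / (2.0 * om);
        if (std::log(unif_rand()) < lp - logpost) rho = prop;
      }
      R[0][0] = R[1][1] = 1.0;
      R[0][1] = R[1][0] = rho;
    }
    // (k == 1 with a threshold trait: R stays fixed at 1)

    // ---- store ----
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int col = 0;
      for (int s = 0; s < k; ++s)
        for (int t = s; t < k; ++t) chains(stored, col++) = G[s][t];
      for (int s = 0; s < k; ++s)
        for (int t = s; t < k; ++t) chains(stored, col++) = C[s][t];
      for (int s = 0; s < k; ++s)
        for (int t = s; t < k; ++t) chains(stored, col++) = R[s][t];
      for (int t = 0; t < k; ++t)
        for (int j = 0; j < p; ++j) chains(stored, col++) = b[t * p + j];
      for (int t = 0; t < k; ++t)
        for (int i = 0; i < q; ++i) {
          a_sum[t * q + i] += a[t * q + i];
          a_ss[t * q + i] += a[t * q + i] * a[t * q + i];
        }
      ++stored;
    }
  }

  NumericMatrix a_mean(q, k), a_sd(q, k);
  for (int t = 0; t < k; ++t)
    for (int i = 0; i < q; ++i) {
      double mu = a_sum[t * q + i] / stored;
      a_mean(i, t) = mu;
      double v = a_ss[t * q + i] / stored - mu * mu;
      a_sd(i, t) = v > 0 ? std::sqrt(v) : 0.0;
    }
  return List::create(_["chains"] = chains, _["a_mean"] = a_mean,
                      _["a_sd"] = a_sd, _["n_stored"] = stored);
}
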