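// Metropolis-within-Gibbs chain for the marker-gene NB deconvolution model.
//
// Layout: counts C and marker matrix B are gene x spot / gene x type;
// spot-level state (theta, pi, Z, H) is spot x type. The NB(r, p) pmf uses
// the mean r*p/(1-p) convention, i.e. base R's prob = 1 - p.
//
// One sweep updates, in this order: pi (Gibbs), Z (Gibbs, dummy column held
// at 0 under shrinkage), theta (MH per spot x type, truncated-normal
// proposal), N (MH per spot, ceiling-truncated-normal), lambda0 (global MH),
// Lambda (MH per marker entry), p (MH per gene). Every accepted value is
// used immediately by subsequent updates. Spot-level proposals are evaluated
// for all spots in one pass (spots are conditionally independent given the
// gene-level parameters), which is mathematically identical to a sequential
// scan.

#include <Rcpp.h>
using namespace Rcpp;

static inline double nb_lp(double k, double r, double l1p, double lp,
                           double lgfk) {
  if (r <= 0.0) return R_NegInf;
  // lgamma(k + r) - lgamma(r) = log prod_{j<k} (r + j); for small integer k
  // the explicit product needs a single log and is much cheaper than two
  // lgamma calls (the product cannot overflow for k < 25, r < 1e6)
  int ki = (int)k;
  if (ki < 25 && r < 1e6) {
    double prod = 1.0;
    for (int j = 0; j < ki; ++j) prod *= r + j;
    double lratio = (ki == 0) ? 0.0 : std::log(prod);
    return lratio - lgfk + r * l1p + k * lp;
  }
  return R::lgammafn(k + r) - R::lgammafn(r) - lgfk + r * l1p + k * lp;
}

static inline double rtnorm_pos(double mu, double sd) {
  double y;
  do {
    y = R::rnorm(mu, sd);
  } while (y <= 0.0);
  return y;
}

// log q(x|y) - log q(y|x) for the positive truncated-normal random walk
static inline double tn_lhr(double x, double y, double s) {
  return R::pnorm(x / s, 0.0, 1.0, 1, 1) - R::pnorm(y / s, 0.0, 1.0, 1, 1);
}

// log(Phi(a) - Phi(b)), a >= b, stable in both tails (log-CDFs below
// zero, log-survival functions above)
static inline double log_pnorm_diff(double a, double b, double s) {
  a /= s;
  b /= s;
  if (a <= 0.0)
    return Rf_logspace_sub(R::pnorm(a, 0.0, 1.0, 1, 1),
                           R::pnorm(b, 0.0, 1.0, 1, 1));
  if (b >= 0.0)
    return Rf_logspace_sub(R::pnorm(b, 0.0, 1.0, 0, 1),
                           R::pnorm(a, 0.0, 1.0, 0, 1));
  return std::log(R::pnorm(a, 0.0, 1.0, 1, 0) -
                  R::pnorm(b, 0.0, 1.0, 1, 0));
}

// same for the ceiling-truncated-normal proposal on positive integers:
// log q(x|y) - log q(y|x) with q(v|u) the pmf of ceil(TN(u, s)) at v
static inline double ceiltn_lhr(double x, double y, double s) {
  return tn_lhr(x, y, s) + log_pnorm_diff(x - y, x - 1.0 - y, s) -
         log_pnorm_diff(y - x, y - 1.0 - x, s);
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericMatrix C, NumericMatrix B,
                   NumericVector l, double sigma_n,
                   double alpha, double a, double b, double a0, double b0,
                   int n_iter, int burn_in, int thinning,
                   double st_theta, double st_n, double st_l0, double st_p,
                   NumericVector st_lam,
                   int adapt_interval, double adapt_eps, double target_acc,
                   bool shrink_dummy, int dummy, // 0-based dummy column
                   bool fix_n, bool fix_lambda, bool normalized_z,
                   NumericMatrix theta0, NumericMatrix pi0,
                   NumericMatrix Z0, NumericVector N0,
                   double lambda0_init, NumericVector p0,
                   NumericMatrix Lambda0) {
  const int G = C.nrow(), S = C.ncol(), T = B.ncol();
  if (B.nrow() != G) stop("B and C disagree on the number of genes");

  // state (copies of inits)
  NumericMatrix theta = clone(theta0), pi = clone(pi0), Z = clone(Z0),
                Lambda = clone(Lambda0);
  NumericVector N = clone(N0), p = clone(p0);
  double lambda0 = lambda0_init;
  NumericVector stlam = clone(st_lam);

  // caches
  NumericVector thsum(S), cg(G), lp(G), l1p(G);
  NumericMatrix H(S, T), W(G, T), M(G, S), L(G, S), lgf(G, S);
  NumericMatrix Mprop(G, S), Lprop(G, S);

  for (int s = 0; s < S; ++s) {
    double ts = 0.0;
    for (int t = 0; t < T; ++t) ts += theta(s, t);
    thsum[s] = ts;
    for (int t = 0; t < T; ++t) H(s, t) = theta(s, t) / ts;
  }
  for (int g = 0; g < G; ++g) {
    cg[g] = (1.0 - p[g]) / p[g];
    lp[g] = std::log(p[g]);
    l1p[g] = std::log1p(-p[g]);
    for (int t = 0; t < T; ++t) W(g, t) = B(g, t) * Lambda(g, t);
  }
  for (int s = 0; s < S; ++s)
    for (int g = 0; g < G; ++g) {
      double m = 0.0;
      for (int t = 0; t < T; ++t) m += W(g, t) * H(s, t);
      M(g, s) = m;
      lgf(g, s) = R::lgammafn(C(g, s) + 1.0);
      L(g, s) = nb_lp(C(g, s), N[s] * cg[g] * (lambda0 + m),
                      l1p[g], lp[g], lgf(g, s));
    }

  const double lga = a * std::log(b) - R::lgammafn(a);
  const double lga0 = a0 * std::log(b0) - R::lgammafn(a0);

  const int n_ret = (n_iter - burn_in) / thinning;
  NumericVector H_draws((R_xlen_t)n_ret * S * T);
  NumericMatrix N_draws(n_ret, S), p_draws(n_ret, G);
  NumericVector l0_draws(n_ret), ll_draws(n_ret);
  NumericVector lam_draws((R_xlen_t)n_ret * G * T);

  // acceptance bookkeeping: window counters (reset at adaptation) and totals
  double wa_th = 0, wp_th = 0, wa_n = 0, wp_n = 0, wa_l0 = 0, wp_l0 = 0,
         wa_p = 0, wp_p = 0;
  NumericVector wa_lam(G), wp_lam(G);
  double ta_th = 0, tp_th = 0, ta_n = 0, tp_n = 0, ta_l0 = 0, tp_l0 = 0,
         ta_p = 0, tp_p = 0, ta_lam = 0, tp_lam = 0;

  std::vector<double> ynew(S), dnew(S);

  int d = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- pi | Z : Beta(alpha/T + Z, 2 - Z) ------------------------------
    for (int t = 0; t < T; ++t)
      for (int s = 0; s < S; ++s)
        pi(s, t) = R::rbeta(alpha / T + Z(s, t), 2.0 - Z(s, t));

    // --- Z | theta, pi --------------------------------------------------
    for (int t = 0; t < T; ++t) {
      if (shrink_dummy && t == dummy) continue;
      for (int s = 0; s < S; ++s) {
        double th = theta(s, t);
        double la = std::log(pi(s, t)) + lga + (a - 1.0) * std::log(th) -
                    b * th;
        double lb = std::log1p(-pi(s, t)) + lga0 +
                    (a0 - 1.0) * std::log(th) - b0 * th;
        if (!normalized_z) { la -= lga; lb -= lga0; }
        double p1 = 1.0 / (1.0 + std::exp(lb - la));
        Z(s, t) = (unif_rand() < p1) ? 1.0 : 0.0;
      }
    }

    // --- theta: MH per (spot, type), full spot likelihood ----------------
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < S; ++s) {
        double x = theta(s, t);
        double y = rtnorm_pos(x, st_theta);
        ynew[s] = y;
        double ns = thsum[s] - x + y;
        dnew[s] = ns;
        for (int g = 0; g < G; ++g) {
          // mu under the proposal: whole H row rescales
          double m = (M(g, s) - W(g, t) * theta(s, t) / thsum[s]) *
                         thsum[s] / ns +
                     W(g, t) * y / ns;
          Mprop(g, s) = m;
          Lprop(g, s) = nb_lp(C(g, s), N[s] * cg[g] * (lambda0 + m),
                              l1p[g], lp[g], lgf(g, s));
        }
      }
      for (int s = 0; s < S; ++s) {
        double x = theta(s, t), y = ynew[s];
        double delta = 0.0;
        for (int g = 0; g < G; ++g) delta += Lprop(g, s) - L(g, s);
        if (Z(s, t) == 1.0)
          delta += (a - 1.0) * (std::log(y) - std::log(x)) - b * (y - x);
        else
          delta += (a0 - 1.0) * (std::log(y) - std::log(x)) - b0 * (y - x);
        delta += tn_lhr(x, y, st_theta);
        wp_th += 1; tp_th += 1;
        if (R_IsNaN(delta)) continue;
        if (std::log(unif_rand()) < delta) {
          wa_th += 1; ta_th += 1;
          theta(s, t) = y;
          thsum[s] = dnew[s];
          for (int j = 0; j < T; ++j) H(s, j) = theta(s, j) / thsum[s];
          for (int g = 0; g < G; ++g) {
            M(g, s) = Mprop(g, s);
            L(g, s) = Lprop(g, s);
          }
        }
      }
    }

    // --- N: MH per spot, ceiling-truncated-normal proposal ---------------
    if (!fix_n) {
      for (int s = 0; s < S; ++s) {
        double x = N[s];
        double y = std::ceil(rtnorm_pos(x, st_n));
        ynew[s] = y;
        for (int g = 0; g < G; ++g)
          Lprop(g, s) = nb_lp(C(g, s), y * cg[g] * (lambda0 + M(g, s)),
                              l1p[g], lp[g], lgf(g, s));
      }
      for (int s = 0; s < S; ++s) {
        double x = N[s], y = ynew[s];
        double delta = 0.0;
        for (int g = 0; g < G; ++g) delta += Lprop(g, s) - L(g, s);
        double dl = y - l[s], dx = x - l[s];
        delta += -(dl * dl - dx * dx) / (2.0 * sigma_n * sigma_n);
        delta += ceiltn_lhr(x, y, st_n);
        wp_n += 1; tp_n += 1;
        if (R_IsNaN(delta)) continue;
        if (std::log(unif_rand()) < delta) {
          wa_n += 1; ta_n += 1;
          N[s] = y;
          for (int g = 0; g < G; ++g) L(g, s) = Lprop(g, s);
        }
      }
    }

    // --- lambda0: global MH ----------------------------------------------
    {
      double x = lambda0;
      double y = rtnorm_pos(x, st_l0);
      double delta = tn_lhr(x, y, st_l0);
      for (int s = 0; s < S; ++s)
        for (int g = 0; g < G; ++g) {
          Lprop(g, s) = nb_lp(C(g, s), N[s] * cg[g] * (y + M(g, s)),
                              l1p[g], lp[g], lgf(g, s));
          delta += Lprop(g, s) - L(g, s);
        }
      wp_l0 += 1; tp_l0 += 1;
      if (!R_IsNaN(delta) && std::log(unif_rand()) < delta) {
        wa_l0 += 1; ta_l0 += 1;
        lambda0 = y;
        std::copy(Lprop.begin(), Lprop.end(), L.begin());
      }
    }

    // --- Lambda: MH per marker entry (B == 1 only) -----------------------
    if (!fix_lambda) {
      for (int t = 0; t < T; ++t)
        for (int g = 0; g < G; ++g) {
          if (B(g, t) != 1.0) continue;
          double x = Lambda(g, t);
          double y = rtnorm_pos(x, stlam[g]);
          double delta = tn_lhr(x, y, stlam[g]);
          for (int s = 0; s < S; ++s) {
            double m = M(g, s) + (y - x) * H(s, t);
            Mprop(g, s) = m;
            Lprop(g, s) = nb_lp(C(g, s), N[s] * cg[g] * (lambda0 + m),
                                l1p[g], lp[g], lgf(g, s));
            delta += Lprop(g, s) - L(g, s);
          }
          wp_lam[g] += 1; tp_lam += 1;
          if (R_IsNaN(delta)) continue;
          if (std::log(unif_rand()) < delta) {
            wa_lam[g] += 1; ta_lam += 1;
            Lambda(g, t) = y;
            W(g, t) = y;
            for (int s = 0; s < S; ++s) {
              M(g, s) = Mprop(g, s);
              L(g, s) = Lprop(g, s);
            }
          }
        }
    }

    // --- p: MH per gene; proposals >= 1 are rejected ----------------------
    for (int g = 0; g < G; ++g) {
      double x = p[g];
      double y = rtnorm_pos(x, st_p);
      wp_p += 1; tp_p += 1;
      if (y >= 1.0) continue; // outside the support
      double cgy = (1.0 - y) / y, l1py = std::log1p(-y),
             lpy = std::log(y);
      double delta = tn_lhr(x, y, st_p);
      for (int s = 0; s < S; ++s) {
        Lprop(g, s) = nb_lp(C(g, s), N[s] * cgy * (lambda0 + M(g, s)),
                            l1py, lpy, lgf(g, s));
        delta += Lprop(g, s) - L(g, s);
      }
      if (R_IsNaN(delta)) continue;
      if (std::log(unif_rand()) < delta) {
        wa_p += 1; ta_p += 1;
        p[g] = y;
        cg[g] = cgy; lp[g] = lpy; l1p[g] = l1py;
        for (int s = 0; s < S; ++s) L(g, s) = Lprop(g, s);
      }
    }

    // --- adaptation (burn-in only) ----------------------------------------
    if (adapt_interval > 0 && iter < burn_in &&
        (iter + 1) % adapt_interval == 0) {
      if (wp_th > 0)
        st_theta *= (wa_th / wp_th < target_acc) ? (1.0 - adapt_eps)
                                                 : (1.0 + adapt_eps);
      if (wp_l0 > 0)
        st_l0 *= (wa_l0 / wp_l0 < target_acc) ? (1.0 - adapt_eps)
                                              : (1.0 + adapt_eps);
      if (wp_p > 0)
        st_p *= (wa_p / wp_p < target_acc) ? (1.0 - adapt_eps)
                                           : (1.0 + adapt_eps);
      for (int g = 0; g < G; ++g)
        if (wp_lam[g] > 0)
          stlam[g] *= (wa_lam[g] / wp_lam[g] < target_acc)
                          ? (1.0 - adapt_eps)
                          : (1.0 + adapt_eps);
      wa_th = wp_th = wa_l0 = wp_l0 = wa_p = wp_p = wa_n = wp_n = 0;
      std::fill(wa_lam.begin(), wa_lam.end(), 0.0);
      std::fill(wp_lam.begin(), wp_lam.end(), 0.0);
    }

    // --- record ------------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in + 1) % thinning == 0 &&
        d < n_ret) {
      double ll = 0.0;
      for (int s = 0; s < S; ++s)
        for (int g = 0; g < G; ++g) ll += L(g, s);
      if (!R_finite(ll))
        stop("non-finite log-likelihood at iteration %d", iter + 1);
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < S; ++s)
          H_draws[d + (R_xlen_t)n_ret * (s + (R_xlen_t)S * t)] = H(s, t);
      for (int t = 0; t < T; ++t)
        for (int g = 0; g < G; ++g)
          lam_draws[d + (R_xlen_t)n_ret * (g + (R_xlen_t)G * t)] =
              Lambda(g, t);
      for (int s = 0; s < S; ++s) N_draws(d, s) = N[s];
      for (int g = 0; g < G; ++g) p_draws(d, g) = p[g];
      l0_draws[d] = lambda0;
      ll_draws[d] = ll;
      ++d;
    }

    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  H_draws.attr("dim") = IntegerVector::create(n_ret, S, T);
  lam_draws.attr("dim") = IntegerVector::create(n_ret, G, T);

  List acc = List::create(
      _["theta"] = tp_th > 0 ? ta_th / tp_th : NA_REAL,
      _["n_cells"] = tp_n > 0 ? ta_n / tp_n : NA_REAL,
      _["lambda0"] = tp_l0 > 0 ? ta_l0 / tp_l0 : NA_REAL,
      _["Lambda"] = tp_lam > 0 ? ta_lam / tp_lam : NA_REAL,
      _["p"] = tp_p > 0 ? ta_p / tp_p : NA_REAL);
  List steps = List::create(_["theta"] = st_theta, _["n_cells"] = st_n,
                            _["lambda0"] = st_l0, _["p"] = st_p,
                            _["Lambda"] = stlam);
  List state = List::create(_["theta"] = theta, _["H"] = H, _["Z"] = Z,
                            _["pi"] = pi, _["n_cells"] = N,
                            _["lambda0"] = lambda0, _["Lambda"] = Lambda,
                            _["p"] = p);
  return List::create(_["H"] = H_draws, _["lambda0"] = l0_draws,
                      _["n_cells"] = N_draws, _["p"] = p_draws,
                      _["Lambda"] = lam_draws, _["loglik"] = ll_draws,
                      _["acceptance"] = acc, _["step_sizes"] = steps,
                      _["final_state"] = state, _["n_retained"] = n_ret);
}
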