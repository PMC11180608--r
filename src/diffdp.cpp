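// Differentiable Needleman-Wunsch kernel.
//
// Conventions shared with the R wrappers:
//  * mu, gap are p x q (1-based in the maths, 0-based here).
//  * The value matrix is (p+1) x (q+1); row/column 0 hold the border
//    initialisation. border = 0 reproduces the printed initialisation
//    (v[0,0] = 1, other borders 0); border = 1 is the path-strict variant
//    (v[0,0] = 0, other borders -Inf) under which v[p,q] is the
//    temperature-scaled log-sum-exp over all monotone paths from (0,0).
//  * weights is p x q x 3 in channel order (m, x, y).
//  * mu_on_gaps = true adds mu[i,j] to the insert/delete branches exactly as
//    the recursion is printed; false is the textbook variant.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// smoothed max over three branches; returns value, fills w[3] with softmax
static inline double smooth_max3(const double s[3], double tau, double w[3]) {
  double m = s[0];
  if (s[1] > m) m = s[1];
  if (s[2] > m) m = s[2];
  if (m == NEG_INF) {
    w[0] = w[1] = w[2] = 0.0;
    return NEG_INF;
  }
  double z = 0.0, e[3];
  for (int k = 0; k < 3; ++k) {
    e[k] = (s[k] == NEG_INF) ? 0.0 : std::exp((s[k] - m) / tau);
    z += e[k];
  }
  for (int k = 0; k < 3; ++k) w[k] = e[k] / z;
  return m + tau * std::log(z);
}

static inline void branch_scores(const NumericMatrix& mu,
                                 const NumericMatrix& gap,
                                 const NumericMatrix& value,
                                 int i, int j, bool mu_on_gaps, double s[3]) {
  // i, j are 1-based cell indices; value is (p+1) x (q+1)
  double m = mu(i - 1, j - 1), g = gap(i - 1, j - 1);
  s[0] = m + value(i - 1, j - 1);
  s[1] = (mu_on_gaps ? m : 0.0) + g + value(i - 1, j);
  s[2] = (mu_on_gaps ? m : 0.0) + g + value(i, j - 1);
}

// [[Rcpp::export]]
List cpp_nw_forward(NumericMatrix mu, NumericMatrix gap, double temperature,
                    int border, bool mu_on_gaps) {
  int p = mu.nrow(), q = mu.ncol();
  NumericMatrix value(p + 1, q + 1);
  NumericVector weights(Dimension(p, q, 3));
  if (border == 0) {
    std::fill(value.begin(), value.end(), 0.0);
    value(0, 0) = 1.0;
  } else {
    std::fill(value.begin(), value.end(), NEG_INF);
    value(0, 0) = 0.0;
  }
  double s[3], w[3];
  for (int i = 1; i <= p; ++i) {
    for (int j = 1; j <= q; ++j) {
      branch_scores(mu, gap, value, i, j, mu_on_gaps, s);
      value(i, j) = smooth_max3(s, temperature, w);
      for (int k = 0; k < 3; ++k)
        weights[(i - 1) + p * (j - 1) + p * q * k] = w[k];
    }
  }
  return List::create(_["value"] = value, _["weights"] = weights);
}

static inline double wgt(const NumericVector& W, int p, int q,
                         int i, int j, int k) {
  // 1-based (i, j) on the padded (p+1) x (q+1) grid of the backward pass:
  // interior weights come from the forward pass; the virtual terminal cell
  // (p+1, q+1) enters diagonally with weight 1, all other pads are 0.
  if (i == p + 1 && j == q + 1) return (k == 0) ? 1.0 : 0.0;
  if (i < 1 || j < 1 || i > p || j > q) return 0.0;
  return W[(i - 1) + p * (j - 1) + p * q * k];
}

// [[Rcpp::export]]
NumericMatrix cpp_nw_expected(NumericVector weights, int p, int q) {
  // e on a padded (p+2) x (q+2) grid, 0-based storage index = math index
  NumericMatrix e(p + 2, q + 2);
  e(p + 1, q + 1) = 1.0;
  for (int i = p; i >= 1; --i) {
    for (int j = q; j >= 1; --j) {
      e(i, j) = wgt(weights, p, q, i + 1, j + 1, 0) * e(i + 1, j + 1) +
                wgt(weights, p, q, i + 1, j, 1) * e(i + 1, j) +
                wgt(weights, p, q, i, j + 1, 2) * e(i, j + 1);
    }
  }
  NumericMatrix out(p, q);
  for (int i = 1; i <= p; ++i)
    for (int j = 1; j <= q; ++j) out(i - 1, j - 1) = e(i, j);
  return out;
}

// Reverse-mode adjoint of (mu, gap) -> (e, v[p,q]); ebar is dL/de (p x q),
// vbar the scalar dL/dv[p,q]. Returns dL/dmu and dL/dgap.
// [[Rcpp::export]]
List cpp_nw_adjoint(NumericMatrix mu, NumericMatrix gap, NumericMatrix value,
                    NumericVector weights, NumericMatrix e,
                    NumericMatrix ebar, double vbar, double temperature,
                    bool mu_on_gaps) {
  int p = mu.nrow(), q = mu.ncol();
  // Stage-2 adjoint: etil[a,b] = ebar[a,b]
  //   + w^m[a,b] etil[a-1,b-1] + w^x[a,b] etil[a-1,b] + w^y[a,b] etil[a,b-1]
  // computed in increasing (a,b); out-of-range etil = 0.
  NumericMatrix etil(p + 1, q + 1); // index 0 row/col are the zero pads
  for (int a = 1; a <= p; ++a) {
    for (int b = 1; b <= q; ++b) {
      etil(a, b) = ebar(a - 1, b - 1) +
        wgt(weights, p, q, a, b, 0) * etil(a - 1, b - 1) +
        wgt(weights, p, q, a, b, 1) * etil(a - 1, b) +
        wgt(weights, p, q, a, b, 2) * etil(a, b - 1);
    }
  }
  // omega adjoints: w^m[a,b] multiplies e[a,b] into e[a-1,b-1], etc.
  // sbar[i,j,k]: adjoint of the branch scores feeding cell (i,j).
  NumericVector sbar(Dimension(p + 2, q + 2, 3)); // padded, zero-initialised
  NumericMatrix dmu(p, q), dgap(p, q);
  for (int i = p; i >= 1; --i) {
    for (int j = q; j >= 1; --j) {
      double wm = wgt(weights, p, q, i, j, 0);
      double wx = wgt(weights, p, q, i, j, 1);
      double wy = wgt(weights, p, q, i, j, 2);
      double om[3] = {wm, wx, wy};
      double obar[3];
      double eij = e(i - 1, j - 1);
      obar[0] = (i > 1 && j > 1) ? eij * etil(i - 1, j - 1) : 0.0;
      obar[1] = (i > 1) ? eij * etil(i - 1, j) : 0.0;
      obar[2] = (j > 1) ? eij * etil(i, j - 1) : 0.0;
      // vbar_ij accumulates from the three consumers of v[i,j] plus the
      // terminal output
      double vb = sbar[i + 1 + (p + 2) * (j + 1) + (p + 2) * (q + 2) * 0] +
                  sbar[i + 1 + (p + 2) * j + (p + 2) * (q + 2) * 1] +
                  sbar[i + (p + 2) * (j + 1) + (p + 2) * (q + 2) * 2];
      if (i == p && j == q) vb += vbar;
      // sbar = omega * vb + (1/tau) * (diag(om) - om om^T) obar
      double dot = om[0] * obar[0] + om[1] * obar[1] + om[2] * obar[2];
      double sb[3];
      for (int k = 0; k < 3; ++k)
        sb[k] = om[k] * vb + (om[k] * obar[k] - om[k] * dot) / temperature;
      for (int k = 0; k < 3; ++k)
        sbar[i + (p + 2) * j + (p + 2) * (q + 2) * k] = sb[k];
      if (mu_on_gaps)
        dmu(i - 1, j - 1) = sb[0] + sb[1] + sb[2];
      else
        dmu(i - 1, j - 1) = sb[0];
      dgap(i - 1, j - 1) = sb[1] + sb[2];
    }
  }
  return List::create(_["dmu"] = dmu, _["dgap"] = dgap);
}

// Directional derivative (forward-over-reverse): given a perturbation
// Z = [zmu, zgap], compute vdot = <grad v, Z> and edot = (Hessian of v) Z
// restricted to the mu block, exactly the two returns of the published
// second-order recursion (with the omega-dot line in its calculus-derived
// form: J_Omega annihilates the common z_mu term).
// [[Rcpp::export]]
List cpp_nw_directional(NumericMatrix mu, NumericMatrix gap,
                        NumericMatrix zmu, NumericMatrix zgap,
                        NumericMatrix value, NumericVector weights,
                        NumericMatrix e, double temperature,
                        bool mu_on_gaps) {
  int p = mu.nrow(), q = mu.ncol();
  NumericMatrix vdot(p + 1, q + 1); // border perturbations are 0
  NumericVector wdot(Dimension(p, q, 3));
  for (int i = 1; i <= p; ++i) {
    for (int j = 1; j <= q; ++j) {
      double zm = zmu(i - 1, j - 1), zg = zgap(i - 1, j - 1);
      double om[3], sdot[3];
      for (int k = 0; k < 3; ++k)
        om[k] = weights[(i - 1) + p * (j - 1) + p * q * k];
      sdot[0] = zm + (om[0] > 0 ? vdot(i - 1, j - 1) : 0.0);
      sdot[1] = (mu_on_gaps ? zm : 0.0) + zg +
                (om[1] > 0 ? vdot(i - 1, j) : 0.0);
      sdot[2] = (mu_on_gaps ? zm : 0.0) + zg +
                (om[2] > 0 ? vdot(i, j - 1) : 0.0);
      double vd = om[0] * sdot[0] + om[1] * sdot[1] + om[2] * sdot[2];
      vdot(i, j) = vd;
      for (int k = 0; k < 3; ++k)
        wdot[(i - 1) + p * (j - 1) + p * q * k] =
          om[k] * (sdot[k] - vd) / temperature;
    }
  }
  // backward: edot via product rule on the e recursion; pads are constant
  NumericMatrix ed(p + 2, q + 2);
  NumericMatrix epad(p + 2, q + 2);
  epad(p + 1, q + 1) = 1.0;
  for (int i = p; i >= 1; --i)
    for (int j = q; j >= 1; --j) epad(i, j) = e(i - 1, j - 1);
  for (int i = p; i >= 1; --i) {
    for (int j = q; j >= 1; --j) {
      double acc = 0.0;
      // (i+1, j+1) m-channel
      if (i + 1 <= p && j + 1 <= q)
        acc += wdot[i + p * j + p * q * 0] * epad(i + 1, j + 1);
      acc += wgt(weights, p, q, i + 1, j + 1, 0) * ed(i + 1, j + 1);
      // (i+1, j) x-channel
      if (i + 1 <= p)
        acc += wdot[i + p * (j - 1) + p * q * 1] * epad(i + 1, j);
      acc += wgt(weights, p, q, i + 1, j, 1) * ed(i + 1, j);
      // (i, j+1) y-channel
      if (j + 1 <= q)
        acc += wdot[(i - 1) + p * j + p * q * 2] * epad(i, j + 1);
      acc += wgt(weights, p, q, i, j + 1, 2) * ed(i, j + 1);
      ed(i, j) = acc;
    }
  }
  NumericMatrix edot(p, q);
  for (int i = 1; i <= p; ++i)
    for (int j = 1; j <= q; ++j) edot(i - 1, j - 1) = ed(i, j);
  return List::create(_["vdot"] = vdot(p, q), _["edot"] = edot);
}

// Classical hard NW under path-strict borders with deterministic
// tie-breaking match > insert(X) > delete(Y).
// [[Rcpp::export]]
List cpp_nw_hard(NumericMatrix mu, NumericMatrix gap, bool mu_on_gaps) {
  int p = mu.nrow(), q = mu.ncol();
  NumericMatrix value(p + 1, q + 1);
  IntegerMatrix ptr(p + 1, q + 1);
  std::fill(value.begin(), value.end(), NEG_INF);
  value(0, 0) = 0.0;
  double s[3];
  for (int i = 1; i <= p; ++i) {
    for (int j = 1; j <= q; ++j) {
      branch_scores(mu, gap, value, i, j, mu_on_gaps, s);
      int best = 0;
      if (s[1] > s[best]) best = 1;
      if (s[2] > s[best]) best = 2;
      value(i, j) = s[best];
      ptr(i, j) = best;
    }
  }
  std::string states;
  std::vector<int> ei, ej;
  int i = p, j = q;
  while (i > 0 || j > 0) {
    int b = ptr(i, j);
    if (i == 0) b = 2;
    else if (j == 0) b = 1;
    if (b == 0) {
      states.push_back('M');
      ei.push_back(i); ej.push_back(j);
      --i; --j;
    } else if (b == 1) {
      states.push_back('X');
      --i;
    } else {
      states.push_back('Y');
      --j;
    }
  }
  std::reverse(states.begin(), states.end());
  std::reverse(ei.begin(), ei.end());
  std::reverse(ej.begin(), ej.end());
  return List::create(_["score"] = value(p, q), _["states"] = states,
                      _["edges_i"] = wrap(ei), _["edges_j"] = wrap(ej));
}
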