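// Metropolis-Hastings within Gibbs for the geoadditive bivariate probit.
// Each coefficient block (linear / P-spline / GMRF-spatial, attached to one
// of the three distribution parameters mu1, mu2, rho) is updated with an
// IWLS Gaussian proposal: precision Z'WZ + K/tau^2, mean the weighted
// least-squares solve of the working response built from the score and
// expected Fisher information of the exact bivariate probit likelihood.
// Smoothing variances get conjugate inverse-gamma draws.  All randomness
// goes through R's RNG so chains are reproducible from set.seed().
//
// The per-record state cache stores the four cell probabilities (and their
// floored reciprocals), the univariate marginals, and the score ingredient
// of the parameter being updated; when one predictor changes, the other
// parameters' marginals are copied rather than recomputed, and the
// bivariate CDF reuses the cached normal tails.
#include <RcppArmadillo.h>
#include "bvn.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double RIDGE = 1e-8;   // proposal-precision ridge (valid MH: the same
                             // density is used for drawing and the ratio)
const double PFLOOR = 1e-12; // cell floor inside scores and weights
const double WMAX = 1e7;

struct Cache {
  arma::vec p11, i11, i10, i01, i00; // cells: p11 and floored reciprocals
  arma::vec ph1, ph2, d1, d2, r;
  arma::vec g[3];   // score ingredient per parameter (g1, g2, bvn density)
  bool gok[3] = {false, false, false};
  double ll = 0.0;
  void resize(int n) {
    p11.set_size(n); i11.set_size(n); i10.set_size(n); i01.set_size(n);
    i00.set_size(n);
    ph1.set_size(n); ph2.set_size(n); d1.set_size(n); d2.set_size(n);
    r.set_size(n);
    for (int k = 0; k < 3; k++) g[k].set_size(n);
  }
  void swap_with(Cache& o) {
    p11.swap(o.p11); i11.swap(o.i11); i10.swap(o.i10); i01.swap(o.i01);
    i00.swap(o.i00);
    ph1.swap(o.ph1); ph2.swap(o.ph2); d1.swap(o.d1); d2.swap(o.d2);
    r.swap(o.r);
    for (int k = 0; k < 3; k++) { g[k].swap(o.g[k]); std::swap(gok[k], o.gok[k]); }
    std::swap(ll, o.ll);
  }
};

struct Block {
  int param;   // 0 = mu1, 1 = mu2, 2 = rho
  int type;    // 0 = linear, 1 = spline, 2 = spatial
  int d;
  arma::mat Z;       // linear
  arma::mat Bx;      // spline basis values, n x (degree+1)
  arma::ivec Bi;     // spline first-column index per row (0-based)
  arma::ivec ri;     // spatial region index per row (0-based)
  arma::uvec freeix; // spatial: non-island coefficient indices
  arma::mat K;
  double Krank;
  bool penalized;
  bool center;
  double tau2;
  arma::vec beta;
  arma::vec etab;    // current contribution Z beta
  double accept = 0.0, tries = 0.0;
};

// Fill the per-record state cache.  changed in {-1, 0, 1, 2}: which
// predictor differs from `base` (-1 = compute everything fresh).  Also
// fills the score ingredient g[changed] (or g for all when fresh is cheap
// to skip: flags are reset instead).
void compute_cache(const arma::ivec& y1, const arma::ivec& y2,
                   const arma::vec& e1, const arma::vec& e2,
                   const arma::vec& er, Cache& c, int changed = -1,
                   const Cache* base = nullptr) {
  int n = e1.n_elem;
  bool fresh = (changed < 0 || base == nullptr);
  if (!fresh) {
    if (changed != 0) { c.ph1 = base->ph1; c.d1 = base->d1; }
    if (changed != 1) { c.ph2 = base->ph2; c.d2 = base->d2; }
    if (changed != 2) c.r = base->r;
  }
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    if (fresh || changed == 2) {
      double r = std::tanh(er[i]);
      if (r > 1.0 - 1e-10) r = 1.0 - 1e-10;
      if (r < -1.0 + 1e-10) r = -1.0 + 1e-10;
      c.r[i] = r;
    }
    if (fresh || changed == 0) {
      c.ph1[i] = R::pnorm(e1[i], 0.0, 1.0, 1, 0);
      c.d1[i] = R::dnorm(e1[i], 0.0, 1.0, 0);
    }
    if (fresh || changed == 1) {
      c.ph2[i] = R::pnorm(e2[i], 0.0, 1.0, 1, 0);
      c.d2[i] = R::dnorm(e2[i], 0.0, 1.0, 0);
    }
    double r = c.r[i], ph1 = c.ph1[i], ph2 = c.ph2[i];
    double p11 = gbp_bvnu_t(-e1[i], -e2[i], r, ph1, ph2);
    double p10 = ph1 - p11, p01 = ph2 - p11, p00 = 1.0 - ph1 - ph2 + p11;
    if (p11 < 0.0) p11 = 0.0;
    if (p10 < 0.0) p10 = 0.0;
    if (p01 < 0.0) p01 = 0.0;
    if (p00 < 0.0) p00 = 0.0;
    c.p11[i] = p11;
    c.i11[i] = 1.0 / std::max(p11, PFLOOR);
    c.i10[i] = 1.0 / std::max(p10, PFLOOR);
    c.i01[i] = 1.0 / std::max(p01, PFLOOR);
    c.i00[i] = 1.0 / std::max(p00, PFLOOR);
    double p;
    if (y1[i] == 1) p = (y2[i] == 1) ? p11 : p10;
    else            p = (y2[i] == 1) ? p01 : p00;
    if (p < 1e-300) p = 1e-300;
    ll += std::log(p);
  }
  c.ll = ll;
  c.gok[0] = c.gok[1] = c.gok[2] = false;
}

// Score ingredient of one parameter at the cached state:
// param 0: g = phi(m1) Phi((m2 - r m1) / s);  param 1: symmetric;
// param 2: bivariate normal density times (1 - r^2) (tanh chain rule).
void ensure_g(Cache& c, int param, const arma::vec& e1, const arma::vec& e2) {
  if (c.gok[param]) return;
  int n = e1.n_elem;
  arma::vec& g = c.g[param];
  if (param == 0) {
    for (int i = 0; i < n; i++) {
      double s = std::sqrt(1.0 - c.r[i] * c.r[i]);
      g[i] = c.d1[i] * R::pnorm((e2[i] - c.r[i] * e1[i]) / s, 0.0, 1.0, 1, 0);
    }
  } else if (param == 1) {
    for (int i = 0; i < n; i++) {
      double s = std::sqrt(1.0 - c.r[i] * c.r[i]);
      g[i] = c.d2[i] * R::pnorm((e1[i] - c.r[i] * e2[i]) / s, 0.0, 1.0, 1, 0);
    }
  } else {
    for (int i = 0; i < n; i++)
      g[i] = gbp_bvn_pdf(e1[i], e2[i], c.r[i]) * (1.0 - c.r[i] * c.r[i]);
  }
  c.gok[param] = true;
}

// Score u_i = d log p_i / d eta_k and expected information
// W_i = sum over the four cells of (d p_cell / d eta_k)^2 / p_cell.
void score_weights(int param, const arma::ivec& y1, const arma::ivec& y2,
                   const arma::vec& e1, const arma::vec& e2, Cache& c,
                   arma::vec& u, arma::vec& w) {
  int n = e1.n_elem;
  ensure_g(c, param, e1, e2);
  u.set_size(n); w.set_size(n);
  const arma::vec& g = c.g[param];
  for (int i = 0; i < n; i++) {
    double ui, wi;
    if (param == 2) {
      double h = g[i];
      double iobs, sign;
      if (y1[i] == 1) { iobs = (y2[i] == 1) ? c.i11[i] : c.i10[i];
                        sign = (y2[i] == 1) ? 1.0 : -1.0; }
      else            { iobs = (y2[i] == 1) ? c.i01[i] : c.i00[i];
                        sign = (y2[i] == 1) ? -1.0 : 1.0; }
      ui = sign * h * iobs;
      wi = h * h * (c.i11[i] + c.i10[i] + c.i01[i] + c.i00[i]);
    } else {
      // cell derivatives w.r.t. the mean m_k: the observed outcome's own
      // marginal splits between the two cells consistent with the other
      // outcome; dm is the full marginal density
      double gi = g[i];
      double dm = (param == 0) ? c.d1[i] : c.d2[i];
      double dobs, iobs;
      int yk = (param == 0) ? (int)y1[i] : (int)y2[i];
      int yo = (param == 0) ? (int)y2[i] : (int)y1[i];
      if (yk == 1) dobs = (yo == 1) ? gi : (dm - gi);
      else         dobs = (yo == 1) ? -gi : -(dm - gi);
      if (y1[i] == 1) iobs = (y2[i] == 1) ? c.i11[i] : c.i10[i];
      else            iobs = (y2[i] == 1) ? c.i01[i] : c.i00[i];
      ui = dobs * iobs;
      double icross = (param == 0) ? c.i01[i] : c.i10[i];
      double iown = (param == 0) ? c.i10[i] : c.i01[i];
      wi = gi * gi * (c.i11[i] + icross) +
           (dm - gi) * (dm - gi) * (iown + c.i00[i]);
    }
    if (!std::isfinite(ui)) ui = 0.0;
    if (!std::isfinite(wi) || wi < 0.0) wi = 0.0;
    if (wi > WMAX) wi = WMAX;
    u[i] = ui;
    w[i] = wi;
  }
}

arma::vec block_eta(const Block& b, const arma::vec& beta) {
  int n = (b.type == 0) ? b.Z.n_rows
          : (b.type == 1 ? b.Bx.n_rows : b.ri.n_elem);
  if (b.type == 0) return b.Z * beta;
  arma::vec out(n);
  if (b.type == 1) {
    int q = b.Bx.n_cols;
    for (int i = 0; i < n; i++) {
      double s = 0.0;
      for (int j = 0; j < q; j++) s += b.Bx(i, j) * beta[b.Bi[i] + j];
      out[i] = s;
    }
  } else {
    for (int i = 0; i < n; i++) out[i] = beta[b.ri[i]];
  }
  return out;
}

// P = Z' diag(w) Z  (+ prior precision added by caller),  bvec = Z' v.
void xtwx(const Block& b, const arma::vec& w, const arma::vec& v,
          arma::mat& P, arma::vec& bvec) {
  int n = w.n_elem;
  if (b.type == 0) {
    P = b.Z.t() * (b.Z.each_col() % w);
    bvec = b.Z.t() * v;
    return;
  }
  P.zeros(b.d, b.d);
  bvec.zeros(b.d);
  if (b.type == 1) {
    int q = b.Bx.n_cols;
    for (int i = 0; i < n; i++) {
      int off = b.Bi[i];
      for (int j = 0; j < q; j++) {
        double zj = b.Bx(i, j);
        bvec[off + j] += zj * v[i];
        double wz = w[i] * zj;
        for (int l = 0; l < q; l++) P(off + j, off + l) += wz * b.Bx(i, l);
      }
    }
  } else {
    for (int i = 0; i < n; i++) {
      int s = b.ri[i];
      P(s, s) += w[i];
      bvec[s] += v[i];
    }
  }
}

struct Proposal {
  arma::vec mean;
  arma::mat R;       // upper Cholesky of the precision
  double logdethalf; // sum log diag(R)
  bool ok;
};

Proposal build_proposal(const Block& b, const arma::vec& u, const arma::vec& w,
                        double tau2) {
  Proposal pr;
  arma::mat P;
  arma::vec bvec;
  arma::vec v = w % b.etab + u;
  xtwx(b, w, v, P, bvec);
  if (b.penalized) P += b.K / tau2;
  P.diag() += RIDGE;
  pr.ok = arma::chol(pr.R, P);
  if (!pr.ok) return pr;
  arma::vec tmp = arma::solve(arma::trimatl(pr.R.t()), bvec);
  pr.mean = arma::solve(arma::trimatu(pr.R), tmp);
  pr.logdethalf = arma::accu(arma::log(pr.R.diag()));
  return pr;
}

double prop_logdens(const Proposal& pr, const arma::vec& x) {
  arma::vec v = pr.R * (x - pr.mean);
  return pr.logdethalf - 0.5 * arma::dot(v, v);
}

double log_prior(const Block& b, const arma::vec& beta, double tau2) {
  if (!b.penalized) return 0.0;
  return -0.5 * arma::dot(beta, b.K * beta) / tau2;
}

Block build_block(const List& bl) {
  Block b;
  b.param = as<int>(bl["param"]);
  b.type = as<int>(bl["type"]);
  b.d = as<int>(bl["d"]);
  b.penalized = as<bool>(bl["penalized"]);
  b.center = bl.containsElementNamed("center") ? as<bool>(bl["center"]) : b.penalized;
  b.tau2 = bl.containsElementNamed("tau2") ? as<double>(bl["tau2"]) : 0.1;
  if (b.type == 0) {
    b.Z = as<arma::mat>(bl["Z"]);
  } else if (b.type == 1) {
    b.Bx = as<arma::mat>(bl["Bx"]);
    b.Bi = as<arma::ivec>(bl["Bi"]);
  } else {
    b.ri = as<arma::ivec>(bl["ri"]);
    b.freeix = as<arma::uvec>(bl["free"]);
  }
  if (b.penalized) {
    b.K = as<arma::mat>(bl["K"]);
    b.Krank = as<double>(bl["rank"]);
  } else {
    b.Krank = 0.0;
  }
  if (bl.containsElementNamed("beta0")) {
    b.beta = as<arma::vec>(bl["beta0"]);
  } else {
    b.beta.zeros(b.d);
  }
  b.etab = block_eta(b, b.beta);
  return b;
}

// One MH-IWLS update of block b.  etas/cache describe the full current
// state and are overwritten on acceptance.  Returns true if accepted.
bool mh_update(Block& b, const arma::ivec& y1, const arma::ivec& y2,
               arma::vec etas[3], Cache& cache, Cache& scratch) {
  b.tries += 1.0;
  arma::vec u, w;
  score_weights(b.param, y1, y2, etas[0], etas[1], cache, u, w);
  Proposal fwd = build_proposal(b, u, w, b.tau2);
  if (!fwd.ok) return false;
  int d = b.d;
  arma::vec z(d);
  for (int j = 0; j < d; j++) z[j] = norm_rand();
  arma::vec beta_p = fwd.mean + arma::solve(arma::trimatu(fwd.R), z);
  if (b.type == 2 && b.freeix.n_elem < (unsigned)d) {
    // islands keep a fixed zero effect
    arma::vec bp2 = arma::zeros(d);
    bp2.elem(b.freeix) = beta_p.elem(b.freeix);
    beta_p = bp2;
  }
  double lq_fwd = prop_logdens(fwd, beta_p);
  arma::vec etab_p = block_eta(b, beta_p);
  arma::vec eta_prop = etas[b.param] - b.etab + etab_p;

  // proposed-state quantities (also give the reverse proposal)
  const arma::vec& e1p = (b.param == 0) ? eta_prop : etas[0];
  const arma::vec& e2p = (b.param == 1) ? eta_prop : etas[1];
  const arma::vec& erp = (b.param == 2) ? eta_prop : etas[2];
  compute_cache(y1, y2, e1p, e2p, erp, scratch, b.param, &cache);
  arma::vec up, wp;
  score_weights(b.param, y1, y2, e1p, e2p, scratch, up, wp);
  arma::vec etab_save = b.etab;
  b.etab = etab_p; // build_proposal reads b.etab
  Proposal rev = build_proposal(b, up, wp, b.tau2);
  b.etab = etab_save;
  if (!rev.ok) return false;
  double lq_rev = prop_logdens(rev, b.beta);

  double la = (scratch.ll + log_prior(b, beta_p, b.tau2) + lq_rev) -
              (cache.ll + log_prior(b, b.beta, b.tau2) + lq_fwd);
  if (std::log(unif_rand()) < la) {
    b.beta = beta_p;
    b.etab = etab_p;
    etas[b.param] = eta_prop;
    cache.swap_with(scratch);
    b.accept += 1.0;
    return true;
  }
  return false;
}

// Move the flat (constant) direction of a penalized block into the
// parameter's intercept; leaves every eta and the penalty value unchanged.
void recenter(Block& b, Block& intercept_block) {
  double c;
  if (b.type == 2) {
    if (b.freeix.n_elem < (unsigned)b.d) return; // islands: keep as is
    c = arma::mean(b.beta);
  } else {
    c = arma::mean(b.etab);
  }
  b.beta -= c;
  b.etab -= c;
  intercept_block.beta[0] += c;
  intercept_block.etab += c;
}

} // namespace

// [[Rcpp::export]]
List C_run_chain(IntegerVector y1_, IntegerVector y2_, List blocks_in,
                 List cfg) {
  arma::ivec y1 = as<arma::ivec>(y1_), y2 = as<arma::ivec>(y2_);
  int n = y1.n_elem;
  int iters = as<int>(cfg["iterations"]);
  int burnin = as<int>(cfg["burnin"]);
  int thin = as<int>(cfg["thin"]);
  double ig_a = as<double>(cfg["ig_a"]);
  double ig_b = as<double>(cfg["ig_b"]);

  int nb = blocks_in.size();
  std::vector<Block> blocks(nb);
  for (int j = 0; j < nb; j++) blocks[j] = build_block(blocks_in[j]);

  // intercept (first linear) block per parameter, for recentring
  int icp[3] = {-1, -1, -1};
  for (int j = 0; j < nb; j++)
    if (blocks[j].type == 0 && icp[blocks[j].param] < 0) icp[blocks[j].param] = j;

  arma::vec etas[3];
  for (int k = 0; k < 3; k++) etas[k].zeros(n);
  for (int j = 0; j < nb; j++) etas[blocks[j].param] += blocks[j].etab;

  Cache cache, scratch;
  cache.resize(n); scratch.resize(n);
  compute_cache(y1, y2, etas[0], etas[1], etas[2], cache);
  if (!std::isfinite(cache.ll))
    stop("non-finite log-likelihood at the initial state");

  int nkeep = (iters - burnin) / thin;
  std::vector<arma::mat> draws(nb);
  int npen = 0;
  for (int j = 0; j < nb; j++) {
    draws[j].set_size(nkeep, blocks[j].d);
    if (blocks[j].penalized) npen++;
  }
  arma::mat tau2_draws(nkeep, npen);
  arma::vec ll_trace(nkeep);

  // sweep order: mu1 blocks, mu2 blocks, rho blocks, then variances
  std::vector<int> order;
  for (int k = 0; k < 3; k++)
    for (int j = 0; j < nb; j++)
      if (blocks[j].param == k) order.push_back(j);

  int kept = 0;
  for (int it = 0; it < iters; it++) {
    for (int oj : order) {
      Block& b = blocks[oj];
      bool acc = mh_update(b, y1, y2, etas, cache, scratch);
      if (acc && b.center && icp[b.param] >= 0 && oj != icp[b.param])
        recenter(b, blocks[icp[b.param]]);
    }
    for (int j = 0; j < nb; j++) {
      Block& b = blocks[j];
      if (!b.penalized) continue;
      double quad = arma::dot(b.beta, b.K * b.beta);
      if (quad < -1e-8) stop("negative penalty quadratic form");
      if (quad < 0.0) quad = 0.0;
      double shape = ig_a + 0.5 * b.Krank;
      double rate = ig_b + 0.5 * quad;
      b.tau2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }
    if (!std::isfinite(cache.ll))
      stop("non-finite log-likelihood after sweep %d", it + 1);
    if (it >= burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      for (int j = 0; j < nb; j++)
        draws[j].row(kept) = blocks[j].beta.t();
      int pj = 0;
      for (int j = 0; j < nb; j++)
        if (blocks[j].penalized) tau2_draws(kept, pj++) = blocks[j].tau2;
      ll_trace[kept] = cache.ll;
      kept++;
    }
  }

  List dr(nb);
  NumericVector arate(nb);
  for (int j = 0; j < nb; j++) {
    dr[j] = wrap(draws[j]);
    arate[j] = blocks[j].tries > 0 ? blocks[j].accept / blocks[j].tries : NA_REAL;
  }
  return List::create(_["draws"] = dr, _["tau2"] = wrap(tau2_draws),
                      _["loglik"] = wrap(ll_trace), _["accept_rate"] = arate,
                      _["kept"] = kept);
}

// Single MH-IWLS block update against a fixed state of the other blocks.
// eta_rest is the predictor of the block's parameter *excluding* the block;
// the other two predictors are passed complete.  flat = TRUE replaces the
// likelihood by a constant (zero score and information), so the draw
// targets the block's Gaussian prior conditional.
// [[Rcpp::export]]
List C_update_block(IntegerVector y1_, IntegerVector y2_, List block_in,
                    NumericVector eta1, NumericVector eta2,
                    NumericVector etarho, NumericVector eta_rest, bool flat) {
  arma::ivec y1 = as<arma::ivec>(y1_), y2 = as<arma::ivec>(y2_);
  int n = y1.n_elem;
  Block b = build_block(block_in);
  arma::vec etas[3];
  etas[0] = as<arma::vec>(eta1);
  etas[1] = as<arma::vec>(eta2);
  etas[2] = as<arma::vec>(etarho);
  arma::vec er = as<arma::vec>(eta_rest);
  etas[b.param] = er + b.etab;

  bool accepted;
  if (flat) {
    b.tries += 1.0;
    arma::vec u = arma::zeros(n), w = arma::zeros(n);
    Proposal fwd = build_proposal(b, u, w, b.tau2);
    if (!fwd.ok) {
      accepted = false;
    } else {
      arma::vec z(b.d);
      for (int j = 0; j < b.d; j++) z[j] = norm_rand();
      arma::vec beta_p = fwd.mean + arma::solve(arma::trimatu(fwd.R), z);
      double lq_fwd = prop_logdens(fwd, beta_p);
      double lq_rev = prop_logdens(fwd, b.beta); // same state: flat likelihood
      double la = (log_prior(b, beta_p, b.tau2) + lq_rev) -
                  (log_prior(b, b.beta, b.tau2) + lq_fwd);
      accepted = std::log(unif_rand()) < la;
      if (accepted) {
        b.beta = beta_p;
        b.accept += 1.0;
      }
    }
  } else {
    Cache cache, scratch;
    cache.resize(n); scratch.resize(n);
    compute_cache(y1, y2, etas[0], etas[1], etas[2], cache);
    accepted = mh_update(b, y1, y2, etas, cache, scratch);
  }
  return List::create(_["beta"] = wrap(b.beta), _["accepted"] = accepted);
}
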