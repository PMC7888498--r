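#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// All randomness goes through R's RNG so runs are reproducible with
// set.seed() on the R side.

static arma::vec rnorm_vec(int k) {
  arma::vec z(k);
  for (int i = 0; i < k; ++i) z[i] = norm_rand();
  return z;
}

// One-sided truncated normal draws, numerically safe in the far tail.
// Draw from N(mu, sd^2) restricted to (0, inf).
static double rtnorm_pos(double mu, double sd) {
  const double a = -mu / sd;  // standardized lower bound
  double z;
  if (a < 0.45) {
    // plenty of mass above the bound: plain rejection
    do { z = norm_rand(); } while (z <= a);
  } else if (a < 5.0) {
    // inverse CDF through the upper tail (precise for moderate a)
    const double pa = R::pnorm(a, 0.0, 1.0, 0, 0);  // P(Z > a)
    z = R::qnorm(unif_rand() * pa, 0.0, 1.0, 0, 0);
    if (z <= a) z = a + 1e-12;
  } else {
    // Robert (1995) exponential rejection for extreme bounds
    const double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      z = a + exp_rand() / lam;
      const double u = unif_rand();
      const double rho = std::exp(-0.5 * (z - lam) * (z - lam));
      if (u <= rho) break;
    }
  }
  return mu + sd * z;
}

// Draw from N(mu, sd^2) restricted to (-inf, 0].
static double rtnorm_neg(double mu, double sd) {
  return -rtnorm_pos(-mu, sd);
}

// [[Rcpp::export]]
double rtnorm_one(double mu, double sd, bool positive) {
  return positive ? rtnorm_pos(mu, sd) : rtnorm_neg(mu, sd);
}

static arma::mat sympd(const arma::mat& M) { return 0.5 * (M + M.t()); }

// Inverse-Wishart draw, convention: W ~ IW(S, nu) iff W^{-1} ~ Wishart(S^{-1}, nu),
// density |W|^{-(nu+p+1)/2} exp(-tr(S W^{-1})/2), mean S/(nu-p-1).
static arma::mat riwish(double nu, const arma::mat& S) {
  const int p = S.n_rows;
  if (nu < p) stop("inverse-Wishart degrees of freedom below dimension");
  arma::mat Sinv = arma::inv_sympd(sympd(S));
  arma::mat L = arma::chol(sympd(Sinv), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat Wish = LA * LA.t();
  return arma::inv_sympd(sympd(Wish));
}

// [[Rcpp::export]]
arma::mat riwish_cpp(double nu, const arma::mat& S) { return riwish(nu, S); }

// Residual covariance draw with one diagonal element pinned to 1
// (threshold-trait identifiability constraint). Uses the conditional
// inverse-Wishart decomposition: with the pinned trait as block 1,
// the scalar W11 is independent of (B, W22.1), so conditioning on
// W11 = 1 leaves the conditional block W22.1 ~ IW(S22.1, nu) and the
// regression vector B | W22.1 ~ N(S12/S11, W22.1/S11) unchanged;
// reconstruct W12 = B, W22 = W22.1 + B B'.
static arma::mat riwish_pinned(double nu, const arma::mat& S, int b) {
  const int p = S.n_rows;
  arma::uvec oth(p - 1);
  for (int t = 0, k = 0; t < p; ++t) if (t != b) oth[k++] = t;
  arma::mat R(p, p, arma::fill::zeros);
  R(b, b) = 1.0;
  if (p == 1) return R;
  const double S11 = S(b, b);
  arma::vec s12 = S.col(b);
  s12 = s12.elem(oth);
  arma::mat S221 = S.submat(oth, oth) - s12 * s12.t() / S11;
  arma::mat W221 = riwish(nu, sympd(S221));
  arma::mat Lc = arma::chol(sympd(W221 / S11), "lower");
  arma::vec bvec = s12 / S11 + Lc * rnorm_vec(p - 1);
  R.submat(oth, oth) = W221 + bvec * bvec.t();
  for (int k = 0; k < p - 1; ++k) {
    R(b, oth[k]) = bvec[k];
    R(oth[k], b) = bvec[k];
  }
  return R;
}

// [[Rcpp::export]]
arma::mat riwish_pinned_cpp(double nu, const arma::mat& S, int b) {
  return riwish_pinned(nu, S, b - 1);
}

// Gibbs sampler for the multiple-trait linear-threshold animal model
//   y = Xb + Za + e,  a ~ N(0, A x G),  e ~ N(0, I x R),
// with at most one binary trait whose residual variance is pinned to 1
// and threshold at 0 (liability augmentation). Missing cells are
// handled by data augmentation so every conditional uses complete
// records. Update order per cycle:
//   liabilities -> missing imputations -> location (CG, covariate,
//   animal blocks) -> G -> R.
//
// Y: n x nt matrix of starting complete data (liabilities and missing
//    cells pre-initialised). miss: 1 where the cell is augmented.
// ybin: observed binary category per record (-1 = unobserved / none).
// bidx: 0-based column of the binary trait in Y (-1 = none).
// cg: 1-based contemporary-group index; xcov: centered covariate;
// cov_use: per-trait 0/1 flag for the covariate.
// anim: 1-based pedigree code per record (ignored if !use_animal).
// [[Rcpp::export]]
List gibbs_ltm_cpp(arma::mat Y, const arma::imat& miss,
                   const arma::ivec& ybin, int bidx,
                   const arma::ivec& cg, int ncg,
                   const arma::vec& xcov, const arma::ivec& cov_use,
                   bool use_cov,
                   const arma::ivec& anim, const arma::sp_mat& Ainv,
                   bool use_animal,
                   int n_cycles, int burn_in, int thin,
                   const arma::mat& G0, double nuG,
                   const arma::mat& R0, double nuR,
                   arma::mat G, arma::mat R,
                   const arma::vec& beta_prec,
                   bool rcov_zero, int verbose_every) {
  const int n = Y.n_rows, nt = Y.n_cols;
  if (nt > 8) stop("at most 8 traits supported");
  const int q = use_animal ? (int)Ainv.n_rows : 0;
  const int n_store = (n_cycles - burn_in) / thin;

  arma::mat beta_cg(ncg, nt, arma::fill::zeros);
  arma::vec bcov(nt, arma::fill::zeros);
  arma::mat a(std::max(q, 1), nt, arma::fill::zeros);
  arma::mat Rinv = arma::inv_sympd(sympd(R));
  arma::mat Ginv = use_animal ? arma::inv_sympd(sympd(G)) : arma::mat();

  // records per animal (each sow has one record; parents may have none)
  std::vector<std::vector<int>> recs;
  if (use_animal) {
    recs.assign(q, {});
    for (int i = 0; i < n; ++i) recs[anim[i] - 1].push_back(i);
  }
  // group sizes for CG levels
  arma::vec ncg_count(ncg, arma::fill::zeros);
  for (int i = 0; i < n; ++i) ncg_count[cg[i] - 1] += 1.0;
  for (int l = 0; l < ncg; ++l)
    if (ncg_count[l] == 0.0) stop("empty contemporary-group level");

  // missing patterns (bitmask over traits)
  std::vector<int> patt(n, 0);
  std::map<int, std::vector<int>> by_patt;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int t = 0; t < nt; ++t) if (miss(i, t)) m |= (1 << t);
    patt[i] = m;
    if (m) by_patt[m].push_back(i);
  }

  const double sxx = use_cov ? arma::dot(xcov, xcov) : 0.0;
  arma::mat E = Y;  // residuals; all effects start at zero
  std::vector<int> binrec;
  if (bidx >= 0)
    for (int i = 0; i < n; ++i) if (ybin[i] >= 0) binrec.push_back(i);

  arma::cube Gs(nt, nt, use_animal ? n_store : 0);
  arma::cube Rs(nt, nt, n_store);
  arma::ivec cycles(n_store);
  arma::mat beta_sum(ncg, nt, arma::fill::zeros);
  arma::vec bcov_sum(nt, arma::fill::zeros);
  arma::mat a_sum(std::max(q, 1), nt, arma::fill::zeros);
  int n_kept = 0, stored = 0;

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // ---- 1. liabilities for observed binary records ----
    if (bidx >= 0) {
      const double v = 1.0 / Rinv(bidx, bidx);
      const double sd = std::sqrt(v);
      for (int i : binrec) {
        double moff = 0.0;
        for (int t = 0; t < nt; ++t)
          if (t != bidx) moff += Rinv(bidx, t) * E(i, t);
        const double eta = Y(i, bidx) - E(i, bidx);
        const double mu = eta - v * moff;
        const double l = ybin[i] == 1 ? rtnorm_pos(mu, sd) : rtnorm_neg(mu, sd);
        Y(i, bidx) = l;
        E(i, bidx) = l - eta;
      }
    }

    // ---- 2. augmentation of missing cells ----
    for (auto& kv : by_patt) {
      const int m = kv.first;
      arma::uvec M, O;
      {
        std::vector<arma::uword> vm, vo;
        for (int t = 0; t < nt; ++t)
          (m & (1 << t)) ? vm.push_back(t) : vo.push_back(t);
        M = arma::uvec(vm);
        O = arma::uvec(vo);
      }
      arma::mat WMM = arma::mat(Rinv).submat(M, M);
      arma::mat WMMinv = arma::inv_sympd(sympd(WMM));
      arma::mat L = arma::chol(sympd(WMMinv), "lower");
      arma::mat B;  // e_M | e_O mean = -WMM^{-1} WMO e_O
      if (O.n_elem) B = -WMMinv * arma::mat(Rinv).submat(M, O);
      for (int i : kv.second) {
        arma::vec mu(M.n_elem, arma::fill::zeros);
        if (O.n_elem) {
          arma::vec eO(O.n_elem);
          for (arma::uword k = 0; k < O.n_elem; ++k) eO[k] = E(i, O[k]);
          mu = B * eO;
        }
        arma::vec eM = mu + L * rnorm_vec(M.n_elem);
        for (arma::uword k = 0; k < M.n_elem; ++k) {
          const int t = M[k];
          const double eta = Y(i, t) - E(i, t);
          E(i, t) = eM[k];
          Y(i, t) = eta + eM[k];
        }
      }
    }

    // ---- 3a. contemporary-group effects (single-site per level) ----
    // beta_prec[t] > 0 adds a proper N(0, 1/beta_prec) prior; needed for
    // the liability trait, where subclasses with all-0 or all-1 outcomes
    // make the flat-prior conditional improper (extreme-category problem)
    for (int t = 0; t < nt; ++t) {
      arma::vec u = E * Rinv.col(t);
      arma::vec S(ncg, arma::fill::zeros);
      for (int i = 0; i < n; ++i) S[cg[i] - 1] += u[i];
      const double wtt = Rinv(t, t);
      const double bp = beta_prec[t];
      arma::vec delta(ncg);
      for (int l = 0; l < ncg; ++l) {
        const double prec = ncg_count[l] * wtt + bp;
        const double mean = (S[l] + ncg_count[l] * wtt * beta_cg(l, t)) / prec;
        const double bnew = mean + norm_rand() / std::sqrt(prec);
        delta[l] = bnew - beta_cg(l, t);
        beta_cg(l, t) = bnew;
      }
      for (int i = 0; i < n; ++i) E(i, t) -= delta[cg[i] - 1];
    }

    // ---- 3b. covariate slopes ----
    if (use_cov) {
      for (int t = 0; t < nt; ++t) {
        if (!cov_use[t]) continue;
        arma::vec u = E * Rinv.col(t);
        const double wtt = Rinv(t, t);
        const double prec = sxx * wtt + beta_prec[t];
        const double mean = (arma::dot(xcov, u) + sxx * wtt * bcov[t]) / prec;
        const double bnew = mean + norm_rand() / std::sqrt(prec);
        const double d = bnew - bcov[t];
        bcov[t] = bnew;
        E.col(t) -= d * xcov;
      }
    }

    // ---- 3c. animal additive effects, one nt-block per animal ----
    if (use_animal) {
      // Simultaneous diagonalization of (Ginv, Rinv): T' Rinv T = I,
      // T' Ginv T = diag(dg). Every animal's conditional precision is
      // ajj*Ginv + nr*Rinv = T^{-T} diag(ajj*dg + nr) T^{-1}, so the
      // per-animal draw needs only two small matrix-vector products.
      arma::mat C = arma::chol(sympd(Rinv), "lower");
      arma::mat Cinv = arma::inv(arma::trimatl(C));
      arma::mat B = Cinv * Ginv * Cinv.t();
      arma::vec dg;
      arma::mat U;
      if (!arma::eig_sym(dg, U, sympd(B))) stop("eigendecomposition failed");
      arma::mat T = Cinv.t() * U;      // nt x nt
      arma::mat Tt = T.t();
      const double* Tp = T.memptr();
      const double* Ttp = Tt.memptr();
      const arma::uword* cptr = Ainv.col_ptrs;
      const arma::uword* ridx = Ainv.row_indices;
      const double* aval = Ainv.values;
      double rhs[8], u[8], w[8], mean[8], ped_acc[8], ysum[8];
      for (int j = 0; j < q; ++j) {
        double ajj = 0.0;
        for (int t = 0; t < nt; ++t) ped_acc[t] = 0.0;
        for (arma::uword p = cptr[j]; p < cptr[j + 1]; ++p) {
          const int k = (int)ridx[p];
          const double v = aval[p];
          if (k == j) { ajj = v; continue; }
          for (int t = 0; t < nt; ++t) ped_acc[t] += v * a(k, t);
        }
        // rhs = -Ginv * ped_acc (+ Rinv * ysum if recorded)
        const int nr = (int)recs[j].size();
        for (int t = 0; t < nt; ++t) {
          double s = 0.0;
          for (int t2 = 0; t2 < nt; ++t2) s += Ginv(t, t2) * ped_acc[t2];
          rhs[t] = -s;
        }
        if (nr > 0) {
          for (int t = 0; t < nt; ++t) ysum[t] = 0.0;
          for (int i : recs[j])
            for (int t = 0; t < nt; ++t) ysum[t] += E(i, t) + a(j, t);
          for (int t = 0; t < nt; ++t) {
            double s = 0.0;
            for (int t2 = 0; t2 < nt; ++t2) s += Rinv(t, t2) * ysum[t2];
            rhs[t] += s;
          }
        }
        // u = T' rhs; scale by conditional precision eigenvalues; back out
        for (int t = 0; t < nt; ++t) {
          double s = 0.0;
          for (int t2 = 0; t2 < nt; ++t2) s += Ttp[t + t2 * nt] * rhs[t2];
          u[t] = s;
        }
        for (int t = 0; t < nt; ++t) {
          const double lam = ajj * dg[t] + nr;
          w[t] = u[t] / lam + norm_rand() / std::sqrt(lam);
        }
        for (int t = 0; t < nt; ++t) {
          double s = 0.0;
          for (int t2 = 0; t2 < nt; ++t2) s += Tp[t + t2 * nt] * w[t2];
          mean[t] = s;
        }
        for (int i : recs[j])
          for (int t = 0; t < nt; ++t) E(i, t) -= mean[t] - a(j, t);
        for (int t = 0; t < nt; ++t) a(j, t) = mean[t];
      }

      // ---- 4. additive covariance G ----
      arma::mat Sa = a.t() * (Ainv * a);
      G = riwish(q + nuG, sympd(Sa + G0));
      Ginv = arma::inv_sympd(sympd(G));
    }

    // ---- 5. residual covariance R ----
    {
      arma::mat Se = E.t() * E + R0;
      const double df = n + nuR;
      if (bidx < 0) {
        R = riwish(df, sympd(Se));
      } else if (nt == 1) {
        R(0, 0) = 1.0;
      } else if (rcov_zero) {
        arma::uvec oth(nt - 1);
        for (int t = 0, k = 0; t < nt; ++t) if (t != bidx) oth[k++] = t;
        arma::mat Rcc = riwish(df, sympd(Se.submat(oth, oth)));
        R.zeros();
        R.submat(oth, oth) = Rcc;
        R(bidx, bidx) = 1.0;
      } else {
        R = riwish_pinned(df, sympd(Se), bidx);
      }
      Rinv = arma::inv_sympd(sympd(R));
    }

    // ---- bookkeeping ----
    if (cyc > burn_in) {
      ++n_kept;
      beta_sum += beta_cg;
      bcov_sum += bcov;
      if (use_animal) a_sum += a;
      if ((cyc - burn_in) % thin == 0) {
        if (use_animal) Gs.slice(stored) = G;
        Rs.slice(stored) = R;
        cycles[stored] = cyc;
        ++stored;
      }
    }
    if (verbose_every > 0 && cyc % verbose_every == 0) {
      Rcout << "cycle " << cyc << "  h2 =";
      for (int t = 0; t < nt; ++t) {
        const double ga = use_animal ? G(t, t) : 0.0;
        Rcout << " " << ga / (ga + R(t, t));
      }
      Rcout << "\n";
    }
    if (cyc % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["G"] = Gs, _["R"] = Rs, _["cycle"] = cycles,
    _["beta_cg"] = beta_sum / std::max(n_kept, 1),
    _["bcov"] = bcov_sum / std::max(n_kept, 1),
    _["a"] = use_animal ? (a_sum / std::max(n_kept, 1)) : arma::mat(),
    _["n_kept"] = n_kept);
}
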