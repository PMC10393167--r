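// Multi-scale clutch engine: Gillespie event loop with a nonlinear per-event
// force balance over all bound adhesion chains.
//
// Units: pN, nm, s. The Green operator G is a dense n_c x n_c compliance
// matrix (nm/pN). Each bound chain b must satisfy the series-compatibility
//   rod_extension(F_b) + F_b / kappa_c + [G F]_b = D_b,   F_b >= 0,
// where D_b is the actin displacement accumulated since the chain bound.

#include <RcppArmadillo.h>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double T_rates = 0, T_equil = 0, T_eval = 0, T_chol = 0, T_tri = 0;
struct Tic {
  std::chrono::high_resolution_clock::time_point t0;
  double* acc;
  Tic(double* a) : t0(std::chrono::high_resolution_clock::now()), acc(a) {}
  ~Tic() {
    *acc += std::chrono::duration<double>(
        std::chrono::high_resolution_clock::now() - t0).count();
  }
};

static const double EXP_CAP = 500.0;

static inline double cexp(double x) {
  if (x > EXP_CAP) x = EXP_CAP;
  if (x < -EXP_CAP) x = -EXP_CAP;
  return std::exp(x);
}

// dimensionless WLC inversion: q(f) with f = F*A/kBT; u = 1-q solves
// 4u^3 + (4f-3)u^2 - 1 = 0 on (0,1]. Safeguarded Newton; u_start warm-starts
// the iteration (pass <= 0 for a cold start).
static double wlc_q_scalar(double f, double u_start = -1.0) {
  if (f <= 0.0) return 0.0;
  double lo = 1e-12, hi = 1.0;
  double u = (u_start > lo && u_start < hi) ? u_start : 1.0 / (1.0 + f);
  if (u <= lo || u >= hi) u = 0.5;
  for (int it = 0; it < 100; ++it) {
    double g = 4.0 * u * u * u + (4.0 * f - 3.0) * u * u - 1.0;
    if (g > 0) hi = u; else lo = u;
    double dg = 12.0 * u * u + 2.0 * (4.0 * f - 3.0) * u;
    double un = u - g / dg;
    if (!std::isfinite(un) || un <= lo || un >= hi) un = 0.5 * (lo + hi);
    if (std::fabs(un - u) < 1e-13 * (1.0 + un)) { u = un; break; }
    u = un;
  }
  return 1.0 - u;
}

// derivative dq/df at the solution
static double wlc_dq_scalar(double q) {
  double u = 1.0 - q;
  return 1.0 / (0.5 / (u * u * u) + 1.0);
}

struct TalinPars {
  arma::vec l0, L0, k_u0, dxu, k_r0, dxf;
  arma::uvec unfoldable;   // 1 if the domain can unfold
  double A, kBT;
  int r3;                  // 0-based index of R3
  int nd;
  // FJC groups: domains sharing the same folded size l0 (usually all of
  // them), so a chain's folded contribution needs one coth per group
  arma::vec l0_grp;        // unique l0 values
  arma::ivec grp_of;       // group index per domain
  int ng;
};

// per-chain mechanical summary of a folding state
struct RodState {
  arma::vec n_fold;        // folded-domain count per FJC group
  double sumL0u;           // unfolded contour length
  mutable double u_warm = -1.0;  // warm start for the WLC inversion
};

static RodState rod_state_of(const TalinPars& tp, const arma::irowvec& folded) {
  RodState rs;
  rs.n_fold.zeros(tp.ng);
  rs.sumL0u = 0.0;
  for (int d = 0; d < tp.nd; ++d) {
    if (folded[d]) rs.n_fold[tp.grp_of[d]] += 1.0;
    else rs.sumL0u += tp.L0[d];
  }
  return rs;
}

// extension (nm) and compliance of one rod at force F.
// coth(b) - 1/b written with a single exp via coth(b) = (e2b+1)/(e2b-1).
static double rod_ext(const TalinPars& tp, const RodState& rs, double F,
                      double& dxdF) {
  double x = 0.0, c = 0.0;
  for (int g = 0; g < tp.ng; ++g) {
    double nf = rs.n_fold[g];
    if (nf == 0.0) continue;
    double l0 = tp.l0_grp[g];
    double beta = F * l0 / tp.kBT;
    if (beta < 1e-4) {
      x += nf * l0 * (beta / 3.0 - beta * beta * beta / 45.0);
      c += nf * l0 * l0 / (3.0 * tp.kBT) * (1.0 - beta * beta / 5.0);
    } else if (beta > 350.0) {
      x += nf * l0 * (1.0 - 1.0 / beta);
      c += nf * l0 * l0 / tp.kBT / (beta * beta);
    } else {
      double e2 = std::exp(2.0 * beta);
      double em = e2 - 1.0;
      double coth = (e2 + 1.0) / em;
      x += nf * l0 * (coth - 1.0 / beta);
      // 1/sinh^2 = 4 e2 / (e2-1)^2
      c += nf * l0 * l0 / tp.kBT * (1.0 / (beta * beta) - 4.0 * e2 / (em * em));
    }
  }
  if (rs.sumL0u > 0.0) {
    double f = F * tp.A / tp.kBT;
    double q = wlc_q_scalar(f, rs.u_warm);
    rs.u_warm = 1.0 - q;
    x += rs.sumL0u * q;
    c += rs.sumL0u * wlc_dq_scalar(q) * tp.A / tp.kBT;
  }
  dxdF = c;
  return x;
}

// Cached Cholesky factor of the active-set Jacobian: while the active set
// is unchanged the previous factor is an excellent preconditioner (the
// Jacobian moves slowly between events), so most events need only
// triangular solves instead of a fresh O(nb^3) factorisation.
struct SolverCache {
  arma::mat R;          // upper Cholesky factor of J(active, active)
  arma::uvec ids;       // global chain ids of the active set
  bool valid = false;
  double n_calls = 0, n_iters = 0, n_chol = 0, n_reuse = 0;
};

extern "C" void dtrsv_(const char* uplo, const char* trans, const char* diag,
                       const int* n, const double* a, const int* lda,
                       double* x, const int* incx);

// in-place solve of (R^T R) x = b given the upper Cholesky factor R,
// via two BLAS triangular solves without materialising R^T
static void chol_solve_inplace(const arma::mat& R, arma::vec& x) {
  int n = (int)R.n_rows, inc = 1;
  dtrsv_("U", "T", "N", &n, R.memptr(), &n, x.memptr(), &inc);
  dtrsv_("U", "N", "N", &n, R.memptr(), &n, x.memptr(), &inc);
}

// Active-set Newton solve of the coupled complementarity system for the
// bound set: chains at slack (F = 0 with residual >= 0) are excluded from
// the Newton subsystem so they cannot pollute the coupled correction.
// Fb is warm-started and overwritten. Returns the max complementarity
// residual.
static double equilibrate_core(const arma::mat& Gbb, const arma::vec& Db,
                               const TalinPars& tp,
                               const std::vector<RodState>& rods,
                               const arma::uvec& idx, double kappa_c,
                               arma::vec& Fb, arma::vec& xtal,
                               double tol, int maxit,
                               SolverCache* cache = nullptr) {
  const arma::uword nb = Db.n_elem;
  arma::vec r(nb), cp(nb), rt(nb), cpt(nb), xt(nb), Ft(nb);
  // full evaluation of residual, compliance and talin extension at Fb
  auto eval_at = [&](const arma::vec& Fv, arma::vec& rv, arma::vec& cv,
                     arma::vec& xv) {
    Tic tic(&T_eval);
    for (arma::uword i = 0; i < nb; ++i) {
      double c;
      double x = rod_ext(tp, rods[idx[i]], Fv[i], c);
      xv[i] = x;
      double ext = x;
      if (kappa_c > 0) { ext += Fv[i] / kappa_c; c += 1.0 / kappa_c; }
      rv[i] = ext - Db[i];
      cv[i] = c;
    }
    rv += Gbb * Fv;
  };
  auto comp_res = [&](const arma::vec& Fv, const arma::vec& rv) {
    double m = 0.0;
    for (arma::uword i = 0; i < nb; ++i) {
      if (Fv[i] > 0.0 || rv[i] < 0.0) {
        double ri = std::fabs(rv[i]);
        if (ri > m) m = ri;
      }
    }
    return m;
  };
  if (cache) cache->n_calls += 1;
  eval_at(Fb, r, cp, xtal);
  double res = comp_res(Fb, r), res_prev = R_PosInf;
  int stale_iters = 0;
  for (int it = 0; it < maxit; ++it) {
    if (res < tol) return res;
    if (cache) cache->n_iters += 1;
    // active set: chains carrying force or wanting to
    arma::uvec act(nb);
    arma::uword na = 0;
    for (arma::uword i = 0; i < nb; ++i)
      if (Fb[i] > 0.0 || r[i] < 0.0) act[na++] = i;
    if (na == 0) return res;
    arma::uvec ia = act.head(na);
    arma::uvec gids = idx(ia);
    bool can_reuse = cache && cache->valid && cache->ids.n_elem == na &&
                     arma::all(cache->ids == gids) && stale_iters < 3 &&
                     !(res_prev < R_PosInf && res > 0.5 * res_prev);
    arma::vec step;
    if (can_reuse) {
      Tic tic(&T_tri);
      step = r(ia);
      chol_solve_inplace(cache->R, step);
      ++stale_iters;
      cache->n_reuse += 1;
    } else {
      if (cache) cache->n_chol += 1;
      Tic tic(&T_chol);
      arma::mat J = Gbb.submat(ia, ia);
      J.diag() += cp(ia);
      arma::mat R;
      if (arma::chol(R, J)) {
        step = r(ia);
        chol_solve_inplace(R, step);
        if (cache) { cache->R = std::move(R); cache->ids = gids;
                     cache->valid = true; }
      } else {
        bool ok = arma::solve(step, J, r(ia));
        if (!ok) break;
        if (cache) cache->valid = false;
      }
      stale_iters = 0;
    }
    res_prev = res;
    // damped update restricted to the active set; forces stay >= 0
    double alpha = 1.0;
    for (int bt = 0; bt < 25; ++bt) {
      Ft = Fb;
      for (arma::uword k = 0; k < na; ++k) {
        double v = Fb[ia[k]] - alpha * step[k];
        Ft[ia[k]] = (v < 0.0) ? 0.0 : v;
      }
      eval_at(Ft, rt, cpt, xt);
      double rest = comp_res(Ft, rt);
      if (rest < res || alpha < 1e-8) {
        Fb = Ft; r = rt; cp = cpt; xtal = xt; res = rest;
        break;
      }
      alpha *= 0.5;
    }
  }
  return res;
}

static TalinPars make_talin(const NumericVector& l0, const NumericVector& L0,
                            double A, double kBT, const LogicalVector& unfoldable,
                            const NumericVector& k_u0, const NumericVector& dxu,
                            const NumericVector& k_r0, const NumericVector& dxf,
                            int r3_index) {
  TalinPars tp;
  tp.nd = l0.size();
  tp.l0 = as<arma::vec>(l0); tp.L0 = as<arma::vec>(L0);
  tp.k_u0 = as<arma::vec>(k_u0); tp.dxu = as<arma::vec>(dxu);
  tp.k_r0 = as<arma::vec>(k_r0); tp.dxf = as<arma::vec>(dxf);
  tp.unfoldable = arma::uvec(tp.nd);
  for (int d = 0; d < tp.nd; ++d) tp.unfoldable[d] = unfoldable[d] ? 1 : 0;
  tp.A = A; tp.kBT = kBT; tp.r3 = r3_index - 1;
  // group domains by folded size
  std::vector<double> uniq;
  tp.grp_of.set_size(tp.nd);
  for (int d = 0; d < tp.nd; ++d) {
    int g = -1;
    for (size_t k = 0; k < uniq.size(); ++k)
      if (uniq[k] == tp.l0[d]) { g = (int)k; break; }
    if (g < 0) { uniq.push_back(tp.l0[d]); g = (int)uniq.size() - 1; }
    tp.grp_of[d] = g;
  }
  tp.ng = (int)uniq.size();
  tp.l0_grp = arma::vec(uniq);
  return tp;
}

// force-dependent unbinding rate
static double off_rate_c(double F, int mode, const arma::vec& lp) {
  // lp = (k1, f1, k2, f2, k3, f3)
  double k = lp[0] * cexp(F / lp[1]);
  if (mode >= 1) k += lp[2] * cexp(-F / lp[3]);
  if (mode >= 2) k += lp[4] * cexp(-F / lp[5]);
  return k;
}

// [[Rcpp::export]]
List ms_equilibrate_cpp(arma::mat G, arma::vec D, LogicalVector bound,
                        IntegerMatrix folded_m, NumericVector l0,
                        NumericVector L0, double A, double kBT,
                        LogicalVector unfoldable, NumericVector k_u0,
                        NumericVector dxu, NumericVector k_r0,
                        NumericVector dxf, int r3_index, double kappa_c,
                        arma::vec F_warm, double tol, int maxit) {
  int n = bound.size();
  TalinPars tp = make_talin(l0, L0, A, kBT, unfoldable, k_u0, dxu, k_r0, dxf,
                            r3_index);
  arma::imat folded(n, tp.nd);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < tp.nd; ++d) folded(i, d) = folded_m(i, d);
  arma::uvec idx(n); arma::uword nb = 0;
  for (int i = 0; i < n; ++i) if (bound[i]) idx[nb++] = i;
  arma::vec F(n, arma::fill::zeros), xtal_full(n, arma::fill::zeros);
  std::vector<RodState> rods(n);
  for (int i = 0; i < n; ++i) rods[i] = rod_state_of(tp, folded.row(i));
  double res = 0.0;
  if (nb > 0) {
    arma::uvec ib = idx.head(nb);
    arma::mat Gbb = G.submat(ib, ib);
    arma::vec Db = D(ib), Fb = F_warm(ib), xt(nb, arma::fill::zeros);
    Fb.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    res = equilibrate_core(Gbb, Db, tp, rods, ib, kappa_c, Fb, xt, tol, maxit);
    F(ib) = Fb;
    xtal_full(ib) = xt;
  }
  return List::create(_["F"] = F, _["x_talin"] = xtal_full,
                      _["residual"] = res, _["F_sub"] = arma::accu(F));
}

// [[Rcpp::export]]
List ms_run_cpp(arma::mat G, double area_nm2, int law_mode, arma::vec law_pars,
                double k_ont, double d_int0, double int_add, double m_r,
                int recruit_mode, double k_onv, NumericVector l0,
                NumericVector L0, double A, double kBT,
                LogicalVector unfoldable, NumericVector k_u0,
                NumericVector dxu, NumericVector k_r0, NumericVector dxf,
                int r3_index, double kappa_c, double F_stall, double v_u,
                double t_f, double record_dt, double tick_dt,
                bool always_bound, double tol, int solver_maxit,
                double max_events) {
  const int n = G.n_rows;
  TalinPars tp = make_talin(l0, L0, A, kBT, unfoldable, k_u0, dxu, k_r0, dxf,
                            r3_index);
  const int nd = tp.nd;

  std::vector<char> bound(n, always_bound ? 1 : 0);
  std::vector<char> vinc(n, 0);
  arma::imat folded(n, nd, arma::fill::ones);
  std::vector<RodState> rods(n);
  for (int i = 0; i < n; ++i) rods[i] = rod_state_of(tp, folded.row(i));
  arma::vec D(n, arma::fill::zeros), F(n, arma::fill::zeros);
  arma::vec xtal(n, arma::fill::zeros);
  double d_int = d_int0, t = 0.0, v = v_u, F_sub = 0.0;
  double worst_resid = 0.0;

  // event rates flattened: [bind(total) | per-chain unbind | chain x domain
  // fold toggles | per-chain vinculin]
  arma::vec krates(1 + n + n * nd + n);

  // accumulators (time integrals)
  double I_P = 0, I_v = 0, I_Pb = 0, I_nv = 0, I_dint = 0, T_bound = 0;
  arma::vec I_dom(nd, arma::fill::zeros);
  // incremental count of bound chains with domain d unfolded
  arma::ivec nu_cnt(nd, arma::fill::zeros);
  double Fmax = 0, xtal_max = 0, xint_max = 0;
  // time integrals of the instantaneous maxima over bound chains
  double I_Fmax = 0, I_xtalmax = 0, I_xintmax = 0;
  double n_vinc_events = 0, n_bind = 0, n_unbind = 0, n_unf = 0, n_ref = 0;

  // trace on a regular grid
  int n_rec = (int)std::floor(t_f / record_dt) + 1;
  arma::mat trace(n_rec, 9, arma::fill::zeros);
  int irec = 0;

  SolverCache cache;
  auto equil = [&]() {
    Tic tic(&T_equil);
    arma::uvec idx(n); arma::uword nb = 0;
    for (int i = 0; i < n; ++i) if (bound[i]) idx[nb++] = i;
    if (nb == 0) { F.zeros(); xtal.zeros(); F_sub = 0.0; return; }
    arma::uvec ib = idx.head(nb);
    arma::mat Gbb = G.submat(ib, ib);
    arma::vec Db = D(ib), Fb = F(ib), xt(nb, arma::fill::zeros);
    Fb.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    double res = equilibrate_core(Gbb, Db, tp, rods, ib, kappa_c, Fb, xt,
                                  tol, solver_maxit, &cache);
    if (res > worst_resid) worst_resid = res;
    F.zeros(); xtal.zeros();
    F(ib) = Fb; xtal(ib) = xt;
    F_sub = arma::accu(Fb);
  };

  auto update_maxima = [&]() {
    for (int i = 0; i < n; ++i) {
      if (!bound[i] && !always_bound) continue;
      if (F[i] > Fmax) Fmax = F[i];
      if (xtal[i] > xtal_max) xtal_max = xtal[i];
      if (kappa_c > 0 && F[i] / kappa_c > xint_max) xint_max = F[i] / kappa_c;
    }
  };

  auto record_upto = [&](double tnow) {
    int nb = 0, nv = 0;
    for (int i = 0; i < n; ++i) { nb += bound[i]; nv += vinc[i]; }
    double xt_now = 0, f_now = 0;
    for (int i = 0; i < n; ++i) {
      if (bound[i]) {
        if (xtal[i] > xt_now) xt_now = xtal[i];
        if (F[i] > f_now) f_now = F[i];
      }
    }
    while (irec < n_rec && irec * record_dt <= tnow + 1e-12) {
      trace(irec, 0) = irec * record_dt;
      trace(irec, 1) = nb;
      trace(irec, 2) = F_sub;
      trace(irec, 3) = F_sub / area_nm2 * 1e6; // Pa
      trace(irec, 4) = v;
      trace(irec, 5) = nv;
      trace(irec, 6) = d_int;
      trace(irec, 7) = f_now;
      trace(irec, 8) = xt_now;
      ++irec;
    }
  };

  auto accumulate = [&](double dt) {
    int nb = 0, nv = 0;
    for (int i = 0; i < n; ++i) { nb += bound[i]; nv += vinc[i]; }
    I_P += dt * F_sub / area_nm2 * 1e6;
    I_v += dt * v;
    I_Pb += dt * (double)nb / n;
    I_nv += dt * nv;
    I_dint += dt * d_int;
    double f_now = 0, xt_now = 0;
    for (int i = 0; i < n; ++i) {
      if (!bound[i]) continue;
      if (F[i] > f_now) f_now = F[i];
      if (xtal[i] > xt_now) xt_now = xtal[i];
    }
    I_Fmax += dt * f_now;
    I_xtalmax += dt * xt_now;
    if (kappa_c > 0) I_xintmax += dt * f_now / kappa_c;
    if (nb > 0) {
      T_bound += dt;
      for (int d = 0; d < nd; ++d)
        I_dom[d] += dt * (double)nu_cnt[d] / nb;
    }
  };

  equil();
  update_maxima();
  record_upto(0.0);

  double n_events = 0;
  double t_last_eq = 0.0;
  while (t < t_f) {
    if (++n_events > max_events)
      stop("event budget exceeded (%.0f events before t_f)", max_events);
    // --- build propensities (frozen at current forces) ---
    auto t_r0 = std::chrono::high_resolution_clock::now();
    double Rtot = 0.0;
    int n_free = 0;
    for (int i = 0; i < n; ++i) if (!bound[i]) ++n_free;
    double r_bind = always_bound ? 0.0 : k_ont * d_int * n_free;
    krates[0] = r_bind; Rtot += r_bind;
    for (int i = 0; i < n; ++i) {
      double k = (!always_bound && bound[i]) ? off_rate_c(F[i], law_mode, law_pars)
                                             : 0.0;
      krates[1 + i] = k; Rtot += k;
    }
    for (int i = 0; i < n; ++i) {
      double Fi = bound[i] ? F[i] : 0.0;
      for (int d = 0; d < nd; ++d) {
        double k = 0.0;
        if (folded(i, d)) {
          if (tp.unfoldable[d])
            k = tp.k_u0[d] * cexp(Fi * tp.dxu[d] / tp.kBT);
        } else {
          if (!(d == tp.r3 && vinc[i]))
            k = tp.k_r0[d] * cexp(-Fi * tp.dxf[d] / tp.kBT);
        }
        krates[1 + n + i * nd + d] = k; Rtot += k;
      }
    }
    for (int i = 0; i < n; ++i) {
      double k = (bound[i] && !folded(i, tp.r3) && !vinc[i]) ? k_onv : 0.0;
      krates[1 + n + n * nd + i] = k; Rtot += k;
    }
    T_rates += std::chrono::duration<double>(
        std::chrono::high_resolution_clock::now() - t_r0).count();

    double tau = (Rtot > 0.0) ? -std::log(unif_rand()) / Rtot : R_PosInf;
    // Propensities are frozen at the current forces, but forces evolve
    // continuously as the actin pulls: refresh the rates at least every
    // tick_dt by advancing without an event (memorylessness makes the
    // discarded exponential draw exact).
    bool tick = tau > tick_dt;
    double dt_adv = tick ? tick_dt : tau;
    if (t + dt_adv >= t_f) {
      double rem = t_f - t;
      accumulate(rem);
      record_upto(t_f - 1e-9); // interior grid points carry the pre-advance state
      double dxf_adv = v * rem;
      for (int i = 0; i < n; ++i) if (bound[i]) D[i] += dxf_adv;
      t = t_f;
      equil();
      v = std::max(0.0, v_u * (1.0 - F_sub / F_stall));
      update_maxima();
      record_upto(t_f); // final point: the equilibrated end state
      break;
    }
    // interval [t, t+dt_adv) carries the pre-advance state
    accumulate(dt_adv);
    record_upto(t + dt_adv);
    t += dt_adv;
    double dx = v * dt_adv;
    for (int i = 0; i < n; ++i) if (bound[i]) D[i] += dx;
    if (tick) {
      equil();
      v = std::max(0.0, v_u * (1.0 - F_sub / F_stall));
      update_maxima();
      t_last_eq = t;
      continue;
    }

    // --- choose and apply the event ---
    bool mech_event = false;  // did the event change the mechanical system?
    double u = unif_rand() * Rtot;
    double cum = 0.0;
    int ev = -1;
    for (arma::uword j = 0; j < krates.n_elem; ++j) {
      cum += krates[j];
      if (u <= cum) { ev = (int)j; break; }
    }
    if (ev < 0) ev = (int)krates.n_elem - 1;
    if (ev == 0) {
      // binding: uniform among free ligands; chain attaches force-free
      int pick = (int)std::floor(unif_rand() * n_free);
      if (pick >= n_free) pick = n_free - 1;
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        if (!bound[i]) {
          if (cnt == pick) {
            bound[i] = 1; D[i] = 0.0; F[i] = 0.0;
            for (int d = 0; d < nd; ++d) if (!folded(i, d)) ++nu_cnt[d];
            break;
          }
          ++cnt;
        }
      }
      n_bind += 1;
    } else if (ev <= n) {
      int i = ev - 1;
      mech_event = true;
      bound[i] = 0; D[i] = 0.0; F[i] = 0.0;
      for (int d = 0; d < nd; ++d) if (!folded(i, d)) --nu_cnt[d];
      if (vinc[i]) {
        vinc[i] = 0;
        if (recruit_mode == 2) d_int = std::max(d_int - int_add, d_int0);
      }
      n_unbind += 1;
    } else if (ev < 1 + n + n * nd) {
      int j = ev - 1 - n;
      int i = j / nd, d = j % nd;
      mech_event = bound[i] != 0;
      if (folded(i, d)) {
        folded(i, d) = 0; n_unf += 1;
        rods[i].n_fold[tp.grp_of[d]] -= 1.0;
        rods[i].sumL0u += tp.L0[d];
        if (bound[i]) ++nu_cnt[d];
      } else {
        folded(i, d) = 1; n_ref += 1;
        rods[i].n_fold[tp.grp_of[d]] += 1.0;
        rods[i].sumL0u -= tp.L0[d];
        if (bound[i]) --nu_cnt[d];
      }
    } else {
      int i = ev - 1 - n - n * nd;
      vinc[i] = 1;
      n_vinc_events += 1;
      if (recruit_mode >= 1) d_int = std::min(d_int + int_add, m_r);
    }
    // binding (chain attaches slack) and vinculin events leave the force
    // balance untouched; re-solving can wait until the next mechanical event
    // or staleness window, like the tick refresh
    if (mech_event || t - t_last_eq >= tick_dt) {
      equil();
      v = std::max(0.0, v_u * (1.0 - F_sub / F_stall));
      update_maxima();
      t_last_eq = t;
    }
  }
  record_upto(t_f);

  arma::vec dom_frac = (T_bound > 0) ? arma::vec(I_dom / T_bound)
                                     : arma::vec(nd, arma::fill::zeros);
  List summary = List::create(
      _["P_mean"] = I_P / t_f, _["v_mean"] = I_v / t_f,
      _["P_b_mean"] = I_Pb / t_f, _["n_vinc_mean"] = I_nv / t_f,
      _["d_int_mean"] = I_dint / t_f, _["F_c_max"] = Fmax,
      _["x_talin_max"] = xtal_max, _["x_int_max"] = xint_max,
      _["F_c_max_tavg"] = I_Fmax / t_f,
      _["x_talin_max_tavg"] = I_xtalmax / t_f,
      _["x_int_max_tavg"] = I_xintmax / t_f,
      _["n_events"] = n_events, _["n_bind"] = n_bind,
      _["n_unbind"] = n_unbind, _["n_unfold"] = n_unf,
      _["n_refold"] = n_ref, _["n_vinc_events"] = n_vinc_events,
      _["worst_residual"] = worst_resid,
      _["domain_unfolded_frac"] = dom_frac);
  summary["n_equil"] = cache.n_calls;
  summary["n_newton"] = cache.n_iters;
  summary["n_chol"] = cache.n_chol;
  summary["n_chol_reuse"] = cache.n_reuse;
  summary["T_rates"] = T_rates; summary["T_equil"] = T_equil;
  summary["T_eval"] = T_eval; summary["T_chol"] = T_chol;
  summary["T_tri"] = T_tri;
  T_rates = T_equil = T_eval = T_chol = T_tri = 0;

  // final state (for inspection / warm restarts)
  LogicalVector bnd(n), vc(n);
  for (int i = 0; i < n; ++i) { bnd[i] = bound[i] == 1; vc[i] = vinc[i] == 1; }
  IntegerMatrix fold_out(n, nd);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < nd; ++d) fold_out(i, d) = folded(i, d);
  List state = List::create(_["bound"] = bnd, _["vinculin"] = vc,
                            _["folded"] = fold_out, _["D"] = D, _["F"] = F,
                            _["x_talin"] = xtal, _["d_int"] = d_int,
                            _["t"] = t, _["v"] = v, _["F_sub"] = F_sub);
  return List::create(_["trace"] = trace, _["summary"] = summary,
                      _["state"] = state);
}
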