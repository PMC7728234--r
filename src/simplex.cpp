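// Dense two-phase primal simplex with bounded variables.
//
// Solves  min c'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite).
// Written for the small dense LPs arising from toy metabolic networks and
// from branch-and-bound nodes of the flux-change minimization MILPs; no
// sparsity exploitation, basis refactorized every iteration (problems here
// have at most a few hundred columns).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PIV_TOL = 1e-9;   // smallest usable pivot
static const double DJ_TOL = 1e-9;    // reduced-cost optimality tolerance
static const double FEAS_TOL = 1e-7;  // phase-1 residual considered zero

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit,
// 4 numerical failure
struct SimplexResult {
  int status;
  vec x;
  double obj;
  int witness;     // entering column for unbounded rays (0-based, -1 none)
  double infeas;   // phase-1 objective on exit
  int iters;
};

// One simplex phase on the working problem (structural + artificial cols).
// basis, at_upper and x are updated in place.
static int simplex_phase(const mat &A, const vec &cost, const vec &lb,
                         const vec &ub, uvec &basis, std::vector<bool> &at_upper,
                         vec &x, int max_iter, int &iters_used, int &witness) {
  const uword m = A.n_rows, n = A.n_cols;
  witness = -1;

  std::vector<bool> in_basis(n, false);
  for (uword i = 0; i < m; ++i) in_basis[basis(i)] = true;

  int iter = 0;
  bool bland = false;
  const int bland_after = 200 + 20 * (int)(m + n);

  while (iter < max_iter) {
    ++iter;
    if (iter > bland_after) bland = true;

    mat B = A.cols(basis);
    vec cB = cost.elem(basis);
    vec y;
    bool ok = solve(y, B.t(), cB, solve_opts::no_approx);
    if (!ok) { iters_used = iter; return 4; }

    // pricing
    int enter = -1;
    double best = 0.0;
    int dir = 0; // +1 entering increases from lower, -1 decreases from upper
    for (uword j = 0; j < n; ++j) {
      if (in_basis[j]) continue;
      if (ub(j) - lb(j) < PIV_TOL) continue; // fixed column can never move
      double dj = cost(j) - dot(A.col(j), y);
      if (!at_upper[j] && dj < -DJ_TOL) {
        if (bland) { enter = (int)j; dir = +1; break; }
        if (-dj > best) { best = -dj; enter = (int)j; dir = +1; }
      } else if (at_upper[j] && dj > DJ_TOL) {
        if (bland) { enter = (int)j; dir = -1; break; }
        if (dj > best) { best = dj; enter = (int)j; dir = -1; }
      }
    }
    if (enter < 0) { iters_used = iter; return 0; } // optimal

    vec w;
    ok = solve(w, B, (vec)A.col(enter), solve_opts::no_approx);
    if (!ok) { iters_used = iter; return 4; }

    // ratio test: x_B moves by -dir * t * w as entering moves by dir * t.
    // Pass 1 finds the minimum blocking step; pass 2 picks, among rows
    // that block at (numerically) that step, the largest pivot.
    double tmax = ub(enter) - lb(enter); // own-bound flip limit
    for (uword i = 0; i < m; ++i) {
      double wi = dir * w(i);
      uword bi = basis(i);
      double t = datum::inf;
      if (wi > PIV_TOL) t = (x(bi) - lb(bi)) / wi;
      else if (wi < -PIV_TOL) t = (ub(bi) - x(bi)) / (-wi);
      if (t < tmax) tmax = t;
    }
    int leave = -1;       // row index in basis (-1: bound flip)
    int leave_to = 0;     // -1 leaving hits lower, +1 hits upper
    double best_piv = 0.0;
    for (uword i = 0; i < m; ++i) {
      double wi = dir * w(i);
      uword bi = basis(i);
      double t = datum::inf;
      int to = 0;
      if (wi > PIV_TOL) { t = (x(bi) - lb(bi)) / wi; to = -1; }
      else if (wi < -PIV_TOL) { t = (ub(bi) - x(bi)) / (-wi); to = +1; }
      if (t <= tmax + 1e-10 && std::fabs(wi) > best_piv) {
        best_piv = std::fabs(wi); leave = (int)i; leave_to = to;
      }
    }

    if (!std::isfinite(tmax)) { // no blocking constraint at all
      witness = enter;
      iters_used = iter;
      return 2;
    }
    if (tmax < 0) tmax = 0; // numerical guard

    // apply step
    x(enter) += dir * tmax;
    for (uword i = 0; i < m; ++i) x(basis(i)) -= dir * tmax * w(i);

    if (leave < 0) {
      // bound flip: entering just switches bound, basis unchanged
      at_upper[enter] = !at_upper[enter];
      // snap to bound to kill drift
      x(enter) = at_upper[enter] ? ub(enter) : lb(enter);
    } else {
      uword out = basis(leave);
      in_basis[out] = false;
      at_upper[out] = (leave_to == +1);
      x(out) = (leave_to == +1) ? ub(out) : lb(out);
      basis(leave) = (uword)enter;
      in_basis[enter] = true;
    }
  }
  iters_used = iter;
  return 3;
}

static SimplexResult solve_bounded_lp(const mat &A, const vec &b, const vec &c,
                                      const vec &lb, const vec &ub,
                                      int max_iter) {
  const uword m = A.n_rows, n = A.n_cols;
  SimplexResult res;
  res.witness = -1;
  res.infeas = 0.0;
  res.iters = 0;

  // quick bound sanity
  for (uword j = 0; j < n; ++j) {
    if (lb(j) > ub(j) + 1e-9) {
      res.status = 1; res.x = zeros<vec>(n); res.obj = datum::nan;
      return res;
    }
  }

  // working problem: structural columns + m artificial columns
  mat Aw(m, n + m, fill::zeros);
  Aw.cols(0, n - 1) = A;

  vec lbw(n + m), ubw(n + m), xw(n + m, fill::zeros);
  lbw.subvec(0, n - 1) = lb;
  ubw.subvec(0, n - 1) = ub;

  // start every structural var nonbasic at the bound of smaller magnitude
  // (nonbasic variables must sit exactly on a bound for bound-flip pivots)
  for (uword j = 0; j < n; ++j)
    xw(j) = (std::fabs(lb(j)) <= std::fabs(ub(j))) ? lb(j) : ub(j);

  vec r = b - Aw.cols(0, n - 1) * xw.subvec(0, n - 1);
  uvec basis(m);
  std::vector<bool> at_upper(n + m, false);
  for (uword j = 0; j < n; ++j)
    at_upper[j] = std::fabs(xw(j) - ub(j)) < std::fabs(xw(j) - lb(j));

  const double BIGUB = 1e30;
  for (uword i = 0; i < m; ++i) {
    uword aj = n + i;
    Aw(i, aj) = (r(i) >= 0) ? 1.0 : -1.0;
    lbw(aj) = 0.0;
    ubw(aj) = BIGUB;
    xw(aj) = std::fabs(r(i));
    basis(i) = aj;
  }

  // phase 1: drive artificials to zero
  vec c1(n + m, fill::zeros);
  c1.subvec(n, n + m - 1).fill(1.0);
  int it1 = 0, wit = -1;
  int st = simplex_phase(Aw, c1, lbw, ubw, basis, at_upper, xw, max_iter,
                         it1, wit);
  res.iters = it1;
  double p1 = accu(xw.subvec(n, n + m - 1));
  res.infeas = p1;
  if (st == 3 || st == 4) { res.status = st; res.x = xw.subvec(0, n - 1); res.obj = datum::nan; return res; }
  if (p1 > FEAS_TOL) { res.status = 1; res.x = xw.subvec(0, n - 1); res.obj = datum::nan; return res; }

  // freeze artificials at zero for phase 2 (they may linger in the basis
  // at value zero; fixing their bounds keeps them there)
  for (uword i = 0; i < m; ++i) { lbw(n + i) = 0.0; ubw(n + i) = 0.0; xw(n + i) = 0.0; }

  vec c2(n + m, fill::zeros);
  c2.subvec(0, n - 1) = c;
  int it2 = 0;
  st = simplex_phase(Aw, c2, lbw, ubw, basis, at_upper, xw, max_iter, it2, wit);
  res.iters += it2;
  res.status = st;
  res.witness = wit;
  res.x = xw.subvec(0, n - 1);
  res.obj = dot(c, res.x);
  return res;
}

//' @noRd
// [[Rcpp::export(name = ".lp_simplex")]]
Rcpp::List lp_simplex(const arma::mat &A, const arma::vec &b,
                      const arma::vec &c, const arma::vec &lb,
                      const arma::vec &ub, int max_iter = 20000) {
  SimplexResult r = solve_bounded_lp(A, b, c, lb, ub, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("status") = r.status,
      Rcpp::Named("x") = r.x,
      Rcpp::Named("obj") = r.obj,
      Rcpp::Named("witness") = r.witness + 1, // 1-based, 0 if none
      Rcpp::Named("infeasibility") = r.infeas,
      Rcpp::Named("iterations") = r.iters);
}

// Batched feasibility checks for the subset-enumeration oracle: for each
// candidate change-set (column of `free_mask`), tighten the bounds of the
// non-free reactions to [ref - beta, ref + beta] and test feasibility of
// A x = b. Returns a logical vector. Used only with small models.
//' @noRd
// [[Rcpp::export(name = ".lp_feasible_batch")]]
Rcpp::LogicalVector lp_feasible_batch(const arma::mat &A, const arma::vec &b,
                                      const arma::vec &lb, const arma::vec &ub,
                                      const arma::vec &ref,
                                      const arma::uvec &counted,
                                      const arma::umat &free_mask,
                                      double beta, int max_iter = 20000) {
  const uword n = A.n_cols;
  const uword ncase = free_mask.n_cols;
  Rcpp::LogicalVector out(ncase);
  vec c(n, fill::zeros);
  for (uword k = 0; k < ncase; ++k) {
    vec lbk = lb, ubk = ub;
    for (uword t = 0; t < counted.n_elem; ++t) {
      if (free_mask(t, k)) continue;
      uword j = counted(t) - 1; // R 1-based
      lbk(j) = std::max(lbk(j), ref(j) - beta);
      ubk(j) = std::min(ubk(j), ref(j) + beta);
    }
    SimplexResult r = solve_bounded_lp(A, b, c, lbk, ubk, max_iter);
    out[k] = (r.status == 0);
  }
  return out;
}
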