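#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Row-column resistor array as a bipartite graph: one node per row line, one per
// column line, cell (i,j) a conductance between row-node i and column-node j.
// Unselected lines float, so the measured quantity between row i and column j is
// the two-point effective conductance of the graph. All pairs share one reduced
// Laplacian inverse per connected component:
//   R_eff(a,b) = M[a,a] + M[b,b] - 2 M[a,b],  M = inv(L with one node grounded),
// and the sensitivity of the measurement to any cell conductance is the squared
// voltage drop across that cell under unit applied voltage:
//   dG_eff(a,b) / dg(p,q) = ((u_p - u_q) / R_eff)^2,  u = M (e_a - e_b).

static void components(const arma::mat& g, int m, int n,
                       std::vector<int>& comp, int& ncomp) {
  const int N = m + n;
  comp.assign(N, -1);
  ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < N; ++s) {
    bool active = false;
    if (s < m) {
      for (int j = 0; j < n; ++j) if (g(s, j) > 0.0) { active = true; break; }
    } else {
      for (int i = 0; i < m; ++i) if (g(i, s - m) > 0.0) { active = true; break; }
    }
    if (!active || comp[s] >= 0) continue;
    comp[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      if (u < m) {
        for (int j = 0; j < n; ++j)
          if (g(u, j) > 0.0 && comp[m + j] < 0) { comp[m + j] = ncomp; stack.push_back(m + j); }
      } else {
        int j = u - m;
        for (int i = 0; i < m; ++i)
          if (g(i, j) > 0.0 && comp[i] < 0) { comp[i] = ncomp; stack.push_back(i); }
      }
    }
    ++ncomp;
  }
}

// forward map; optionally also the Jacobian dF(i,j)/dg(p,q)
// (cell index = column-major, q * m + p)
static void eq_forward(const arma::mat& g, double floor_g,
                       arma::mat& out, arma::mat* J) {
  const int m = g.n_rows, n = g.n_cols;
  arma::mat gf = g;
  gf.elem(arma::find(gf < floor_g)).zeros();

  out.zeros(m, n);
  if (J) J->zeros(m * n, m * n);

  std::vector<int> comp;
  int ncomp = 0;
  components(gf, m, n, comp, ncomp);

  std::vector<int> loc(m + n, -1);
  for (int c = 0; c < ncomp; ++c) {
    std::vector<int> nodes;
    for (int u = 0; u < m + n; ++u) if (comp[u] == c) nodes.push_back(u);
    const int k = (int) nodes.size();
    if (k < 2) continue;
    for (int t = 0; t < k; ++t) loc[nodes[t]] = t;

    arma::mat L(k, k, arma::fill::zeros);
    for (int t = 0; t < k; ++t) {
      int u = nodes[t];
      if (u >= m) continue;
      for (int j = 0; j < n; ++j) {
        double gij = gf(u, j);
        if (gij > 0.0) {
          int tc = loc[m + j];
          L(t, t)   += gij;
          L(tc, tc) += gij;
          L(t, tc)  -= gij;
          L(tc, t)  -= gij;
        }
      }
    }

    arma::mat Mred;
    {
      arma::mat Lred = L.submat(0, 0, k - 2, k - 2);
      bool ok = arma::inv_sympd(Mred, Lred);
      if (!ok) ok = arma::inv(Mred, Lred);
      if (!ok) Rcpp::stop("singular network Laplacian (component of %d nodes)", k);
    }
    // embed grounded node as zero row/column
    arma::mat M(k, k, arma::fill::zeros);
    M.submat(0, 0, k - 2, k - 2) = Mred;

    // component cell list (all row-column pairs inside the component)
    std::vector<int> crow, ccol;
    for (int i = 0; i < m; ++i)
      if (comp[i] == c)
        for (int j = 0; j < n; ++j)
          if (comp[m + j] == c) { crow.push_back(i); ccol.push_back(j); }

    arma::vec u(k);
    for (size_t e = 0; e < crow.size(); ++e) {
      int i = crow[e], j = ccol[e];
      int a = loc[i], b = loc[m + j];
      for (int t = 0; t < k; ++t) u(t) = M(t, a) - M(t, b);
      double R = u(a) - u(b);
      if (R <= 0.0) continue;
      out(i, j) = 1.0 / R;
      if (J) {
        int ridx = j * m + i;
        for (size_t f = 0; f < crow.size(); ++f) {
          int p = crow[f], q = ccol[f];
          double dv = (u(loc[p]) - u(loc[m + q])) / R;
          (*J)(ridx, q * m + p) = dv * dv;
        }
      }
    }
    for (int t = 0; t < k; ++t) loc[nodes[t]] = -1;
  }
}

// [[Rcpp::export(.eq_map)]]
arma::mat eq_map_cpp(const arma::mat& g_in, double floor_g) {
  arma::mat out;
  eq_forward(g_in, floor_g, out, nullptr);
  return out;
}

// Crosstalk inversion.
//
// method "newton" (default): projected Newton with the analytic Jacobian and
// step halving; quadratic convergence, robust also when the crosstalk exceeds
// the direct-cell conductance (heavily loaded mats).
// method "fixed_point": damped crosstalk subtraction
//   g^{t+1} = clamp0( g^t - damping * (F(g^t) - meas) ),
// cheap but only convergent when the crosstalk term is a contraction.
// [[Rcpp::export(.invert_map)]]
List invert_map_cpp(const arma::mat& meas, double damping, double tol,
                    int max_iter, double floor_g,
                    std::string method = "newton",
                    Nullable<NumericMatrix> g_init = R_NilValue) {
  const int m = meas.n_rows, n = meas.n_cols;
  arma::mat g;
  if (g_init.isNotNull()) {
    g = as<arma::mat>(g_init.get());
  } else {
    g = meas;
  }
  g.elem(arma::find(g < 0.0)).zeros();

  arma::mat F, J;
  arma::mat best = g;
  double best_resid = R_PosInf;
  bool converged = false;
  int it;

  // Measurements distorted by sensor lag or quantization need not lie in the
  // image of the forward map, so the residual has a floor: stop early once it
  // stalls (no 0.1% improvement over `stall_limit` consecutive iterations)
  // and return the best iterate.
  const int stall_limit = 3;
  int stalled = 0;

  if (method == "fixed_point") {
    for (it = 0; it < max_iter; ++it) {
      eq_forward(g, floor_g, F, nullptr);
      arma::mat r = F - meas;
      double resid = arma::abs(r).max();
      if (resid < best_resid * (1.0 - 1e-3)) stalled = 0; else ++stalled;
      if (resid < best_resid) { best_resid = resid; best = g; }
      if (resid <= tol) { converged = true; break; }
      if (stalled >= stall_limit) break;
      g -= damping * r;
      g.elem(arma::find(g < 0.0)).zeros();
    }
  } else if (method == "newton") {
    // Progress is judged on the sum of squared residuals: on distorted
    // (inconsistent) measurements the max residual is pinned by a few cells
    // clamped at zero and would mask genuine improvement elsewhere.
    double prev_sse = R_PosInf;
    for (it = 0; it < max_iter; ++it) {
      eq_forward(g, floor_g, F, &J);
      arma::mat r = F - meas;
      double resid = arma::abs(r).max();
      double sse = arma::accu(r % r);
      if (resid < best_resid) best_resid = resid;
      best = g;
      if (resid <= tol) { converged = true; break; }
      if (sse >= prev_sse * (1.0 - 1e-4)) ++stalled; else stalled = 0;
      if (stalled >= stall_limit) break;
      prev_sse = sse;
      // isolated measurements (no network row): take the value directly
      for (int ii = 0; ii < m * n; ++ii)
        if (J(ii, ii) == 0.0 && arma::all(J.row(ii) == 0.0)) J(ii, ii) = 1.0;
      arma::vec step;
      if (!arma::solve(step, J, arma::vectorise(r),
                       arma::solve_opts::no_approx)) break;
      double scale = 1.0;
      arma::mat g_new = g;
      bool improved = false;
      for (int h = 0; h < 6; ++h) {
        arma::mat g_try = g - scale * arma::reshape(step, m, n);
        g_try.elem(arma::find(g_try < 0.0)).zeros();
        arma::mat F2;
        eq_forward(g_try, floor_g, F2, nullptr);
        double sse2 = arma::accu(arma::square(F2 - meas));
        if (sse2 < sse) { g_new = g_try; improved = true; break; }
        scale *= 0.5;
      }
      if (!improved) break;                 // no descent direction left
      g = g_new;
    }
  } else {
    Rcpp::stop("unknown inversion method '%s'", method.c_str());
  }

  return List::create(_["g"] = best,
                      _["converged"] = converged,
                      _["iterations"] = converged ? (it + 1) : it,
                      _["residual"] = best_resid);
}
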