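// ADMM for the fused graphical lasso over G populations.
// Mirrors the pure-R step functions in R/fgl.R exactly (Gauss-Seidel sweep
// over the precision matrices, off-diagonal soft-thresholded slacks with the
// unpenalized diagonal carried through, zero-diagonal scaled duals).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat soft_keepdiag(const mat &M, double a) {
  mat R = sign(M) % clamp(abs(M) - a, 0.0, datum::inf);
  R.diag() = M.diag();
  return R;
}

static void zero_diag(mat &M) { M.diag().zeros(); }

static double offdiag_l1(const mat &M) {
  return accu(abs(M)) - accu(abs(M.diag()));
}

// [[Rcpp::export]]
Rcpp::List fgl_admm_cpp(Rcpp::List S_list, double l1, double l2,
                        double r1, double r2, int max_iter, double eps,
                        bool ones_init, Rcpp::Nullable<Rcpp::List> init_theta,
                        bool keep_trace) {
  const int G = S_list.size();
  std::vector<mat> S(G);
  for (int g = 0; g < G; ++g) S[g] = Rcpp::as<mat>(S_list[g]);
  const int p = S[0].n_rows;

  std::vector<mat> Th(G), Z(G), V(G);
  std::vector<mat> Dl(std::max(G - 1, 0)), U(std::max(G - 1, 0));
  if (init_theta.isNotNull()) {
    Rcpp::List it(init_theta);
    for (int g = 0; g < G; ++g) Th[g] = Rcpp::as<mat>(it[g]);
  } else {
    for (int g = 0; g < G; ++g)
      Th[g] = inv_sympd(S[g] + 0.1 * eye(p, p));
  }
  for (int g = 0; g < G; ++g) {
    Z[g] = Th[g];
    V[g] = ones_init ? mat(p, p, fill::ones) : mat(p, p, fill::zeros);
  }
  for (int g = 0; g < G - 1; ++g) {
    Dl[g] = Th[g] - Th[g + 1];
    U[g] = ones_init ? mat(p, p, fill::ones) : mat(p, p, fill::zeros);
  }

  std::vector<double> obj_trace;
  std::vector<double> logdets(G, 0.0);
  double rel = datum::inf;
  int it_done = 0;
  bool converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    double denom = 0.0;
    for (int g = 0; g < G; ++g) denom += accu(abs(Th[g]));
    std::vector<mat> Th_old = Th;

    // Theta sweep (Gauss-Seidel: later groups see the refreshed neighbours)
    for (int g = 0; g < G; ++g) {
      mat Y = S[g] + r1 * (V[g] - Z[g]);
      int nfus = 0;
      if (G > 1) {
        if (g == 0) {
          Y += r2 * (U[0] - Dl[0] - Th[1]);
          nfus = 1;
        } else if (g == G - 1) {
          Y -= r2 * (U[G - 2] - Dl[G - 2] + Th[G - 2]);
          nfus = 1;
        } else {
          Y -= r2 * (U[g - 1] - Dl[g - 1] + Th[g - 1]);
          Y += r2 * (U[g] - Dl[g] - Th[g + 1]);
          nfus = 2;
        }
      }
      const double rt = r1 + nfus * r2;
      Y = (Y + Y.t()) / 2.0;
      vec d;
      mat Q;
      eig_sym(d, Q, Y);
      vec dv = (-d + sqrt(square(d) + 4.0 * rt)) / (2.0 * rt);
      Th[g] = Q * diagmat(dv) * Q.t();
      Th[g] = (Th[g] + Th[g].t()) / 2.0;
      logdets[g] = accu(log(dv));
    }

    // Slack updates
    for (int g = 0; g < G; ++g)
      Z[g] = soft_keepdiag(Th[g] + V[g], l1 / r1);
    for (int g = 0; g < G - 1; ++g)
      Dl[g] = soft_keepdiag(Th[g] - Th[g + 1] + U[g], l2 / r2);

    // Scaled duals, off-diagonal convention
    for (int g = 0; g < G; ++g) {
      V[g] += Th[g] - Z[g];
      zero_diag(V[g]);
    }
    for (int g = 0; g < G - 1; ++g) {
      U[g] += Th[g] - Th[g + 1] - Dl[g];
      zero_diag(U[g]);
    }

    if (keep_trace) {
      double obj = 0.0;
      for (int g = 0; g < G; ++g)
        obj += dot(S[g], Th[g]) - logdets[g] + l1 * offdiag_l1(Th[g]);
      for (int g = 0; g < G; ++g)
        for (int h = g + 1; h < G; ++h)
          obj += l2 * offdiag_l1(Th[g] - Th[h]);
      obj_trace.push_back(obj);
    }

    double num = 0.0;
    for (int g = 0; g < G; ++g) num += accu(abs(Th[g] - Th_old[g]));
    rel = num / denom;
    it_done = it;
    if (rel <= eps) {
      converged = true;
      break;
    }
  }

  Rcpp::List Th_out(G);
  for (int g = 0; g < G; ++g) Th_out[g] = Th[g];
  return Rcpp::List::create(
      Rcpp::Named("Theta") = Th_out,
      Rcpp::Named("objective_trace") = obj_trace,
      Rcpp::Named("iterations") = it_done,
      Rcpp::Named("relative_change") = rel,
      Rcpp::Named("converged") = converged);
}
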