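// Group LASSO solver for the latent overlapping-group design.
//
// Minimises  (1/2n) ||y - X w||^2 + lambda * sum_g w_g ||v_g||_2
// where the first `nu` columns of X are unpenalized and the remaining
// columns partition into disjoint groups (the latent expansion makes
// overlapping groups disjoint). The solver is a monotone FISTA (proximal
// gradient with Nesterov acceleration, backtracking line search and a
// non-increase safeguard) run on the active set of groups, with full KKT
// screening passes to admit violating groups; Gram-matrix updates make
// each inner iteration O(|active|^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Problem {
  const mat& G;         // X'X, p x p
  const vec& Xty;       // X'y
  double yty;
  int n;
  std::vector<uvec> groups;  // 0-based column indices per penalized group
  vec wg;               // group weights
  int nu;               // number of unpenalized leading columns
};

// Smooth part h(w) = (1/2n) w'Gw - (1/n) Xty'w + (1/2n) yty restricted to
// columns idx (all other coordinates are exactly zero).
double smooth_obj(const Problem& pb, const mat& Gs, const vec& Xtys,
                  const vec& w) {
  return (0.5 * dot(w, Gs * w) - dot(Xtys, w) + 0.5 * pb.yty) / pb.n;
}

double penalty(const Problem& pb, const std::vector<uvec>& gidx,
               const std::vector<int>& act, const vec& w, double lambda) {
  double pen = 0.0;
  for (size_t a = 0; a < act.size(); ++a) {
    pen += pb.wg(act[a]) * norm(w.elem(gidx[a]), 2);
  }
  return lambda * pen;
}

// Group soft-threshold of u with step `st` on the restricted coordinates.
void prox(const Problem& pb, const std::vector<uvec>& gidx,
          const std::vector<int>& act, double lambda, double st, vec& u) {
  for (size_t a = 0; a < act.size(); ++a) {
    const uvec& ix = gidx[a];
    double nrm = norm(u.elem(ix), 2);
    double thr = st * lambda * pb.wg(act[a]);
    if (nrm <= thr) {
      u.elem(ix).zeros();
    } else {
      u.elem(ix) *= (1.0 - thr / nrm);
    }
  }
}

}  // namespace

// Solve at one lambda from a warm start; w_full has length p.
// Returns iterations used; fills w_full, obj, kkt_gap, converged.
static int solve_one(const Problem& pb, double lambda, double tol,
                     double kkt_tol, int max_iter, vec& w_full,
                     double& obj_out, double& kkt_out, bool& conv_out) {
  const int p = pb.G.n_rows;
  const int n_groups = pb.groups.size();

  std::vector<bool> active(n_groups, false);
  for (int g = 0; g < n_groups; ++g) {
    if (norm(w_full.elem(pb.groups[g]), 2) > 0) active[g] = true;
  }

  int total_iter = 0;
  double L = 1.0;  // backtracking estimate, carried across restarts
  bool converged = false;
  double obj = datum::inf;

  for (int outer = 0; outer < 60 && !converged; ++outer) {
    // Assemble the restricted problem (unpenalized + active groups).
    std::vector<int> act;
    std::vector<uword> idx_vec;
    for (int j = 0; j < pb.nu; ++j) idx_vec.push_back(j);
    std::vector<uvec> gidx;  // group member positions inside idx
    for (int g = 0; g < n_groups; ++g) {
      if (!active[g]) continue;
      act.push_back(g);
      uvec loc(pb.groups[g].n_elem);
      for (uword k = 0; k < pb.groups[g].n_elem; ++k) {
        loc(k) = idx_vec.size();
        idx_vec.push_back(pb.groups[g](k));
      }
      gidx.push_back(loc);
    }
    uvec idx(idx_vec);
    mat Gs = pb.G.submat(idx, idx);
    vec Xtys = pb.Xty.elem(idx);

    vec x = w_full.elem(idx);
    vec xv = x;            // momentum point
    double t = 1.0;
    double fx = smooth_obj(pb, Gs, Xtys, x) +
      penalty(pb, gidx, act, x, lambda);
    obj = fx;

    int stall = 0;
    bool just_restarted = false;
    while (total_iter < max_iter) {
      ++total_iter;
      vec grad = (Gs * xv - Xtys) / pb.n;
      double hy = smooth_obj(pb, Gs, Xtys, xv);
      // Backtracking line search on the smooth part.
      vec z;
      double hz;
      for (int bt = 0; bt < 60; ++bt) {
        z = xv - grad / L;
        prox(pb, gidx, act, lambda, 1.0 / L, z);
        hz = smooth_obj(pb, Gs, Xtys, z);
        vec d = z - xv;
        if (hz <= hy + dot(grad, d) + 0.5 * L * dot(d, d) + 1e-15) break;
        L *= 2.0;
      }
      double fz = hz + penalty(pb, gidx, act, z, lambda);
      // slack is relative: at objective magnitudes ~1e3 an absolute test
      // rejects genuine descent once changes reach rounding noise
      double slack = 1e-13 * std::max(1.0, std::abs(fx));

      if (fz <= fx + slack) {    // monotone step: accept z
        double t_next = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
        vec x_prev = x;
        x = z;
        double rel = std::abs(fx - fz) / std::max(1.0, std::abs(fz));
        fx = fz;
        xv = x + ((t - 1.0) / t_next) * (x - x_prev);
        t = t_next;
        just_restarted = false;
        if (rel < tol) { if (++stall >= 2) break; } else stall = 0;
        L = std::max(L * 0.9, 1e-12);
      } else if (just_restarted) {
        break;                   // descent impossible: numerically optimal
      } else {                   // adaptive restart: plain PG from x next
        xv = x;
        t = 1.0;
        just_restarted = true;
      }
    }
    obj = fx;

    // Exact refinement on the identified active set: iterate the
    // stationarity system  (Gs/n + lambda * blockdiag(w_g/||x_g|| I)) x =
    // Xtys/n, which converges past the double-precision descent floor of
    // the objective-based FISTA phase. Groups whose norm collapses are
    // treated as inactive.
    // The exact refinement is only worth its dense solves when a tight
    // certificate is requested; loose CV fits skip it. It iterates the
    // stationarity fixed point and keeps the refined point only if its
    // restricted KKT gap improves on the FISTA iterate (objective values
    // cannot arbitrate here: their rounding noise exceeds the descent).
    if (kkt_tol <= 1e-5) {
      auto restricted_gap = [&](const vec& xx) {
        vec gr = (Gs * xx - Xtys) / pb.n;
        double mg = 0.0;
        for (int j = 0; j < pb.nu; ++j) {
          mg = std::max(mg, std::abs(gr(j)));
        }
        for (size_t a = 0; a < gidx.size(); ++a) {
          vec vg = xx.elem(gidx[a]);
          double nrm = norm(vg, 2);
          vec gg = gr.elem(gidx[a]);
          if (nrm > 0) {
            mg = std::max(mg, norm(gg + lambda * pb.wg(act[a]) * vg / nrm,
                                   2));
          } else {
            mg = std::max(mg, std::max(0.0, norm(gg, 2) -
                                                lambda * pb.wg(act[a])));
          }
        }
        return mg;
      };
      vec x_try = x;
      // Picard warm-up: solve with frozen per-group ridge weights.
      for (int ref = 0; ref < 30; ++ref) {
        std::vector<uword> keep;
        for (int j = 0; j < pb.nu; ++j) keep.push_back(j);
        std::vector<size_t> solid;
        for (size_t a = 0; a < gidx.size(); ++a) {
          double nrm = norm(x_try.elem(gidx[a]), 2);
          if (nrm < 1e-10) {
            x_try.elem(gidx[a]).zeros();
          } else {
            solid.push_back(a);
            for (uword k = 0; k < gidx[a].n_elem; ++k) {
              keep.push_back(gidx[a](k));
            }
          }
        }
        uvec kp(keep);
        mat A = Gs.submat(kp, kp) / pb.n;
        vec rhs = Xtys.elem(kp) / pb.n;
        uword pos = pb.nu;
        for (size_t si = 0; si < solid.size(); ++si) {
          size_t a = solid[si];
          double nrm = norm(x_try.elem(gidx[a]), 2);
          double add = lambda * pb.wg(act[a]) / nrm;
          for (uword k = 0; k < gidx[a].n_elem; ++k) {
            A(pos, pos) += add;
            ++pos;
          }
        }
        vec xk;
        if (!solve(xk, A, rhs, solve_opts::likely_sympd)) break;
        vec x_new = x_try;
        x_new.elem(kp) = xk;
        double step_sz = norm(x_new - x_try, 2) /
          std::max(1.0, norm(x_new, 2));
        x_try = x_new;
        if (step_sz < 1e-14) break;
      }
      // Newton phase on the smooth stationarity system restricted to the
      // surviving groups (quadratic convergence where Picard crawls).
      {
        std::vector<uword> keep;
        for (int j = 0; j < pb.nu; ++j) keep.push_back(j);
        std::vector<size_t> solid;
        std::vector<uvec> gloc;
        for (size_t a = 0; a < gidx.size(); ++a) {
          double nrm = norm(x_try.elem(gidx[a]), 2);
          if (nrm < 1e-10) {
            x_try.elem(gidx[a]).zeros();
            continue;
          }
          solid.push_back(a);
          uvec loc(gidx[a].n_elem);
          for (uword k = 0; k < gidx[a].n_elem; ++k) {
            loc(k) = keep.size();
            keep.push_back(gidx[a](k));
          }
          gloc.push_back(loc);
        }
        uvec kp(keep);
        mat A0 = Gs.submat(kp, kp) / pb.n;
        vec rhs = Xtys.elem(kp) / pb.n;
        vec xk = x_try.elem(kp);
        auto Fres = [&](const vec& v) {
          vec F = A0 * v - rhs;
          for (size_t si = 0; si < solid.size(); ++si) {
            vec vg = v.elem(gloc[si]);
            double nrm = norm(vg, 2);
            if (nrm > 0) {
              F.elem(gloc[si]) += lambda * pb.wg(act[solid[si]]) * vg / nrm;
            }
          }
          return F;
        };
        double fnorm = norm(Fres(xk), 2);
        for (int nt = 0; nt < 30 && fnorm > 1e-14; ++nt) {
          mat J = A0;
          bool ok = true;
          for (size_t si = 0; si < solid.size(); ++si) {
            vec vg = xk.elem(gloc[si]);
            double nrm = norm(vg, 2);
            if (nrm < 1e-12) { ok = false; break; }
            double lw = lambda * pb.wg(act[solid[si]]);
            mat Jg = (lw / nrm) * eye(vg.n_elem, vg.n_elem) -
              (lw / (nrm * nrm * nrm)) * (vg * vg.t());
            J.submat(gloc[si], gloc[si]) += Jg;
          }
          if (!ok) break;
          vec dlt;
          if (!solve(dlt, J, -Fres(xk))) break;
          double stp = 1.0;
          bool moved = false;
          for (int h = 0; h < 20; ++h) {
            vec cand = xk + stp * dlt;
            double fn = norm(Fres(cand), 2);
            if (fn < fnorm) {
              xk = cand;
              fnorm = fn;
              moved = true;
              break;
            }
            stp *= 0.5;
          }
          if (!moved) break;
        }
        x_try.elem(kp) = xk;
      }
      if (restricted_gap(x_try) < restricted_gap(x)) {
        x = x_try;
        fx = smooth_obj(pb, Gs, Xtys, x) +
          penalty(pb, gidx, act, x, lambda);
      }
      obj = fx;
    }

    // Write back the restricted solution.
    w_full.zeros();
    w_full.elem(idx) = x;

    // Full KKT pass: drop empty groups, admit violators.
    vec grad_full = (pb.G.cols(idx) * x - pb.Xty) / pb.n;
    double max_gap = 0.0;
    for (int j = 0; j < pb.nu; ++j) {
      max_gap = std::max(max_gap, std::abs(grad_full(j)));
    }
    bool added = false;
    for (int g = 0; g < n_groups; ++g) {
      vec vg = w_full.elem(pb.groups[g]);
      double nrm = norm(vg, 2);
      vec gg = grad_full.elem(pb.groups[g]);
      if (nrm > 0) {
        double gap = norm(gg + lambda * pb.wg(g) * vg / nrm, 2);
        max_gap = std::max(max_gap, gap);
      } else {
        double gap = norm(gg, 2) - lambda * pb.wg(g);
        if (gap > 0) max_gap = std::max(max_gap, gap);
        if (!active[g] && gap > std::min(kkt_tol, 1e-9)) {
          active[g] = true;
          added = true;
        }
      }
    }
    kkt_out = max_gap;
    if (!added && max_gap <= kkt_tol) {
      converged = true;
    } else if (!added && total_iter >= max_iter) {
      break;
    } else if (!added) {
      // objective converged but KKT slack too large: tighten and continue
      tol *= 0.01;
      if (tol < 1e-16) break;
    }
  }
  obj_out = obj;
  conv_out = converged;
  return total_iter;
}

// [[Rcpp::export]]
Rcpp::List gl_path_cpp(const arma::mat& X, const arma::vec& y,
                       const Rcpp::List& groups, const arma::vec& weights,
                       int nu, const arma::vec& lambdas, double tol,
                       double kkt_tol, int max_iter,
                       Rcpp::Nullable<Rcpp::NumericVector> w0 =
                           R_NilValue) {
  const int p = X.n_cols;
  const int n = X.n_rows;
  mat G = X.t() * X;
  vec Xty = X.t() * y;
  double yty = dot(y, y);

  Problem pb{G, Xty, yty, n, {}, weights, nu};
  pb.groups.reserve(groups.size());
  for (int g = 0; g < groups.size(); ++g) {
    uvec ix = Rcpp::as<uvec>(groups[g]);
    pb.groups.push_back(ix - 1);  // 1-based from R
  }

  const int nl = lambdas.n_elem;
  mat W(p, nl, fill::zeros);
  vec obj(nl), kkt(nl);
  ivec iters(nl);
  Rcpp::LogicalVector conv(nl);

  vec w(p, fill::zeros);
  if (w0.isNotNull()) w = Rcpp::as<vec>(w0.get());
  for (int l = 0; l < nl; ++l) {
    double o, k;
    bool c;
    int it = solve_one(pb, lambdas(l), tol, kkt_tol, max_iter, w, o, k, c);
    W.col(l) = w;
    obj(l) = o;
    kkt(l) = k;
    iters(l) = it;
    conv(l) = c;
  }
  return Rcpp::List::create(
      Rcpp::Named("coef") = W, Rcpp::Named("objective") = obj,
      Rcpp::Named("kkt_gap") = kkt, Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = conv);
}
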