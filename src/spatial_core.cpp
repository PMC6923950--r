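#include <Rcpp.h>
#include <cmath>

// Coarse-grained 3D colony lattice: per-cube three-state growth kinetics,
// thresholded cell-mass movement between the six face neighbours, and
// flux-based nutrient transfer, advanced by explicit Euler steps.
//
// Index layout: idx = i + Ni*(j + Nj*k) with k the vertical axis (0-based);
// layers 1..agar_layers (1-based) inside the disc footprint are agar.
//
// Neighbour contributions are accumulated as (x-pair + y-pair) + z-pair so
// that a lattice state with exact 4-fold rotational symmetry about the
// vertical axis stays bitwise symmetric under the non-associative floating
// point sums.

static inline void cube_reaction(const double mg, const double g,
                                 const double me, const double e,
                                 const double *p, double *dy) {
  const double grow_g = p[0] * mg * g;
  const double sw = p[2] * mg / (g + p[3]);
  const double grow_e = p[1] * me * e;
  dy[0] = grow_g - sw - p[4] * mg;
  dy[1] = -grow_g / p[6];
  dy[2] = grow_e + sw - p[5] * me;
  dy[3] = grow_g / p[7] - grow_e / p[8];
  dy[4] = p[4] * mg + p[5] * me;
}

// [[Rcpp::export]]
Rcpp::List colony_run_cpp(Rcpp::NumericVector mg, Rcpp::NumericVector me,
                          Rcpp::NumericVector mq, Rcpp::NumericVector g,
                          Rcpp::NumericVector e, Rcpp::IntegerVector dims,
                          Rcpp::LogicalVector agar, Rcpp::NumericVector pars,
                          double th, double lambda_mass, double lambda_agar,
                          double lambda_col, int agar_layers, double dt,
                          int n_steps, int sample_every,
                          bool keep_snapshots = false, double neg_tol = 1e-9) {
  const int Ni = dims[0], Nj = dims[1], Nk = dims[2];
  const R_xlen_t N = (R_xlen_t)Ni * Nj * Nk;
  if (mg.size() != N) Rcpp::stop("field size does not match dims");

  std::vector<double> MG(mg.begin(), mg.end()), ME(me.begin(), me.end()),
      MQ(mq.begin(), mq.end()), G(g.begin(), g.end()), E(e.begin(), e.end());
  std::vector<double> mtot(N), gth(N);
  std::vector<double> dMG(N), dME(N), dMQ(N), dG(N), dE(N);

  const int n_samples = n_steps / sample_every + 1;
  Rcpp::NumericVector s_times(n_samples);
  Rcpp::IntegerVector s_cols(n_samples);
  Rcpp::NumericVector s_mass(n_samples);
  Rcpp::List snaps(keep_snapshots ? n_samples : 0);

  const int strd_i = 1, strd_j = Ni, strd_k = Ni * Nj;
  int status = 0;
  double t_fail = 0.0;

  auto record = [&](int s_idx, double t) {
    int cols = 0;
    double mass = 0.0;
    for (int j = 0; j < Nj; ++j)
      for (int i = 0; i < Ni; ++i) {
        bool occ = false;
        for (int k = agar_layers; k < Nk; ++k) {
          const R_xlen_t c = i + strd_j * j + (R_xlen_t)strd_k * k;
          if (!agar[c] && MG[c] + ME[c] + MQ[c] > 0.0) { occ = true; break; }
        }
        if (occ) ++cols;
      }
    for (R_xlen_t c = 0; c < N; ++c) mass += MG[c] + ME[c] + MQ[c];
    s_times[s_idx] = t;
    s_cols[s_idx] = cols;
    s_mass[s_idx] = mass;
    if (keep_snapshots) {
      snaps[s_idx] = Rcpp::List::create(
          Rcpp::Named("m_g") = Rcpp::NumericVector(MG.begin(), MG.end()),
          Rcpp::Named("m_e") = Rcpp::NumericVector(ME.begin(), ME.end()),
          Rcpp::Named("m_q") = Rcpp::NumericVector(MQ.begin(), MQ.end()),
          Rcpp::Named("g") = Rcpp::NumericVector(G.begin(), G.end()),
          Rcpp::Named("e") = Rcpp::NumericVector(E.begin(), E.end()));
    }
  };

  record(0, 0.0);
  int s_idx = 1;

  for (int step = 1; step <= n_steps && status == 0; ++step) {
    for (R_xlen_t c = 0; c < N; ++c) {
      mtot[c] = MG[c] + ME[c] + MQ[c];
      gth[c] = std::max(mtot[c] - th, 0.0);
    }

    for (int k = 0; k < Nk; ++k) {
      const int k1 = k + 1; // 1-based layer
      for (int j = 0; j < Nj; ++j) {
        for (int i = 0; i < Ni; ++i) {
          const R_xlen_t c = i + strd_j * j + (R_xlen_t)strd_k * k;
          const bool c_agar = agar[c];
          const double m_c = mtot[c];

          // ---- cell mass movement (excluded from/into agar) ----
          double mv[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}}; // axis x state
          if (!c_agar) {
            const int off[6] = {-strd_i, strd_i, -strd_j, strd_j,
                                -strd_k, strd_k};
            const bool ok[6] = {i > 0, i < Ni - 1, j > 0, j < Nj - 1,
                                k > 0, k < Nk - 1};
            for (int dir = 0; dir < 6; ++dir) {
              if (!ok[dir]) continue;
              const R_xlen_t b = c + off[dir];
              if (agar[b]) continue;
              const double diff = gth[b] - gth[c];
              if (diff == 0.0) continue;
              const int ax = dir / 2;
              if (diff < 0.0) { // this cube is the donor (m_c > th > 0)
                mv[ax][0] += diff * (MG[c] / m_c);
                mv[ax][1] += diff * (ME[c] / m_c);
                mv[ax][2] += diff * (MQ[c] / m_c);
              } else {          // neighbour is the donor
                const double m_b = mtot[b];
                mv[ax][0] += diff * (MG[b] / m_b);
                mv[ax][1] += diff * (ME[b] / m_b);
                mv[ax][2] += diff * (MQ[b] / m_b);
              }
            }
          }

          // ---- nutrient transfer ----
          // glucose domain: agar cubes plus cubes with positive cell mass
          double gfl[3] = {0, 0, 0};
          if (c_agar || m_c > 0.0) {
            const int off[6] = {-strd_i, strd_i, -strd_j, strd_j,
                                -strd_k, strd_k};
            const bool ok[6] = {i > 0, i < Ni - 1, j > 0, j < Nj - 1,
                                k > 0, k < Nk - 1};
            for (int dir = 0; dir < 6; ++dir) {
              if (!ok[dir]) continue;
              const R_xlen_t b = c + off[dir];
              if (!(agar[b] || mtot[b] > 0.0)) continue;
              const int k1b = (dir == 4) ? k1 - 1 : (dir == 5) ? k1 + 1 : k1;
              const double rate =
                  (k1 > agar_layers + 1 ||
                   (k1 == agar_layers + 1 && k1b == k1 + 1))
                      ? lambda_col
                      : lambda_agar;
              gfl[dir / 2] += rate * (G[b] - G[c]);
            }
          }

          // ethanol domain: cubes with positive cell mass only
          double efl[3] = {0, 0, 0};
          if (m_c > 0.0) {
            const int off[6] = {-strd_i, strd_i, -strd_j, strd_j,
                                -strd_k, strd_k};
            const bool ok[6] = {i > 0, i < Ni - 1, j > 0, j < Nj - 1,
                                k > 0, k < Nk - 1};
            for (int dir = 0; dir < 6; ++dir) {
              if (!ok[dir]) continue;
              const R_xlen_t b = c + off[dir];
              if (!(mtot[b] > 0.0)) continue;
              efl[dir / 2] += lambda_col * (E[b] - E[c]);
            }
          }

          // ---- local reactions ----
          double rx[5] = {0, 0, 0, 0, 0};
          if (!c_agar) cube_reaction(MG[c], G[c], ME[c], E[c], pars.begin(), rx);

          dMG[c] = rx[0] + lambda_mass * ((mv[0][0] + mv[1][0]) + mv[2][0]);
          dME[c] = rx[2] + lambda_mass * ((mv[0][1] + mv[1][1]) + mv[2][1]);
          dMQ[c] = rx[4] + lambda_mass * ((mv[0][2] + mv[1][2]) + mv[2][2]);
          dG[c] = rx[1] + ((gfl[0] + gfl[1]) + gfl[2]);
          dE[c] = rx[3] + ((efl[0] + efl[1]) + efl[2]);
        }
      }
    }

    for (R_xlen_t c = 0; c < N && status == 0; ++c) {
      MG[c] += dt * dMG[c];
      ME[c] += dt * dME[c];
      MQ[c] += dt * dMQ[c];
      G[c] += dt * dG[c];
      E[c] += dt * dE[c];
      double *vals[5] = {&MG[c], &ME[c], &MQ[c], &G[c], &E[c]};
      for (int q = 0; q < 5; ++q) {
        if (*vals[q] < 0.0) {
          if (*vals[q] <= -neg_tol) { status = 6; t_fail = step * dt; break; }
          *vals[q] = 0.0;
        }
        if (!std::isfinite(*vals[q])) { status = 3; t_fail = step * dt; break; }
      }
    }

    if (status == 0 && step % sample_every == 0) record(s_idx++, step * dt);
  }

  return Rcpp::List::create(
      Rcpp::Named("times") = s_times, Rcpp::Named("col_counts") = s_cols,
      Rcpp::Named("total_mass") = s_mass, Rcpp::Named("snapshots") = snaps,
      Rcpp::Named("m_g") = Rcpp::NumericVector(MG.begin(), MG.end()),
      Rcpp::Named("m_e") = Rcpp::NumericVector(ME.begin(), ME.end()),
      Rcpp::Named("m_q") = Rcpp::NumericVector(MQ.begin(), MQ.end()),
      Rcpp::Named("g") = Rcpp::NumericVector(G.begin(), G.end()),
      Rcpp::Named("e") = Rcpp::NumericVector(E.begin(), E.end()),
      Rcpp::Named("status") = status, Rcpp::Named("t_fail") = t_fail);
}
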