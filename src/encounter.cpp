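#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Overdamped Brownian dynamics of N enzymes in a periodic Lx x Ly domain
// with n circular target sites of diameter a. An encounter is registered
// when an active enzyme enters a site disc; the enzyme then stays inactive
// for the deterministic latency t_off but keeps diffusing. To prevent the
// registration count from diverging with the integration resolution
// (boundary re-crossings of a pure threshold rule grow without bound as
// dt -> 0), re-registration at the same site is re-armed with hysteresis:
// the enzyme must first move one site diameter away from the site center.
// In facilitated mode a filament of length l oriented along y is centered
// at every site; off-filament enzymes cannot cross a filament (a crossing
// step attaches them at the crossing point), on-filament enzymes diffuse 1D
// along y with the same D, leave at the ends, or are displaced off by 2a at
// rate k_off. Uses the R RNG; seed via set.seed() before calling.

static inline double wrap_pos(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard against floating-point round-up
  return x;
}
static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// [[Rcpp::export]]
List encounter_sim_cpp(int N, double D, double Lx, double Ly,
                       NumericMatrix sites, double a, double t_off,
                       double dt, double T, bool facilitated, double l,
                       double k_off, int n_snapshots) {
  const int n_sites = sites.nrow();
  const double rad = a / 2.0, rad2 = rad * rad;
  const double r_arm = a, r_arm2 = r_arm * r_arm;   // hysteresis radius
  const double sig = std::sqrt(2.0 * D * dt);
  const long n_steps = (long)std::ceil(T / dt);
  const long snap_every = std::max(1L, n_steps / std::max(1, n_snapshots));

  std::vector<double> x(N), y(N), ux(N, 0.0), uy(N, 0.0);
  std::vector<double> active_at(N, 0.0), u_fil(N, 0.0);
  std::vector<int> on_fil(N, -1), armed_block(N, -1), last_site(N, -1);
  std::vector<int> run_len(N, 0);
  std::vector<int> counts(n_sites, 0);
  std::vector<int> runs;
  std::vector<double> sx(n_sites), sy(n_sites);
  for (int s = 0; s < n_sites; ++s) { sx[s] = sites(s, 0); sy[s] = sites(s, 1); }

  for (int e = 0; e < N; ++e) {
    x[e] = unif_rand() * Lx;
    y[e] = unif_rand() * Ly;
  }

  std::vector<double> snap_t;
  std::vector<std::vector<double>> snap_x, snap_y;
  snap_t.push_back(0.0); snap_x.push_back(ux); snap_y.push_back(uy);

  const double p_off = (k_off > 0.0) ? k_off * dt : 0.0;

  // register an encounter of enzyme e at site s at time t
  auto register_hit = [&](int e, int s, double t) {
    counts[s]++;
    active_at[e] = t + t_off;
    armed_block[e] = s;
    if (last_site[e] == s) run_len[e]++;
    else {
      if (run_len[e] > 0) runs.push_back(run_len[e]);
      last_site[e] = s;
      run_len[e] = 1;
    }
  };

  for (long k = 1; k <= n_steps; ++k) {
    const double t = k * dt;
    for (int e = 0; e < N; ++e) {
      if (on_fil[e] >= 0) {
        const int f = on_fil[e];
        if (p_off > 0.0 && unif_rand() < p_off) {     // lateral displacement
          const double sgn = (unif_rand() < 0.5) ? -1.0 : 1.0;
          x[e] = wrap_pos(sx[f] + sgn * 2.0 * a, Lx);
          ux[e] += sgn * 2.0 * a;
          y[e] = wrap_pos(sy[f] + u_fil[e], Ly);
          on_fil[e] = -1;
        } else {
          const double du = sig * norm_rand();
          double u = u_fil[e] + du;
          if (std::fabs(u) > l / 2.0) {               // leave at an end
            const double uc = (u > 0 ? 1.0 : -1.0) * l / 2.0;
            uy[e] += uc - u_fil[e];
            u_fil[e] = uc;
            x[e] = sx[f];
            y[e] = wrap_pos(sy[f] + uc, Ly);
            on_fil[e] = -1;
          } else {
            uy[e] += du;
            u_fil[e] = u;
            y[e] = wrap_pos(sy[f] + u, Ly);
            if (std::fabs(u) <= rad && t >= active_at[e] &&
                armed_block[e] != f)
              register_hit(e, f, t);
          }
        }
      } else {
        // free 2D diffusion
        const double dx = sig * norm_rand();
        const double dy = sig * norm_rand();
        bool attached = false;
        if (facilitated) {
          for (int f = 0; f < n_sites; ++f) {
            const double s1 = min_image(x[e] - sx[f], Lx);
            const double s2 = s1 + dx;
            if ((s1 > 0 && s2 <= 0) || (s1 < 0 && s2 >= 0)) {
              const double frac = (s1 == s2) ? 0.0 : s1 / (s1 - s2);
              const double ycr = y[e] + dy * frac;
              const double u = min_image(ycr - sy[f], Ly);
              if (std::fabs(u) <= l / 2.0) {          // attach at crossing
                ux[e] += -s1;
                uy[e] += dy * frac;
                x[e] = wrap_pos(sx[f], Lx);
                y[e] = wrap_pos(sy[f] + u, Ly);
                on_fil[e] = f;
                u_fil[e] = u;
                if (std::fabs(u) <= rad && t >= active_at[e] &&
                    armed_block[e] != f)
                  register_hit(e, f, t);
                attached = true;
                break;
              }
            }
          }
        }
        if (!attached) {
          x[e] = wrap_pos(x[e] + dx, Lx);
          y[e] = wrap_pos(y[e] + dy, Ly);
          ux[e] += dx; uy[e] += dy;
          if (t >= active_at[e]) {
            for (int s = 0; s < n_sites; ++s) {
              if (s == armed_block[e]) continue;
              const double ddx = min_image(x[e] - sx[s], Lx);
              if (std::fabs(ddx) > rad) continue;
              const double ddy = min_image(y[e] - sy[s], Ly);
              if (ddx * ddx + ddy * ddy <= rad2) { register_hit(e, s, t); break; }
            }
          }
        }
      }
      // hysteresis re-arm: same-site registration unblocks only once the
      // enzyme has moved one site diameter away from the site center
      const int b = armed_block[e];
      if (b >= 0) {
        const double ddx = min_image(x[e] - sx[b], Lx);
        const double ddy = min_image(y[e] - sy[b], Ly);
        if (ddx * ddx + ddy * ddy > r_arm2) armed_block[e] = -1;
      }
    }
    if (k % snap_every == 0 || k == n_steps) {
      snap_t.push_back(t); snap_x.push_back(ux); snap_y.push_back(uy);
    }
  }
  for (int e = 0; e < N; ++e)
    if (run_len[e] > 0) runs.push_back(run_len[e]);   // censored runs counted

  const int n_snap = (int)snap_t.size();
  NumericMatrix mx(n_snap, N), my(n_snap, N);
  NumericVector tv(n_snap);
  for (int i = 0; i < n_snap; ++i) {
    tv[i] = snap_t[i];
    for (int e = 0; e < N; ++e) { mx(i, e) = snap_x[i][e]; my(i, e) = snap_y[i][e]; }
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["run_lengths"] = IntegerVector(runs.begin(), runs.end()),
                      _["snap_t"] = tv, _["snap_x"] = mx, _["snap_y"] = my,
                      _["T"] = n_steps * dt);
}
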