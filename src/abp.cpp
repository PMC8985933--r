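#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Wrap an angle into (-pi, pi].
static inline double wrap_pi(double a) {
  a = a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (a <= -M_PI) a = M_PI;
  return a;
}

// Euler-Maruyama integration of the active-Brownian fish model in a
// circular tank: self-propulsion at speed v0 along the heading, soft wall
// repulsion (strength kw, range rw), wall-alignment torque (kwt, rwt)
// acting only on fish near the wall and moving towards it, short-range
// avoidance torque (ka, ra) turning a fish away from close neighbors, and
// rotational white noise of strength 2*Dr.
//
// Draws from R's RNG (seed with set.seed() before calling). Positions are
// stored every out_every steps once `discard` time units have elapsed;
// out_every = 0 disables storage. The returned fraction_in_center counts
// every post-discard step of every fish with |r| < R/sqrt(2).
// [[Rcpp::export(name = ".abp_run_cpp")]]
List abp_run_cpp(int n, double v0, double dr, double mu, double mur,
                 double kw, double rw, double kwt, double rwt,
                 double ka, double ra, double R, double dt,
                 double duration, double discard, int out_every) {
  if (n < 1) stop("need at least one fish");
  if (dt <= 0) stop("dt must be > 0");
  if (discard >= duration) stop("discard must be smaller than duration");

  const long nsteps = (long)std::llround(duration / dt);
  const long dsteps = (long)std::llround(discard / dt);
  const double rc = R / std::sqrt(2.0);   // inner-half radius
  const double sig = std::sqrt(2.0 * dr * dt);

  std::vector<double> x(n), y(n), th(n);
  // initial condition: random spot along the wall, at distance rw from it,
  // heading parallel to the wall with random chirality
  for (int i = 0; i < n; ++i) {
    double phi = 2.0 * M_PI * unif_rand();
    double rad = R - rw;
    x[i] = rad * std::cos(phi);
    y[i] = rad * std::sin(phi);
    double chir = (unif_rand() < 0.5) ? 1.0 : -1.0;
    th[i] = wrap_pi(phi + chir * M_PI / 2.0);
  }

  long nframes = 0;
  if (out_every > 0)
    nframes = (nsteps - dsteps - 1) / out_every + 1;
  NumericMatrix ox(out_every > 0 ? nframes : 0, n),
                oy(out_every > 0 ? nframes : 0, n),
                oth(out_every > 0 ? nframes : 0, n);

  std::vector<double> fx(n), fy(n), tq(n);
  long ncenter = 0, ncount = 0, frame = 0;

  for (long s = 0; s < nsteps; ++s) {
    // forces and torques from the current (synchronous) state
    for (int i = 0; i < n; ++i) {
      double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      double rx = (r > 0) ? x[i] / r : 1.0, ry = (r > 0) ? y[i] / r : 0.0;
      double ex = std::cos(th[i]), ey = std::sin(th[i]);
      double f = 0.0;
      if (R - rw - r < 0) f = kw * (R - rw - r);   // soft repulsion, inward
      fx[i] = f * rx;
      fy[i] = f * ry;
      double tau = 0.0;
      double edotr = ex * rx + ey * ry;
      if (R - rwt - r < 0 && edotr > 0) {
        double ecrossr = ex * ry - ey * rx;
        tau += kwt * edotr * ecrossr * (R - rwt - r);
      }
      if (ka != 0.0 && n > 1) {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double dij = std::sqrt(dx * dx + dy * dy);
          if (dij >= ra) continue;
          double ux, uy;
          if (dij > 0) {
            ux = dx / dij; uy = dy / dij;
          } else {           // coincident fish: random separation direction
            double a = 2.0 * M_PI * unif_rand();
            ux = std::cos(a); uy = std::sin(a);
          }
          // (r_ij x e_i)_z : turns the heading away from the neighbor
          tau += ka * (ux * ey - uy * ex) * (ra - dij);
        }
      }
      tq[i] = tau;
    }
    // Euler-Maruyama update
    for (int i = 0; i < n; ++i) {
      double ex = std::cos(th[i]), ey = std::sin(th[i]);
      x[i] += (v0 * ex + mu * fx[i]) * dt;
      y[i] += (v0 * ey + mu * fy[i]) * dt;
      double dth = mur * tq[i] * dt;
      if (dr > 0) dth += sig * norm_rand();
      th[i] = wrap_pi(th[i] + dth);
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(th[i]))
        stop("non-finite state at step %ld", s);
      double r2 = x[i] * x[i] + y[i] * y[i];
      if (r2 > R * R)
        stop("fish escaped the tank at step %ld (|r| = %.3f)", s,
             std::sqrt(r2));
      if (s >= dsteps) {
        ++ncount;
        if (r2 < rc * rc) ++ncenter;
      }
    }
    if (out_every > 0 && s >= dsteps && (s - dsteps) % out_every == 0) {
      for (int i = 0; i < n; ++i) {
        ox(frame, i) = x[i];
        oy(frame, i) = y[i];
        oth(frame, i) = th[i];
      }
      ++frame;
    }
  }

  return List::create(
    _["x"] = ox, _["y"] = oy, _["theta"] = oth,
    _["fraction_in_center"] = (double)ncenter / (double)ncount,
    _["n_steps_counted"] = (double)ncount);
}
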