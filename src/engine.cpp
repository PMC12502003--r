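#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-loop engine shared by the calibration and continuous phases.
//
// Plant (forward Euler at the task rate): x' = x + dt * lambda * (x + s*u),
// where s is the control-sign convention (+1: plant acts on x + u).
// Controller: delayed proportional feedback u = -s * gain * x[n - d] plus
// Gaussian motor noise, with a Poisson/exponential lapse process that
// freezes u, and a re-centering pause (u = 0) for one delay period after
// task start and after every crash reset.
//
// mode 0: continuous phase -- lambda fixed, run n_max steps.
// mode 1: calibration -- lambda ramps linearly; on crash lambda is reset to
//         reset_fraction * crash lambda; stop after n_crashes_target crashes.
//
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed() on the R side; noise-free parameter settings consume no
// random numbers and are fully deterministic.
// [[Rcpp::export]]
List cst_engine_cpp(const int mode, const int n_max, const double dt,
                    const double lambda0, const double ramp_rate,
                    const double crash_fraction, const double reset_fraction,
                    const int n_crashes_target, const double control_sign,
                    const double gain, const int delay_samples,
                    const double motor_noise_sd, const double lapse_rate_hz,
                    const double lapse_duration_s, const double disturbance_sd,
                    const double x0) {
  std::vector<double> xs, us, lams;
  std::vector<int> flags, crash_idx;
  std::vector<double> crash_lam, crash_t;
  xs.reserve(n_max); us.reserve(n_max); lams.reserve(n_max); flags.reserve(n_max);

  double x = x0, lam = lambda0, u_prev = 0.0, lapse_left = 0.0;
  int pause_left = delay_samples;  // percept not yet available at task start
  const double p_lapse = (lapse_rate_hz > 0.0) ? -std::expm1(-lapse_rate_hz * dt) : 0.0;
  int n_crashes = 0;

  for (int n = 0; n < n_max; ++n) {
    xs.push_back(x);
    lams.push_back(lam);

    // controller
    double u;
    if (lapse_left > 0.0) {              // attentional lapse: control freeze
      u = u_prev;
      lapse_left -= dt;
    } else if (p_lapse > 0.0 && unif_rand() < p_lapse) {
      lapse_left = R::rexp(lapse_duration_s) - dt;
      u = (n == 0) ? 0.0 : u_prev;
    } else if (pause_left > 0) {         // re-centering after start/reset
      u = 0.0;
      --pause_left;
    } else {
      const double xd = xs[n - delay_samples];
      double corr = -gain * xd;  // corrective displacement, mirrored sign
      if (motor_noise_sd > 0.0) corr += R::rnorm(0.0, motor_noise_sd);
      u = control_sign * corr;
    }
    if (u > 1.0) u = 1.0;
    if (u < -1.0) u = -1.0;
    u_prev = u;
    us.push_back(u);

    // crash check on the current state
    const bool crashed = std::fabs(x) >= crash_fraction;
    flags.push_back(crashed ? 1 : 0);

    if (crashed) {
      ++n_crashes;
      crash_idx.push_back(n + 1);        // 1-based sample index
      crash_lam.push_back(lam);
      crash_t.push_back(n * dt);
      if (mode == 1 && n_crashes >= n_crashes_target) break;
      x = x0;
      pause_left = delay_samples;
      if (mode == 1) lam *= reset_fraction;  // no ramp increment on the reset step
    } else {
      x += dt * lam * (x + control_sign * u);
      if (disturbance_sd > 0.0) x += R::rnorm(0.0, disturbance_sd);
      if (x > 1.0) x = 1.0;
      if (x < -1.0) x = -1.0;
      if (mode == 1) lam += ramp_rate * dt;
    }
  }

  const bool timeout = (mode == 1) && (n_crashes < n_crashes_target);
  return List::create(
    _["stim_x"] = wrap(xs), _["user_x"] = wrap(us), _["lambda_val"] = wrap(lams),
    _["crash_flag"] = wrap(flags), _["crash_index"] = wrap(crash_idx),
    _["crash_lambda"] = wrap(crash_lam), _["crash_time_s"] = wrap(crash_t),
    _["timeout"] = timeout);
}
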