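#' @useDynLib rhythmevo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' FitzHugh-Nagumo oscillator parameters
#'
#' Parameter set for the noise-driven FitzHugh-Nagumo relaxation oscillator
#' used as the phenomenological generator of ultradian activity series:
#' \deqn{dv = (v - v^3/3 - w + I)\,dt/\tau + \sigma\,dW,\quad
#'       dw = \epsilon (v + a - b w)\,dt/\tau}
#' with stochastic forcing on the activation variable \eqn{v} only. One model
#' time unit corresponds to `tau_s` seconds, so `tau_s` rescales the
#' oscillation period without changing the limit-cycle shape.
#'
#' @param epsilon timescale separation between activation and recovery
#'   (dimensionless, > 0). Smaller values give more relaxation-like
#'   (sharp-burst) oscillations.
#' @param a recovery offset (dimensionless).
#' @param b recovery gain (dimensionless).
#' @param drive constant input current \eqn{I} (dimensionless). With the
#'   defaults, `drive = 0.5` sits in the oscillatory regime and `drive = 0`
#'   in the excitable (sub-threshold) regime where noise kicks out
#'   irregular bursts.
#' @param noise_sd standard deviation of the stochastic forcing per unit
#'   square-root model time (>= 0; 0 gives the deterministic system).
#' @param obs_noise_sd standard deviation of additive observation noise
#'   applied to the sampled, unit-rescaled activity signal (>= 0). The noise
#'   is temporally correlated on the minute scale (white noise low-pass
#'   filtered with the same 15-point Gaussian kernel the metric pipeline
#'   uses, then scaled to this sd), emulating segmentation jitter and
#'   lighting drift in image-derived activity. It is the main control of the
#'   coherence factor: broadband, so it lowers rhythmicity without
#'   displacing the dominant period, and correlated, so it is not removed by
#'   the pipeline's smoothing.
#' @param tau_s seconds per model time unit (default 60: model time in
#'   minutes). The classic parameterization oscillates with a period of about
#'   36 model time units, i.e. ~36 min at the default.
#' @param dt_s integration step in seconds (default 1).
#' @param burn_in_s transient discarded before sampling, in seconds.
#' @return a list of class `fhn_params`.
#' @seealso [simulate_fhn_series()], [fhn_presets()]
#' @export
fhn_params <- function(epsilon = 0.08, a = 0.7, b = 0.8, drive = 0.5,
                       noise_sd = 0, obs_noise_sd = 0, tau_s = 60, dt_s = 1,
                       burn_in_s = 3600) {
  stopifnot(epsilon > 0, dt_s > 0, noise_sd >= 0, obs_noise_sd >= 0,
            burn_in_s >= 0, tau_s > 0)
  structure(list(epsilon = epsilon, a = a, b = b, drive = drive,
                 noise_sd = noise_sd, obs_noise_sd = obs_noise_sd,
                 tau_s = tau_s, dt_s = dt_s, burn_in_s = burn_in_s),
            class = "fhn_params")
}

#' Simulate an activity series from a noise-driven FitzHugh-Nagumo oscillator
#'
#' Integrates the stochastic FitzHugh-Nagumo system by Euler-Maruyama at step
#' `dt_s`, discards the burn-in transient, keeps the activation variable at
#' every `sample_interval_s`, and rescales the result to the unit interval
#' (the convention used for all activity series in the package). A series
#' whose raw range is numerically negligible (the deterministic system at a
#' stable fixed point) is returned shifted to its minimum but not stretched.
#'
#' @param params an [fhn_params()] object.
#' @param duration_s recording length in seconds (after burn-in).
#' @param sample_interval_s sampling interval in seconds (>= `dt_s`; default
#'   30 as in the study design).
#' @param seed integer RNG seed; identical `(params, seed)` give identical
#'   output.
#' @param level,species,colony_id,individual_id,series_id metadata passed to
#'   [activity_series()].
#' @return an [activity_series()] with `source = "synthetic"`.
#' @examples
#' s <- simulate_fhn_series(fhn_params(), duration_s = 4 * 3600, seed = 1)
#' range(s$values)
#' @export
simulate_fhn_series <- function(params, duration_s,
                                sample_interval_s = 30, seed = 1L,
                                level = "colony", species = NA_character_,
                                colony_id = NA_character_,
                                individual_id = NA_character_,
                                series_id = "fhn") {
  stopifnot(inherits(params, "fhn_params"))
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (sample_interval_s < params$dt_s)
    stop("sample_interval_s must be >= dt_s", call. = FALSE)
  thin <- round(sample_interval_s / params$dt_s)
  if (abs(thin * params$dt_s - sample_interval_s) > 1e-9)
    stop("sample_interval_s must be an integer multiple of dt_s",
         call. = FALSE)
  n_burn <- ceiling(params$burn_in_s / params$dt_s)
  n_keep <- floor(duration_s / sample_interval_s)
  n_steps <- n_burn + n_keep * thin
  dt_model <- params$dt_s / params$tau_s
  set.seed(seed)
  v <- .fhn_integrate(n_steps, dt_model, params$epsilon, params$a, params$b,
                      params$drive, params$noise_sd, v0 = -1, w0 = 1)
  v <- v[n_burn + thin * seq_len(n_keep)]
  unit <- function(x) {
    rng <- range(x)
    span <- rng[2] - rng[1]
    if (span > 1e-8 * max(1, abs(rng[2]))) (x - rng[1]) / span else x - rng[1]
  }
  v <- unit(v)
  if (params$obs_noise_sd > 0) {
    e <- as.numeric(stats::filter(stats::rnorm(n_keep), .gauss_kernel(15L),
                                  circular = TRUE))
    v <- unit(v + e / stats::sd(e) * params$obs_noise_sd)
  }
  activity_series(v, sample_interval_s = sample_interval_s, level = level,
                  species = species, colony_id = colony_id,
                  individual_id = individual_id, source = "synthetic",
                  series_id = series_id)
}

# Self-calibration of the oscillator's period against process noise: the
# stochastic forcing shortens the effective oscillation period (noise kicks
# the trajectory over the excitation threshold early). Median dominant period
# in model time units, measured from the generator itself (30 realizations
# per knot, 8.5 h records at 30 s sampling, tau_s = 60); model-time dynamics
# do not depend on tau_s, so the table applies at any time scaling.
.fhn_period_knots <- data.frame(
  noise = c(0.05, 0.08, 0.12, 0.18, 0.27, 0.40, 0.60, 0.90, 1.35, 1.60,
            2.00, 2.60),
  period = c(40.32, 40.32, 38.05, 38.05, 36.99, 33.90, 30.20, 26.91, 25.40,
             25.40, 28.51, 39.19))

# expected dominant period (model time units) at a given process-noise level;
# log-log interpolation, flat beyond the calibrated range
.fhn_expected_period <- function(noise_sd) {
  exp(stats::approx(log(.fhn_period_knots$noise),
                    log(.fhn_period_knots$period),
                    xout = log(max(noise_sd, 1e-6)), rule = 2)$y)
}

#' Oscillator presets spanning the rhythm phenospace corners
#'
#' Four parameter sets spanning the corners of the (rhythmicity, period)
#' phenospace: strongly rhythmic vs. noise-dominated crossed with short
#' (~20 min) vs. long (~80 min) dominant period. Rhythmicity is controlled by
#' the process-noise level (strong stochastic forcing makes burst timing
#' irregular), period by the time-unit scaling `tau_s`, chosen per preset so
#' the noise-induced period shortening is compensated and the two rhythmicity
#' levels share the same target periods.
#'
#' @return named list of [fhn_params()] objects: `high_beta_short`,
#'   `high_beta_long`, `low_beta_short`, `low_beta_long`.
#' @export
fhn_presets <- function() {
  tau_for <- function(period_min, noise)
    60 * period_min / .fhn_expected_period(noise)
  list(
    high_beta_short = fhn_params(noise_sd = 0.05, tau_s = tau_for(20, 0.05)),
    high_beta_long  = fhn_params(noise_sd = 0.05, tau_s = tau_for(80, 0.05)),
    low_beta_short  = fhn_params(noise_sd = 1.2, tau_s = tau_for(20, 1.2)),
    low_beta_long   = fhn_params(noise_sd = 1.2, tau_s = tau_for(80, 1.2))
  )
}
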