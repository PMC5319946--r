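#' Locomotion profile for the trajectory emission model
#'
#' Parameters of the biased correlated random walk standing in for a real
#' rat: mean movement speed, a unitless preference weight for the
#' inner/open region (1 = neutral, larger values pull the walk toward the
#' preferred region, values below 1 push it away), a rearing event rate,
#' and the tracking system's sampling interval.
#'
#' @param mean_speed cm/s (>= 0).
#' @param inner_zone_bias preference weight in `[0, Inf)`; internally
#'   capped to `[1e-8, 1e8]`.
#' @param rearing_rate rearing events per minute (>= 0).
#' @param dt sampling interval in s (0 < dt <= duration).
#' @param duration trial duration in s (default 300).
#' @return object of class `locomotion_profile`.
#' @export
locomotion_profile <- function(mean_speed, inner_zone_bias = 1, rearing_rate = 0,
                               dt = 0.1, duration = 300) {
  check_number(mean_speed, "mean_speed", lower = 0)
  check_number(inner_zone_bias, "inner_zone_bias", lower = 0)
  check_number(rearing_rate, "rearing_rate", lower = 0)
  check_number(duration, "duration", lower = 1e-9)
  check_number(dt, "dt", lower = 1e-9, upper = duration)
  structure(list(mean_speed = mean_speed,
                 inner_zone_bias = min(max(inner_zone_bias, 1e-8), 1e8),
                 rearing_rate = rearing_rate, dt = dt, duration = duration),
            class = "locomotion_profile")
}

# shape of the multiplicative gamma noise on step lengths (cv = 1/3)
SPEED_SHAPE <- 9

#' Simulate a single-trial trajectory
#'
#' Open field: a biased correlated random walk with radially reflecting
#' boundaries; the heading is blended toward (or away from) the arena
#' centre with gain `tanh(0.4 * log(inner_zone_bias))`, so bias 1 is an
#' unbiased walk and the large-bias limit parks the animal in the inner
#' zone.  EPM: the walk is specialised to the corridor geometry as a
#' skeleton walk along the arm axes; at the centre the next arm is chosen
#' with odds `inner_zone_bias : 1` per open vs closed arm.  Step lengths
#' carry multiplicative gamma noise with mean `mean_speed * dt`, so the
#' realised mean speed matches the profile.  A Poisson rearing count
#' (`rearing_rate` events/min) is attached as attribute `rearing_count`.
#'
#' @param arena an [of_arena()] or [epm_arena()].
#' @param profile a [locomotion_profile()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return a [trajectory()] with `floor(duration/dt) + 1` samples, all
#'   inside the arena.
#' @export
simulate_trajectory <- function(arena, profile, seed = NULL) {
  stopifnot(inherits(arena, "arena"), inherits(profile, "locomotion_profile"))
  with_seed(seed, {
    n <- floor(profile$duration / profile$dt)
    times <- seq(0, by = profile$dt, length.out = n + 1)
    if (arena$kind == "open_field") {
      step <- if (profile$mean_speed > 0)
        profile$mean_speed * profile$dt * rgamma(n, SPEED_SHAPE, SPEED_SHAPE)
      else rep(0, n)
      gain <- tanh(0.4 * log(profile$inner_zone_bias))
      pos <- crw_walk_cpp(n, 0, 0, runif(1, 0, 2 * pi), step,
                          turn_sd = 1.1 * sqrt(profile$dt), bias_gain = gain,
                          r_min = 0, r_max = arena$outer_radius)
      tr <- trajectory(times, pos[, 1], pos[, 2], arena, duration = profile$duration)
    } else {
      tr <- epm_skeleton_walk(arena, profile)
    }
    attr(tr, "rearing_count") <- rpois(1, profile$rearing_rate * profile$duration / 60)
    tr
  })
}

# Skeleton walk: the rat moves along the arm axes, choosing at the centre
# an arm with odds bias:1 (open:closed), walks out to a random depth and
# returns.  Waypoints are then sampled onto the dt grid.
epm_skeleton_walk <- function(arena, profile) {
  dt <- profile$dt; dur <- profile$duration
  n <- floor(dur / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  if (profile$mean_speed <= 0)
    return(trajectory(times, rep(0, n + 1), rep(0, n + 1), arena, duration = dur))
  h <- arena$arm_width / 2
  axes <- list(open1 = c(1, 0), open2 = c(-1, 0), closed1 = c(0, 1), closed2 = c(0, -1))
  b <- profile$inner_zone_bias
  w_arm <- c(b, b, 1, 1) / (2 * b + 2)
  wt <- c(0); wx <- c(0); wy <- c(0)
  t_now <- 0
  while (t_now < dur) {
    ax <- axes[[sample.int(4, 1, prob = w_arm)]]
    depth <- runif(1, h + 0.2 * arena$arm_length, h + 0.95 * arena$arm_length)
    # constant speed: per-visit speed noise would bias the realised mean
    # speed (slow visits last longer) toward the harmonic mean
    v <- profile$mean_speed
    leg <- depth / v
    wt <- c(wt, t_now + leg, t_now + 2 * leg)
    wx <- c(wx, ax[1] * depth, 0)
    wy <- c(wy, ax[2] * depth, 0)
    t_now <- t_now + 2 * leg
  }
  x <- stats::approx(wt, wx, xout = times, rule = 2)$y
  y <- stats::approx(wt, wy, xout = times, rule = 2)$y
  trajectory(times, x, y, arena, duration = dur)
}

#' Simulate a two-bottle drinking observation
#'
#' Inverse of the sucrose-preference formula: splits a total intake into
#' sucrose and water consumptions according to a true preference, each with
#' additive Gaussian measurement noise.  Masses pushed below zero by noise
#' are clamped to 0 (a bottle cannot gain weight) and flagged.
#'
#' @param true_preference fraction in (0, 1).
#' @param total_intake total g drunk (> 0).
#' @param noise_sd measurement noise sd in g.
#' @param seed integer seed or `NULL`.
#' @return list with `sucrose_consumed`, `water_consumed` (g, >= 0) and
#'   `clamped` (logical).
#' @export
simulate_drinking <- function(true_preference, total_intake, noise_sd = 0.5, seed = NULL) {
  check_number(true_preference, "true_preference", lower = 1e-12, upper = 1 - 1e-12)
  check_number(total_intake, "total_intake", lower = 1e-12)
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    s <- true_preference * total_intake + rnorm(1, 0, noise_sd)
    w <- (1 - true_preference) * total_intake + rnorm(1, 0, noise_sd)
    clamped <- s < 0 || w < 0
    list(sucrose_consumed = max(s, 0), water_consumed = max(w, 0), clamped = clamped)
  })
}

#' Simulate a von Frey response series
#'
#' Logistic response model around a true threshold: the positive-response
#' probability at an applied force `f` is
#' `plogis(slope * log(f / true_threshold))`, which is exactly 0.5 at the
#' true threshold and increases with force.  `slope = Inf` gives the step
#' responder (positive iff `f >= true_threshold`).  Each force in
#' `force_set` is applied `n_applications_per_force` times, in the given
#' (descending, per the filament protocol) order.
#'
#' @param true_threshold g (> 0).
#' @param force_set filament forces in g.
#' @param n_applications_per_force applications per filament.
#' @param slope unitless logistic steepness on the log-force scale.
#' @param seed integer seed or `NULL`.
#' @return a [von_frey_series()].
#' @export
simulate_von_frey <- function(true_threshold, force_set = c(15, 10, 8, 6, 4, 2),
                              n_applications_per_force = 5, slope = 8, seed = NULL) {
  check_number(true_threshold, "true_threshold", lower = 1e-12)
  if (length(force_set) == 0) abort_validation("force_set must be nonempty")
  check_number(n_applications_per_force, "n_applications_per_force", lower = 1, integer = TRUE)
  with_seed(seed, {
    forces <- rep(force_set, each = n_applications_per_force)
    p <- if (is.infinite(slope)) as.numeric(forces >= true_threshold)
         else plogis(slope * log(forces / true_threshold))
    von_frey_series(forces, rbinom(length(forces), 1, p) == 1, force_set = force_set)
  })
}
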