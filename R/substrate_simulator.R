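## Monte-Carlo random-walk PGSE synthesis. Internal units: um, ms,
## um^2/ms, mT/m. Phase: gamma * G . x integrated over both pulses with
## alternating sign; scale factor 1e-12 maps (mT/m * um * ms) to SI.
PHASE_SCALE <- GAMMA_H * 1e-12

#' Define a diffusion substrate
#'
#' A substrate is a mixture of sphere / stick / tensor components with
#' signal fractions summing to 1; the synthetic ground truth for the
#' resolution experiments.
#'
#' @param components list of component lists, each with `kind`
#'   ("sphere", "stick" or "tensor"), `fraction`, and geometry: `radius`
#'   (um) and `diffusivity` for spheres, `diffusivity` for sticks,
#'   `eigenvalues` = c(D_par, D_perp) (um^2/ms) for tensors.
#' @return an object of class `sandi_substrate`.
#' @export
substrate <- function(components) {
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (any(fr < 0)) stop("component fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("component fractions must sum to 1")
  kinds <- vapply(components, `[[`, character(1), "kind")
  if (!all(kinds %in% c("sphere", "stick", "tensor"))) {
    stop("component kind must be sphere, stick or tensor")
  }
  structure(list(components = components), class = "sandi_substrate")
}

#' Monte-Carlo walker configuration
#'
#' @param n_walkers number of random walkers (>= 1000 for oracle use).
#' @param steps_per_delta number of time steps per gradient pulse
#'   duration; the step duration is `delta / steps_per_delta`.
#' @param rng_seed integer seed.
#' @return an object of class `walker_config`.
#' @export
walker_config <- function(n_walkers = 1e5, steps_per_delta = 20,
                          rng_seed = 1L) {
  if (n_walkers < 1) stop("n_walkers must be positive")
  if (steps_per_delta < 10) stop("steps_per_delta must be >= 10")
  structure(list(n_walkers = as.integer(n_walkers),
                 steps_per_delta = as.integer(steps_per_delta),
                 rng_seed = as.integer(rng_seed)),
            class = "walker_config")
}

## signed fraction of [t0, t0+dt] covered by the two gradient pulses
pulse_weights <- function(times, dt, delta, Delta) {
  ov <- function(a, b) pmax(0, pmin(times + dt, b) - pmax(times, a))
  (ov(0, delta) - ov(Delta, Delta + delta)) / dt
}

## common walk harness: returns per-measurement signal + SE given a
## function producing per-walker phase integrals for unit gradient
mc_signal_from_integrals <- function(scheme, phase_int) {
  m <- scheme$measurements
  n <- nrow(phase_int$I)
  sig <- numeric(nrow(m))
  se <- numeric(nrow(m))
  dirs <- as.matrix(m[, c("gx", "gy", "gz")])
  for (i in seq_len(nrow(m))) {
    if (m$G[i] == 0 || m$b[i] <= scheme$shell_tolerance) {
      sig[i] <- 1
      se[i] <- 0
      next
    }
    phi <- PHASE_SCALE * m$G[i] * (phase_int$I %*% dirs[i, ])
    cphi <- cos(phi)
    sig[i] <- mean(cphi)
    se[i] <- stats::sd(cphi) / sqrt(n)
  }
  list(signal = sig, se = se)
}

#' Monte-Carlo PGSE signal of spins in a reflecting sphere
#'
#' Random walkers start uniformly inside an impermeable sphere and
#' reflect specularly at the wall (with sub-step splitting); the signal
#' is the ensemble average of \eqn{\cos\phi} with the phase accumulated
#' over both gradient pulses. Serves as the independent oracle for
#' [sphere_gpd_signal()].
#'
#' @param R sphere radius (um).
#' @param D diffusivity (um^2/ms).
#' @param scheme a `sandi_scheme` (all measurements must share timings).
#' @param config a `walker_config`.
#' @param adaptive refine the time step so that the RMS step length
#'   stays below R/5 (default); with `adaptive = FALSE` the configured
#'   step is used as-is and a discretisation warning is raised when the
#'   step length exceeds R/5.
#' @return list with `signal` and `se` (standard error), one entry per
#'   measurement.
#' @export
mc_sphere_signal <- function(R, D, scheme, config = walker_config(),
                             adaptive = TRUE) {
  stopifnot(inherits(scheme, "sandi_scheme"),
            inherits(config, "walker_config"))
  delta <- scheme$measurements$delta[1]
  Delta <- scheme$measurements$Delta[1]
  dt <- delta / config$steps_per_delta
  dt_wall <- (R / 5)^2 / (6 * D)
  if (adaptive) {
    dt <- min(dt, dt_wall)
  } else if (dt > dt_wall) {
    warning("MC step length exceeds R/5; refine steps_per_delta")
  }
  T_total <- Delta + delta
  n_steps <- ceiling(T_total / dt)
  times <- (seq_len(n_steps) - 1) * dt
  w <- pulse_weights(times, dt, delta, Delta)
  I <- with_seed(config$rng_seed,
                 mc_sphere_integrals_cpp(config$n_walkers, R, D, dt, w))
  out <- mc_signal_from_integrals(scheme, list(I = I))
  out$max_radius <- attr(I, "max_radius")
  out
}

#' Monte-Carlo PGSE signal of a powder of sticks
#'
#' One-dimensional free diffusion along per-walker random orientations
#' (uniform on the sphere); the direction-averaged value converges to
#' [stick_powder_signal()].
#'
#' @param D diffusivity along the stick (um^2/ms).
#' @inheritParams mc_sphere_signal
#' @return list with `signal` and `se` per measurement.
#' @export
mc_stick_signal <- function(D, scheme, config = walker_config()) {
  stopifnot(inherits(scheme, "sandi_scheme"),
            inherits(config, "walker_config"))
  delta <- scheme$measurements$delta[1]
  Delta <- scheme$measurements$Delta[1]
  dt <- delta / config$steps_per_delta
  T_total <- Delta + delta
  n_steps <- ceiling(T_total / dt)
  times <- (seq_len(n_steps) - 1) * dt
  w <- pulse_weights(times, dt, delta, Delta)
  I <- with_seed(config$rng_seed,
                 mc_stick_integrals_cpp(config$n_walkers, D, dt, w))
  mc_signal_from_integrals(scheme, list(I = I))
}

## noiseless per-measurement expectation of one component
component_signal <- function(comp, scheme, sphere_mode, config) {
  m <- scheme$measurements
  b0 <- m$b <= scheme$shell_tolerance
  out <- numeric(nrow(m))
  if (comp$kind == "sphere") {
    if (sphere_mode == "mc") {
      out <- mc_sphere_signal(comp$radius, comp$diffusivity, scheme,
                              config)$signal
    } else {
      for (i in seq_len(nrow(m))) {
        out[i] <- if (b0[i]) 1 else
          sphere_gpd_signal(m$G[i], m$delta[i], m$Delta[i],
                            comp$radius, comp$diffusivity)
      }
    }
  } else if (comp$kind == "stick") {
    out <- ifelse(b0, 1, stick_powder_signal(m$b, comp$diffusivity))
  } else {                          # tensor
    ev <- comp$eigenvalues
    out <- ifelse(b0, 1,
                  zeppelin_powder_signal(m$b, ev[1], ev[2]))
  }
  out
}

#' Simulate the noisy PGSE signal of a substrate
#'
#' Fraction-weighted sum of the per-measurement component signals
#' (analytic for stick/tensor; analytic or Monte-Carlo for spheres),
#' followed by per-measurement Rician noise. Powder substrates are
#' isotropic ensembles, so the per-measurement expectation equals the
#' powder average at that measurement's b.
#'
#' @param sub a `sandi_substrate`.
#' @param scheme a `sandi_scheme`.
#' @param noise a `noise_model`, or NULL for a noiseless signal.
#' @param seed integer seed for the noise draw.
#' @param sphere_mode "analytic" (default) or "mc".
#' @param config a `walker_config` used when `sphere_mode = "mc"`.
#' @return per-measurement signal vector.
#' @export
simulate_substrate_signal <- function(sub, scheme, noise = NULL, seed = 1L,
                                      sphere_mode = c("analytic", "mc"),
                                      config = walker_config()) {
  stopifnot(inherits(sub, "sandi_substrate"))
  sphere_mode <- match.arg(sphere_mode)
  sig <- numeric(nrow(scheme$measurements))
  for (comp in sub$components) {
    sig <- sig + comp$fraction *
      component_signal(comp, scheme, sphere_mode, config)
  }
  if (!is.null(noise)) sig <- add_rician_noise(sig, noise, rng_seed = seed)
  sig
}

#' Export per-measurement signals as CSV
#'
#' Writes a two-column table (`measurement`, `signal`) keyed by the
#' scheme line number.
#'
#' @param signals numeric vector.
#' @param path output path.
#' @export
export_signals_csv <- function(signals, path) {
  utils::write.csv(data.frame(measurement = seq_along(signals),
                              signal = signals),
                   path, row.names = FALSE)
  invisible(NULL)
}
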