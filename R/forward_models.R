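## Unit conventions, used throughout:
##   b in s/mm^2, diffusivities in um^2/ms, radii in um, timings in ms,
##   gradients in mT/m. The dimensionless product bD is b*D*1e-3.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

bd_product <- function(b, D) b * D * 1e-3

#' SANDI tissue parameters
#'
#' Ground-truth or fitted parameter set of the three-compartment SANDI
#' model: intra-neurite (sticks), intra-soma (spheres) and extra-cellular
#' (Gaussian) signal fractions, their diffusivities and the soma radius.
#'
#' @param f_neurite,f_soma,f_extra signal fractions; must be non-negative
#'   and sum to 1.
#' @param D_in intra-neurite diffusivity (um^2/ms).
#' @param D_is intra-soma diffusivity (um^2/ms).
#' @param D_ec extra-cellular diffusivity: a single isotropic value or a
#'   length-2 vector (D_par, D_perp) for a zeppelin (um^2/ms).
#' @param R_s soma radius (um).
#' @return an object of class `sandi_parameters`.
#' @export
sandi_parameters <- function(f_neurite, f_soma, f_extra,
                             D_in = 2.4, D_is = 3.0, D_ec = 3.0, R_s = 8) {
  fr <- c(f_neurite, f_soma, f_extra)
  if (any(fr < 0)) stop("signal fractions must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("signal fractions must sum to 1")
  if (any(c(D_in, D_is, D_ec) <= 0) || any(c(D_in, D_is, D_ec) > 3.0)) {
    stop("diffusivities must lie in (0, 3] um^2/ms")
  }
  if (R_s <= 0 || R_s > 20) stop("R_s must lie in (0, 20] um")
  if (!length(D_ec) %in% 1:2) stop("D_ec must have length 1 or 2")
  structure(list(f_neurite = f_neurite, f_soma = f_soma, f_extra = f_extra,
                 D_in = D_in, D_is = D_is, D_ec = D_ec, R_s = R_s),
            class = "sandi_parameters")
}

#' Rician noise model
#'
#' @param snr signal-to-noise ratio at b = 0 (dimensionless).
#' @param S0 noise-free b = 0 signal level; the Gaussian channel standard
#'   deviation is `S0 / snr`.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(snr, S0 = 1) {
  if (snr <= 0) stop("snr must be positive")
  structure(list(snr = snr, sigma = S0 / snr), class = "noise_model")
}

#' Powder-averaged stick signal
#'
#' Direction average of the zero-radius cylinder ("stick") compartment,
#' \eqn{\bar A = \sqrt{\pi/(4 b D)}\,\mathrm{erf}(\sqrt{b D})}; the
#' standard model for neurites.
#'
#' @param b b-value (s/mm^2); vectorised.
#' @param D diffusivity along the stick (um^2/ms).
#' @return normalised signal in (0, 1].
#' @export
stick_powder_signal <- function(b, D) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(D <= 0)) stop("D must be positive")
  x <- bd_product(b, D)
  out <- ifelse(x < 1e-12, 1, sqrt(pi / (4 * pmax(x, 1e-12))) * erf(sqrt(x)))
  out
}

#' Isotropic Gaussian ("ball") signal
#'
#' @param b b-value (s/mm^2); vectorised.
#' @param D diffusivity (um^2/ms).
#' @return `exp(-bD)`.
#' @export
ball_signal <- function(b, D) {
  if (any(b < 0) || any(D < 0)) stop("b and D must be non-negative")
  exp(-bd_product(b, D))
}

#' Powder-averaged zeppelin (axially symmetric tensor) signal
#'
#' Direction average of an axially symmetric Gaussian tensor:
#' \eqn{e^{-b D_\perp}} times the stick average at \eqn{b (D_\parallel -
#' D_\perp)}. Reduces to the ball at \eqn{D_\parallel = D_\perp} and to
#' the stick at \eqn{D_\perp = 0}.
#'
#' @param b b-value (s/mm^2); vectorised.
#' @param D_par,D_perp parallel and perpendicular diffusivities
#'   (um^2/ms), `D_par >= D_perp >= 0`.
#' @return normalised signal in (0, 1].
#' @export
zeppelin_powder_signal <- function(b, D_par, D_perp) {
  if (D_par < D_perp) stop("D_par must be >= D_perp")
  if (D_perp < 0) stop("D_perp must be non-negative")
  dd <- D_par - D_perp
  if (dd < 1e-12) return(ball_signal(b, D_par))
  exp(-bd_product(b, D_perp)) * stick_powder_signal(b, dd)
}

## cache for the roots a_m of d/dx j_1(x) = 0
.sandir_cache <- new.env(parent = emptyenv())

#' Roots of the derivative of the first spherical Bessel function
#'
#' Successive positive solutions of \eqn{j_1'(x) = 0}, i.e. of
#' \eqn{(x^2 - 2)\sin x + 2x\cos x = 0}; these set the eigenmodes of
#' diffusion restricted in a reflecting sphere. Cached after the first
#' call.
#'
#' @param m number of roots.
#' @return numeric vector of the first `m` roots (first is about 2.0816).
#' @export
sphere_bessel_roots <- function(m = 20) {
  key <- "j1prime_roots"
  have <- .sandir_cache[[key]]
  if (is.null(have) || length(have) < m) {
    g <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
    xs <- seq(1, 10 + 4 * m, by = 0.05)
    gs <- g(xs)
    sgn <- which(gs[-1] * gs[-length(gs)] < 0)
    roots <- vapply(sgn, function(i) {
      stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root
    }, numeric(1))
    .sandir_cache[[key]] <- roots
    have <- roots
  }
  have[seq_len(m)]
}

#' Restricted-diffusion signal in a sphere (GPD approximation)
#'
#' Gaussian-phase-distribution expression (Murday-Cotts/Balinov) for the
#' PGSE signal of spins diffusing inside an impermeable reflecting
#' sphere; the soma compartment of SANDI. The signal is isotropic, so it
#' equals its own powder average.
#'
#' @param G gradient amplitude (mT/m); vectorised.
#' @param delta,Delta pulse timings (ms).
#' @param R sphere radius (um).
#' @param D_is intra-sphere diffusivity (um^2/ms).
#' @param m_roots number of series terms.
#' @param tol relative size of the last retained term above which a
#'   precision warning is raised.
#' @return normalised signal in (0, 1].
#' @export
sphere_gpd_signal <- function(G, delta, Delta, R, D_is,
                              m_roots = 20, tol = 1e-5) {
  if (any(G < 0)) stop("G must be non-negative")
  if (delta <= 0 || Delta < delta || R <= 0 || D_is <= 0) {
    stop("delta, Delta, R, D_is must be positive with Delta >= delta")
  }
  a <- sphere_bessel_roots(m_roots)
  R_si <- R * 1e-6            # m
  D_si <- D_is * 1e-9         # m^2/s
  d_si <- delta * 1e-3        # s
  Dl_si <- Delta * 1e-3
  al <- a / R_si              # 1/m
  Da2 <- D_si * al^2          # 1/s
  num <- 2 * Da2 * d_si - 2 +
    2 * exp(-Da2 * d_si) + 2 * exp(-Da2 * Dl_si) -
    exp(-Da2 * (Dl_si - d_si)) - exp(-Da2 * (Dl_si + d_si))
  den <- D_si^2 * al^6 * (R_si^2 * al^2 - 2)
  terms <- num / den          # units m^2 s^2? -> multiplied by gamma^2 G^2
  ssum <- sum(terms)
  if (abs(terms[length(terms)]) > tol * abs(ssum)) {
    warning("GPD series truncation: last term above tolerance")
  }
  G_si <- G * 1e-3            # T/m
  lnS <- -2 * GAMMA_H^2 * G_si^2 * ssum
  exp(lnS)
}

per_shell_G <- function(scheme, shells = group_shells(scheme)) {
  vapply(shells, function(s) mean(scheme$measurements$G[s$indices]),
         numeric(1))
}

shell_timings <- function(scheme, shells = group_shells(scheme)) {
  list(delta = vapply(shells, function(s)
         mean(scheme$measurements$delta[s$indices]), numeric(1)),
       Delta = vapply(shells, function(s)
         mean(scheme$measurements$Delta[s$indices]), numeric(1)))
}

#' Composite SANDI powder signal per shell
#'
#' Fraction-weighted sum of the powder-averaged compartment signals,
#' \eqn{\bar S/S_0 = f_{neurite}\,A_{stick} + f_{soma}\,A_{sphere} +
#' f_{extra}\,A_{ec}}, evaluated at each shell of the scheme. The
#' extra-cellular term is a ball for scalar `D_ec` and a zeppelin for a
#' (D_par, D_perp) pair.
#'
#' @param scheme a `sandi_scheme` with at least one non-zero shell.
#' @param params a `sandi_parameters`.
#' @return named numeric vector, one normalised value per shell
#'   (ascending b; 1 at the b0 shell).
#' @export
sandi_powder_signal <- function(scheme, params) {
  stopifnot(inherits(scheme, "sandi_scheme"),
            inherits(params, "sandi_parameters"))
  shells <- group_shells(scheme)
  if (length(shells) < 2) stop("scheme needs at least one non-zero shell")
  bc <- vapply(shells, `[[`, numeric(1), "b_center")
  Gc <- per_shell_G(scheme, shells)
  tm <- shell_timings(scheme, shells)
  out <- numeric(length(shells))
  for (i in seq_along(shells)) {
    if (bc[i] <= scheme$shell_tolerance) {
      out[i] <- 1
      next
    }
    sph <- sphere_gpd_signal(Gc[i], tm$delta[i], tm$Delta[i],
                             params$R_s, params$D_is)
    stk <- stick_powder_signal(bc[i], params$D_in)
    ec <- if (length(params$D_ec) == 1) {
      ball_signal(bc[i], params$D_ec)
    } else {
      zeppelin_powder_signal(bc[i], params$D_ec[1], params$D_ec[2])
    }
    out[i] <- params$f_neurite * stk + params$f_soma * sph +
      params$f_extra * ec
  }
  names(out) <- sprintf("b%.0f", bc)
  out
}

#' Add Rician noise to signals
#'
#' Replaces each value S by \eqn{\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}}
#' with independent Gaussian \eqn{\epsilon_i \sim N(0, \sigma^2)},
#' \eqn{\sigma = S_0/\mathrm{SNR}} — the magnitude-MRI noise model.
#'
#' @param signals non-negative numeric vector (per measurement).
#' @param noise a `noise_model`.
#' @param rng_seed integer seed; the same seed reproduces the same draw.
#' @return noisy signal vector of the same length.
#' @export
add_rician_noise <- function(signals, noise, rng_seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(signals < 0)) stop("signals must be non-negative")
  if (!is.finite(noise$sigma) || noise$sigma == 0) return(signals)
  with_seed(rng_seed, {
    n <- length(signals)
    e1 <- stats::rnorm(n, 0, noise$sigma)
    e2 <- stats::rnorm(n, 0, noise$sigma)
    sqrt((signals + e1)^2 + e2^2)
  })
}
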