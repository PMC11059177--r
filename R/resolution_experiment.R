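## Radius-recoverability simulation study: sweep ground-truth sphere
## radius x sphere signal fraction, fit each noisy realisation with the
## dictionary, and classify each cell by the median radius error.

#' Configuration of a resolution experiment
#'
#' @param radii ground-truth sphere radii grid (um), ascending.
#' @param fractions sphere signal fraction grid (percent), ascending;
#'   the intra+extra-cellular scenario restricts fractions to <= 50.
#' @param scenario "intra" (sphere + stick remainder) or "intra_extra"
#'   (sphere and stick at 1:1, tensor remainder).
#' @param n_reps noisy repetitions per grid cell (>= 10).
#' @param snr signal-to-noise ratio at b0 (Inf for noiseless).
#' @param tau acceptable absolute median radius error (um).
#' @param sphere_D_range range (um^2/ms) from which each repetition's
#'   substrate sphere diffusivity is drawn uniformly. The default
#'   `c(3, 3)` matches the dictionary's fixed isotropic-restricted
#'   diffusivity, so recovery errors isolate protocol resolution; a
#'   wider range (e.g. `c(0.1, 3)`) adds substrate/model mismatch as a
#'   further confounder.
#' @param seed integer master seed.
#' @return an object of class `resolution_config`.
#' @export
resolution_config <- function(radii = 1:15,
                              fractions = if (scenario == "intra_extra")
                                seq(10, 50, 10) else seq(10, 100, 10),
                              scenario = c("intra", "intra_extra"),
                              n_reps = 100, snr = 50, tau = 2,
                              sphere_D_range = c(3.0, 3.0), seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(radii) == 0 || is.unsorted(radii, strictly = TRUE)) {
    stop("radii grid must be non-empty and ascending")
  }
  if (length(fractions) == 0 || is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions grid must be non-empty and ascending")
  }
  if (tau <= 0) stop("tau must be positive")
  if (n_reps < 10) stop("n_reps must be >= 10")
  if (length(sphere_D_range) != 2 || sphere_D_range[1] > sphere_D_range[2] ||
      sphere_D_range[1] <= 0) {
    stop("sphere_D_range must be an ascending positive pair")
  }
  structure(list(radii = radii, fractions = fractions, scenario = scenario,
                 n_reps = as.integer(n_reps), snr = snr, tau = tau,
                 sphere_D_range = sphere_D_range, seed = as.integer(seed)),
            class = "resolution_config")
}

#' Build the substrate of one simulation cell
#'
#' "intra": sphere at fraction f_s, stick remainder. "intra_extra":
#' sphere and stick in equal proportion f_s each, tensor remainder
#' 1 - 2 f_s (so f_s must be <= 50%). Sphere D = 3.0, stick D = 2.4
#' um^2/ms; tensor eigenvalues (2.4, 0.8) um^2/ms.
#'
#' @param scenario "intra" or "intra_extra".
#' @param R_GT ground-truth sphere radius (um).
#' @param f_sphere sphere signal fraction in percent.
#' @param sphere_D intra-sphere diffusivity (um^2/ms).
#' @param stick_D,tensor_ev stick diffusivity and tensor eigenvalues.
#' @return a `sandi_substrate`.
#' @export
make_substrate <- function(scenario = c("intra", "intra_extra"),
                           R_GT, f_sphere, sphere_D = 3.0, stick_D = 2.4,
                           tensor_ev = c(2.4, 0.8)) {
  scenario <- match.arg(scenario)
  if (f_sphere < 0 || f_sphere > 100) stop("f_sphere must be in [0, 100]")
  fs <- f_sphere / 100
  if (scenario == "intra") {
    comps <- list(
      list(kind = "sphere", fraction = fs, radius = R_GT,
           diffusivity = sphere_D),
      list(kind = "stick", fraction = 1 - fs, diffusivity = stick_D))
  } else {
    if (fs > 0.5 + 1e-12) {
      stop("intra_extra scenario requires f_sphere <= 50%")
    }
    comps <- list(
      list(kind = "sphere", fraction = fs, radius = R_GT,
           diffusivity = sphere_D),
      list(kind = "stick", fraction = fs, diffusivity = stick_D),
      list(kind = "tensor", fraction = 1 - 2 * fs,
           eigenvalues = tensor_ev))
  }
  # drop zero-fraction components
  comps <- Filter(function(c) c$fraction > 1e-12, comps)
  substrate(comps)
}

#' Run one radius-recoverability scenario
#'
#' For each (radius, fraction) grid cell: synthesise `n_reps`
#' per-measurement substrate signals (one substrate draw per repetition,
#' with the sphere diffusivity sampled from `sphere_D_range`), add
#' per-measurement Rician noise, take the spherical mean, fit the
#' dictionary and record the median fitted soma radius. Deterministic
#' for a given seed.
#'
#' @param scheme a `sandi_scheme`.
#' @param config a `resolution_config`.
#' @param fit_cfg a `fit_config` used for the dictionary fits.
#' @return an object of class `resolution_grid`: a data.frame with one
#'   row per cell (`radius`, `fraction`, `median_R_hat`, `error`,
#'   `class`) carrying the config, scheme fingerprint and the threshold
#'   scan bound (`r_scan_max`, the largest dictionary radius) as
#'   attributes.
#' @export
run_scenario <- function(scheme, config, fit_cfg = fit_config()) {
  stopifnot(inherits(scheme, "sandi_scheme"),
            inherits(config, "resolution_config"))
  dict <- build_dictionary(scheme, fit_cfg)
  m <- scheme$measurements
  shells <- group_shells(scheme)
  shell_of <- integer(nrow(m))
  for (i in seq_along(shells)) shell_of[shells[[i]]$indices] <- i
  bc <- vapply(shells, `[[`, numeric(1), "b_center")
  Gc <- per_shell_G(scheme, shells)
  tm <- shell_timings(scheme, shells)
  dw_shell <- which(bc > scheme$shell_tolerance)
  # per-measurement stick and tensor signals are substrate-independent
  stick_meas <- ifelse(m$b <= scheme$shell_tolerance, 1,
                       stick_powder_signal(m$b, 2.4))
  tensor_meas <- ifelse(m$b <= scheme$shell_tolerance, 1,
                        zeppelin_powder_signal(m$b, 2.4, 0.8))
  cells <- expand.grid(radius = config$radii, fraction = config$fractions)
  n_cells <- nrow(cells)
  draws <- with_seed(config$seed, list(
    seeds = matrix(sample.int(.Machine$integer.max - 1,
                              n_cells * config$n_reps), nrow = n_cells),
    D_is = matrix(stats::runif(n_cells * config$n_reps,
                               config$sphere_D_range[1],
                               config$sphere_D_range[2]), nrow = n_cells)))
  nm <- if (is.finite(config$snr)) noise_model(config$snr) else NULL
  med_R <- numeric(n_cells)
  for (ci in seq_len(n_cells)) {
    R_GT <- cells$radius[ci]
    fs <- cells$fraction[ci] / 100
    w_stick <- if (config$scenario == "intra") 1 - fs else fs
    w_tensor <- if (config$scenario == "intra") 0 else 1 - 2 * fs
    if (w_tensor < -1e-12) {
      stop("intra_extra scenario requires fractions <= 50%")
    }
    base <- w_stick * stick_meas + w_tensor * tensor_meas
    Rh <- numeric(config$n_reps)
    for (r in seq_len(config$n_reps)) {
      sph_shell <- rep(1, length(shells))
      for (si in dw_shell) {
        sph_shell[si] <- sphere_gpd_signal(Gc[si], tm$delta[si],
                                           tm$Delta[si], R_GT,
                                           draws$D_is[ci, r])
      }
      clean <- base + fs * sph_shell[shell_of]
      sig <- if (is.null(nm)) clean else
        add_rician_noise(clean, nm, rng_seed = draws$seeds[ci, r])
      fit <- fit_voxel(spherical_mean(sig, scheme), dict, fit_cfg)
      Rh[r] <- fit$R_hat
    }
    med_R[ci] <- stats::median(Rh, na.rm = TRUE)
  }
  err <- med_R - cells$radius
  cls <- ifelse(is.na(err), "under",
                ifelse(err > config$tau, "over",
                       ifelse(err < -config$tau, "under", "acceptable")))
  grid <- data.frame(radius = cells$radius, fraction = cells$fraction,
                     median_R_hat = med_R, error = err, class = cls,
                     stringsAsFactors = FALSE)
  structure(grid, class = c("resolution_grid", "data.frame"),
            config = config,
            r_scan_max = max(dict$atoms$radius, na.rm = TRUE),
            scheme_fingerprint = dict$fingerprint)
}

#' Smallest radius above which recovery stays acceptable
#'
#' Returns the smallest grid radius R* such that every grid radius
#' >= R* (up to `r_max`) is classified acceptable at the given sphere
#' fraction; `Inf` when even the largest scanned radius fails. The scan
#' is bounded by the largest dictionary radius, because ground-truth
#' radii beyond the dictionary's representable range measure grid
#' truncation rather than protocol resolution.
#'
#' @param grid a `resolution_grid`.
#' @param f_s sphere fraction (percent), must be on the grid.
#' @param r_max largest ground-truth radius scanned; defaults to the
#'   grid's `r_scan_max` attribute (the maximum dictionary radius).
#' @return radius in um, or Inf.
#' @export
recovery_threshold_radius <- function(grid, f_s, r_max = NULL) {
  if (is.null(r_max)) r_max <- attr(grid, "r_scan_max")
  if (is.null(r_max)) r_max <- max(grid$radius)
  col <- grid[grid$fraction == f_s & grid$radius <= r_max, ]
  if (nrow(col) == 0) stop("fraction not on the grid")
  col <- col[order(col$radius), ]
  ok <- col$class == "acceptable"
  # last radius with a failure anywhere at or above it
  bad <- which(!ok)
  if (length(bad) == 0) return(col$radius[1])
  if (max(bad) == nrow(col)) return(Inf)
  col$radius[max(bad) + 1]
}

#' Smallest fraction above which recovery stays acceptable
#'
#' Mirror of [recovery_threshold_radius()] along the fraction axis at a
#' fixed ground-truth radius.
#'
#' @param grid a `resolution_grid`.
#' @param R_GT ground-truth radius (um), must be on the grid.
#' @return fraction in percent, or Inf.
#' @export
recovery_threshold_fraction <- function(grid, R_GT) {
  row <- grid[grid$radius == R_GT, ]
  if (nrow(row) == 0) stop("radius not on the grid")
  row <- row[order(row$fraction), ]
  ok <- row$class == "acceptable"
  bad <- which(!ok)
  if (length(bad) == 0) return(row$fraction[1])
  if (max(bad) == nrow(row)) return(Inf)
  row$fraction[max(bad) + 1]
}

#' Export a resolution grid as CSV (and optionally a heatmap)
#'
#' Writes the long-format cell table (`radius`, `fraction`,
#' `median_R_hat`, `error`, `class`); the CSV round-trips losslessly via
#' [read_grid_csv()]. When ggplot2 is available and `heatmap_path` is
#' given, also renders the signed-error heatmap.
#'
#' @param grid a `resolution_grid`.
#' @param path CSV output path.
#' @param heatmap_path optional image path (.png or .svg).
#' @export
export_grid <- function(grid, path, heatmap_path = NULL) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  if (!is.null(heatmap_path)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; heatmap skipped")
      return(invisible(NULL))
    }
    cfg <- attr(grid, "config")
    lim <- max(abs(grid$error[is.finite(grid$error)]), 1)
    p <- ggplot2::ggplot(as.data.frame(grid),
                         ggplot2::aes(x = fraction, y = radius,
                                      fill = error)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                    high = "red", limits = c(-lim, lim),
                                    name = "median error (um)") +
      ggplot2::labs(x = "sphere signal fraction (%)",
                    y = "ground-truth radius (um)",
                    title = sprintf("Radius recovery (%s)",
                                    if (is.null(cfg)) "" else cfg$scenario))
    ggplot2::ggsave(heatmap_path, p, width = 6, height = 5, dpi = 150)
  }
  invisible(NULL)
}

#' Read a resolution grid CSV written by [export_grid()]
#'
#' @param path CSV path.
#' @return a `resolution_grid` data.frame (without config attributes).
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("resolution_grid", "data.frame"))
}
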