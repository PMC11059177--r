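## AMICO-style dictionary fitting: linearise the SANDI model into a
## small library of per-shell powder signals and solve a regularised
## non-negative least-squares problem per voxel.

#' Fit configuration for the dictionary inverse problem
#'
#' @param lambda_l2 Tikhonov weight, dimensionless relative to the
#'   spectral norm of the dictionary matrix.
#' @param normalize_fractions if TRUE (default) compartment fractions
#'   are weight shares summing to 1.
#' @param shell_tolerance b-value tolerance (s/mm^2) used when grouping
#'   shells.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(lambda_l2 = 1e-3, normalize_fractions = TRUE,
                       shell_tolerance = 50) {
  if (lambda_l2 < 0) stop("lambda_l2 must be non-negative")
  structure(list(lambda_l2 = lambda_l2,
                 normalize_fractions = normalize_fractions,
                 shell_tolerance = shell_tolerance),
            class = "fit_config")
}

default_sphere_radii <- function() seq(1.5, 12, length.out = 9)

#' Build the SANDI signal dictionary for a scheme
#'
#' Default composition: 1 stick (D = 2.4 um^2/ms), 9 spheres (D = 3.0
#' um^2/ms, radii equally spaced 1.5-12 um) and 3 balls (D = 0.4, 1.6,
#' 3.0 um^2/ms) — 13 atoms. The matrix holds the normalised powder
#' signal of each atom at each shell of the scheme (the b0 row is all
#' ones).
#'
#' @param scheme a `sandi_scheme` with at least 2 shells.
#' @param config a `fit_config`.
#' @param stick_D,sphere_D diffusivities of the stick and sphere atoms
#'   (um^2/ms).
#' @param sphere_radii sphere-atom radii (um).
#' @param ball_D ball-atom diffusivities (um^2/ms).
#' @return an object of class `sandi_dictionary` with `atoms` (metadata
#'   data.frame), `matrix` (shells x atoms), `b_centers` and a scheme
#'   `fingerprint`.
#' @export
build_dictionary <- function(scheme, config = fit_config(),
                             stick_D = 2.4, sphere_D = 3.0,
                             sphere_radii = default_sphere_radii(),
                             ball_D = c(0.4, 1.6, 3.0)) {
  stopifnot(inherits(scheme, "sandi_scheme"))
  shells <- group_shells(scheme)
  if (length(shells) < 2) stop("degenerate scheme: need at least 2 shells")
  bc <- vapply(shells, `[[`, numeric(1), "b_center")
  Gc <- per_shell_G(scheme, shells)
  tm <- shell_timings(scheme, shells)
  is_b0 <- bc <= scheme$shell_tolerance
  atoms <- data.frame(
    kind = c("stick", rep("sphere", length(sphere_radii)),
             rep("ball", length(ball_D))),
    radius = c(NA, sphere_radii, rep(NA, length(ball_D))),
    diffusivity = c(stick_D, rep(sphere_D, length(sphere_radii)), ball_D))
  A <- matrix(NA_real_, nrow = length(shells), ncol = nrow(atoms))
  for (j in seq_len(nrow(atoms))) {
    for (i in seq_along(shells)) {
      if (is_b0[i]) {
        A[i, j] <- 1
      } else if (atoms$kind[j] == "stick") {
        A[i, j] <- stick_powder_signal(bc[i], atoms$diffusivity[j])
      } else if (atoms$kind[j] == "sphere") {
        A[i, j] <- sphere_gpd_signal(Gc[i], tm$delta[i], tm$Delta[i],
                                     atoms$radius[j], atoms$diffusivity[j])
      } else {
        A[i, j] <- ball_signal(bc[i], atoms$diffusivity[j])
      }
    }
  }
  fp <- sprintf("%d shells | b %s | delta %.3g | Delta %.3g",
                length(shells), paste(round(bc), collapse = "/"),
                tm$delta[1], tm$Delta[1])
  structure(list(atoms = atoms, matrix = A, b_centers = bc,
                 fingerprint = fp),
            class = "sandi_dictionary")
}

#' @export
print.sandi_dictionary <- function(x, ...) {
  cat("SANDI dictionary:", nrow(x$atoms), "atoms x",
      length(x$b_centers), "shells\n")
  cat(" ", x$fingerprint, "\n")
  invisible(x)
}

#' Spherical (powder) mean of a diffusion-weighted signal
#'
#' Arithmetic mean of the per-measurement signal within each shell,
#' normalised by the mean b0 signal; the b0 shell maps to exactly 1.
#'
#' @param dwi_signals per-measurement signal vector.
#' @param scheme matching `sandi_scheme` (one measurement per entry).
#' @return per-shell normalised means, ascending b.
#' @export
spherical_mean <- function(dwi_signals, scheme) {
  stopifnot(inherits(scheme, "sandi_scheme"))
  if (length(dwi_signals) != nrow(scheme$measurements)) {
    stop("signal length does not match scheme")
  }
  shells <- group_shells(scheme)
  i0 <- b0_shell_index(scheme, shells)
  s0 <- mean(dwi_signals[shells[[i0]]$indices])
  if (!is.finite(s0) || s0 <= 0) stop("mean b0 signal must be positive")
  out <- vapply(shells, function(s) mean(dwi_signals[s$indices]) / s0,
                numeric(1))
  out[i0] <- 1
  names(out) <- sprintf("b%.0f",
                        vapply(shells, `[[`, numeric(1), "b_center"))
  out
}

#' Fit one voxel's powder signal against the dictionary
#'
#' Solves the regularised non-negative inverse problem
#' \eqn{\min_{w \ge 0} \|A w - s\|^2 + \lambda^2 \|w\|^2} (Lawson-Hanson
#' NNLS on the Tikhonov-augmented system) and summarises the atom
#' weights into compartment fractions and a soma-radius point estimate.
#'
#' @param powder per-shell powder means (length = number of shells);
#'   negative values are clamped to 0 with a warning.
#' @param dictionary a `sandi_dictionary`.
#' @param config a `fit_config`; `lambda_l2` is scaled by the spectral
#'   norm of the dictionary matrix.
#' @return an object of class `sandi_fit`: `f_soma`, `f_neurite`,
#'   `f_extra`, `R_hat` (um; NA when the sphere weight is below 1e-6),
#'   `residual_rmse`, `weights`, `converged`.
#' @export
fit_voxel <- function(powder, dictionary, config = fit_config()) {
  stopifnot(inherits(dictionary, "sandi_dictionary"))
  A <- dictionary$matrix
  if (length(powder) != nrow(A)) {
    stop("powder length does not match dictionary shell count")
  }
  if (all(powder == 0)) stop("all-zero powder signal")
  if (any(powder < 0)) {
    warning("negative powder values clamped to 0")
    powder <- pmax(powder, 0)
  }
  lam <- config$lambda_l2 * norm(A, type = "2")
  if (lam > 0) {
    Aa <- rbind(A, diag(lam, ncol(A)))
    sa <- c(powder, numeric(ncol(A)))
  } else {
    Aa <- A
    sa <- powder
  }
  sol <- tryCatch(pracma::lsqnonneg(Aa, sa),
                  error = function(e) NULL)
  converged <- !is.null(sol)
  w <- if (converged) pmax(sol$x, 0) else rep(0, ncol(A))
  kinds <- dictionary$atoms$kind
  tot <- sum(w)
  share <- function(k) if (tot > 0) sum(w[kinds == k]) / tot else NA_real_
  f_soma <- share("sphere")
  f_neurite <- share("stick")
  f_extra <- share("ball")
  R_hat <- soma_radius_estimate(w, dictionary)
  resid <- sqrt(mean((A %*% w - powder)^2))
  structure(list(f_soma = f_soma, f_neurite = f_neurite,
                 f_extra = f_extra, R_hat = R_hat,
                 residual_rmse = resid, weights = w,
                 converged = converged),
            class = "sandi_fit")
}

#' @export
print.sandi_fit <- function(x, ...) {
  cat(sprintf(
    "SANDI fit: f_soma=%.3f f_neurite=%.3f f_extra=%.3f R_hat=%s um (rmse %.2e)\n",
    x$f_soma, x$f_neurite, x$f_extra,
    ifelse(is.na(x$R_hat), "NA", sprintf("%.2f", x$R_hat)),
    x$residual_rmse))
  invisible(x)
}

#' Soma-radius point estimate from atom weights
#'
#' Weight-weighted arithmetic mean of the sphere-atom radii; NA when
#' the total sphere weight is below 1e-6.
#'
#' @param weights atom weight vector (same order as the dictionary).
#' @param dictionary a `sandi_dictionary`.
#' @return radius in um, or NA.
#' @export
soma_radius_estimate <- function(weights, dictionary) {
  sph <- dictionary$atoms$kind == "sphere"
  ws <- weights[sph]
  if (sum(ws) < 1e-6) return(NA_real_)
  sum(ws * dictionary$atoms$radius[sph]) / sum(ws)
}

#' Fit SANDI parameter maps over a masked volume
#'
#' Applies [spherical_mean()] and [fit_voxel()] to every voxel inside
#' the mask of a 4D diffusion-weighted volume.
#'
#' @param dwi 4D array (x, y, z, measurement).
#' @param mask 3D array (non-zero = fit); spatial grid must match `dwi`.
#' @param scheme matching `sandi_scheme` (length = 4th dimension).
#' @param config a `fit_config`.
#' @param dictionary optional prebuilt `sandi_dictionary`.
#' @return named list of 3D maps (`f_soma`, `f_neurite`, `f_extra`,
#'   `R_hat`, `residual`), NaN outside the mask.
#' @export
fit_volume <- function(dwi, mask, scheme, config = fit_config(),
                       dictionary = NULL) {
  dm <- dim(dwi)
  if (length(dm) != 4) stop("dwi must be a 4D array")
  # tolerate squeezed trailing singleton dimensions (e.g. single-slice
  # masks read back as 2D)
  dmk <- dim(mask)
  if (length(dmk) < 3 && all(dm[1:3][-seq_along(dmk)] == 1)) {
    dim(mask) <- c(dmk, rep(1L, 3 - length(dmk)))
  }
  if (length(dim(mask)) != 3 || !all(dim(mask) == dm[1:3])) {
    stop("mask/dwi spatial grids differ")
  }
  if (dm[4] != nrow(scheme$measurements)) {
    stop("scheme length does not match 4th dimension of dwi")
  }
  if (is.null(dictionary)) dictionary <- build_dictionary(scheme, config)
  maps <- lapply(1:5, function(i) array(NaN, dm[1:3]))
  names(maps) <- c("f_soma", "f_neurite", "f_extra", "R_hat", "residual")
  idx <- which(mask != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- dwi[idx[r, 1], idx[r, 2], idx[r, 3], ]
    fit <- fit_voxel(spherical_mean(v, scheme), dictionary, config)
    maps$f_soma[idx[r, , drop = FALSE]] <- fit$f_soma
    maps$f_neurite[idx[r, , drop = FALSE]] <- fit$f_neurite
    maps$f_extra[idx[r, , drop = FALSE]] <- fit$f_extra
    maps$R_hat[idx[r, , drop = FALSE]] <- fit$R_hat
    maps$residual[idx[r, , drop = FALSE]] <- fit$residual_rmse
  }
  maps
}

#' Write a dictionary cache as CSV
#'
#' Stores atom metadata and the per-shell signal matrix side by side;
#' [read_dictionary_csv()] restores the object.
#'
#' @param dictionary a `sandi_dictionary`.
#' @param path output path.
#' @export
write_dictionary_csv <- function(dictionary, path) {
  m <- as.data.frame(t(dictionary$matrix))
  names(m) <- sprintf("b%.0f", dictionary$b_centers)
  utils::write.csv(cbind(dictionary$atoms, m), path, row.names = FALSE)
  invisible(NULL)
}

#' Read a dictionary cache written by [write_dictionary_csv()]
#'
#' @param path CSV path.
#' @return a `sandi_dictionary` (without a scheme fingerprint).
#' @export
read_dictionary_csv <- function(path) {
  d <- utils::read.csv(path)
  meta_cols <- c("kind", "radius", "diffusivity")
  sig_cols <- setdiff(names(d), meta_cols)
  bc <- as.numeric(sub("^b", "", sig_cols))
  structure(list(atoms = d[, meta_cols],
                 matrix = t(as.matrix(d[, sig_cols])),
                 b_centers = bc, fingerprint = "from-csv"),
            class = "sandi_dictionary")
}
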