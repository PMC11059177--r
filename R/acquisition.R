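#' Gyromagnetic ratio of the proton
#'
#' Constant used in all pulsed-gradient spin-echo (PGSE) b-value and
#' gradient conversions, in rad s^-1 T^-1.
#'
#' @export
GAMMA_H <- 2.6751e8

## run an expression under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Convert gradient amplitude to b-value (PGSE)
#'
#' Computes the diffusion weighting of a rectangular pulsed-gradient
#' spin-echo experiment, \eqn{b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)}.
#'
#' @param G gradient amplitude (mT/m); vectorised.
#' @param delta gradient pulse duration \eqn{\delta} (ms).
#' @param Delta pulse separation \eqn{\Delta} (ms).
#' @return b-value in s/mm^2.
#' @examples
#' b_value_from_gradient(62.6, 19, 36)  # approximately 3000 s/mm^2
#' @export
b_value_from_gradient <- function(G, delta, Delta) {
  if (any(G < 0)) stop("G must be non-negative")
  if (any(delta <= 0)) stop("delta must be positive")
  if (any(Delta < delta)) stop("invalid timing: Delta must be >= delta")
  G_si <- G * 1e-3            # T/m
  d_si <- delta * 1e-3        # s
  D_si <- Delta * 1e-3        # s
  b_si <- GAMMA_H^2 * G_si^2 * d_si^2 * (D_si - d_si / 3)  # s/m^2
  b_si * 1e-6                 # s/mm^2
}

#' Convert b-value to gradient amplitude (PGSE)
#'
#' Inverse of [b_value_from_gradient()].
#'
#' @param b b-value (s/mm^2); vectorised.
#' @inheritParams b_value_from_gradient
#' @return gradient amplitude in mT/m.
#' @export
gradient_from_b <- function(b, delta, Delta) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(delta <= 0)) stop("delta must be positive")
  if (any(Delta < delta)) stop("invalid timing: Delta must be >= delta")
  d_si <- delta * 1e-3
  D_si <- Delta * 1e-3
  b_si <- b * 1e6
  G_si <- sqrt(b_si / (GAMMA_H^2 * d_si^2 * (D_si - d_si / 3)))
  G_si * 1e3
}

#' Construct a PGSE acquisition scheme
#'
#' An acquisition scheme is an ordered table of measurements, each with a
#' b-value (s/mm^2), a unit gradient direction, a gradient amplitude
#' (mT/m) and pulse timings \eqn{\delta}, \eqn{\Delta} (ms), plus a
#' b-value tolerance used to group measurements into shells.
#'
#' @param b numeric vector of b-values (s/mm^2).
#' @param directions n x 3 matrix of gradient directions; rows with b > 0
#'   are normalised to unit length (with a warning when far from unit).
#' @param delta,Delta pulse timings (ms), scalar or per measurement.
#' @param G gradient amplitudes (mT/m); computed from b when NULL.
#' @param shell_tolerance b-value tolerance for shell grouping (s/mm^2).
#' @return an object of class `sandi_scheme`.
#' @export
acquisition_scheme <- function(b, directions, delta, Delta, G = NULL,
                               shell_tolerance = 50) {
  b <- as.numeric(b)
  n <- length(b)
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (nrow(directions) != n) stop("directions must have one row per b-value")
  delta <- rep_len(delta, n)
  Delta <- rep_len(Delta, n)
  if (any(delta <= 0)) stop("delta must be positive")
  if (any(Delta < delta)) stop("invalid timing: Delta must be >= delta")
  nrm <- sqrt(rowSums(directions^2))
  dw <- b > shell_tolerance
  if (any(nrm[dw] == 0)) stop("zero direction at non-zero b-value")
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit gradient directions normalised")
  }
  directions[dw, ] <- directions[dw, , drop = FALSE] / nrm[dw]
  if (is.null(G)) {
    G <- gradient_from_b(b, delta, Delta)
  } else {
    G <- rep_len(as.numeric(G), n)
    b_chk <- b_value_from_gradient(G, delta, Delta)
    bad <- b > shell_tolerance & abs(b_chk - b) > 0.01 * pmax(b, 1)
    if (any(bad)) {
      stop("b, G, delta, Delta inconsistent with the Stejskal-Tanner relation")
    }
  }
  m <- data.frame(b = b, gx = directions[, 1], gy = directions[, 2],
                  gz = directions[, 3], G = G, delta = delta, Delta = Delta)
  structure(list(measurements = m, shell_tolerance = shell_tolerance),
            class = "sandi_scheme")
}

#' @export
print.sandi_scheme <- function(x, ...) {
  sh <- group_shells(x)
  cat("PGSE acquisition scheme:", nrow(x$measurements), "measurements,",
      length(sh), "shells\n")
  for (s in sh) {
    cat(sprintf("  b = %6.0f s/mm2 : %3d directions (G = %.1f mT/m)\n",
                s$b_center, length(s$indices),
                max(x$measurements$G[s$indices])))
  }
  invisible(x)
}

#' Quasi-uniform gradient directions by electrostatic repulsion
#'
#' Places `n` points on the unit sphere by minimising the Coulomb energy
#' of the point set together with its antipodes, starting from a seeded
#' random configuration. Deterministic for a given seed.
#'
#' @param n number of directions.
#' @param seed integer seed.
#' @param n_iter repulsion iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsion_directions <- function(n, seed = 1L, n_iter = 200L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    x <- matrix(stats::rnorm(3 * n), ncol = 3)
    x <- x / sqrt(rowSums(x^2))
    if (n == 1) return(x)
    step <- 0.05
    for (it in seq_len(n_iter)) {
      frc <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d1 <- sweep(x, 2, x[i, ], FUN = "-")      # xj - xi
        d2 <- sweep(-x, 2, x[i, ], FUN = "-")     # antipodes
        r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
        r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
        r1[i] <- Inf                              # self
        f <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
        frc[i, ] <- f
      }
      # project force onto tangent plane, take a small step, renormalise
      frc <- frc - x * rowSums(frc * x)
      x <- x + step * frc / max(sqrt(rowSums(frc^2)), 1e-12)
      x <- x / sqrt(rowSums(x^2))
      step <- step * 0.97
    }
    x
  })
}

make_shelled_scheme <- function(b_shells, n_dirs, delta, Delta,
                                shell_tolerance = 50, seed = 42L) {
  bs <- numeric(0)
  dirs <- NULL
  for (k in seq_along(b_shells)) {
    n <- n_dirs[k]
    b <- b_shells[k]
    if (b <= shell_tolerance) {
      d <- matrix(0, n, 3)
    } else {
      d <- repulsion_directions(n, seed = seed + k)
    }
    bs <- c(bs, rep(b, n))
    dirs <- rbind(dirs, d)
  }
  acquisition_scheme(bs, dirs, delta, Delta, shell_tolerance = shell_tolerance)
}

#' Clinical (Prisma-like) acquisition protocol
#'
#' Multi-shell PGSE protocol of a clinical 3T system with 80 mT/m
#' maximum gradient strength: b = 0/700/1000/2000/3000 s/mm^2 with
#' 12/6/20/45/66 measurements and pulse timings delta = 19 ms,
#' Delta = 36 ms. Directions are laid out by seeded electrostatic
#' repulsion per shell.
#'
#' @return a `sandi_scheme`.
#' @export
prisma_protocol <- function() {
  make_shelled_scheme(b_shells = c(0, 700, 1000, 2000, 3000),
                      n_dirs = c(12, 6, 20, 45, 66),
                      delta = 19, Delta = 36)
}

#' Research-grade (CONNECTOM-like) acquisition protocol
#'
#' A representative high-b multi-shell scheme for a 300 mT/m research
#' gradient system: b = 0/1000/2000/3000/5000/7000/10000 s/mm^2 with
#' 12/12/32/48/60/60/60 measurements, delta = 10 ms, Delta = 25 ms
#' (peak gradient about 254 mT/m at b = 10000 s/mm^2). The scheme is a
#' stand-in for published research schemes whose tables are not
#' redistributed here; any scheme file in the text dialect of
#' [read_scheme_file()] can replace it.
#'
#' @param scheme_file optional path to a scheme file overriding every
#'   default field.
#' @return a `sandi_scheme`.
#' @export
connectom_like_protocol <- function(scheme_file = NULL) {
  if (!is.null(scheme_file)) return(read_scheme_file(scheme_file))
  make_shelled_scheme(b_shells = c(0, 1000, 2000, 3000, 5000, 7000, 10000),
                      n_dirs = c(12, 12, 32, 48, 60, 60, 60),
                      delta = 10, Delta = 25, seed = 99L)
}

#' Group scheme measurements into b-shells
#'
#' Partitions the measurements of a scheme into shells of similar
#' b-value: measurements join an existing shell when their b lies within
#' `shell_tolerance` of the running shell centre. Every measurement
#' belongs to exactly one shell.
#'
#' @param scheme a `sandi_scheme`.
#' @return list of shells, sorted by ascending b; each a list with
#'   `b_center` (mean b of members) and `indices` (measurement rows).
#' @export
group_shells <- function(scheme) {
  stopifnot(inherits(scheme, "sandi_scheme"))
  b <- scheme$measurements$b
  if (length(b) == 0) stop("empty scheme")
  tol <- scheme$shell_tolerance
  ord <- order(b)
  groups <- list()
  cur <- c(ord[1])
  for (i in ord[-1]) {
    if (b[i] - mean(b[cur]) <= tol) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- c(i)
    }
  }
  groups[[length(groups) + 1]] <- cur
  lapply(groups, function(idx) {
    list(b_center = mean(b[idx]), indices = sort(idx))
  })
}

b0_shell_index <- function(scheme, shells = group_shells(scheme)) {
  ctr <- vapply(shells, `[[`, numeric(1), "b_center")
  idx <- which(ctr <= scheme$shell_tolerance)
  if (length(idx) == 0) {
    stop("scheme has no b0 shell (b <= shell_tolerance)")
  }
  idx[1]
}

#' Read an FSL-dialect gradient table
#'
#' Reads bval (one whitespace-separated row of b-values) and bvec (three
#' rows: x, y, z components) files into an acquisition scheme. Zero-norm
#' direction vectors are accepted only at b-values within the shell
#' tolerance; non-unit vectors at b > 0 are normalised with a warning.
#'
#' @param bval_path,bvec_path file paths.
#' @param delta,Delta pulse timings (ms) to attach to every measurement.
#' @param shell_tolerance b-value tolerance (s/mm^2).
#' @return a `sandi_scheme`.
#' @export
load_gradient_table <- function(bval_path, bvec_path, delta, Delta,
                                shell_tolerance = 50) {
  bval <- scan(bval_path, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3) stop("bvec file must have exactly 3 rows")
  if (ncol(bvec) != length(bval)) {
    stop("bval/bvec column counts differ")
  }
  acquisition_scheme(bval, t(bvec), delta, Delta,
                     shell_tolerance = shell_tolerance)
}

#' Write an FSL-dialect gradient table
#'
#' Inverse of [load_gradient_table()].
#'
#' @param scheme a `sandi_scheme`.
#' @param bval_path,bvec_path output paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  m <- scheme$measurements
  cat(paste(format(m$b, scientific = FALSE, trim = TRUE), collapse = " "),
      "\n", sep = "", file = bval_path)
  v <- t(as.matrix(m[, c("gx", "gy", "gz")]))
  write(apply(v, 1, paste, collapse = " "), file = bvec_path)
  invisible(NULL)
}

#' Read a plain-text scheme file
#'
#' One line per measurement: `gx gy gz |G|(T/m) Delta(s) delta(s) TE(s)`.
#' Lines starting with `#` (and an optional `VERSION:` header) are
#' skipped. b-values are computed from G and the timings.
#'
#' @param path file path.
#' @param shell_tolerance b-value tolerance (s/mm^2).
#' @return a `sandi_scheme`.
#' @export
read_scheme_file <- function(path, shell_tolerance = 50) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|VERSION|$)", ln)]
  f <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  if (ncol(f) < 7) stop("scheme file needs 7 columns per line")
  G <- f[, 4] * 1e3        # T/m -> mT/m
  Delta <- f[, 5] * 1e3    # s -> ms
  delta <- f[, 6] * 1e3
  b <- b_value_from_gradient(G, delta, Delta)
  acquisition_scheme(b, f[, 1:3], delta, Delta, G = G,
                     shell_tolerance = shell_tolerance)
}

#' Write a plain-text scheme file
#'
#' Inverse of [read_scheme_file()]; TE is written as delta + Delta plus
#' a 10 ms margin, and is not used on reading.
#'
#' @param scheme a `sandi_scheme`.
#' @param path output path.
#' @export
write_scheme_file <- function(scheme, path) {
  m <- scheme$measurements
  te <- (m$delta + m$Delta + 10) * 1e-3
  lines <- sprintf("%.10f %.10f %.10f %.10f %.6f %.6f %.6f",
                   m$gx, m$gy, m$gz, m$G * 1e-3,
                   m$Delta * 1e-3, m$delta * 1e-3, te)
  writeLines(c("VERSION: 1", lines), path)
  invisible(NULL)
}
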