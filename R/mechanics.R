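#' RBC mechanical parameters
#'
#' Particle constants for the three-force model. The elastic contact follows
#' a Hertz-type law `k * overlap^(3/2)` with the overlap in meters; the
#' depletion aggregation force derives from a Morse potential
#' \deqn{\Phi(\delta) = DA\,(e^{2B(\delta_0-\delta)} - 2e^{B(\delta_0-\delta)}),}
#' where `DA` merges the surface energy and the cell-cell apposition area
#' into a single energy scale; drag is pseudosteady Stokes drag
#' `6*pi*mu*R*(u - v)` toward the local flow velocity.
#'
#' @section Calibration:
#' The depletion constants are exposed for calibration because the nominal
#' default `DA = 1e-25` J puts the aggregation force (scale `2*DA*B` =
#' 2e-18 N) many orders of magnitude below the drag scale (~1e-10 N), so
#' cohesion is then dynamically irrelevant. The physically admissible range
#' adopted by this package is `DA` in \[1e-25, 2e-16\] J: the upper bound is
#' a depletion interaction energy density of ~10 uJ/m^2 (dextran- or
#' fibrinogen-mediated RBC adhesion scale) acting over an apposition area of
#' order `R^2` (~1.6e-11 m^2). Calibrated values used for quantitative
#' reproduction should be recorded in the run manifest. `B` (inverse
#' interaction range) and `delta0` (equilibrium surface gap) should stay at
#' their defaults, which match the ~0.1 um depletion-layer scale.
#'
#' @param R RBC radius (m). Default 4 um.
#' @param m RBC mass (kg). Default 2.94e-13 kg.
#' @param k elastic contact prefactor (N m^-3/2, overlap in meters).
#' @param DA depletion energy scale (J). Default 1e-25 J.
#' @param B Morse scaling factor (1/m). Default 1e7 /m.
#' @param delta0 reference surface separation (m). Default 11 nm.
#' @param mu medium dynamic viscosity (Pa s). Default 1.2e-3 (plasma-like).
#' @param r_cut pair-interaction cutoff on the surface distance (m).
#'   Default 1 um = 10/B, where the Morse terms are below `exp(-10)` of
#'   their scale `2*DA*B`.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(R = 4e-6, m = 2.94e-13, k = 3e-6,
                        DA = 1e-25, B = 1e7, delta0 = 11e-9,
                        mu = 1.2e-3, r_cut = 1e-6) {
  vals <- list(R = R, m = m, k = k, DA = DA, B = B, delta0 = delta0,
               mu = mu, r_cut = r_cut)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1 ||
        !is.finite(vals[[nm]]) || vals[[nm]] <= 0) {
      stop(sprintf("mech_params: '%s' must be a single positive number", nm))
    }
  }
  # truncating the Morse force at r_cut must be negligible on its 2*DA*B scale
  if (exp(-B * (r_cut - delta0)) >= 1e-4) {
    stop("r_cut too small: Morse truncation error exceeds 1e-4 of 2*DA*B")
  }
  structure(vals, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("RBC mechanical parameters\n")
  cat(sprintf("  R = %.3g um, m = %.3g kg, k = %.3g N m^-3/2\n",
              x$R * 1e6, x$m, x$k))
  cat(sprintf("  DA = %.3g J, B = %.3g 1/m, delta0 = %.3g nm\n",
              x$DA, x$B, x$delta0 * 1e9))
  cat(sprintf("  mu = %.3g Pa s, r_cut = %.3g um, drag tau = %.3g us\n",
              x$mu, x$r_cut * 1e6, x$m / (6 * pi * x$mu * x$R) * 1e6))
  invisible(x)
}

#' Pair geometry between two particle centers
#'
#' @param xi,xj length-2 center positions (m) of particles i and j.
#' @return List with center distance `d`, surface distance
#'   `delta = d - 2R` (needs `R` separately; here `delta` is left to the
#'   force functions), and the unit vector `n_ij` from j to i.
#' @keywords internal
pair_geometry <- function(xi, xj) {
  dvec <- xi - xj
  d <- sqrt(sum(dvec^2))
  if (d == 0) stop("coincident particle centers: pair direction undefined")
  list(d = d, n_ij = dvec / d)
}

#' Hertzian elastic contact force
#'
#' Repulsive contact force `k * (2R - d)^(3/2) n_ij` for center distance
#' `d < 2R`, zero otherwise; continuous at contact onset.
#'
#' @param mp a [mech_params()] object.
#' @param d center-center distance (m), `d > 0`.
#' @param n_ij unit vector from particle j to particle i.
#' @return Force vector (N) acting on particle i.
#' @export
elastic_force <- function(mp, d, n_ij = c(1, 0)) {
  if (d <= 0) stop("coincident particle centers: pair direction undefined")
  ov <- 2 * mp$R - d
  if (ov <= 0) return(c(0, 0))
  mp$k * ov^1.5 * n_ij
}

#' Morse depletion potential
#'
#' @param mp a [mech_params()] object.
#' @param delta surface distance `d - 2R` (m); may be negative for overlap.
#' @return List with the dimensionless Morse `shape`
#'   (`exp(2B(delta0-delta)) - 2 exp(B(delta0-delta))`, minimum -1 at
#'   `delta = delta0`) and the absolute `energy = DA * shape` (J).
#' @export
morse_potential <- function(mp, delta) {
  s <- exp(2 * mp$B * (mp$delta0 - delta)) - 2 * exp(mp$B * (mp$delta0 - delta))
  list(shape = s, energy = mp$DA * s)
}

# overlap beyond which the Morse repulsion is frozen (overflow guard; the
# elastic contact term dominates there anyway)
MORSE_OVERLAP_GUARD <- -0.5e-6

#' Depletion (Morse) aggregation force
#'
#' `2 DA B (exp(2B(delta0-delta)) - exp(B(delta0-delta))) n_ij`: repulsive
#' below the equilibrium separation `delta0`, attractive between `delta0`
#' and the cutoff `r_cut`, zero beyond the cutoff. For overlaps deeper than
#' 0.5 um the magnitude is clamped at its value there to avoid floating-point
#' overflow of the exponentials.
#'
#' @inheritParams elastic_force
#' @return Force vector (N) acting on particle i (positive along `n_ij` =
#'   repulsive).
#' @export
aggregation_force <- function(mp, d, n_ij = c(1, 0)) {
  delta <- d - 2 * mp$R
  if (delta > mp$r_cut) return(c(0, 0))
  delta <- max(delta, MORSE_OVERLAP_GUARD)
  mag <- 2 * mp$DA * mp$B *
    (exp(2 * mp$B * (mp$delta0 - delta)) - exp(mp$B * (mp$delta0 - delta)))
  mag * n_ij
}

#' Pseudosteady Stokes drag force
#'
#' `6 pi mu R (u_local - v_particle)`: the force drives the particle toward
#' the local flow velocity.
#'
#' @param mp a [mech_params()] object.
#' @param u_local local flow velocity vector (m/s).
#' @param v_particle particle velocity vector (m/s).
#' @return Force vector (N).
#' @export
drag_force <- function(mp, u_local, v_particle) {
  stopifnot(all(is.finite(u_local)), all(is.finite(v_particle)))
  6 * pi * mp$mu * mp$R * (u_local - v_particle)
}

#' Per-particle force accumulation
#'
#' Sums, for every particle, the pairwise elastic + aggregation forces over
#' all pairs within the interaction cutoff (axially periodic minimum-image
#' distances), the Hertzian wall contact, and Stokes drag at the particle's
#' position. Pairwise contributions are exactly antisymmetric.
#'
#' @param mp a [mech_params()] object.
#' @param fp a [flow_params()] object.
#' @param pos N x 2 matrix of positions (m).
#' @param vel N x 2 matrix of velocities (m/s).
#' @param t time (s).
#' @param method `"cell"` (linked-cell neighbor search, default) or
#'   `"all"` (brute-force all pairs; used as a cross-check).
#' @param include_wall,include_drag logical; include the wall contact / the
#'   drag term (disabled for isolated pair-force checks).
#' @return N x 2 matrix of total forces (N).
#' @export
accumulate_forces <- function(mp, fp, pos, vel, t, method = c("cell", "all"),
                              include_wall = TRUE, include_drag = TRUE) {
  method <- match.arg(method)
  pos <- as.matrix(pos); vel <- as.matrix(vel)
  stopifnot(ncol(pos) == 2, all(dim(vel) == dim(pos)))
  f <- pair_forces_cpp(pos, engine_par(fp, mp), method == "all", include_wall)
  if (include_drag) {
    u <- cbind(velocity_at(fp, t, pos[, 1], pos[, 2]), 0)
    f <- f + 6 * pi * mp$mu * mp$R * (u - vel)
  }
  f
}

# flat parameter vector handed to the C++ core
engine_par <- function(fp, mp) {
  c(A_f = fp$A_f, B_f = fp$B_f, omega = fp$omega, k_f = fp$k_f,
    h = fp$h, L = fp$L,
    R = mp$R, m = mp$m, k = mp$k, DA = mp$DA, B = mp$B,
    delta0 = mp$delta0, mu = mp$mu, r_cut = mp$r_cut)
}
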