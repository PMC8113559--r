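#' Pulsatile flow-field parameters
#'
#' Parameters of the analytic sinusoidal pulsatile velocity field
#' \deqn{u(t,x,y) = \{A_f \sin(\omega t - k_f x) + B_f\}\,(1 - 4y^2/h^2),}
#' a Poiseuille profile across the tube modulated by a sinusoid traveling
#' along its axis. All values are SI.
#'
#' @param A_f velocity amplitude (m/s). Default 1 mm/s.
#' @param B_f mean flow velocity (m/s), must be positive. Default 4 mm/s.
#' @param f pulse frequency (Hz). Default 1 Hz (60 BPM).
#' @param h tube diameter (m). Default 0.12 mm.
#' @param L tube length (m). Default 0.5 mm.
#' @param k_f wavenumber (1/m). The default, `4*pi/L`, places exactly two
#'   wavelengths in the tube so the field is periodic over its length,
#'   consistent with the periodic axial boundary of the particle engine.
#' @return An object of class `flow_params`: a list with fields `A_f`, `B_f`,
#'   `f`, `omega` (`2*pi*f`), `k_f`, `h`, `L` and the derived period `T = 1/f`.
#' @examples
#' p <- flow_params()
#' velocity_at(p, t = 0, x = 0, y = 0)  # centerline mean velocity, 4 mm/s
#' @export
flow_params <- function(A_f = 1e-3, B_f = 4e-3, f = 1,
                        h = 0.12e-3, L = 0.5e-3, k_f = 4 * pi / L) {
  stopifnot(is.numeric(A_f), is.numeric(B_f), is.numeric(f),
            is.numeric(h), is.numeric(L), is.numeric(k_f))
  if (h <= 0) stop("tube diameter h must be positive")
  if (L <= 0) stop("tube length L must be positive")
  if (f <= 0) stop("frequency f must be positive")
  if (B_f <= 0) stop("mean flow velocity B_f must be positive")
  if (A_f < 0) stop("velocity amplitude A_f must be non-negative")
  if (k_f < 0) stop("wavenumber k_f must be non-negative")
  structure(list(A_f = A_f, B_f = B_f, f = f, omega = 2 * pi * f,
                 k_f = k_f, h = h, L = L, T = 1 / f),
            class = "flow_params")
}

#' @export
print.flow_params <- function(x, ...) {
  cat("Sinusoidal pulsatile flow field\n")
  cat(sprintf("  A_f = %.3g mm/s, B_f = %.3g mm/s, f = %.3g Hz\n",
              x$A_f * 1e3, x$B_f * 1e3, x$f))
  cat(sprintf("  k_f = %.4g 1/m (%.3g wavelengths per tube length)\n",
              x$k_f, x$k_f * x$L / (2 * pi)))
  cat(sprintf("  tube: diameter %.3g um, length %.3g um\n",
              x$h * 1e6, x$L * 1e6))
  invisible(x)
}

check_y_domain <- function(p, y) {
  if (any(abs(y) > p$h / 2 + 1e-15)) {
    stop("radial coordinate outside tube: |y| > h/2")
  }
}

#' Axial velocity of the pulsatile field
#'
#' @param p a [flow_params()] object.
#' @param t time (s).
#' @param x axial coordinate (m); any value (the field is periodic in `x`
#'   under the default wavenumber).
#' @param y radial coordinate (m), `|y| <= h/2`.
#' @return Axial velocity (m/s). Vectorized over `t`, `x`, `y`.
#' @export
velocity_at <- function(p, t, x, y) {
  check_y_domain(p, y)
  (p$A_f * sin(p$omega * t - p$k_f * x) + p$B_f) * (1 - 4 * y^2 / p$h^2)
}

#' Radial shear rate of the pulsatile field
#'
#' The radial velocity gradient `du/dy`, antisymmetric in `y`, vanishing on
#' the centerline and extremal at the walls.
#'
#' @inheritParams velocity_at
#' @return Radial shear rate (1/s).
#' @export
radial_shear_at <- function(p, t, x, y) {
  check_y_domain(p, y)
  -(p$A_f * sin(p$omega * t - p$k_f * x) + p$B_f) * (8 * y / p$h^2)
}

#' Axial shear rate of the pulsatile field
#'
#' The axial velocity gradient `du/dx`, carried entirely by the traveling
#' sinusoid; it vanishes at the walls and is extremal on the centerline.
#'
#' @inheritParams velocity_at
#' @return Axial shear rate (1/s).
#' @export
axial_shear_at <- function(p, t, x, y) {
  check_y_domain(p, y)
  (-p$A_f * p$k_f * cos(p$omega * t - p$k_f * x)) * (1 - 4 * y^2 / p$h^2)
}

#' Grid specification over the tube cross-section
#'
#' A uniform `nx` x `ny` grid of cells covering the tube, with field values
#' sampled at cell centers. The default 100 x 100 grid gives 5 um x 1.2 um
#' cells for the default geometry, smaller than one RBC.
#'
#' @param p a [flow_params()] object (supplies the tube extents).
#' @param nx,ny number of cells along the axis / across the tube.
#' @return An object of class `grid_spec` with cell-center coordinate vectors
#'   `xc` (length `nx`) and `yc` (length `ny`) and cell sizes `dx`, `dy`.
#' @export
grid_spec <- function(p, nx = 100L, ny = 100L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  dx <- p$L / nx
  dy <- p$h / ny
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 xc = (seq_len(nx) - 0.5) * dx,
                 yc = -p$h / 2 + (seq_len(ny) - 0.5) * dy,
                 L = p$L, h = p$h),
            class = "grid_spec")
}

#' Shear-rate decomposition of the flow field on a grid
#'
#' Evaluates the velocity and its analytic axial/radial shear-rate
#' decomposition at every cell center, together with the shear magnitude
#' \eqn{\sqrt{\dot\gamma_x^2+\dot\gamma_y^2}} and direction (the angle of the
#' gradient vector, `atan2`-resolved to (-pi, pi]).
#'
#' @param p a [flow_params()] object.
#' @param g a [grid_spec()] object.
#' @param t time (s).
#' @return An object of class `shear_snapshot`: list with time `t`, the grid,
#'   and `nx` x `ny` matrices `u`, `gx`, `gy`, `gmag`, `phi` indexed
#'   `[ix, iy]`.
#' @export
shear_decompose <- function(p, g, t) {
  stopifnot(inherits(p, "flow_params"), inherits(g, "grid_spec"),
            length(t) == 1, is.finite(t))
  X <- matrix(g$xc, g$nx, g$ny)
  Y <- matrix(g$yc, g$nx, g$ny, byrow = TRUE)
  u <- velocity_at(p, t, X, Y)
  gx <- axial_shear_at(p, t, X, Y)
  gy <- radial_shear_at(p, t, X, Y)
  structure(list(t = t, grid = g, u = u, gx = gx, gy = gy,
                 gmag = sqrt(gx^2 + gy^2), phi = atan2(gy, gx)),
            class = "shear_snapshot")
}

#' @export
print.shear_snapshot <- function(x, ...) {
  cat(sprintf("Shear-field snapshot at t = %.4g s (%d x %d grid)\n",
              x$t, x$grid$nx, x$grid$ny))
  cat(sprintf("  u: [%.3g, %.3g] mm/s; gx: [%.3g, %.3g] 1/s; gy: [%.3g, %.3g] 1/s\n",
              min(x$u) * 1e3, max(x$u) * 1e3, min(x$gx), max(x$gx),
              min(x$gy), max(x$gy)))
  invisible(x)
}

#' Axial-to-radial shear-rate ratio in a center band
#'
#' Ratio of the band means of the absolute axial and radial shear rates over
#' all grid cells within `band_width` of the tube axis. A band mean (rather
#' than a pointwise ratio) is used because the radial shear changes sign on
#' the centerline, where a pointwise ratio diverges.
#'
#' @inheritParams shear_decompose
#' @param band_width full width of the center band (m). Default 16 um.
#' @return `mean(|gx|) / mean(|gy|)` over cells with `|y| <= band_width/2`.
#' @export
center_band_ratio <- function(p, g, t, band_width = 16e-6) {
  stopifnot(band_width > 0, band_width < p$h)
  keep <- abs(g$yc) <= band_width / 2
  if (!any(keep)) stop("center band contains no grid cells")
  snap <- shear_decompose(p, g, t)
  mean(abs(snap$gx[, keep])) / mean(abs(snap$gy[, keep]))
}

#' Export a shear-field snapshot as a long table
#'
#' @param snap a [shear_decompose()] snapshot.
#' @param path optional CSV path; when given the table is also written there.
#' @return (Invisibly for written files) a data.frame with one row per grid
#'   cell: `t, x_center, y_center, u, gx, gy, gmag, phi`, SI units.
#' @export
field_table <- function(snap, path = NULL) {
  g <- snap$grid
  df <- data.frame(
    t = snap$t,
    x_center = rep(g$xc, times = g$ny),
    y_center = rep(g$yc, each = g$nx),
    u = as.vector(snap$u),
    gx = as.vector(snap$gx),
    gy = as.vector(snap$gy),
    gmag = as.vector(snap$gmag),
    phi = as.vector(snap$phi)
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
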