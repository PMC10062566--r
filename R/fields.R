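#' Specify a diffusion-encoding gradient field
#'
#' Three idealised field shapes are supported: a linear gradient along z
#' (\eqn{B_z = G_1 z}), a hypothetical one-dimensional quadratic field
#' (\eqn{B_z = G_2 z^2}), and the physically realisable Z2 field
#' \eqn{B_z = G_2 (z^2 - (x^2 + y^2)/2)}, the second-order solution of
#' Laplace's equation with a saddle point at the origin.
#'
#' @param kind One of `"linear_z"`, `"quadratic_1d"`, `"z2_3d"`.
#' @param G1 Linear gradient strength, T m^-1 (used by `linear_z` only).
#' @param G2 Field curvature, T m^-2 (used by the quadratic kinds).
#' @return An object of class `gradient_field`.
#' @examples
#' f <- gradient_field("z2_3d", G2 = 25)
#' evaluate_field(f, c(0, 0, 1e-3))
#' @export
gradient_field <- function(kind = c("linear_z", "quadratic_1d", "z2_3d"),
                           G1 = 0, G2 = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(G1) || length(G1) != 1L || !is.finite(G1))
    stop_invalid("'G1' must be a finite number")
  if (!is.numeric(G2) || length(G2) != 1L || !is.finite(G2))
    stop_invalid("'G2' must be a finite number")
  structure(list(kind = kind, G1 = G1, G2 = G2), class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  strength <- if (x$kind == "linear_z") sprintf("G1 = %g T/m", x$G1)
              else sprintf("G2 = %g T/m^2", x$G2)
  cat(sprintf("<gradient_field> %s, %s\n", x$kind, strength))
  invisible(x)
}

#' Evaluate the z-component of a gradient field
#'
#' @param field A [gradient_field()].
#' @param position Numeric 3-vector `(x, y, z)` in metres, or an `n x 3`
#'   matrix of positions.
#' @return `Bz` in tesla (length-n vector for a matrix input).
#' @export
evaluate_field <- function(field, position) {
  stopifnot(inherits(field, "gradient_field"))
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1L)
  if (ncol(p) != 3L) stop_invalid("'position' must have 3 columns (x, y, z)")
  if (!all(is.finite(p))) stop_invalid("'position' must be finite")
  bz <- switch(field$kind,
    linear_z     = field$G1 * p[, 3L],
    quadratic_1d = field$G2 * p[, 3L]^2,
    z2_3d        = field$G2 * (p[, 3L]^2 - 0.5 * (p[, 1L]^2 + p[, 2L]^2))
  )
  unname(bz)
}

#' Describe a modified Helmholtz gradient-coil pair
#'
#' Two identical coaxial coils, symmetric about the origin, each wound over a
#' finite length and radial build. With an axial separation larger than the
#' coil radius the pair produces a local on-axis field-magnitude minimum at
#' the centre (in 3D a saddle point), approximating a Z2 encoding field near
#' the origin. Defaults reproduce the prototype insert: 27 windings over
#' 11 mm length per coil, inner/outer winding radii 5.25/6.25 mm, 12 mm gap
#' between the facing coil ends.
#'
#' @param turns_per_coil Number of windings per coil.
#' @param coil_length Axial length of each winding block, m.
#' @param inner_radius,outer_radius Radial extent of the winding block, m.
#' @param separation Axial separation between the two coils, m. Interpreted
#'   per `separation_is`: the gap between the facing ends of the windings
#'   (default) or the centre-to-centre distance.
#' @param current Coil current, A (same polarity in both coils).
#' @param winding_layout `"uniform_block"` distributes the turns on a
#'   `n_radial x n_axial` filament grid over the winding cross-section;
#'   `"single_layer"` places all turns at `inner_radius` along the length.
#' @param separation_is `"gap"` or `"centre_to_centre"`.
#' @param n_radial,n_axial Filament discretisation of the winding block.
#' @return An object of class `coil_geometry`.
#' @export
coil_geometry <- function(turns_per_coil = 27,
                          coil_length = 11e-3,
                          inner_radius = 5.25e-3,
                          outer_radius = 6.25e-3,
                          separation = 12e-3,
                          current = 1,
                          winding_layout = c("uniform_block", "single_layer"),
                          separation_is = c("gap", "centre_to_centre"),
                          n_radial = 3L, n_axial = 9L) {
  winding_layout <- match.arg(winding_layout)
  separation_is <- match.arg(separation_is)
  if (turns_per_coil < 1) stop_invalid("'turns_per_coil' must be >= 1")
  if (inner_radius <= 0 || outer_radius <= inner_radius)
    stop_invalid("need 0 < inner_radius < outer_radius")
  if (coil_length <= 0 || separation <= 0)
    stop_invalid("lengths must be positive")
  gap <- if (separation_is == "gap") separation else separation - coil_length
  if (gap <= 0) stop_invalid("centre-to-centre separation must exceed coil_length")
  structure(list(
    turns_per_coil = turns_per_coil, coil_length = coil_length,
    inner_radius = inner_radius, outer_radius = outer_radius,
    gap = gap, current = current, winding_layout = winding_layout,
    n_radial = as.integer(n_radial), n_axial = as.integer(n_axial)
  ), class = "coil_geometry")
}

# Filament decomposition of both coils: data.frame(radius, z, turns).
coil_filaments <- function(geom) {
  centre_offset <- (geom$gap + geom$coil_length) / 2
  if (geom$winding_layout == "single_layer") {
    n <- geom$turns_per_coil
    zloc <- (seq_len(n) - 0.5) / n * geom$coil_length - geom$coil_length / 2
    one <- data.frame(radius = geom$inner_radius, z = zloc, turns = 1)
  } else {
    nr <- max(3L, geom$n_radial)
    na <- max(9L, geom$n_axial)
    r <- geom$inner_radius +
      ((seq_len(nr) - 0.5) / nr) * (geom$outer_radius - geom$inner_radius)
    zloc <- ((seq_len(na) - 0.5) / na - 0.5) * geom$coil_length
    one <- expand.grid(radius = r, z = zloc)
    one$turns <- geom$turns_per_coil / (nr * na)
  }
  rbind(
    transform(one, z = z + centre_offset),
    transform(one, z = z - centre_offset)
  )
}

#' On-axis field profile of the coil pair
#'
#' Sums the analytic on-axis circular-loop field
#' \eqn{B_z(z) = \mu_0 I R^2 / (2 (R^2 + (z - z_0)^2)^{3/2})} over every
#' filament of both coils.
#'
#' @param geom A [coil_geometry()].
#' @param z_grid Axial positions, m.
#' @return Numeric vector of `Bz` (T), one per grid point.
#' @export
coil_axis_profile <- function(geom, z_grid) {
  stopifnot(inherits(geom, "coil_geometry"))
  if (geom$turns_per_coil < 1) stop_invalid("coil has no turns")
  if (!all(is.finite(z_grid))) stop_invalid("'z_grid' must be finite")
  zmax <- geom$gap / 2 + geom$coil_length
  if (any(abs(z_grid) > zmax))
    warning("z_grid extends beyond the coil envelope (|z| > gap/2 + coil_length)")
  fil <- coil_filaments(geom)
  bz <- numeric(length(z_grid))
  for (i in seq_len(nrow(fil))) {
    R2 <- fil$radius[i]^2
    bz <- bz + fil$turns[i] * MU0 * geom$current * R2 /
      (2 * (R2 + (z_grid - fil$z[i])^2)^1.5)
  }
  bz
}

#' Fit the field curvature near the coil centre
#'
#' Least-squares fit of \eqn{B_z \approx B_0 + G_2 z^2} restricted to
#' `|z| <= fit_halfwidth`, returning the curvature `G2` in T m^-2.
#'
#' @param z_grid Axial positions, m.
#' @param bz Field values, T.
#' @param fit_halfwidth Half-width of the fit window around z = 0, m.
#' @return Fitted curvature `G2` (T m^-2); 0 for a constant profile.
#' @export
fit_curvature <- function(z_grid, bz, fit_halfwidth = 2e-3) {
  stopifnot(length(z_grid) == length(bz))
  keep <- abs(z_grid) <= fit_halfwidth
  if (sum(keep) < 5L)
    stop_invalid("need at least 5 grid points within the fit window")
  z2 <- z_grid[keep]^2
  y <- bz[keep]
  if (max(z2) - min(z2) == 0 || stats::var(y) == 0) return(0)
  unname(coef(lm(y ~ z2))[2L])
}
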