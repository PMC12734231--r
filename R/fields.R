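#' Gridded intraventricular velocity field
#'
#' Cartesian-sampled velocity on a uniform isotropic grid with a boolean
#' chamber mask, the container for vorticity evaluation.
#'
#' @param x,y,z node coordinate vectors (mm or m; uniform, equal spacing in
#'   all three directions — anisotropic grids are rejected).
#' @param v numeric array `nx x ny x nz x 3` of velocities.
#' @param mask logical array `nx x ny x nz`; must be non-empty.
#' @return object of class `grid_velocity_field`.
#' @export
grid_velocity_field <- function(x, y, z, v, mask) {
  hs <- c(diff(x), diff(y), diff(z))
  h <- hs[1L]
  if (h <= 0 || any(abs(hs - h) > 1e-9 * h))
    stop("grid must be uniform with equal (isotropic) spacing in x, y, z")
  stopifnot(length(dim(v)) == 4L, dim(v)[4L] == 3L,
            all(dim(v)[1:3] == c(length(x), length(y), length(z))))
  mask <- array(as.logical(mask), dim = dim(v)[1:3])
  if (!any(mask)) stop("mask is empty")
  structure(list(x = x, y = y, z = z, v = v, mask = mask, h = h),
            class = "grid_velocity_field")
}

#' Solid-body rotation fixture
#'
#' v = Omega x r about the z axis inside a spherical mask; the vorticity
#' modulus is exactly 2*Omega at every masked node.
#'
#' @param omega angular velocity (rad/s) about +z.
#' @param n nodes per axis.
#' @param extent grid half-width (the grid spans `[-extent, extent]`).
#' @param mask_radius radius of the spherical mask; must fit in the grid.
#' @return a [grid_velocity_field()].
#' @export
solid_body_rotation_field <- function(omega, n = 33L, extent = 1,
                                      mask_radius = 0.8 * extent) {
  if (!is.finite(omega)) stop("omega must be finite")
  if (mask_radius > extent) stop("mask exceeds grid bounds")
  xs <- seq(-extent, extent, length.out = n)
  X <- array(xs, dim = c(n, n, n))
  Y <- aperm(X, c(2L, 1L, 3L))
  Z <- aperm(X, c(3L, 2L, 1L))
  v <- array(0, dim = c(n, n, n, 3L))
  v[, , , 1L] <- -omega * Y
  v[, , , 2L] <- omega * X
  grid_velocity_field(xs, xs, xs, v, X^2 + Y^2 + Z^2 <= mask_radius^2)
}

#' Hill's spherical vortex fixture
#'
#' Classical analytic vortex ring: inside radius `a` the azimuthal vorticity
#' grows linearly with the cylindrical radius, outside the flow is
#' irrotational (potential flow past a sphere, co-moving frame). The
#' volume-mean vorticity modulus over the sphere is `(45*pi/32) * U / a`.
#'
#' @param U translation speed of the vortex (m/s).
#' @param a vortex radius (m).
#' @param n nodes per axis.
#' @param extent grid half-width (default `1.25 * a`).
#' @return a [grid_velocity_field()] with the sphere as mask.
#' @export
hill_vortex_field <- function(U, a, n = 49L, extent = 1.25 * a) {
  stopifnot(U > 0, a > 0)
  xs <- seq(-extent, extent, length.out = n)
  X <- array(xs, dim = c(n, n, n))
  Y <- aperm(X, c(2L, 1L, 3L))
  Z <- aperm(X, c(3L, 2L, 1L))
  S2 <- X^2 + Y^2                       # cylindrical radius^2
  R2 <- S2 + Z^2
  inside <- R2 <= a^2
  uz <- us_over_s <- array(0, dim = c(n, n, n))
  uz[inside] <- -(3 * U / (2 * a^2)) * (a^2 - Z[inside]^2 - 2 * S2[inside])
  us_over_s[inside] <- -(3 * U / (2 * a^2)) * Z[inside]
  out <- !inside
  r <- sqrt(R2[out]); r[r == 0] <- a
  uz[out] <- -U * (1 - a^3 / r^3) - 3 * U * a^3 * S2[out] / (2 * r^5)
  us_over_s[out] <- 3 * U * a^3 * Z[out] / (2 * r^5)
  v <- array(0, dim = c(n, n, n, 3L))
  v[, , , 1L] <- us_over_s * X
  v[, , , 2L] <- us_over_s * Y
  v[, , , 3L] <- uz
  grid_velocity_field(xs, xs, xs, v, inside)
}
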