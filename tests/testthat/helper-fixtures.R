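# shared fixtures built in code

# unit cube (12 triangles, outward-oriented), side in mm
unit_cube <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),     # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),     # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),     # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),     # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6))     # x = 1, normal +x
  list(vertices = V, triangles = tri)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ + a * d), 2 * (b * d - a * c_),
           2 * (b * c_ - a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d + a * b),
           2 * (b * d + a * c_), 2 * (c_ * d - a * b), a^2 - b^2 - c_^2 + d^2),
         3L, 3L)
}

rotate_sequence <- function(mesh, R) {
  verts <- mesh$vertices
  for (f in seq_len(dim(verts)[3]))
    verts[, , f] <- verts[, , f] %*% t(R)
  mesh_sequence(verts, mesh$triangles, mesh$times, mesh$period,
                cap = mesh$cap, aortic = mesh$aortic, validate = FALSE)
}

# hdf_series wrapper around a prescribed longitudinal force signal
fabricate_hdf <- function(fz, period, i_ED = 1L, i_ES) {
  n <- length(fz)
  structure(list(times = (seq_len(n) - 1L) * period / n,
                 f = cbind(0, 0, fz), F_newton = NULL, V = rep(100, n),
                 i_ED = i_ED, i_ES = i_ES, period = period,
                 rho = 1060, g = 9.81),
            class = "hdf_series")
}

# smooth periodic velocity field with analytic curl, for convergence checks
trig_field <- function(n, extent = 1) {
  xs <- seq(-extent, extent, length.out = n)
  k <- pi / extent
  X <- array(xs, dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  v <- array(0, dim = c(n, n, n, 3))
  v[, , , 1] <- sin(k * Z)
  v[, , , 2] <- sin(k * X)
  v[, , , 3] <- sin(k * Y)
  curl <- sqrt((k * cos(k * Y))^2 + (k * cos(k * Z))^2 + (k * cos(k * X))^2)
  mask <- X^2 + Y^2 + Z^2 <= (0.75 * extent)^2
  list(field = grid_velocity_field(xs, xs, xs, v, mask), curl = curl)
}
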