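test_that("boundary velocities are exact for rigid and sinusoidal motion", {
  s <- uv_sphere(10, 16, 8)
  Tp <- 0.8
  # static mesh: zero velocity
  st <- rigid_translation_sequence(s, function(t) rep(0, length(t)), Tp, 16)
  expect_lt(max(abs(boundary_velocity(st))), 1e-12)
  # sinusoidal displacement: spectral derivative matches the analytic one
  amp <- 2; n <- 32
  rb <- rigid_translation_sequence(
    s, function(t) -amp * (2 * pi / Tp)^2 * sin(2 * pi * t / Tp), Tp, n)
  vel <- boundary_velocity(rb)
  tt <- rb$times
  # d(t) = amp*sin(2*pi*t/T) solves d'' = a, so v = amp*(2*pi/T)*cos(...)
  v_true <- amp * (2 * pi / Tp) * cos(2 * pi * tt / Tp)
  expect_lt(max(abs(vel[1, 3, ] - v_true)) / max(abs(v_true)), 1e-10)
  # centred differences are within 1% at 32 frames
  velc <- boundary_velocity(rb, method = "central")
  expect_lt(max(abs(velc[1, 3, ] - v_true)) / max(abs(v_true)), 0.01)
  expect_error(boundary_velocity(mesh_sequence(rb$vertices[, , 1:2],
                                               rb$triangles, rb$times[1:2],
                                               Tp, validate = FALSE)),
               "3 frames")
})

test_that("closed-surface identity holds to 1e-6 relative", {
  g <- generate_ventricle_sequence(ventricle_spec(90, 36, 76, n_frames = 12),
                                   n_theta = 24, n_phi = 12)
  fixtures <- list(uv_sphere(17, 32, 16),
                   list(vertices = frame_vertices(g$mesh, 4),
                        triangles = g$mesh$triangles))
  for (fix in fixtures) {
    V <- fix$vertices; tri <- fix$triangles
    vol <- mesh_volume(V, tri) * 1000
    nds <- lvmech:::triangle_area_vectors(V, tri)
    xc <- lvmech:::triangle_centroids(V, tri)
    for (a in list(c(1, 0, 0), c(0.3, -1.2, 2.5))) {
      lhs <- colSums(xc * as.numeric(nds %*% a))
      expect_lt(max(abs(lhs - a * vol)) / max(abs(a * vol)), 1e-6)
    }
  }
})

test_that("rigid sinusoidal translation yields 100% dimensionless amplitude", {
  g0 <- 9.81
  s <- uv_sphere(20, 32, 16)
  Tp <- 0.8
  rb <- rigid_translation_sequence(
    s, function(t) g0 * 1000 * sin(2 * pi * t / Tp), Tp, 32)
  h <- hdf_time_series(rb, orifice = "none")
  expect_equal(max(abs(h$f[, 3])), 100, tolerance = 0.02)
  # transverse components vanish; convective term contributes nothing
  expect_lt(max(abs(h$f[, 1:2])), 1e-9)
  # doubling the density leaves the dimensionless force unchanged
  h2 <- hdf_time_series(rb, rho = 2120, orifice = "none")
  expect_equal(h2$f, h$f, tolerance = 1e-12)
  # static mesh gives identically zero force
  st <- rigid_translation_sequence(s, function(t) rep(0, length(t)), Tp, 16)
  expect_lt(max(abs(hdf_time_series(st, orifice = "none")$f)), 1e-12)
})

test_that("dimensionless force is equivariant under a rigid rotation", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 16)
  g <- generate_ventricle_sequence(sp, n_theta = 20, n_phi = 10)
  reg <- register_sequence(g$mesh, g$landmarks)
  h <- hdf_time_series(reg$mesh)
  set.seed(5)
  R <- random_rotation()
  hrot <- hdf_time_series(rotate_sequence(reg$mesh, R))
  expect_equal(hrot$f, h$f %*% t(R), tolerance = 1e-8)
})

test_that("orifice plug velocities follow the binary valve logic", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 16)
  g <- generate_ventricle_sequence(sp, n_theta = 20, n_phi = 10)
  vc <- volume_curve(g$mesh)
  plug <- orifice_plug_velocity(vc, mv_area = 400, av_area = 300)
  eject <- vc$dVdt < 0
  fill <- vc$dVdt > 0
  expect_true(all(plug$av_speed[eject] > 0))
  expect_true(all(plug$mv_speed[eject] == 0))
  expect_true(all(plug$mv_speed[fill] > 0))
  expect_true(all(plug$av_speed[fill] == 0))
  # Q/A arithmetic: -300 mL/s through 3 cm^2 is 100 cm/s outward
  vc$dVdt <- rep(-300, length(vc$dVdt))
  p2 <- orifice_plug_velocity(vc, 400, 300)
  expect_equal(p2$av_speed, rep(1000, nrow(p2)))
  expect_error(orifice_plug_velocity(vc, 400, 0), "zero orifice")
})

test_that("ejection drives a positive longitudinal force toward the aorta", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 26)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  reg <- register_sequence(g$mesh, g$landmarks)
  vc <- volume_curve(reg$mesh)
  h <- hdf_time_series(reg$mesh, vc = vc)
  sys <- which(vc$dVdt < -0.2 * max(abs(vc$dVdt)) &
               vc$times < vc$times[vc$i_ES])
  expect_gt(mean(h$f[sys, 3]), 0)
})

test_that("force parameters reproduce the sine closed forms at 64 samples", {
  A <- 7; n <- 64
  fz <- A * sin(2 * pi * (0:(n - 1)) / n)
  h <- fabricate_hdf(fz, period = 1, i_ES = n / 2 + 1L)
  p <- hdf_parameters(h)
  expect_equal(p$LVLF, A / sqrt(2), tolerance = 0.005)
  expect_equal(p$LVsysLF, A / sqrt(2), tolerance = 0.005)
  expect_equal(p$LVsysIm, 2 * A / pi, tolerance = 0.005)
  expect_equal(p$LVs, 2 * A / pi, tolerance = 0.005)
  # no positive lobe after the suction interval within this cycle
  expect_true(is.na(p$LVdiaIm))

  # zero force: amplitudes are zero, lobes flagged absent
  p0 <- hdf_parameters(fabricate_hdf(rep(0, n), 1, i_ES = n / 2 + 1L))
  expect_equal(p0$LVLF, 0)
  expect_true(is.na(p0$LVsysIm))
  expect_true(is.na(p0$LVs))
})

test_that("the full parameter set is extracted from a ventricle fit", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 26)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  fit <- lv_mechanics(g$mesh, g$landmarks)
  p <- fit$hdf_parameters
  expect_true(all(is.finite(unlist(p[c("LVLF", "LVsysLF", "LVsysIm", "LVs",
                                       "LVdiaLF", "LVdiaIm")]))))
  expect_gt(p$LVLF, 0)
  expect_gt(p$LVsysIm, 0)
  # suction window starts after the systolic positive lobe
  expect_gt(p$windows$suction$from, p$windows$systolic$from)
})
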