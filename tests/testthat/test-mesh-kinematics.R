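test_that("divergence-theorem volume matches closed forms", {
  s <- uv_sphere(1, 96, 48)
  expect_lt(abs(mesh_volume(s$vertices, s$triangles) * 1000 - 4 * pi / 3) /
            (4 * pi / 3), 0.005)
  cube <- unit_cube()
  expect_equal(mesh_volume(cube$vertices, cube$triangles) * 1000, 1)
  flipped <- cube$triangles[, c(1, 3, 2)]
  expect_error(mesh_volume(cube$vertices, flipped), "inward")
  expect_equal(mesh_volume(cube$vertices, flipped, orientation = "signed") * 1000,
               -1)
})

test_that("watertightness check catches open and doubled surfaces", {
  cube <- unit_cube()
  expect_true(is_watertight(cube$triangles))
  expect_false(is_watertight(cube$triangles[-1, ]))
  expect_false(is_watertight(rbind(cube$triangles, cube$triangles[1, ])))
})

test_that("volume curve recovers EF and the constructed E/A ratio", {
  sp <- ventricle_spec(66, 21, 174, e_a_ratio = 1.5, n_frames = 11)
  g <- generate_ventricle_sequence(sp, n_theta = 32, n_phi = 16)
  vc <- volume_curve(g$mesh)
  expect_equal(round(vc$EF), 68)
  expect_equal(vc$i_ED, 1L)
  # EF from the mesh matches the spec-implied EF to < 1%
  expect_lt(abs(vc$EF - 100 * (66 - 21) / 66), 1)

  # two-bump derivative with amplitudes 300 and 50 -> E/A = 6
  wf <- volume_waveform(90, 36, 0.8, 0.35, e_a_ratio = 6)
  tt <- (0:255) / 256 * 0.8
  vc2 <- volume_curve(tt, V = wf$V(tt), period = 0.8)
  expect_equal(vc2$e_a_ratio, 6, tolerance = 0.01)
  expect_lt(vc2$t_E_peak, vc2$t_A_peak)
  # dV/dt of the detected curve integrates to ~0 over the cycle (periodicity)
  d <- vc2$dense
  expect_lt(abs(mean(d$dVdt)) , 1e-6 * max(abs(d$dVdt)))
})

test_that("volume curve warns below the 10-frame QC threshold", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 16, n_phi = 10)
  m <- g$mesh
  keep <- seq(1, 12, length.out = 9)
  short <- mesh_sequence(m$vertices[, , keep], m$triangles, m$times[keep],
                         m$period, cap = m$cap, aortic = m$aortic)
  expect_warning(volume_curve(short), "10 frames")
})

test_that("registration is idempotent, invertible and volume-preserving", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  reg1 <- register_sequence(g$mesh, g$landmarks)
  v0 <- mesh_volume(g$mesh)
  expect_equal(mesh_volume(reg1$mesh), v0, tolerance = 1e-12)

  # a registered sequence registers to itself
  reg2 <- register_sequence(reg1$mesh, reg1$landmarks)
  expect_lt(max(abs(reg2$mesh$vertices - reg1$mesh$vertices)), 1e-9)
  expect_lt(max(abs(reg2$transform - diag(4))), 1e-10)

  # a known rotation is undone
  set.seed(42)
  R <- random_rotation()
  rot <- rotate_sequence(reg1$mesh, R)
  lm_rot <- landmarks(reg1$landmarks$annulus_center %*% t(R),
                      reg1$landmarks$aortic_center %*% t(R),
                      reg1$landmarks$apex %*% t(R))
  reg3 <- register_sequence(rot, lm_rot)
  expect_lt(max(abs(reg3$mesh$vertices - reg1$mesh$vertices)), 1e-8)

  # degenerate axis
  lm_bad <- reg1$landmarks
  lm_bad$apex <- lm_bad$annulus_center
  expect_error(landmarks(lm_bad$annulus_center, lm_bad$aortic_center,
                         lm_bad$apex), "apex")
})

test_that("cycle resampling is band-limited-exact and validated", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 32)
  g <- generate_ventricle_sequence(sp, n_theta = 16, n_phi = 10)
  # resampling onto the original grid is an identity
  rs <- resample_cycle(g$mesh, 32)
  expect_lt(max(abs(rs$vertices - g$mesh$vertices)), 1e-8)
  # 32 -> 16 -> 32 round trip stays close for smooth motion
  rt <- resample_cycle(resample_cycle(g$mesh, 16), 32)
  scale <- max(abs(g$mesh$vertices))
  expect_lt(max(abs(rt$vertices - g$mesh$vertices)) / scale, 0.02)
  # resampled volume curve tracks the original at the original times
  vrs <- mesh_volume(resample_cycle(g$mesh, 24))
  wf_v <- g$truth$waveform$V((0:23) / 24 * sp$period)
  expect_lt(max(abs(vrs - wf_v) / wf_v), 0.01)
  expect_error(resample_cycle(g$mesh, 8), ">= 10")
})

test_that("cohort averaging is exact for identical and mirrored inputs", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 16, n_phi = 10)
  avg <- average_cohort(list(g$mesh, g$mesh))
  expect_equal(avg$vertices, g$mesh$vertices)

  m2 <- g$mesh; m3 <- g$mesh
  m2$vertices[5, 1, ] <- m2$vertices[5, 1, ] + 0.25
  m3$vertices[5, 1, ] <- m3$vertices[5, 1, ] - 0.25
  avg2 <- average_cohort(list(m2, m3))
  expect_equal(avg2$vertices, g$mesh$vertices)

  short <- mesh_sequence(g$mesh$vertices[, , 1:10], g$mesh$triangles,
                         g$mesh$times[1:10], g$mesh$period,
                         cap = g$mesh$cap, aortic = g$mesh$aortic)
  expect_error(average_cohort(list(g$mesh, short)), "frame-count")
})

test_that("mesh sequences round-trip losslessly through PLY + sidecar", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 16, n_phi = 10)
  d <- withr::local_tempdir()
  write_mesh_sequence(g$mesh, g$landmarks, file.path(d, "seq"),
                      truth = g$truth, phase = "Rest", subject = "S01",
                      seed = 1)
  back <- read_mesh_sequence(file.path(d, "seq"))
  expect_equal(back$mesh$vertices, g$mesh$vertices)
  expect_identical(back$mesh$triangles, g$mesh$triangles)
  expect_equal(back$mesh$period, g$mesh$period)
  expect_equal(back$landmarks$apex, g$landmarks$apex)
  expect_identical(back$meta$phase, "Rest")
  expect_false(back$qc_warning)

  # permuted connectivity in one frame is a topology error
  ply <- file.path(d, "seq", "frame_005.ply")
  lines <- readLines(ply)
  i <- grep("^3 ", lines)[1]
  parts <- strsplit(lines[i], " ")[[1]]
  lines[i] <- paste(parts[c(1, 2, 4, 3)], collapse = " ")
  writeLines(lines, ply)
  expect_error(read_mesh_sequence(file.path(d, "seq")), "topology|watertight")
})

test_that("reader flags sequences below 10 frames per cycle", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 16, n_phi = 10)
  keep <- 1:9 * 0 + 1:9
  short <- mesh_sequence(g$mesh$vertices[, , keep], g$mesh$triangles,
                         g$mesh$times[keep], g$mesh$period,
                         cap = g$mesh$cap, aortic = g$mesh$aortic)
  lm9 <- landmarks(g$landmarks$annulus_center[keep, ],
                   g$landmarks$aortic_center[keep, ],
                   g$landmarks$apex[keep, ])
  d <- withr::local_tempdir()
  write_mesh_sequence(short, lm9, file.path(d, "s9"))
  expect_warning(back <- read_mesh_sequence(file.path(d, "s9")), "10 frames")
  expect_true(back$qc_warning)
})
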