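test_that("triangle strain matches affine closed forms", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.2, 1, 0))
  # identity: zero strain
  expect_equal(unname(triangle_deformation_gradient(tri, tri)$eigenvalues),
               c(0, 0), tolerance = 1e-14)
  # uniform scaling by 0.7: both eigenvalues -0.3
  expect_equal(unname(triangle_deformation_gradient(tri, 0.7 * tri)$eigenvalues),
               c(-0.3, -0.3), tolerance = 1e-12)
  # rigid rotation removed by polar decomposition
  set.seed(1)
  for (i in 1:5) {
    R <- random_rotation()
    shift <- stats::rnorm(3)
    cur <- sweep(tri %*% t(R), 2, shift, "+")
    expect_lt(max(abs(triangle_deformation_gradient(tri, cur)$eigenvalues)),
              1e-12)
  }
  # anisotropic in-plane stretches 0.60 / 0.85
  A <- diag(c(0.6, 0.85, 1))
  ev <- triangle_deformation_gradient(tri, tri %*% A,
                                      long_axis = c(1, 0, 0))$eigenvalues
  expect_equal(unname(ev), c(-0.40, -0.15), tolerance = 1e-12)
  expect_error(triangle_deformation_gradient(tri, tri[c(1, 1, 2), ]),
               "degenerate")
})

test_that("directional strain probes the stretch along a tangent direction", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  iso <- triangle_deformation_gradient(tri, 0.7 * tri, long_axis = c(1, 0, 0))
  expect_equal(directional_strain(iso, c(1, 0, 0)), -0.3, tolerance = 1e-12)
  expect_equal(directional_strain(iso, c(0.3, 0.7, 0)), -0.3, tolerance = 1e-12)
  an <- triangle_deformation_gradient(tri, tri %*% diag(c(0.6, 0.9, 1)),
                                      long_axis = c(1, 0, 0))
  expect_equal(directional_strain(an, c(1, 0, 0)), -0.4, tolerance = 1e-12)
  expect_equal(directional_strain(an, c(0, 1, 0)), -0.1, tolerance = 1e-12)
  expect_error(directional_strain(an, c(0, 0, 1)), "tangent")
})

test_that("strain field is zero at the reference and respects GPS <= GSS", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 16)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  f_ed <- principal_strain_field(g$mesh, frame = 1)
  expect_lt(max(abs(f_ed$lambda_p), na.rm = TRUE), 1e-12)
  gs <- global_strain_series(g$mesh)
  expect_true(all(gs$GPS <= gs$GSS + 1e-9))
  expect_lt(max(abs(gs[1, c("GPS", "GSS", "GLS", "GCS")])), 1e-10)
})

test_that("eigenvalues are indifferent to a rigid rotation of every frame", {
  sp <- ventricle_spec(90, 36, 76, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 20, n_phi = 10)
  gs <- global_strain_series(g$mesh)
  set.seed(3)
  for (i in 1:3) {
    R <- random_rotation()
    rot <- rotate_sequence(g$mesh, R)
    # eigenvalue fields are frame-indifferent; probe axes rotate with the body
    gs_rot <- global_strain_series(rot, long_axis = as.numeric(R %*% c(0, 0, 1)))
    expect_lt(max(abs(gs_rot$GPS - gs$GPS)), 1e-10)
    expect_lt(max(abs(gs_rot$GSS - gs$GSS)), 1e-10)
  }
})

test_that("axisymmetric generators recover the imposed stretches", {
  # circumferential (hoop) stretch is exactly s^((1-p)/2) for the split map
  sp <- ventricle_spec(90, 36, 76, twist_deg = 0, long_circ_split = 0.25,
                       n_frames = 16)
  g <- generate_ventricle_sequence(sp, n_theta = 32, n_phi = 16)
  v <- mesh_volume(g$mesh)
  es <- which.min(v)
  s_es <- v[es] / v[1]
  gs <- global_strain_series(g$mesh)
  gcs_true <- 100 * (s_es^(0.375) - 1)
  expect_lt(abs(gs$GCS[es] - gcs_true), 1)      # within 1 strain-percent
  # the imposed axial scaling bounds the meridional strain from below
  gls_axial <- 100 * (s_es^0.25 - 1)
  expect_gt(gs$GLS[es], gcs_true - 1)
  expect_lt(gs$GLS[es], gls_axial + 1)

  # isotropic mode: both eigenvalues equal s^(1/3) - 1 everywhere
  spi <- ventricle_spec(90, 36, 76, twist_deg = 0, n_frames = 16)
  gi <- generate_ventricle_sequence(spi, n_theta = 24, n_phi = 12,
                                    deformation = "isotropic")
  vi <- mesh_volume(gi$mesh)
  esi <- which.min(vi)
  fld <- principal_strain_field(gi$mesh, frame = esi)
  lam_true <- (vi[esi] / vi[1])^(1 / 3) - 1
  expect_lt(max(abs(fld$lambda_p - lam_true), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(fld$lambda_s - lam_true), na.rm = TRUE), 1e-9)
})

test_that("area-weighted directional strain is exact under isotropic contraction", {
  sp <- ventricle_spec(90, 36, 76, twist_deg = 0, n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 20, n_phi = 10,
                                   deformation = "isotropic")
  v <- mesh_volume(g$mesh)
  es <- which.min(v)
  lam <- (v[es] / v[1])^(1 / 3) - 1
  fld <- principal_strain_field(g$mesh, frame = es)
  ds <- directional_strain(fld, c(0, 0, 1))
  w <- fld$ref_area[!fld$masked] / sum(fld$ref_area[!fld$masked])
  expect_equal(sum(w * ds[!fld$masked]), lam, tolerance = 1e-10)
})

test_that("a leading dominant contraction produces the early positive GSS peak", {
  sp <- ventricle_spec(90, 36, 76, twist_deg = 0, split_lead = 1,
                       n_frames = 32)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  gs <- global_strain_series(g$mesh)
  es <- which.min(mesh_volume(g$mesh))
  # positive secondary-strain peak early in systole, negative at end systole
  expect_gt(max(gs$GSS[2:es]), 0)
  expect_lt(which.max(gs$GSS), es)
  expect_lt(gs$GSS[es], 0)
  expect_lt(gs$GPS[es], gs$GSS[es])
})

test_that("principal directions align with meridians under longitudinal shortening", {
  sp <- ventricle_spec(90, 36, 76, twist_deg = 0, long_circ_split = 1,
                       n_frames = 12)
  g <- generate_ventricle_sequence(sp, n_theta = 24, n_phi = 12)
  v <- mesh_volume(g$mesh)
  es <- which.min(v)
  fld <- principal_strain_field(g$mesh, frame = es)
  wall <- !fld$cap & !fld$masked
  k <- attr(fld, "core")
  # local longitudinal direction is u1 by construction; the principal
  # direction should be within 5 degrees of it on average
  dirs <- as.matrix(fld[wall, c("dir_x", "dir_y", "dir_z")])
  cosang <- abs(rowSums(dirs * k$u1[wall, ]))
  ang <- acos(pmin(cosang, 1)) * 180 / pi
  expect_lt(mean(ang), 5)
})
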