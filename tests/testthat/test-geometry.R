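# Cylindrical frame fitting, generic-size normalization, skin projection
# and pose construction.

test_that("bounding cylinder radius is enclosing, not least squares", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(50 * cos(th), 50 * sin(th), runif(40, 0, 100))
  fr <- fit_cylinder(pts)
  expect_equal(fr$R_c, 50, tolerance = 1e-6)
  expect_equal(fr$h_range, range(pts[, 3]))
  # one outlier: the circle must still enclose it (with its center free
  # to shift, the minimal radius here is (80 + 50) / 2, not 50)
  pts2 <- rbind(pts, c(80, 0, 50))
  fr2 <- fit_cylinder(pts2)
  expect_equal(fr2$R_c, 65, tolerance = 1e-6)
  ctr <- c(sum(fr2$axis_point * fr2$u), sum(fr2$axis_point * fr2$v))
  d2 <- sqrt((pts2[, 1] - ctr[1])^2 + (pts2[, 2] - ctr[2])^2)
  expect_true(all(d2 <= fr2$R_c + 1e-6))
  expect_equal(sqrt(sum((c(80, 0) - ctr)^2)), fr2$R_c,
               tolerance = 1e-6)          # the outlier sits on the circle
  on_axis <- cbind(0, 0, seq_len(12))
  expect_error(fit_cylinder(on_axis), "degenerate")
})

test_that("minimal enclosing circle agrees with the brute-force oracle", {
  for (sd in 1:5) {
    with_seed(sd, {
      P <- cbind(rnorm(30, sd = 20), rnorm(30, sd = 12))
      pts3 <- cbind(P, runif(30, 0, 50))
      fr <- fit_cylinder(pts3)
      ref <- oracle_mec(sweep(P, 2, c(0, 0)))
      expect_equal(fr$R_c, ref$r, tolerance = 1e-6)
      # all points enclosed, at least one on the boundary
      d <- sqrt((P[, 1] - sum(fr$axis_point * fr$u))^2 +
                  (P[, 2] - sum(fr$axis_point * fr$v))^2)
      expect_true(all(d <= fr$R_c + 1e-6))
      expect_gt(max(d), fr$R_c - 1e-6)
    })
  }
})

test_that("generic-scale mapping is an exact affine with exact inverse", {
  sc <- generate_phantom(phantom_config(seed = 4))
  fr <- fit_cylinder(scene_bone_points(sc))
  with_seed(1, {
    pts <- cbind(runif(50, -80, 80), runif(50, -80, 80), runif(50, 0, 170))
    expect_equal(from_generic(fr, to_generic(fr, pts)), pts,
                 tolerance = 1e-9)
  })
  # identity when the frame already has generic dimensions
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  gpts <- cbind(100 * cos(th), 100 * sin(th), seq(0, 200, length.out = 36))
  gfr <- fit_cylinder(gpts)
  expect_equal(gfr$R_c, 100, tolerance = 1e-6)
  expect_equal(to_generic(gfr, gpts), gpts, tolerance = 1e-5)
  # axial displacements scale linearly: patient h-extent twice generic
  wide <- cbind(100 * cos(th), 100 * sin(th), seq(0, 400, length.out = 36))
  wfr <- fit_cylinder(wide)
  p1 <- to_generic(wfr, list(h = 100, theta = 0))
  p2 <- to_generic(wfr, list(h = 110, theta = 0))
  expect_equal(p2$h - p1$h, 5)            # 10 mm -> 5 mm in generic scale
})

test_that("surface projection finds the first skin hit along inward rays", {
  # full-ring bone points give a frame coaxial with the skin cylinder
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- cbind(84 * cos(th), 84 * sin(th),
                rep(c(20, 150), length.out = 72))
  fr <- fit_cylinder(ring)
  skin <- cylinder_skin(0, 0, 95, c(0, 170))
  pr <- surface_project(85, 30, fr, skin)
  expect_equal(sqrt(sum(pr$contact_point[1:2]^2)), 95, tolerance = 1e-6)
  expect_equal(pr$skin_normal,
               c(cos(30 * pi / 180), sin(30 * pi / 180), 0),
               tolerance = 1e-6)
  expect_equal(pr$contact_point[3], 85, tolerance = 1e-6)
  # off the cropped skin: no intersection
  expect_null(surface_project(500, 0, fr, skin))
})

test_that("projection onto a bumped mesh skin matches an inclusion-march
           oracle", {
  mesh <- cylinder_mesh(0, 0, 90, c(0, 170), n_seg = 64)
  # raise a vertical ridge near theta = 0 (the mesh has vertices only on
  # its end rings, so the bump spans the full height there)
  v <- mesh$vertices
  sel <- abs(atan2(v[, 2], v[, 1])) < 0.4 & v[, 1]^2 + v[, 2]^2 > 1
  v[sel, 1:2] <- v[sel, 1:2] * 1.12
  bumped <- mesh_shape(v, mesh$faces, "bumped")
  expect_true(mesh_is_watertight(bumped))
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring <- cbind(84 * cos(th), 84 * sin(th),
                rep(c(20, 150), length.out = 72))
  fr <- fit_cylinder(ring)
  pr <- surface_project(85, 0, fr, bumped)
  expect_gt(sqrt(sum(pr$contact_point[1:2]^2)), 95)  # on the bump
  # independent oracle: march the inward ray, first point inside the mesh
  ts <- seq(150, 50, by = -0.1)
  pts <- cbind(ts, 0, 85)                 # x descending towards the axis
  first_in <- ts[which(shape_inside(bumped, pts))[1]]
  expect_equal(pr$contact_point[1], first_in, tolerance = 0.2)
})

test_that("pose construction honours the rotation conventions", {
  sc <- easy_scene()
  fr <- fit_cylinder(scene_bone_points(sc))
  p0 <- build_pose(85, 20, 0, 0, fr, sc$skin)
  expect_equal(p0$centerline, -p0$skin_normal, tolerance = 1e-9)
  expect_equal(p0$tilt, 0, tolerance = 1e-9)
  expect_false(p0$terminal_tilt)
  # phi = 90 degrees turns the long axis onto the cylinder axis
  p90 <- build_pose(85, 20, 90, 0, fr, sc$skin)
  expect_equal(p90$long_axis, c(0, 0, 1), tolerance = 1e-9)
  # tilt flag switches exactly beyond 20 degrees
  expect_false(build_pose(85, 20, 0, 20, fr, sc$skin)$terminal_tilt)
  expect_true(build_pose(85, 20, 0, 20.01, fr, sc$skin)$terminal_tilt)
  expect_equal(build_pose(85, 20, 0, 12, fr, sc$skin)$tilt, 12,
               tolerance = 1e-9)
})

test_that("a full phi revolution returns the identical probe frame", {
  sc <- easy_scene()
  fr <- fit_cylinder(scene_bone_points(sc))
  for (phi in c(0, 37, 123)) {
    a <- build_pose(60, -25, phi, 5, fr, sc$skin)
    b <- build_pose(60, -25, phi + 360, 5, fr, sc$skin)
    expect_equal(a$centerline, b$centerline, tolerance = 1e-9)
    expect_equal(a$long_axis, b$long_axis, tolerance = 1e-9)
  }
})

test_that("poses serialize with their world transform", {
  sc <- easy_scene()
  fr <- fit_cylinder(scene_bone_points(sc))
  p <- build_pose(85, 10, 4, 6, fr, sc$skin)
  m <- pose_transform(p)
  expect_equal(m[1:3, 3], p$centerline)
  expect_equal(det(m[1:3, 1:3]), 1, tolerance = 1e-9)
  rec <- jsonlite::fromJSON(pose_to_json(p))
  expect_equal(rec$h, 85)
  expect_equal(rec$transform[1:3, 4], p$contact_point, tolerance = 1e-12)
})
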