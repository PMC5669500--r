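test_that("classifier labels canonical shapes", {
  expect_identical(classify_shape(build_icosphere(2))$label, "sphere")
  tube <- tube_seed_mesh()
  expect_identical(classify_shape(tube)$label, "tube")
  disk <- disk_seed_mesh()
  expect_identical(classify_shape(disk)$label, "disk")
})

test_that("classifier is invariant under rigid motion and scaling", {
  m <- tube_seed_mesh()
  base <- classify_shape(m)$label
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  x2 <- (m$x %*% R) * 2.7
  m2 <- trimesh(sweep(x2, 2, c(4, -2, 9), `+`), m$tri,
                l_min = m$l_min * 2.7, l_max = m$l_max * 2.7)
  expect_identical(classify_shape(m2)$label, base)
})

test_that("barrier extraction reproduces an analytic double-well profile", {
  # quartic double well in da with known extrema:
  # E(x) = x^4/4 - x^2/2 has minima at +-1 (E = -1/4), maximum at 0 (E = 0)
  x <- seq(-1.5, 1.5, by = 0.05)
  branch <- data.frame(da = x + 1.2, E_b = x^4 / 4 - x^2 / 2)
  bar <- extract_barriers(branch)
  expect_equal(bar$H1, 0.25, tolerance = 1e-9)
  roles <- bar$stationary$role
  expect_true("tube_min" %in% roles && "tube_disk_top" %in% roles)
  # monotone profile: no barrier reported
  mono <- data.frame(da = seq(0.9, 1.5, by = 0.05),
                     E_b = seq(2, 1, length.out = 13))
  b2 <- extract_barriers(mono)
  expect_true(is.na(b2$H1))
})

test_that("two-barrier profiles yield both H1 and H2 with correct roles", {
  # smooth profile mimicking the shape branch: minima near 1.44 (tube),
  # 1.04 (disk), 0.85 (cup), maxima near 1.30 and 0.95
  ctrl <- data.frame(da = c(0.80, 0.85, 0.95, 1.04, 1.30, 1.44, 1.50),
                     E = c(2.01, 2.00, 2.05, 2.01, 2.27, 2.20, 2.24))
  sf <- splinefun(ctrl$da, ctrl$E, method = "fmm")
  da <- seq(0.8, 1.5, by = 0.02)
  branch <- data.frame(da = da, E_b = sf(da))
  bar <- extract_barriers(branch)
  expect_false(is.na(bar$H1))
  expect_false(is.na(bar$H2))
  expect_gt(bar$H1, 0)
  expect_gt(bar$H2, 0)
  st <- bar$stationary
  expect_lt(st$da[match("disk_min", st$role)], st$da[match("tube_min", st$role)])
  expect_lt(st$da[match("disk_cup_top", st$role)], st$da[match("disk_min", st$role)])
})

test_that("success rate applies the 75 percent criterion", {
  all_cup <- rep("cup", 35)
  expect_true(success_rate(all_cup)$successful)
  r26 <- success_rate(c(rep("cup", 26), rep("tube", 9)))
  expect_equal(r26$fraction, 26 / 35, tolerance = 1e-12)
  expect_false(r26$successful)
  r27 <- success_rate(c(rep("cup", 27), rep("tube", 8)))
  expect_equal(r27$fraction, 27 / 35, tolerance = 1e-12)
  expect_true(r27$successful)
})

test_that("descriptors are scale invariant and computed from the mesh alone", {
  m <- disk_seed_mesh()
  d1 <- shape_descriptors(m)
  m2 <- trimesh(m$x * 3, m$tri, l_min = m$l_min * 3, l_max = m$l_max * 3)
  d2 <- shape_descriptors(m2)
  expect_equal(d2$asphericity, d1$asphericity, tolerance = 1e-9)
  expect_equal(d2$v, d1$v, tolerance = 1e-9)
  expect_equal(d2$pocket_depth, d1$pocket_depth, tolerance = 1e-9)
  expect_equal(d2$lam1 / d2$lam3, d1$lam1 / d1$lam3, tolerance = 1e-9)
})
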