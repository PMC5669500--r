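test_that("built S-dimer geometry: zero reference energy, contour, tips", {
  ch <- build_s_dimer()
  expect_equal(chain_internal_energy(ch), 0, tolerance = 1e-18)
  expect_equal(nrow(ch$x), 16L)
  # unit bonds spanning the double quarter-arc
  expect_equal(unname(ch$ref_bonds), rep(1, 15), tolerance = 1e-9)
  # planar S (no tilt): tip-to-tip distance = 2*sqrt(2)*arc_radius
  rho <- 1 / (2 * sin(pi / 30))
  flat <- build_s_dimer(arc_radius = rho, tilt = 0)
  tip <- sqrt(sum((flat$x[16, ] - flat$x[1, ])^2))
  expect_equal(tip, 2 * sqrt(2) * rho, tolerance = 0.03)
  # contour length ~ pi * arc_radius
  expect_equal(sum(flat$ref_bonds), pi * rho, tolerance = 0.01)
})

test_that("straight chain: collinear reference with zero energy", {
  ch <- build_straight_chain()
  expect_equal(chain_internal_energy(ch), 0, tolerance = 1e-18)
  expect_equal(unname(ch$theta0), rep(pi, 14), tolerance = 1e-9)
  # bending one interior angle by dth costs K_ang/2 * dth^2
  bent <- ch
  dth <- 0.1
  bent$x[16, ] <- bent$x[15, ] + c(cos(dth), sin(dth), 0)
  e <- chain_internal_energy(bent, K_bond = 1e4, K_ang = 1e3, K_dih = 500)
  expect_equal(e, 0.5 * 1e3 * dth^2, tolerance = 1e-6)
})

test_that("bond stretching follows the printed stiffness arithmetic", {
  ch <- build_straight_chain()
  st <- ch
  st$x[16, 1] <- st$x[15, 1] + 1.01
  e <- chain_internal_energy(st, K_bond = 1e4, K_ang = 1e3, K_dih = 500)
  expect_equal(e, 0.5 * 1e4 * 0.01^2, tolerance = 1e-9)
  # flexible vs rigid: same deformation, five-fold cheaper angles
  bent <- ch
  bent$x[16, ] <- bent$x[15, ] + c(cos(0.2), sin(0.2), 0)
  e_rigid <- chain_internal_energy(bent, K_ang = 1e3)
  e_flex <- chain_internal_energy(bent, K_ang = 200)
  expect_equal(e_rigid / e_flex, 5, tolerance = 1e-9)
})

test_that("internal energy is rigid-motion invariant", {
  ch <- build_s_dimer()
  # displace into a generic pose first so the energy is nonzero
  ch$x[8, ] <- ch$x[8, ] + c(0.05, -0.02, 0.03)
  e0 <- chain_internal_energy(ch)
  expect_gt(e0, 0)
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mv <- ch
  mv$x <- ch$x %*% Rz + matrix(c(3, -7, 2), nrow(ch$x), 3, byrow = TRUE)
  expect_equal(chain_internal_energy(mv), e0, tolerance = 1e-9)
})

test_that("bead-surface distance agrees with a brute-force oracle", {
  m <- build_icosphere(1)
  set.seed(4)
  # independent oracle: dense barycentric sampling of every triangle
  grid <- expand.grid(u = seq(0, 1, length.out = 60),
                      v = seq(0, 1, length.out = 60))
  grid <- grid[grid$u + grid$v <= 1, ]
  oracle <- function(p) {
    best <- Inf; bt <- NA
    for (t in seq_len(nrow(m$tri))) {
      a <- m$x[m$tri[t, 1], ]; b <- m$x[m$tri[t, 2], ]; cc <- m$x[m$tri[t, 3], ]
      pts <- cbind(a[1] + grid$u * (b[1] - a[1]) + grid$v * (cc[1] - a[1]),
                   a[2] + grid$u * (b[2] - a[2]) + grid$v * (cc[2] - a[2]),
                   a[3] + grid$u * (b[3] - a[3]) + grid$v * (cc[3] - a[3]))
      d <- min(sqrt(rowSums(sweep(pts, 2, p)^2)))
      if (d < best) { best <- d; bt <- t }
    }
    c(best, bt)
  }
  for (k in 1:5) {
    p <- rnorm(3) * 2
    got <- bead_surface_distance(p, m)
    ref <- oracle(p)
    expect_equal(got$d, ref[1], tolerance = 0.02)
  }
  # a bead directly above a triangle centroid at small height
  t1 <- m$tri[1, ]
  cen <- colMeans(m$x[t1, ])
  n <- phagosim:::cross3(m$x[t1[2], ] - m$x[t1[1], ], m$x[t1[3], ] - m$x[t1[1], ])
  n <- n / sqrt(sum(n^2))
  bd <- bead_surface_distance(cen + 0.05 * n, m)
  expect_equal(bd$d, 0.05, tolerance = 1e-9)
  expect_equal(bd$triangle, 1L)
  expect_equal(bd$side, 1)
})

test_that("square-well adhesion energy and its linearity in U", {
  m <- build_icosphere(2)
  areas <- phagosim:::tri_areas_raw(m$x, m$tri)
  ch <- build_straight_chain(4)
  # place all beads far outside the well
  ch$x <- ch$x + matrix(c(0, 0, 30), 4, 3, byrow = TRUE)
  p <- adhesion_params(U = 2, d0 = 0.5, d1 = 1)
  expect_equal(adhesion_energy(list(ch), m, p)$E_bd, 0)
  # one bead inside the well above triangle 1
  t1 <- m$tri[1, ]
  cen <- colMeans(m$x[t1, ])
  n <- phagosim:::cross3(m$x[t1[2], ] - m$x[t1[1], ], m$x[t1[3], ] - m$x[t1[1], ])
  n <- n / sqrt(sum(n^2))
  one <- build_straight_chain(4)
  one$x <- sweep(one$x %*% diag(3), 2, cen + 0.75 * n - one$x[1, ], `+`)
  one$x[2:4, ] <- one$x[2:4, ] + matrix(c(0, 0, 30), 3, 3, byrow = TRUE)
  a1 <- adhesion_energy(list(one), m, p)
  expect_equal(a1$E_bd, -2 * areas[a1$map$triangle[1]], tolerance = 1e-9)
  p2 <- adhesion_params(U = 4, d0 = 0.5, d1 = 1)
  expect_equal(adhesion_energy(list(one), m, p2)$E_bd, 2 * a1$E_bd,
               tolerance = 1e-12)
  # scoring inside the hard core is an error for the caller to prevent
  deep <- one
  deep$x[1, ] <- cen + 0.2 * n
  expect_error(adhesion_energy(list(deep), m, p), "hard-core")
})

test_that("reduced binding strength conversion round-trips", {
  expect_equal(u_to_U(0, 10, 0.43), 0)
  u <- 0.12; kap <- 10
  abar <- surface_area(build_icosphere(3)) / 1280
  U <- u_to_U(u, kap, abar)
  expect_equal(U_to_u(U, kap, abar), u, tolerance = 1e-12)
  expect_equal(U, u * 8 * pi * kap / (16 * abar), tolerance = 1e-12)
})

test_that("excluded-volume checks reject the right configurations", {
  m <- build_icosphere(2)
  p <- adhesion_params(U = 1)
  far <- build_straight_chain(4)
  far$x <- far$x + matrix(c(0, 0, 30), 4, 3, byrow = TRUE)
  far2 <- build_straight_chain(4)
  far2$x <- far2$x + matrix(c(0, 20, 30), 4, 3, byrow = TRUE)
  expect_true(excluded_volume_check(list(far, far2), m, p)$ok)
  close2 <- far2
  close2$x <- far$x + matrix(c(0, 0.99, 0), 4, 3, byrow = TRUE)
  res <- excluded_volume_check(list(far, close2), m, p)
  expect_false(res$ok)
  expect_match(res$reason, "separation")
  # side-flag change (membrane crossing) is rejected
  ok0 <- excluded_volume_check(list(far), m, p)
  flip_sides <- -ok0$sides
  expect_false(excluded_volume_check(list(far), m, p, prev_sides = flip_sides)$ok)
})
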