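test_that("fused-sphere meshes are valid and close to v = 1/sqrt(n)", {
  for (n in 2:4) {
    m <- fused_spheres_mesh(n, subdivision = 3, seed = 7)
    expect_length(validate_mesh(m), 0)
    cnt <- mesh_counts(m)
    expect_identical(unname(cnt["n_t"] - cnt["n_e"] + cnt["n_v"]), 2L)
    st <- shape_state(m)
    expect_equal(st$v, 1 / sqrt(n), tolerance = 0.02)
    expect_gt(st$da, 1.2)  # pearled, elongated initial state
  }
  # n = 1 degenerates to the plain icosphere
  expect_identical(mesh_counts(fused_spheres_mesh(1, subdivision = 2)),
                   mesh_counts(build_icosphere(2)))
})

test_that("narrower necks drive v toward the ideal fused value", {
  v_narrow <- shape_state(fused_spheres_mesh(3, neck_radius_fraction = 0.06,
                                             subdivision = 3, seed = 5))$v
  v_wide <- shape_state(fused_spheres_mesh(3, neck_radius_fraction = 0.25,
                                           subdivision = 3, seed = 5))$v
  ideal <- 1 / sqrt(3)
  expect_lt(abs(v_narrow - ideal), abs(v_wide - ideal) + 0.01)
})

test_that("dimer placement puts every bead in the adhesion well", {
  m <- fused_spheres_mesh(3, subdivision = 3, seed = 7)
  p <- adhesion_params(U = 1)
  ch <- place_dimers(m, 6, shape = "s", params = p)
  expect_length(ch, 6)
  ad <- adhesion_energy(ch, m, p)
  expect_lt(ad$E_bd, 0)
  expect_true(all(ad$map$bound))
  expect_true(all(ad$map$d > p$d0))
  expect_true(excluded_volume_check(ch, m, p)$ok)
})

test_that("rotating all chains about the fusion axis keeps them bound", {
  m <- fused_spheres_mesh(3, subdivision = 3, seed = 7)
  p <- adhesion_params(U = 1)
  ch <- place_dimers(m, 6, shape = "s", params = p)
  e0 <- adhesion_energy(ch, m, p)$E_bd
  th <- 0.4
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- lapply(ch, function(c_) { c_$x <- c_$x %*% Rz; c_ })
  n_bound <- sum(adhesion_energy(rot, m, p)$map$bound)
  # rotational near-symmetry: almost all beads stay in the well, and the
  # adhesion energy changes only at the discreteness level
  expect_gt(n_bound, 90)
  e1 <- adhesion_energy(rot, m, p)$E_bd
  expect_lt(abs(e1 - e0) / abs(e0), 0.12)
})

test_that("straight chains and four-sphere configurations also place", {
  m3 <- fused_spheres_mesh(3, subdivision = 3, seed = 7)
  chs <- place_dimers(m3, 6, shape = "straight")
  expect_length(chs, 6)
  expect_true(all(vapply(chs, function(c_) c_$shape == "straight", logical(1))))
  m4 <- fused_spheres_mesh(4, subdivision = 3, seed = 7)
  ch4 <- place_dimers(m4, 6, shape = "s")
  expect_length(ch4, 6)
})

test_that("fusing a vesicle onto a shape keeps genus 0 and shifts targets", {
  host <- fused_spheres_mesh(3, subdivision = 2, seed = 5)
  R_add <- attr(host, "sphere_radius")
  attr(host, "A_ideal") <- 3 * 4 * pi * R_add^2
  attr(host, "V_ideal") <- 3 * 4 / 3 * pi * R_add^3
  out <- fuse_vesicle_to_shape(host, R_add,
                               attachment_point = c(0, 0, max(host$x[, 3])),
                               subdivision = 2, seed = 5)
  cnt <- mesh_counts(out)
  expect_identical(unname(cnt["n_t"] - cnt["n_e"] + cnt["n_v"]), 2L)
  v_target <- reduced_volume(attr(out, "A_ideal"), attr(out, "V_ideal"))
  expect_equal(v_target, 0.5, tolerance = 1e-6)   # 3 + 1 equal spheres
  # zero-radius addition leaves the mesh untouched
  same <- fuse_vesicle_to_shape(host, 0, c(0, 0, 0))
  expect_identical(same$x, host$x)
})
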