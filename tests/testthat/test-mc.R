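test_that("incremental energy bookkeeping matches full recomputation", {
  m <- build_icosphere(2)
  mod <- free_vesicle_model(m)
  # long enough that tens of thousands of moves have been attempted, with
  # cache refresh disabled so drift would be visible
  sc <- mc_schedule(60, temperature = 1, stride = 0, seed = 5,
                    refresh_every = 100000L)
  r <- run_mc(m, mod, sc)
  expect_equal(r$E_b, bending_energy(r$mesh, mod$kappa), tolerance = 1e-8)
  expect_equal(r$A, surface_area(r$mesh), tolerance = 1e-10)
  expect_equal(r$V, signed_volume(r$mesh), tolerance = 1e-10)
  expect_equal(r$da, area_difference(r$mesh), tolerance = 1e-8)
})

test_that("identical seed and configuration give bit-identical trajectories", {
  m <- build_icosphere(1)
  mod <- free_vesicle_model(m)
  sc <- mc_schedule(40, temperature = 1, stride = 10, seed = 123)
  r1 <- run_mc(m, mod, sc)
  r2 <- run_mc(m, mod, sc)
  expect_identical(r1$mesh$x, r2$mesh$x)
  expect_identical(r1$mesh$tri, r2$mesh$tri)
  expect_identical(r1$obs, r2$obs)
  r3 <- run_mc(m, mod, mc_schedule(40, temperature = 1, stride = 10, seed = 124))
  expect_false(identical(r1$mesh$x, r3$mesh$x))
})

test_that("at zero temperature only downhill moves are accepted", {
  m <- build_icosphere(1)
  # start from a perturbed sphere so there is energy to dissipate
  set.seed(2)
  x <- m$x * (1 + 0.02 * rnorm(nrow(m$x)))
  m2 <- trimesh(x, m$tri, l_min = m$l_min, l_max = m$l_max)
  mod <- free_vesicle_model(m2)
  sc <- mc_schedule(150, temperature = 0, stride = 5, seed = 3, tune = FALSE,
                    width_vertex = 0.05)
  r <- run_mc(m2, mod, sc)
  tot <- rowSums(r$obs[, c("E_b", "E_area", "E_vol")])
  expect_true(all(diff(tot) <= 1e-6))
})

test_that("the engine samples the Boltzmann distribution of a bond", {
  # two-bead chain far from the membrane: the only energy is the harmonic
  # bond 0.5*K*(L-1)^2 with radial Jacobian L^2. Exact moments and bin
  # probabilities come from quadrature of the closed-form density.
  m <- build_icosphere(1)
  K <- 100
  mod <- energy_model(kappa = 20, K_A = 1e6, K_V = 1e6,
                      A_ref = surface_area(m), V_ref = signed_volume(m),
                      U = 0, K_bond = K, K_ang = 1e3, K_dih = 500)
  ch <- build_straight_chain(2)
  ch$x <- ch$x + matrix(c(0, 0, 40), 2, 3, byrow = TRUE)
  sc <- mc_schedule(4000, temperature = 1, stride = 1, seed = 17,
                    tune = FALSE, width_vertex = 0.1, width_bead = 0.35)
  r <- run_mc(m, mod, sc, chains = list(ch))
  Ed <- r$obs$E_d[-(1:200)]
  # exact reference by quadrature
  Lg <- seq(0.25, 1.75, length.out = 20001)
  w <- Lg^2 * exp(-0.5 * K * (Lg - 1)^2)
  w <- w / sum(w)
  Ed_mean_exact <- sum(w * 0.5 * K * (Lg - 1)^2)
  g <- phagosim:::statistical_inefficiency(Ed)
  n_eff <- length(Ed) / g
  se <- sd(Ed) / sqrt(n_eff)
  expect_lt(abs(mean(Ed) - Ed_mean_exact), 3 * se)
  # chi-squared goodness of fit of the sampled bond-energy histogram
  brk <- c(0, 0.05, 0.15, 0.3, 0.5, 0.8, 1.3, 2, Inf)
  pexp_ <- vapply(seq_len(length(brk) - 1), function(i) {
    e <- 0.5 * K * (Lg - 1)^2
    sum(w[e >= brk[i] & e < brk[i + 1]])
  }, numeric(1))
  Ed_thin <- Ed[seq(1, length(Ed), by = max(1, round(g)))]
  obs <- tabulate(findInterval(Ed_thin, brk), nbins = length(brk) - 1)
  keep <- pexp_ > 1e-4
  ct <- suppressWarnings(chisq.test(obs[keep], p = pexp_[keep] / sum(pexp_[keep])))
  expect_gt(ct$p.value, 0.01)
})

test_that("width tuning reaches the target acceptance window", {
  m <- build_icosphere(2)
  mod <- free_vesicle_model(m)
  tw <- tune_move_widths(m, mod, n_sweeps = 300, seed = 8)
  expect_gt(tw$acc["vertex"], 0.3)
  expect_lt(tw$acc["vertex"], 0.5)
  expect_true(tw$ok)
})

test_that("area and volume stay within about a tenth of a percent", {
  m <- build_icosphere(3)
  mod <- free_vesicle_model(m, K_A = 4e6, K_V = 4e6)
  r <- run_mc(m, mod, mc_schedule(800, temperature = 1, stride = 10, seed = 2))
  o <- tail(r$obs, 40)
  expect_lt(sd(o$A) / mod$A_ref, 1e-3)
  expect_lt(sd(o$V) / mod$V_ref, 1e-3)
  expect_lt(abs(mean(o$A) / mod$A_ref - 1), 5e-3)
  expect_lt(abs(mean(o$V) / mod$V_ref - 1), 5e-3)
})

test_that("rigid chains behave as rigid bodies in the stiff limit", {
  m <- build_icosphere(1)
  mod <- energy_model(kappa = 20, K_A = 1e6, K_V = 1e6,
                      A_ref = surface_area(m), V_ref = signed_volume(m),
                      K_bond = 1e6, K_ang = 1e6, K_dih = 1e6)
  ch <- build_s_dimer()
  ch$x <- ch$x + matrix(c(0, 0, 30), 16, 3, byrow = TRUE)
  sc <- mc_schedule(400, temperature = 1, stride = 10, seed = 6,
                    tune = FALSE, width_bead = 0.05)
  r <- run_mc(m, mod, sc, chains = list(ch))
  e2e0 <- sqrt(sum((ch$x[16, ] - ch$x[1, ])^2))
  e2e1 <- sqrt(sum((r$chains[[1]]$x[16, ] - r$chains[[1]]$x[1, ])^2))
  expect_lt(abs(e2e1 / e2e0 - 1), 0.01)
})

test_that("annealing returns the minimum repeat and cools the energy", {
  sa <- simulated_annealing(1, da_target = NULL,
                            model = energy_model(kappa = 20),
                            mesh = build_icosphere(2),
                            sweeps = list(ramp_v = 100, ramp_da = 50,
                                          equil = 150, cool = 300),
                            n_repeats = 3, seed = 21)
  # v = 1, unconstrained da: the sphere is the ground state, E_b -> 8 pi k
  expect_lt(sa$E_b_8pk, 1.05)
  expect_equal(sa$E_b, min(sa$repeats$E_b), tolerance = 1e-12)
  expect_lte(sa$E_b, median(sa$repeats$E_b))
})

test_that("shape_branch_scan returns an ordered, labeled branch table", {
  br <- shape_branch_scan(0.7, da_grid = c(1.15, 1.05),
                          model = energy_model(kappa = 20),
                          subdivision = 2L, n_repeats = 1L,
                          sweeps = list(ramp_v = 100, ramp_da = 150,
                                        equil = 100, cool = 250),
                          seed = 5, init = "sphere")
  expect_equal(br$da, c(1.15, 1.05))
  expect_true(all(is.finite(br$E_b_8pk)))
  expect_true(all(br$E_b_8pk > 0.9))
  expect_true(all(abs(br$da_out - br$da) < 0.01))   # constraint honored
  expect_true(is.character(br$label))
  expect_equal(dim(attr(br, "repeats")), c(2, 1))
})
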