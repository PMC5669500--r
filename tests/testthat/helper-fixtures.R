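# shared fixtures built in code (seed meshes come from the package's
# exported tube_seed_mesh / disk_seed_mesh constructors)

free_vesicle_model <- function(mesh, kappa = 20, K_A = 1e6, K_V = 1e6) {
  energy_model(kappa = kappa, K_A = K_A, K_V = K_V,
               A_ref = surface_area(mesh), V_ref = signed_volume(mesh))
}

# exact biased sampling from a 1-D potential by inverse-CDF on a fine grid
sample_biased <- function(Ffun, center, k, n, lims = c(-2, 2), seed = 1) {
  set.seed(seed)
  x <- seq(lims[1], lims[2], length.out = 40001)
  dens <- exp(-(Ffun(x) + 0.5 * k * (x - center)^2))
  cdf <- cumsum(dens) / sum(dens)
  keep <- !duplicated(cdf)
  approx(cdf[keep], x[keep], xout = runif(n), rule = 2)$y
}
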