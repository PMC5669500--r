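#' Analytic seed meshes for the shape branch
#'
#' Branch minimizations converge far faster (and more reproducibly) when
#' started inside the right basin. These constructors build axisymmetric
#' seed surfaces at a prescribed reduced volume — a spherocylinder for the
#' tube branch, an oblate ellipsoid for the disk branch — triangulated with
#' near-unit edges and tether-re-equilibrated.
#'
#' @param v_target reduced volume of the seed (the aspect ratio is solved
#'   from it).
#' @param A_target surface area in squared tether lengths; the default
#'   matches the 642-vertex resolution (1280 triangles of mean area
#'   `sqrt(3)/4`).
#' @param seed RNG seed of the tether re-equilibration.
#' @return a `trimesh`.
#' @export
tube_seed_mesh <- function(v_target = 1 / sqrt(3),
                           A_target = 1280 * sqrt(3) / 4, seed = 3L) {
  stopifnot(v_target > 0, v_target < 1)
  # spherocylinder (radius a, cylinder length L): v depends only on L/a
  f <- function(LoA) {
    A <- 2 * pi * LoA + 4 * pi
    V <- pi * LoA + 4 / 3 * pi
    6 * sqrt(pi) * V / A^1.5 - v_target
  }
  LoA <- uniroot(f, c(1e-3, 200))$root
  a <- sqrt(A_target / (2 * pi * LoA + 4 * pi))
  prof <- spherocylinder_profile(a, LoA * a)
  rv <- revolution_mesh(prof)
  relax_tether(rv$x, rv$tri, relax_sweeps = 200, seed = seed)
}

#' @rdname tube_seed_mesh
#' @export
disk_seed_mesh <- function(v_target = 1 / sqrt(3),
                           A_target = 1280 * sqrt(3) / 4, seed = 3L) {
  stopifnot(v_target > 0, v_target < 1)
  f <- function(boa) oblate_v(boa) - v_target
  boa <- uniroot(f, c(0.02, 0.999))$root
  t <- seq(0, pi, length.out = 4001)
  z <- -boa * cos(t); r <- sin(t)
  A1 <- sum(2 * pi * (r[-1] + r[-4001]) / 2 * sqrt(diff(z)^2 + diff(r)^2))
  scl <- sqrt(A_target / A1)
  prof <- oblate_profile(scl, boa * scl)
  rv <- revolution_mesh(prof)
  relax_tether(rv$x, rv$tri, relax_sweeps = 200, seed = seed)
}

oblate_v <- function(boa) {
  t <- seq(0, pi, length.out = 4001)
  z <- -boa * cos(t); r <- sin(t)
  A <- sum(2 * pi * (r[-1] + r[-4001]) / 2 * sqrt(diff(z)^2 + diff(r)^2))
  V <- 4 / 3 * pi * boa
  6 * sqrt(pi) * V / A^1.5
}

spherocylinder_profile <- function(a, L, n = 1500) {
  q <- seq(0, pi / 2, length.out = n %/% 3)
  z <- c(-L / 2 - a * cos(q), seq(-L / 2, L / 2, length.out = n %/% 3),
         L / 2 + a * sin(q))
  r <- c(a * sin(q), rep(a, n %/% 3), a * cos(q))
  keep <- !duplicated(cbind(z, r))
  z <- z[keep]; r <- r[keep]
  data.frame(s = cumsum(c(0, sqrt(diff(z)^2 + diff(r)^2))), z = z, r = r)
}

oblate_profile <- function(a, b, n = 2000) {
  t <- seq(0, pi, length.out = n)
  z <- -b * cos(t); r <- a * sin(t)
  keep <- !duplicated(cbind(z, r))
  z <- z[keep]; r <- r[keep]
  data.frame(s = cumsum(c(0, sqrt(diff(z)^2 + diff(r)^2))), z = z, r = r)
}

#' Barrier heights of the shape branch by seeded continuation
#'
#' Measures the tube-to-disk barrier `H1` (and optionally the disk-to-cup
#' barrier `H2`) at fixed reduced volume: the tube side is annealed at the
#' metastable tube minimum and at barrier-top candidates starting from a
#' spherocylinder seed; the disk side is annealed at the disk minimum and
#' continued downward in the area difference (disk to bowl to cup) from an
#' oblate seed. Each quantity is the difference of per-point minimum
#' bending energies over independent repeats, in `8 pi kappa` units.
#'
#' @param v_target reduced volume of the branch.
#' @param da_tube tube-minimum area difference.
#' @param da_tops barrier-top candidate grid (the maximum of the annealed
#'   energies over this grid is the top).
#' @param da_disk disk-minimum area difference (`NULL` skips H2).
#' @param da_down downward continuation grid for the disk-to-cup barrier.
#' @param model an `energy_model`.
#' @param n_repeats independent anneals per point.
#' @param sweeps SA phase lengths (`ramp_da`, `equil`, `cool`) for the
#'   tube side.
#' @param disk_sweeps phase lengths for the disk-side continuation (the
#'   disk branch converges with lighter schedules); defaults to `sweeps`.
#' @param seed master seed.
#' @return list `H1`, `H2`, `tube` (per-point table), `disk` (per-point
#'   table).
#' @export
branch_barriers <- function(v_target = 1 / sqrt(3),
                            da_tube = 1.44,
                            da_tops = c(1.33, 1.30, 1.28),
                            da_disk = 1.04,
                            da_down = c(1.00, 0.96, 0.92),
                            model = energy_model(kappa = 20),
                            n_repeats = 3L,
                            sweeps = list(ramp_da = 800, equil = 6000,
                                          cool = 8000),
                            disk_sweeps = NULL,
                            seed = 1L) {
  if (is.null(disk_sweeps)) disk_sweeps <- sweeps
  m0 <- tube_seed_mesh(v_target, seed = seed)
  A <- surface_area(m0)
  Vt <- v_target * A^1.5 / (6 * sqrt(pi))
  mod <- modifyList(model, list(A_ref = A, V_ref = Vt, K_da = 5e6, da0 = da_tube))
  class(mod) <- "energy_model"
  point_min <- function(mesh, da, sd0) {
    es <- vapply(seq_len(n_repeats), function(s)
      anneal_to(mesh, mod, da, sweeps = sweeps, widths = c(0.08, 0.15),
                seed = sd0 + s)$E_b, numeric(1))
    min(es) / (8 * pi * model$kappa)
  }
  tube_tab <- data.frame(da = c(da_tube, da_tops))
  tube_tab$E_b_8pk <- vapply(seq_len(nrow(tube_tab)), function(i)
    point_min(m0, tube_tab$da[i], seed + 100 * i), numeric(1))
  H1 <- max(tube_tab$E_b_8pk[-1]) - tube_tab$E_b_8pk[1]
  H2 <- NA_real_
  disk_tab <- NULL
  if (!is.null(da_disk)) {
    md <- disk_seed_mesh(v_target, seed = seed)
    # continuation downward from the disk minimum, per repeat
    grid <- c(da_disk, sort(da_down, decreasing = TRUE))
    EbM <- matrix(NA_real_, length(grid), n_repeats)
    for (s in seq_len(n_repeats)) {
      mesh <- md
      for (i in seq_along(grid)) {
        r <- anneal_to(mesh, mod, grid[i], sweeps = disk_sweeps,
                       widths = c(0.08, 0.15), seed = seed + 7000 * s + i)
        EbM[i, s] <- r$E_b / (8 * pi * model$kappa)
        mesh <- r$mesh
      }
    }
    disk_tab <- data.frame(da = grid, E_b_8pk = apply(EbM, 1, min))
    H2 <- max(disk_tab$E_b_8pk[-1]) - disk_tab$E_b_8pk[1]
  }
  list(H1 = H1, H2 = H2, tube = tube_tab, disk = disk_tab)
}
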