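#' Monte Carlo schedule
#'
#' Move widths, step counts and bookkeeping parameters of a Metropolis run.
#' One MC step is one sweep: `n_v` vertex-move attempts, `n_e` edge-flip
#' attempts and one attempt per protein bead, in random order. Move widths
#' are tuned during warm-up toward a target acceptance of about 40% and can
#' be frozen afterwards to preserve detailed balance.
#'
#' @param n_sweeps number of sweeps.
#' @param temperature temperature in k_B T units (scalar, or vector of
#'   length `n_sweeps` for annealing profiles).
#' @param width_vertex,width_bead half-widths of the cubic displacement
#'   proposals (tether lengths).
#' @param tune adapt widths during the run (warm-up only; disable for
#'   production sampling).
#' @param tune_interval sweeps between width adjustments.
#' @param target_acceptance target move acceptance rate.
#' @param stride sweeps between recorded observable frames (0 = none).
#' @param seed RNG seed (recorded in every output).
#' @param refresh_every full cache recomputation interval (sweeps), bounding
#'   floating-point drift of the incremental energy bookkeeping.
#' @return object of class `mc_schedule`.
#' @export
mc_schedule <- function(n_sweeps, temperature = 1, width_vertex = 0.1,
                        width_bead = 0.15, tune = TRUE, tune_interval = 25L,
                        target_acceptance = 0.4, stride = 50L, seed = 1L,
                        refresh_every = 500L) {
  stopifnot(n_sweeps >= 0, all(temperature >= 0), width_vertex > 0,
            width_bead > 0)
  structure(list(n_sweeps = as.integer(n_sweeps), temperature = temperature,
                 width_vertex = width_vertex, width_bead = width_bead,
                 tune = tune, tune_interval = as.integer(tune_interval),
                 target_acceptance = target_acceptance,
                 stride = as.integer(stride), seed = seed,
                 refresh_every = as.integer(refresh_every)),
            class = "mc_schedule")
}

chains_for_engine <- function(chains) {
  if (is.null(chains)) return(list())
  if (inherits(chains, "dimer_chain")) chains <- list(chains)
  lapply(chains, function(ch) {
    list(x = ch$x, theta0 = ch$theta0,
         gamma0 = if (anyNA(ch$gamma0)) NULL else ch$gamma0)
  })
}

#' Run Metropolis Monte Carlo sweeps
#'
#' Samples membrane (and protein) configurations with probability
#' proportional to the Boltzmann factor `exp(-E / k_B T)`. Tether and
#' excluded-volume violations are hard rejections. Energy bookkeeping is
#' incremental per move. Identical seed and configuration give a
#' bit-identical trajectory (single-threaded).
#'
#' @param mesh a `trimesh`.
#' @param model an `energy_model` (constraint terms active when their
#'   stiffness is positive; reference values must then be set).
#' @param schedule an `mc_schedule`.
#' @param chains optional list of `dimer_chain` objects.
#' @param V_ref_profile optional per-sweep reference-volume ramp.
#' @param da0_profile optional per-sweep area-difference target ramp.
#' @param bias_k,bias_c umbrella bias `0.5 * bias_k * (da - bias_c)^2`
#'   added to the energy (0 = off).
#' @param record_da record the area difference every sweep (umbrella
#'   sampling time series).
#' @return object of class `mc_run`: updated `mesh` and `chains`, an
#'   observable data.frame `obs` (step, energy terms, A, V, v, da,
#'   acceptance rates), final scalars, acceptance rates, tuned widths, and
#'   `da_series` when requested.
#' @export
run_mc <- function(mesh, model, schedule, chains = NULL,
                   V_ref_profile = NULL, da0_profile = NULL,
                   bias_k = 0, bias_c = 0, record_da = FALSE,
                   repair = FALSE) {
  stopifnot(inherits(mesh, "trimesh"), inherits(model, "energy_model"),
            inherits(schedule, "mc_schedule"))
  ns <- schedule$n_sweeps
  Tvec <- rep_len(schedule$temperature, ns)
  Vref <- if (is.null(V_ref_profile)) {
    if (model$K_V > 0 && is.na(model$V_ref)) stop("K_V active but V_ref unset")
    if (is.na(model$V_ref)) 1.0 else model$V_ref
  } else rep_len(V_ref_profile, ns)
  da0 <- if (is.null(da0_profile)) {
    if (model$K_da > 0 && is.na(model$da0)) stop("K_da active but da0 unset")
    if (is.na(model$da0)) 1.0 else model$da0
  } else rep_len(da0_profile, ns)
  if (model$K_A > 0 && is.na(model$A_ref)) stop("K_A active but A_ref unset")
  em <- list(kappa = model$kappa, K_A = model$K_A, K_V = model$K_V,
             K_da = model$K_da,
             A_ref = if (is.na(model$A_ref)) 1.0 else model$A_ref,
             U = model$U, d0 = model$d0, d1 = model$d1,
             K_bond = model$K_bond, K_ang = model$K_ang, K_dih = model$K_dih,
             bias_k = bias_k, bias_c = bias_c)
  res <- cpp_run_mc(mesh$x, mesh$tri - 1L, mesh$l_min, mesh$l_max,
                    chains_for_engine(chains), em,
                    Tvec, Vref, da0,
                    schedule$width_vertex, schedule$width_bead,
                    schedule$tune, schedule$tune_interval,
                    schedule$target_acceptance,
                    schedule$stride, as.double(schedule$seed), record_da,
                    schedule$refresh_every, repair)
  out_mesh <- trimesh(res$x, res$tri + 1L, l_min = mesh$l_min,
                      l_max = mesh$l_max)
  out_chains <- NULL
  if (!is.null(chains)) {
    if (inherits(chains, "dimer_chain")) chains <- list(chains)
    out_chains <- chains
    for (i in seq_along(out_chains)) out_chains[[i]]$x <- res$chains[[i]]
  }
  obs <- as.data.frame(res$obs)
  names(obs) <- c("step", "E_b", "E_area", "E_vol", "E_da", "E_bias",
                  "E_bd", "E_d", "A", "V", "v", "da", "acc_vertex",
                  "acc_flip")
  structure(list(mesh = out_mesh, chains = out_chains, obs = obs,
                 da_series = if (record_da) res$da_series else NULL,
                 E_b = res$E_b, A = res$A, V = res$V, v = res$v, da = res$da,
                 E_bd = res$E_bd, E_d = res$E_d,
                 acc = c(vertex = res$acc_vertex, flip = res$acc_flip,
                         bead = res$acc_bead),
                 widths = c(vertex = res$width_vertex, bead = res$width_bead),
                 seed = schedule$seed),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("mc_run: E_b = %.2f k_B T, A = %.2f, V = %.2f, v = %.4f, da = %.4f\n",
              x$E_b, x$A, x$V, x$v, x$da))
  cat(sprintf("acceptance: vertex %.2f, flip %.3f%s\n", x$acc["vertex"],
              x$acc["flip"],
              if (!is.na(x$acc["bead"])) sprintf(", bead %.2f", x$acc["bead"]) else ""))
  invisible(x)
}

#' Tune move widths to the target acceptance
#'
#' Runs short tuning batches at fixed temperature, adapting the vertex (and
#' bead) proposal widths until the measured acceptance is within
#' `[target - 0.05, target + 0.05]`. Widths should be frozen afterwards
#' (detailed balance).
#'
#' @inheritParams run_mc
#' @param n_sweeps tuning length in sweeps.
#' @param target target acceptance rate (default 0.4).
#' @param seed RNG seed.
#' @return list `width_vertex`, `width_bead`, `acc` (measured after
#'   tuning), and `ok` (whether the window was reached).
#' @export
tune_move_widths <- function(mesh, model, chains = NULL, n_sweeps = 200L,
                             target = 0.4, seed = 1L) {
  n_sweeps <- max(50L, n_sweeps)
  sc <- mc_schedule(n_sweeps, temperature = 1, tune = TRUE,
                    tune_interval = 10L, target_acceptance = target,
                    stride = 0L, seed = seed)
  r <- run_mc(mesh, model, sc, chains = chains)
  # measure with frozen widths
  sc2 <- mc_schedule(max(50L, n_sweeps %/% 4L), temperature = 1, tune = FALSE,
                     width_vertex = r$widths["vertex"],
                     width_bead = r$widths["bead"], stride = 0L,
                     seed = seed + 1)
  r2 <- run_mc(r$mesh, model, sc2, chains = r$chains)
  ok <- abs(r2$acc["vertex"] - target) <= 0.05 + 0.02
  list(width_vertex = unname(r$widths["vertex"]),
       width_bead = unname(r$widths["bead"]),
       acc = r2$acc, ok = unname(ok))
}

# default printed-protocol sweep counts, scaled for desk runs
sa_phases <- function(scale = 5e-3) {
  n <- function(x) max(50L, as.integer(round(x * scale)))
  list(ramp_v = n(1e6), ramp_da = n(1e6), equil = n(5e5), cool = n(5e5))
}

#' Anneal a configuration to a target area difference
#'
#' Continuation-style simulated annealing from the current state: the
#' area-difference target is ramped linearly from its current value to
#' `da_target` at unit temperature, the system is equilibrated, then cooled
#' linearly to near zero temperature. Used both inside full SA runs and for
#' warm-started branch scans.
#'
#' @param mesh starting `trimesh` (typically a relaxed or previously
#'   annealed state at the right reduced volume).
#' @param model `energy_model`; `K_da` must be positive and `A_ref`,
#'   `V_ref` set.
#' @param da_target target area difference.
#' @param sweeps list with `ramp_da`, `equil`, `cool` sweep counts.
#' @param widths numeric `c(vertex, bead)` move widths (frozen).
#' @param seed RNG seed.
#' @param T_final final temperature of the linear cooling ramp.
#' @return `mc_run` at the end of cooling (near-minimum energy state).
#' @export
anneal_to <- function(mesh, model, da_target, sweeps = sa_phases()[-1],
                      widths = c(0.1, 0.15), seed = 1L, T_final = 1e-3) {
  da_now <- area_difference(mesh)
  n2 <- sweeps$ramp_da; n3 <- sweeps$equil; n4 <- sweeps$cool
  sc <- mc_schedule(n2 + n3 + n4,
                    temperature = c(rep(1, n2 + n3),
                                    seq(1, T_final, length.out = n4)),
                    width_vertex = widths[1], width_bead = widths[2],
                    tune = FALSE, stride = 0L, seed = seed)
  run_mc(mesh, model, sc,
         da0_profile = c(seq(da_now, da_target, length.out = n2),
                         rep(da_target, n3 + n4)))
}

#' Simulated annealing to a shape-branch minimum
#'
#' Full SA protocol: starting from a spherical vesicle (or a supplied
#' mesh), the reference volume is ramped linearly to the target reduced
#' volume, the area-difference target is then ramped to `da_target`, the
#' system is equilibrated and finally cooled linearly to near-zero
#' temperature. The protocol is repeated `n_repeats` times with different
#' seeds and the repeat with minimum bending energy is reported.
#'
#' @param v_target target reduced volume in (0, 1].
#' @param da_target target area difference (`NULL` leaves the area
#'   difference unconstrained: plain energy minimization at fixed v).
#' @param model an `energy_model`; `A_ref`/`V_ref`/`da0` are derived here.
#' @param mesh starting mesh (default: icosphere with 642 vertices).
#' @param sweeps list of phase lengths (`ramp_v`, `ramp_da`, `equil`,
#'   `cool`), see `sa_phases()`.
#' @param n_repeats independent SA repeats (default 10).
#' @param seed master seed; repeat r uses `seed + r - 1`.
#' @param K_da area-difference constraint stiffness (default 5e6).
#' @return list: best `mc_run` (`$best`), its bending energy in `8 pi
#'   kappa` units (`$E_b_8pk`), and `$repeats` (data.frame of all repeats).
#' @export
simulated_annealing <- function(v_target, da_target = NULL,
                                model = energy_model(), mesh = NULL,
                                sweeps = sa_phases(), n_repeats = 10L,
                                seed = 1L, K_da = 5e6) {
  stopifnot(v_target > 0, v_target <= 1)
  if (is.null(mesh)) mesh <- build_icosphere(3L)
  A_ref <- surface_area(mesh)
  V_target <- v_target * A_ref^1.5 / (6 * sqrt(pi))
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sd <- seed + r - 1
    tw <- tune_move_widths(mesh, modifyList(model, list(K_A = model$K_A,
                                                        A_ref = A_ref,
                                                        V_ref = signed_volume(mesh),
                                                        K_da = 0)),
                           n_sweeps = 50L, seed = sd)
    widths <- c(tw$width_vertex, tw$width_bead)
    m1 <- modifyList(model, list(A_ref = A_ref, V_ref = V_target, K_da = 0))
    class(m1) <- "energy_model"
    sc1 <- mc_schedule(sweeps$ramp_v, temperature = 1,
                       width_vertex = widths[1], width_bead = widths[2],
                       tune = TRUE, stride = 0L, seed = sd)
    r1 <- run_mc(mesh, m1, sc1,
                 V_ref_profile = seq(signed_volume(mesh), V_target,
                                     length.out = sweeps$ramp_v))
    widths <- r1$widths
    if (is.null(da_target)) {
      n3 <- sweeps$equil; n4 <- sweeps$cool
      sc <- mc_schedule(n3 + n4,
                        temperature = c(rep(1, n3),
                                        seq(1, 1e-3, length.out = n4)),
                        width_vertex = widths[1], width_bead = widths[2],
                        tune = FALSE, stride = 0L, seed = sd)
      runs[[r]] <- run_mc(r1$mesh, m1, sc)
    } else {
      m2 <- modifyList(m1, list(K_da = K_da, da0 = da_target))
      class(m2) <- "energy_model"
      runs[[r]] <- anneal_to(r1$mesh, m2, da_target, sweeps = sweeps[-1],
                             widths = widths, seed = sd)
    }
  }
  eb <- vapply(runs, `[[`, numeric(1), "E_b")
  best <- which.min(eb)
  rep_tab <- data.frame(repeat_ = seq_len(n_repeats), seed = seed + seq_len(n_repeats) - 1,
                        E_b = eb, E_b_8pk = eb / (8 * pi * model$kappa),
                        v = vapply(runs, `[[`, numeric(1), "v"),
                        da = vapply(runs, `[[`, numeric(1), "da"))
  list(best = runs[[best]], E_b = eb[best],
       E_b_8pk = eb[best] / (8 * pi * model$kappa), repeats = rep_tab)
}

#' Scan the shape branch in the area difference
#'
#' Traces the locus of annealed bending-energy minima versus the area
#' difference at fixed reduced volume, the branch whose local extrema define
#' the tube-to-disk barrier `H1` and the disk-to-cup barrier `H2`. The scan
#' uses continuation: the first (largest) grid point is annealed from a
#' fused-sphere or spherical initial condition, and each subsequent point is
#' re-annealed from the previous minimum. Independent repeats with
#' different seeds are combined by taking the per-point minimum.
#'
#' @param v_target fixed reduced volume of the branch.
#' @param da_grid area-difference grid (sorted internally in decreasing
#'   order; the branch is traced downward from the fused/tube side).
#' @param model an `energy_model`.
#' @param subdivision icosphere subdivision of the working mesh (3 = 642
#'   vertices).
#' @param n_repeats independent scan repeats.
#' @param sweeps SA phase lengths, see `sa_phases()`.
#' @param seed master seed.
#' @param init `"fused"` starts from linearly fused spheres with
#'   `n = round(1/v^2)` (natural for branches entered from the post-fusion
#'   side); `"sphere"` ramps a sphere down to `v_target` first.
#' @param classify label each branch point with `classify_shape`.
#' @return data.frame: `da`, minimum `E_b`, `E_b_8pk`, measured `da_out`,
#'   `v_out`, shape `label`, plus attribute `"repeats"` with the per-repeat
#'   energy matrix.
#' @export
shape_branch_scan <- function(v_target, da_grid, model = energy_model(),
                              subdivision = 3L, n_repeats = 3L,
                              sweeps = sa_phases(), seed = 1L,
                              init = c("fused", "sphere"),
                              classify = TRUE) {
  init <- match.arg(init)
  da_grid <- sort(unique(da_grid), decreasing = TRUE)
  np <- length(da_grid)
  EbM <- matrix(NA_real_, np, n_repeats)
  daM <- vM_ <- matrix(NA_real_, np, n_repeats)
  meshes <- vector("list", np)
  for (r in seq_len(n_repeats)) {
    sd <- seed + 1000 * (r - 1)
    if (init == "fused") {
      n <- max(1L, round(1 / v_target^2))
      mesh <- fused_spheres_mesh(n, subdivision = subdivision, seed = sd)
    } else {
      mesh <- build_icosphere(subdivision)
    }
    A_ref <- surface_area(mesh)
    V_target <- v_target * A_ref^1.5 / (6 * sqrt(pi))
    m0 <- modifyList(model, list(A_ref = A_ref, V_ref = V_target, K_da = 0))
    class(m0) <- "energy_model"
    tw <- tune_move_widths(mesh, modifyList(m0, list(V_ref = signed_volume(mesh))),
                           n_sweeps = 50L, seed = sd)
    widths <- c(tw$width_vertex, tw$width_bead)
    nr <- max(50L, sweeps$ramp_v %/% 4L)  # short v ramp: init is near target
    sc <- mc_schedule(nr, temperature = 1, width_vertex = widths[1],
                      tune = TRUE, stride = 0L, seed = sd)
    rv <- run_mc(mesh, m0, sc,
                 V_ref_profile = seq(signed_volume(mesh), V_target,
                                     length.out = nr))
    mesh <- rv$mesh; widths <- rv$widths
    m1 <- modifyList(m0, list(K_da = 5e6, da0 = 1))
    class(m1) <- "energy_model"
    for (p in seq_len(np)) {
      res <- anneal_to(mesh, m1, da_grid[p], sweeps = sweeps[-1],
                       widths = widths, seed = sd + p)
      EbM[p, r] <- res$E_b
      daM[p, r] <- res$da; vM_[p, r] <- res$v
      if (which.min(EbM[p, seq_len(r)]) == r) meshes[[p]] <- res$mesh
      mesh <- res$mesh  # continuation
    }
  }
  Eb <- apply(EbM, 1, min)
  best <- apply(EbM, 1, which.min)
  out <- data.frame(da = da_grid, E_b = Eb,
                    E_b_8pk = Eb / (8 * pi * model$kappa),
                    da_out = daM[cbind(seq_len(np), best)],
                    v_out = vM_[cbind(seq_len(np), best)])
  out$label <- if (classify)
    vapply(meshes, function(m) classify_shape(m)$label, character(1))
  else NA_character_
  attr(out, "repeats") <- EbM
  attr(out, "meshes") <- meshes
  out
}

#' Production run of a vesicle with protein chains
#'
#' Fixed-temperature Metropolis run of a membrane with adhered protein
#' chains: the protein-run constraint stiffnesses (`K_A = 2e5`,
#' `K_V = 5e5`) preserve area and reduced volume while the shape and the
#' chains evolve on their coupled energy surface. The final frame is
#' labeled with `classify_shape`.
#'
#' @param mesh starting `trimesh` (typically `fused_spheres_mesh`).
#' @param chains list of `dimer_chain`s placed on the mesh
#'   (`place_dimers`).
#' @param model an `energy_model`; if `A_ref`/`V_ref` are unset they are
#'   taken from the current mesh.
#' @param n_sweeps run length in sweeps.
#' @param seed RNG seed.
#' @param stride observable recording stride.
#' @param widths optional frozen move widths (tuned briefly when `NULL`).
#' @return the `mc_run` with an added `$label` (final shape).
#' @export
production_run <- function(mesh, chains, model, n_sweeps = 1e4, seed = 1L,
                           stride = 100L, widths = NULL) {
  if (is.na(model$A_ref)) model$A_ref <- surface_area(mesh)
  if (is.na(model$V_ref)) model$V_ref <- signed_volume(mesh)
  if (is.null(widths)) {
    tw <- tune_move_widths(mesh, model, chains = chains, n_sweeps = 100L,
                           seed = seed)
    widths <- c(tw$width_vertex, tw$width_bead)
  }
  sc <- mc_schedule(n_sweeps, temperature = 1, width_vertex = widths[1],
                    width_bead = widths[2], tune = FALSE, stride = stride,
                    seed = seed)
  r <- run_mc(mesh, model, sc, chains = chains)
  r$label <- classify_shape(r$mesh)$label
  r
}
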