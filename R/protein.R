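#' Coarse-grained scaffold protein chains
#'
#' An Atg17 dimer is modeled as 16 beads on a chain whose reference geometry
#' encodes the S-shaped double crescent seen in crystal and solution
#' structures: two tangent-continuous quarter-circle arcs with opposite
#' turning, their planes tilted relative to each other. Harmonic bond,
#' angle and dihedral terms restrain the chain to this reference shape.
#'
#' @name dimer_chain
NULL

new_dimer_chain <- function(x, shape) {
  x <- as.matrix(x)
  nb <- nrow(x)
  bonds <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nb, , drop = FALSE])^2))
  th <- chain_angles(x)
  ga <- if (shape == "straight") rep(NA_real_, max(0L, nb - 3L)) else chain_dihedrals(x)
  structure(list(x = x, n_beads = nb, L0 = 1,
                 theta0 = th, gamma0 = ga, shape = shape,
                 ref_bonds = bonds),
            class = "dimer_chain")
}

#' @export
print.dimer_chain <- function(x, ...) {
  cat(sprintf("dimer_chain (%s): %d beads, contour %.3f l, end-to-end %.3f l\n",
              x$shape, x$n_beads, sum(x$ref_bonds),
              sqrt(sum((x$x[x$n_beads, ] - x$x[1, ])^2))))
  invisible(x)
}

chain_angles <- function(x) {
  nb <- nrow(x)
  if (nb < 3) return(numeric(0))
  vapply(2:(nb - 1), function(i) {
    u <- x[i - 1, ] - x[i, ]; w <- x[i + 1, ] - x[i, ]
    acos(pmin(1, pmax(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
  }, numeric(1))
}

chain_dihedrals <- function(x) {
  nb <- nrow(x)
  if (nb < 4) return(numeric(0))
  vapply(seq_len(nb - 3L), function(i) {
    b1 <- x[i + 1, ] - x[i, ]
    b2 <- x[i + 2, ] - x[i + 1, ]
    b3 <- x[i + 3, ] - x[i + 2, ]
    c1 <- cross3(b1, b2); c2 <- cross3(b2, b3)
    n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
    if (n1 < 1e-12 || n2 < 1e-12) return(0)
    atan2(sum(cross3(c1, c2) * b2) / sqrt(sum(b2^2)), sum(c1 * c2))
  }, numeric(1))
}

cross3 <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                           u[3] * w[1] - u[1] * w[3],
                           u[1] * w[2] - u[2] * w[1])

#' Build an S-shaped dimer chain
#'
#' Beads are placed with unit bond length along two tangent-continuous
#' quarter-circle arcs of equal radius turning in opposite directions (the
#' "S"), the second arc plane tilted by `tilt` about the common tangent.
#' The default radius `1/(2 sin(pi/30))` makes 15 unit bonds span the two
#' quarter arcs exactly. The reference bond length is `L0 = 1`, and the
#' reference angles/dihedrals are recorded from the built geometry, so the
#' internal energy of the freshly built chain is zero.
#'
#' @param arc_radius radius of each quarter-circle arc (tether lengths).
#' @param tilt angle between the two arc planes, radians (default 15 deg).
#' @param n_beads number of beads (default 16).
#' @return a `dimer_chain` with shape tag `"s"`.
#' @export
build_s_dimer <- function(arc_radius = 1 / (2 * sin(pi / 30)),
                          tilt = 15 * pi / 180, n_beads = 16L) {
  stopifnot(arc_radius > 0, n_beads >= 4L)
  rho <- arc_radius
  delta <- 2 * asin(1 / (2 * rho))  # turning per unit chord
  n1 <- ceiling(n_beads / 2)        # beads on arc 1
  c1 <- c(0, rho, 0)
  p_arc1 <- function(phi) c1 + rho * c(sin(phi), -cos(phi), 0)
  ph1 <- (seq_len(n1) - 1) * delta
  x <- t(vapply(ph1, p_arc1, numeric(3)))
  # junction: end of quarter arc 1
  J <- p_arc1(pi / 2)
  tJ <- c(cos(pi / 2), sin(pi / 2), 0)           # tangent at junction
  n2dir <- rot_about(c(1, 0, 0), tJ, tilt)       # opposite-side normal, tilted
  c2 <- J + rho * n2dir
  p_arc2 <- function(psi) c2 + rho * (-n2dir * cos(psi) + tJ * sin(psi))
  # first bead past the junction: solve for unit bond across the junction
  last1 <- x[n1, ]
  froot <- function(psi) sqrt(sum((p_arc2(psi) - last1)^2)) - 1
  lo <- 0; hi <- 2 * delta
  while (froot(hi) < 0) hi <- hi + delta
  psi0 <- uniroot(froot, c(lo, hi), tol = 1e-12)$root
  ps2 <- psi0 + (seq_len(n_beads - n1) - 1) * delta
  x <- rbind(x, t(vapply(ps2, p_arc2, numeric(3))))
  new_dimer_chain(x, shape = "s")
}

rot_about <- function(v, axis, ang) {
  a <- axis / sqrt(sum(axis^2))
  v * cos(ang) + cross3(a, v) * sin(ang) + a * sum(a * v) * (1 - cos(ang))
}

#' Build a straight reference chain
#'
#' Collinear chain with unit bonds and reference angles `theta0 = pi`. The
#' dihedral term is undefined on a collinear reference and is omitted for
#' straight chains (their `gamma0` is `NA`).
#'
#' @param n_beads number of beads (default 16).
#' @return a `dimer_chain` with shape tag `"straight"`.
#' @export
build_straight_chain <- function(n_beads = 16L) {
  x <- cbind(seq_len(n_beads) - 1, 0, 0)
  new_dimer_chain(x, shape = "straight")
}

#' Chain internal (shape-restraint) energy
#'
#' `E_d = K_bond/2 sum(dL^2) + K_ang/2 sum(dth^2) + K_dih/2 sum(dga^2)` with
#' deviations taken from the reference bond length `L0 = 1`, reference
#' angles and reference dihedrals. Dihedral deviations are wrapped into
#' `(-pi, pi]`. Zero at the reference geometry; invariant under rigid-body
#' motion. `K_ang` between 200 and 1e3 k_B T spans flexible to rigid dimers.
#'
#' @param chain a `dimer_chain` (current coordinates in `chain$x`).
#' @param K_bond,K_ang,K_dih stiffnesses in k_B T.
#' @return energy in k_B T.
#' @export
chain_internal_energy <- function(chain, K_bond = 1e4, K_ang = 1e3,
                                  K_dih = 500) {
  x <- chain$x
  nb <- nrow(x)
  bonds <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nb, , drop = FALSE])^2))
  e <- 0.5 * K_bond * sum((bonds - chain$L0)^2)
  th <- chain_angles(x)
  e <- e + 0.5 * K_ang * sum((th - chain$theta0)^2)
  if (!anyNA(chain$gamma0)) {
    ga <- chain_dihedrals(x)
    dg <- (ga - chain$gamma0 + pi) %% (2 * pi) - pi
    e <- e + 0.5 * K_dih * sum(dg^2)
  }
  e
}

#' Square-well adhesion parameters
#'
#' Bead-membrane adhesion: infinite below the hard core `d0 = l/2`, a flat
#' attractive well `-U * A_i` of the closest triangle `i` for
#' `d0 < d <= d1`, zero beyond `d1`. The binding strength is reported as the
#' reduced coefficient `u = U * A_Atg / (8 pi kappa)` with
#' `A_Atg = n_beads * Abar` the dimer footprint.
#'
#' @param U binding energy per unit membrane area (k_B T / l^2).
#' @param d0 hard-core distance (default 1/2 tether length).
#' @param d1 outer well range (default 1 tether length; not stated by the
#'   underlying model, so exposed for sensitivity checks).
#' @return object of class `adhesion_params`.
#' @export
adhesion_params <- function(U = 0, d0 = 0.5, d1 = 1) {
  stopifnot(U >= 0, d0 > 0, d1 > d0)
  structure(list(U = U, d0 = d0, d1 = d1), class = "adhesion_params")
}

#' Convert reduced binding strength u to U (and back)
#'
#' `u = U * A_Atg / (8 pi kappa)` with `A_Atg = n_beads * Abar`, where
#' `Abar` is the mean triangle area of the tessellation.
#'
#' @param u reduced binding strength.
#' @param kappa bending rigidity (k_B T).
#' @param abar mean triangle area (l^2).
#' @param n_beads beads per dimer (default 16).
#' @return `U` in k_B T per l^2 (`u_to_U`) or `u` (`U_to_u`).
#' @export
u_to_U <- function(u, kappa, abar, n_beads = 16) {
  stopifnot(kappa > 0, abar > 0)
  u * 8 * pi * kappa / (n_beads * abar)
}

#' @rdname u_to_U
#' @param U binding energy per unit area.
#' @export
U_to_u <- function(U, kappa, abar, n_beads = 16) {
  stopifnot(kappa > 0, abar > 0)
  U * n_beads * abar / (8 * pi * kappa)
}

#' Distance from a point to the membrane surface
#'
#' Exact Euclidean point-to-triangle distance minimized over all triangles:
#' the normal distance when the normal projection falls inside the closest
#' triangle, otherwise the distance to its nearest edge or corner. The side
#' flag is the sign of the offset along the closest triangle's outward
#' normal (+1 outside, -1 inside).
#'
#' @param p numeric length-3 point.
#' @param mesh a `trimesh`.
#' @return list `d`, `triangle` (index), `side` (+1/-1).
#' @export
bead_surface_distance <- function(p, mesh) {
  res <- cpp_point_mesh_distance(p, mesh$x, mesh$tri - 1L)
  list(d = res$d, triangle = res$triangle + 1L, side = res$side)
}

#' Adhesion energy of bead chains on the membrane
#'
#' Each bead within the attractive well of its closest triangle contributes
#' `-U * A_i`; `E_bd = -U * A_bd` with `A_bd` the summed areas of bound
#' triangles. Scoring a bead inside the hard core is an error: such
#' configurations are unreachable and proposals creating them must be
#' rejected by the caller.
#'
#' @param chains list of `dimer_chain` objects.
#' @param mesh a `trimesh`.
#' @param params an `adhesion_params`.
#' @return list `E_bd` and `map` (data.frame: chain, bead, d, triangle,
#'   side, bound).
#' @export
adhesion_energy <- function(chains, mesh, params) {
  if (inherits(chains, "dimer_chain")) chains <- list(chains)
  areas <- tri_areas_raw(mesh$x, mesh$tri)
  rows <- list()
  for (ci in seq_along(chains)) {
    x <- chains[[ci]]$x
    for (bi in seq_len(nrow(x))) {
      bd <- bead_surface_distance(x[bi, ], mesh)
      if (bd$d <= params$d0)
        stop("hard-core overlap: bead ", bi, " of chain ", ci,
             " at distance ", signif(bd$d, 4), " <= d0 = ", params$d0)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ci, bead = bi, d = bd$d, triangle = bd$triangle,
        side = bd$side, bound = bd$d <= params$d1)
    }
  }
  map <- do.call(rbind, rows)
  E_bd <- -params$U * sum(areas[map$triangle[map$bound]])
  list(E_bd = E_bd, map = map)
}

#' Hard-constraint check for a proposed protein/membrane configuration
#'
#' Rejects (returns `ok = FALSE`) when any bead pair from *different* chains
#' is closer than one tether length, when any bead is inside the membrane
#' hard core `d0`, or when a bead's side flag changed relative to the last
#' accepted state (membrane crossing).
#'
#' @param chains list of `dimer_chain` objects (proposed coordinates).
#' @param mesh a `trimesh`.
#' @param params an `adhesion_params`.
#' @param prev_sides optional numeric vector of side flags from the last
#'   accepted state (beads in chain-major order).
#' @param min_sep minimum inter-chain bead separation (default 1 l).
#' @return list `ok` (logical) and `reason` (`NA` when accepted).
#' @export
excluded_volume_check <- function(chains, mesh, params, prev_sides = NULL,
                                  min_sep = 1) {
  if (inherits(chains, "dimer_chain")) chains <- list(chains)
  all_x <- do.call(rbind, lapply(chains, `[[`, "x"))
  cid <- rep(seq_along(chains), vapply(chains, function(c) nrow(c$x), integer(1)))
  if (length(chains) > 1L) {
    dm <- as.matrix(dist(all_x))
    inter <- outer(cid, cid, `!=`)
    if (any(dm[inter] < min_sep))
      return(list(ok = FALSE, reason = "inter-chain bead separation below l"))
  }
  sides <- numeric(nrow(all_x))
  for (i in seq_len(nrow(all_x))) {
    bd <- bead_surface_distance(all_x[i, ], mesh)
    if (bd$d <= params$d0)
      return(list(ok = FALSE, reason = "bead inside membrane hard core"))
    sides[i] <- bd$side
  }
  if (!is.null(prev_sides) && any(sides != prev_sides))
    return(list(ok = FALSE, reason = "bead crossed the membrane"))
  list(ok = TRUE, reason = NA_character_, sides = sides)
}
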