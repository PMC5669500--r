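#' Per-triangle areas and outward unit normals
#' @param mesh a `trimesh`.
#' @return list with `area` (n_t) and `normal` (n_t x 3).
#' @export
triangle_geometry <- function(mesh) {
  n <- tri_cross(mesh$x, mesh$tri)
  a2 <- sqrt(rowSums(n * n))
  list(area = a2 / 2, normal = n / a2)
}

# signed dihedral angle phi_ij for every edge: angle between the outward
# normals of the two adjacent triangles, positive where the surface is
# locally convex outward. The sign is carried by the triple product of the
# two normals with the directed edge as oriented in the first triangle.
edge_dihedrals <- function(mesh, geom = triangle_geometry(mesh)) {
  e <- mesh$edges; et <- mesh$edge_tri
  n1 <- geom$normal[et[, 1], , drop = FALSE]
  n2 <- geom$normal[et[, 2], , drop = FALSE]
  # directed edge as traversed by triangle et[,1]
  dir_ij <- vapply(seq_len(nrow(e)), function(k) {
    orient_pair(mesh$tri[et[k, 1], ], e[k, 1], e[k, 2])
  }, logical(1))
  i <- ifelse(dir_ij, e[, 1], e[, 2])
  j <- ifelse(dir_ij, e[, 2], e[, 1])
  ed <- mesh$x[j, , drop = FALSE] - mesh$x[i, , drop = FALSE]
  len <- sqrt(rowSums(ed * ed))
  ed <- ed / len
  cr <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
              n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
              n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  s <- rowSums(cr * ed)
  cphi <- pmin(1, pmax(-1, rowSums(n1 * n2)))
  phi <- atan2(s, cphi)
  list(phi = phi, length = len)
}

#' Per-vertex mean-curvature contribution and vertex area
#'
#' Discretization of the mean curvature on a triangulated surface:
#' `M_a = 1/4 * sum_e l_e * phi_e` over the edges at vertex `a`, where
#' `phi_e` is the signed dihedral angle between the adjacent triangle
#' normals (positive convex outward), and `A_a = 1/3 * sum` of adjacent
#' triangle areas, so that the vertex areas add up to the total area.
#'
#' @param mesh a `trimesh`.
#' @return data.frame with columns `M` and `A`, one row per vertex.
#' @export
vertex_curvature_area <- function(mesh) {
  geom <- triangle_geometry(mesh)
  dih <- edge_dihedrals(mesh, geom)
  nv <- nrow(mesh$x)
  w <- 0.25 * dih$length * dih$phi
  M <- numeric(nv)
  tab <- rowsum(c(w, w), c(mesh$edges[, 1], mesh$edges[, 2]))
  M[as.integer(rownames(tab))] <- tab
  Av <- numeric(nv)
  tab <- rowsum(rep(geom$area / 3, 3), as.vector(mesh$tri))
  Av[as.integer(rownames(tab))] <- tab
  data.frame(M = M, A = Av)
}

#' Discretized Helfrich bending energy
#'
#' `E_b = 2 * kappa * sum_a M_a^2 / A_a` over vertices, the mesh form of the
#' continuum bending energy `(kappa/2) * integral (c1 + c2)^2 dA` of a
#' symmetric bilayer with zero spontaneous curvature. Equals `8 * pi * kappa`
#' for a sphere (any radius) up to discretization error; invariant under
#' rigid motions and uniform rescaling.
#'
#' @param mesh a `trimesh`.
#' @param kappa bending rigidity in k_B T.
#' @return energy in k_B T.
#' @export
bending_energy <- function(mesh, kappa = 20) {
  va <- vertex_curvature_area(mesh)
  2 * kappa * sum(va$M^2 / va$A)
}

#' Signed enclosed volume
#'
#' Sum of signed tetrahedron contributions `V_i = (1/3) (n_i . R_i) A_i`
#' with `R_i` a point of triangle `i` relative to an arbitrary reference
#' point; independent of that point for a closed surface and positive for
#' outward orientation.
#'
#' @param mesh a `trimesh`.
#' @return volume (cubic tether lengths).
#' @export
signed_volume <- function(mesh) {
  x1 <- mesh$x[mesh$tri[, 1], , drop = FALSE]
  x2 <- mesh$x[mesh$tri[, 2], , drop = FALSE]
  x3 <- mesh$x[mesh$tri[, 3], , drop = FALSE]
  sum(x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) +
      x1[, 2] * (x2[, 3] * x3[, 1] - x2[, 1] * x3[, 3]) +
      x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])) / 6
}

#' Total surface area
#' @param mesh a `trimesh`.
#' @return area (square tether lengths).
#' @export
surface_area <- function(mesh) sum(tri_areas_raw(mesh$x, mesh$tri))

#' Reduced volume
#'
#' `v = 6 sqrt(pi) V / A^(3/2)`, 1 for a sphere and smaller for deflated or
#' fused vesicles.
#'
#' @param A area.
#' @param V volume.
#' @return dimensionless reduced volume.
#' @export
reduced_volume <- function(A, V) 6 * sqrt(pi) * V / A^1.5

#' Reduced volume after fusing n equal spheres
#'
#' Area- and volume-conserving fusion of `n` equal spherical vesicles gives
#' `v_n = 1 / sqrt(n)`: 0.707, 0.577, 0.5 for n = 2, 3, 4.
#'
#' @param n number of fused vesicles.
#' @return dimensionless reduced volume `1/sqrt(n)`.
#' @export
fused_reduced_volume <- function(n) {
  stopifnot(all(n >= 1))
  1 / sqrt(n)
}

#' Area difference (shape index)
#'
#' Normalized integral of the mean curvature over the surface,
#' `da = (integral M dA) / (2 sqrt(pi A))`, so that a sphere gives exactly 1
#' in the continuum limit. Scale-invariant; the reaction coordinate for the
#' tube -> disk -> cup shape branch.
#'
#' @param mesh a `trimesh`.
#' @return dimensionless area difference.
#' @export
area_difference <- function(mesh) {
  va <- vertex_curvature_area(mesh)
  sum(va$M) / (2 * sqrt(pi * sum(va$A)))
}

#' Derived scalar state of a membrane shape
#'
#' @param mesh a `trimesh`.
#' @param kappa bending rigidity in k_B T for the reported bending energy.
#' @return data.frame row: area `A`, volume `V`, reduced volume `v`, area
#'   difference `da`, bending energy `E_b`, and `E_b` in `8 pi kappa` units.
#' @export
shape_state <- function(mesh, kappa = 20) {
  va <- vertex_curvature_area(mesh)
  A <- sum(va$A)
  V <- signed_volume(mesh)
  Eb <- 2 * kappa * sum(va$M^2 / va$A)
  data.frame(A = A, V = V, v = reduced_volume(A, V),
             da = sum(va$M) / (2 * sqrt(pi * A)),
             E_b = Eb, E_b_8pk = Eb / (8 * pi * kappa))
}

#' Energy model: couplings, stiffnesses and reference values
#'
#' Collects every coupling constant of the membrane + protein energy:
#' bending rigidity `kappa`; harmonic constraint stiffnesses `K_A`, `K_V`,
#' `K_da` with reference values `A_ref`, `V_ref`, `da0`; square-well adhesion
#' (`U` per unit area, hard core `d0`, range `d1`); and chain stiffnesses
#' `K_bond`, `K_ang`, `K_dih`. All energies in k_B T, lengths in tether
#' units. A constraint term is active when its stiffness is positive and its
#' reference value is set.
#'
#' @param kappa bending rigidity (k_B T); 20 for free vesicles, 10 in
#'   protein runs.
#' @param K_A,K_V area/volume constraint stiffnesses (k_B T); order 1e6 for
#'   free vesicles, `2e5`/`5e5` in protein runs.
#' @param K_da area-difference constraint stiffness (k_B T); `5e6` in
#'   annealing runs, 0 disables the term.
#' @param A_ref,V_ref,da0 reference area, volume, area difference.
#' @param U adhesion energy per unit membrane area (k_B T / l^2).
#' @param d0 hard-core bead-membrane distance (default `1/2`).
#' @param d1 outer range of the attractive well (default 1 tether length).
#' @param K_bond,K_ang,K_dih chain stiffnesses (k_B T).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(kappa = 20, K_A = 1e6, K_V = 1e6, K_da = 0,
                         A_ref = NA, V_ref = NA, da0 = NA,
                         U = 0, d0 = 0.5, d1 = 1,
                         K_bond = 1e4, K_ang = 1e3, K_dih = 500) {
  stopifnot(kappa > 0, K_A >= 0, K_V >= 0, K_da >= 0, d1 > d0, d0 > 0, U >= 0)
  structure(list(kappa = kappa, K_A = K_A, K_V = K_V, K_da = K_da,
                 A_ref = A_ref, V_ref = V_ref, da0 = da0,
                 U = U, d0 = d0, d1 = d1,
                 K_bond = K_bond, K_ang = K_ang, K_dih = K_dih),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy_model:\n")
  cat(sprintf("  kappa = %g k_B T (8 pi kappa = %.4g)\n", x$kappa, 8 * pi * x$kappa))
  cat(sprintf("  K_A = %g, K_V = %g, K_da = %g\n", x$K_A, x$K_V, x$K_da))
  cat(sprintf("  A_ref = %g, V_ref = %g, da0 = %g\n", x$A_ref, x$V_ref, x$da0))
  cat(sprintf("  adhesion U = %g (d0 = %g, d1 = %g)\n", x$U, x$d0, x$d1))
  cat(sprintf("  chain K_bond = %g, K_ang = %g, K_dih = %g\n",
              x$K_bond, x$K_ang, x$K_dih))
  invisible(x)
}

#' Total energy breakdown of a configuration
#'
#' `E = E_b + E_area + E_vol [+ E_da] [+ E_bd + E_d]` with harmonic
#' constraint terms `K (1 - Q/Q_ref)^2` for Q = A, V, da, square-well
#' adhesion energy `E_bd` and chain internal energy `E_d`. Without chains the
#' breakdown reduces to the free-vesicle energy.
#'
#' @param mesh a `trimesh`.
#' @param chains `NULL`, a single `dimer_chain`, or a list of them.
#' @param model an `energy_model`.
#' @return data.frame row with each term and the `total`.
#' @export
total_energy <- function(mesh, chains = NULL, model = energy_model()) {
  st <- shape_state(mesh, model$kappa)
  E_area <- E_vol <- E_da <- 0
  if (model$K_A > 0) {
    if (is.na(model$A_ref)) stop("K_A active but A_ref unset")
    E_area <- model$K_A * (1 - st$A / model$A_ref)^2
  }
  if (model$K_V > 0) {
    if (is.na(model$V_ref)) stop("K_V active but V_ref unset")
    E_vol <- model$K_V * (1 - st$V / model$V_ref)^2
  }
  if (model$K_da > 0) {
    if (is.na(model$da0)) stop("K_da active but da0 unset")
    E_da <- model$K_da * (1 - st$da / model$da0)^2
  }
  E_bd <- 0; E_d <- 0
  if (!is.null(chains)) {
    if (inherits(chains, "dimer_chain")) chains <- list(chains)
    ad <- adhesion_energy(chains, mesh,
                          adhesion_params(U = model$U, d0 = model$d0, d1 = model$d1))
    E_bd <- ad$E_bd
    E_d <- sum(vapply(chains, chain_internal_energy, numeric(1),
                      K_bond = model$K_bond, K_ang = model$K_ang,
                      K_dih = model$K_dih))
  }
  data.frame(E_b = st$E_b, E_area = E_area, E_vol = E_vol, E_da = E_da,
             E_bd = E_bd, E_d = E_d,
             total = st$E_b + E_area + E_vol + E_da + E_bd + E_d)
}
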