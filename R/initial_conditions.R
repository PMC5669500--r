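#' Linearly fused multi-sphere mesh
#'
#' Builds the post-fusion initial condition: `n` equal spheres in a linear
#' arrangement, punctured at their contact points and joined by narrow
#' catenoid necks, as a single closed genus-0 mesh. The axisymmetric
#' fused-sphere profile is triangulated ring by ring with near-unit edge
#' lengths and then re-equilibrated with a short tether-repair Monte Carlo
#' run, so the result satisfies the tether bounds. The sphere radius
#' is chosen so the mean triangle area equals that of a unit-tether
#' equilateral triangle; the reduced volume is close to `1/sqrt(n)` (necks
#' perturb it slightly).
#'
#' @param n number of fused spheres (n = 1 gives a plain icosphere).
#' @param neck_radius_fraction catenoid neck radius as a fraction of the
#'   sphere radius (default 0.1; must be in (0, 0.5)).
#' @param subdivision icosphere subdivision level (3 = 642 vertices).
#' @param relax_sweeps length of the tether re-equilibration run.
#' @param seed RNG seed of the relaxation.
#' @return a `trimesh` with attribute `"profile"` (the axisymmetric
#'   generating curve: arclength `s`, axial `z`, radius `r`), attribute
#'   `"necks"` (z positions of the necks), and attribute `"sphere_radius"`.
#' @export
fused_spheres_mesh <- function(n, neck_radius_fraction = 0.1,
                               subdivision = 3L, relax_sweeps = 300L,
                               seed = 1L) {
  stopifnot(n >= 1, neck_radius_fraction > 0, neck_radius_fraction < 0.5)
  if (n == 1) return(build_icosphere(subdivision))
  nt <- 20L * 4L^subdivision
  # sphere radius: total area n * 4 pi R^2 = nt * sqrt(3)/4 (unit tether)
  R <- sqrt(nt * sqrt(3) / (16 * pi * n))
  rn <- neck_radius_fraction * R
  prof <- fused_profile(n, R, rn)
  rev_ <- revolution_mesh(prof)
  mesh <- relax_tether(rev_$x, rev_$tri, relax_sweeps = relax_sweeps,
                       seed = seed)
  attr(mesh, "profile") <- prof
  attr(mesh, "necks") <- (2 * seq_len(n - 1) - n) * R
  attr(mesh, "sphere_radius") <- R
  mesh
}

# triangulate a surface of revolution with near-unit edge lengths: rings at
# ring_step arclength spacing, each with ~2*pi*r vertices, joined by greedy
# triangle strips; fan caps at the poles.
revolution_mesh <- function(prof, edge = 1, ring_step = sqrt(3) / 2) {
  smax <- max(prof$s)
  svals <- seq(ring_step, smax - ring_step, by = ring_step)
  x <- matrix(0, 0, 3)
  rings <- list()
  for (j in seq_along(svals)) {
    rj <- approx(prof$s, prof$r, xout = svals[j])$y
    zj <- approx(prof$s, prof$z, xout = svals[j])$y
    k <- max(3L, round(2 * pi * rj / edge))
    # keep azimuthal chords of tiny rings above the lower tether bound
    rj <- max(rj, 0.55 * edge / sin(pi / k))
    phi <- 2 * pi * (seq_len(k) - 1) / k + (j %% 2) * pi / k
    idx <- nrow(x) + seq_len(k)
    x <- rbind(x, cbind(rj * cos(phi), rj * sin(phi), zj))
    rings[[j]] <- idx
  }
  p_bot <- nrow(x) + 1L; x <- rbind(x, c(0, 0, min(prof$z)))
  p_top <- nrow(x) + 1L; x <- rbind(x, c(0, 0, max(prof$z)))
  tris <- list()
  r1 <- rings[[1]]
  tris[[1]] <- cbind(p_bot, r1[c(2:length(r1), 1)], r1)   # ring 1 backward
  for (j in seq_len(length(rings) - 1))
    tris[[length(tris) + 1L]] <- strip_rings(x, rings[[j]], rings[[j + 1]])
  rm <- rings[[length(rings)]]
  tris[[length(tris) + 1L]] <- cbind(p_top, rm, rm[c(2:length(rm), 1)])  # forward
  tri <- do.call(rbind, tris)
  m <- list(x = x, tri = tri)
  # enforce outward orientation
  vol <- sum(x[tri[, 1], 1] * (x[tri[, 2], 2] * x[tri[, 3], 3] -
                               x[tri[, 2], 3] * x[tri[, 3], 2]) +
             x[tri[, 1], 2] * (x[tri[, 2], 3] * x[tri[, 3], 1] -
                               x[tri[, 2], 1] * x[tri[, 3], 3]) +
             x[tri[, 1], 3] * (x[tri[, 2], 1] * x[tri[, 3], 2] -
                               x[tri[, 2], 2] * x[tri[, 3], 1])) / 6
  if (vol < 0) m$tri <- tri[, c(1, 3, 2)]
  m
}

# greedy strip between lower ring L and upper ring U (both CCW about +z):
# lower-ring edges forward, upper-ring edges backward, so orientation is
# globally consistent across strips and caps.
strip_rings <- function(x, L, U) {
  nl <- length(L); nu <- length(U)
  # align start vertices
  d0 <- vapply(seq_len(nu), function(k) sum((x[L[1], ] - x[U[k], ])^2),
               numeric(1))
  U <- U[c(which.min(d0):nu, seq_len(which.min(d0) - 1))]
  i <- 0L; k <- 0L
  tris <- matrix(0L, nl + nu, 3L); q <- 0L
  while (i < nl || k < nu) {
    a <- L[i %% nl + 1L]; an <- L[(i + 1L) %% nl + 1L]
    b <- U[k %% nu + 1L]; bn <- U[(k + 1L) %% nu + 1L]
    advL <- i < nl &&
      (k >= nu || sum((x[an, ] - x[b, ])^2) <= sum((x[bn, ] - x[a, ])^2))
    q <- q + 1L
    if (advL) { tris[q, ] <- c(a, an, b); i <- i + 1L }
    else      { tris[q, ] <- c(a, bn, b); k <- k + 1L }
  }
  tris
}

# axisymmetric profile of n tangent spheres with catenoid neck bridges,
# centered on z = 0, parameterized by arclength.
fused_profile <- function(n, R, rn, n_samp = 4000L) {
  centers <- (2 * seq_len(n) - n - 1) * R
  contacts <- (2 * seq_len(n - 1) - n) * R
  zmin <- centers[1] - R; zmax <- centers[n] + R
  # catenoid half-width: intersection of rn*cosh(dz/rn) with the sphere arc
  half <- vapply(seq_len(n - 1), function(k) {
    zc <- contacts[k]; c1 <- centers[k]
    f <- function(dz) rn * cosh(dz / rn) - sqrt(pmax(0, R^2 - (zc - dz - c1)^2))
    # first crossing: catenoid above the sphere arc near the contact, below
    # beyond it (the second crossing, where cosh grows away again, is ignored)
    grid <- seq(1e-6 * R, 0.9 * R, length.out = 400)
    fg <- vapply(grid, f, numeric(1))
    ix <- which(fg <= 0)[1]
    if (is.na(ix) || ix == 1) stop("neck radius too large for catenoid bridge")
    uniroot(f, c(grid[ix - 1], grid[ix]))$root
  }, numeric(1))
  z <- seq(zmin, zmax, length.out = n_samp)
  r <- numeric(n_samp)
  for (i in seq_len(n_samp)) {
    zi <- z[i]
    k <- which.min(abs(zi - centers))
    rr <- sqrt(max(0, R^2 - (zi - centers[k])^2))
    for (q in seq_len(n - 1)) {
      if (abs(zi - contacts[q]) < half[q])
        rr <- rn * cosh((zi - contacts[q]) / rn)
    }
    r[i] <- rr
  }
  s <- cumsum(c(0, sqrt(diff(z)^2 + diff(r)^2)))
  data.frame(s = s, z = z, r = r)
}

# tether re-equilibration: run MC in repair mode (moves that do not worsen
# an existing violation are allowed) until all edges sit inside the target
# interval, then a short ordinary equilibration.
relax_tether <- function(x, tri, relax_sweeps = 300L, seed = 1L,
                         kappa = 20) {
  target <- tether_bounds(1)
  mesh <- trimesh(x, tri, l_min = target[1], l_max = target[2])
  A_ref <- surface_area(mesh); V_ref <- signed_volume(mesh)
  model <- energy_model(kappa = kappa, K_A = 1e6, K_V = 1e6,
                        A_ref = A_ref, V_ref = V_ref)
  for (round in 1:12) {
    len <- edge_lengths(mesh)
    if (round > 1 && all(len >= mesh$l_min & len <= mesh$l_max)) break
    sc <- mc_schedule(relax_sweeps, temperature = 0.2, width_vertex = 0.05,
                      tune = TRUE, stride = 0L, seed = seed + round)
    mesh <- run_mc(mesh, model, sc, repair = TRUE)$mesh
  }
  len <- edge_lengths(mesh)
  if (any(len < mesh$l_min | len > mesh$l_max))
    warning("tether re-equilibration left ",
            sum(len < mesh$l_min | len > mesh$l_max),
            " edge(s) outside the tether interval")
  mesh
}

#' Place dimer chains at the necks of a fused-sphere mesh
#'
#' Places `n_dimers` chains in groups of three straddling the connecting
#' necks, all on the same side of the fusion axis (the configuration is
#' equivalent under a common rotation about the axis). Beads are laid along
#' the axial offset profile at distance `(d0 + d1)/2` from the surface,
#' centered on the neck, so each bead starts inside the adhesion range.
#' Chains keep the reference geometry (S or straight) from their builder;
#' the placed coordinates generally carry a small internal strain.
#'
#' @param mesh a mesh built by `fused_spheres_mesh` (needs the `"profile"`
#'   attribute).
#' @param n_dimers number of chains (default 6: two groups of three).
#' @param shape `"s"` or `"straight"`.
#' @param params `adhesion_params` (supplies `d0`, `d1`).
#' @param azimuths azimuthal bead-group offsets within a group (radians,
#'   around the placement side; wide enough that neighboring chains stay a
#'   tether length apart at the narrow necks).
#' @param necks which necks to use (default: necks 1 and 2 for three fused
#'   spheres; outermost necks otherwise).
#' @return list of `dimer_chain` objects, each within adhesion range and
#'   free of hard-core violations (error if placement fails).
#' @export
place_dimers <- function(mesh, n_dimers = 6L, shape = c("s", "straight"),
                         params = adhesion_params(U = 0),
                         azimuths = c(-1.2, 0, 1.2), necks = NULL) {
  shape <- match.arg(shape)
  prof <- attr(mesh, "profile")
  if (is.null(prof)) stop("mesh has no profile attribute (not a fused_spheres_mesh?)")
  neck_z <- attr(mesh, "necks")
  # use the axisymmetric profile of the *relaxed* mesh itself, so the offset
  # placement sits at the right height above the actual surface
  prof <- empirical_profile(mesh, prof)
  if (is.null(necks)) {
    necks <- if (length(neck_z) <= 2) seq_along(neck_z)
             else c(1L, length(neck_z))
  }
  per_group <- ceiling(n_dimers / length(necks))
  h <- (params$d0 + params$d1) / 2
  build_set <- function(az_scale) {
    chains <- list()
    for (gi in seq_along(necks)) {
      zc <- neck_z[necks[gi]]
      s_c <- approx(prof$z, prof$s, xout = zc)$y
      # stagger groups azimuthally so chains from neighboring necks do not
      # collide where they overlap on the shared sphere
      g_off <- 0.6 * az_scale * (gi - 1)
      for (di in seq_len(per_group)) {
        if (length(chains) >= n_dimers) break
        ref <- if (shape == "s") build_s_dimer() else build_straight_chain()
        nb <- ref$n_beads
        offsets <- seq_len(nb) - (nb + 1) / 2    # unit spacing, centered
        # axial stagger keeps mid-chain beads apart at the narrow waist
        s_di <- s_c + (di - (per_group + 1) / 2) * 0.8
        ref$x <- place_on_offset_profile(
          prof, s_di, offsets, h,
          az_scale * azimuths[(di - 1) %% length(azimuths) + 1] + g_off)
        chains[[length(chains) + 1L]] <- ref
      }
    }
    # beads whose distance to the actual (relaxed) mesh falls outside the
    # adhesion range are projected to height h along the local surface
    # normal; in-range beads keep the smooth analytic placement
    mar <- 0.05 * (params$d1 - params$d0)
    for (it in 1:6) {
      n_fix <- 0L
      for (ci in seq_along(chains)) {
        x <- chains[[ci]]$x
        for (b in seq_len(nrow(x))) {
          bd <- bead_surface_distance(x[b, ], mesh)
          if (bd$d > params$d0 + mar && bd$d <= params$d1 - mar &&
              bd$side > 0) next
          tr <- mesh$tri[bd$triangle, ]
          nrm <- cross3(mesh$x[tr[2], ] - mesh$x[tr[1], ],
                        mesh$x[tr[3], ] - mesh$x[tr[1], ])
          nrm <- nrm / sqrt(sum(nrm^2))
          foot <- x[b, ] - bd$side * bd$d * nrm
          x[b, ] <- foot + h * nrm
          n_fix <- n_fix + 1L
        }
        chains[[ci]]$x <- x
      }
      if (n_fix == 0L) break
    }
    chains
  }
  chains <- NULL
  for (az_scale in c(1, 1.15, 1.3, 1.45)) {
    cand <- build_set(az_scale)
    ds <- unlist(lapply(cand, function(ch)
      vapply(seq_len(nrow(ch$x)), function(b)
        bead_surface_distance(ch$x[b, ], mesh)$d, numeric(1))))
    ok_range <- all(ds > params$d0) && all(ds <= params$d1)
    ok_excl <- ok_range && excluded_volume_check(cand, mesh, params)$ok
    if (ok_excl) { chains <- cand; break }
  }
  if (is.null(chains))
    stop("dimer placement failed: could not satisfy adhesion range and ",
         "excluded volume at any azimuthal spread")
  chains
}

# walk along the offset profile (surface of revolution pushed outward by h
# along its in-plane normal) and return bead positions at unit arclength
# spacing around s_center, at azimuth phi.
place_on_offset_profile <- function(prof, s_center, offsets, h, phi) {
  # offset curve points
  dz <- c(diff(prof$z), NA); dr <- c(diff(prof$r), NA)
  ds <- sqrt(dz^2 + dr^2)
  tz <- dz / ds; tr_ <- dr / ds
  k <- nrow(prof)
  tz[k] <- tz[k - 1]; tr_[k] <- tr_[k - 1]
  # in-plane outward normal of the revolved surface: (dz, -dr) rotated:
  # for profile traversed with increasing z, outward normal ~ (dr/ds? ...)
  nz <- -tr_; nr <- tz
  zoff <- prof$z + h * nz
  roff <- prof$r + h * nr
  soff <- cumsum(c(0, sqrt(diff(zoff)^2 + diff(roff)^2)))
  s0 <- approx(prof$s, soff, xout = s_center)$y
  st <- s0 + offsets
  zb <- approx(soff, zoff, xout = st)$y
  rb <- approx(soff, roff, xout = st)$y
  cbind(rb * cos(phi), rb * sin(phi), zb)
}

#' Fuse a spherical vesicle onto an existing mesh
#'
#' Attaches an icosphere to the outer surface of `mesh` at the given point
#' by removing one vertex disk on each surface and stitching the two
#' boundary rings with a band of triangles (a narrow neck), preserving
#' genus 0. The reference area and volume targets returned with the mesh
#' are the sums of the ideal constituent values, so constraint-driven runs
#' relax toward `v = 1/sqrt(n+1)` for equal-size additions.
#'
#' @param mesh host `trimesh`.
#' @param radius sphere radius of the added vesicle.
#' @param attachment_point length-3 point; the nearest host vertex is used.
#' @param subdivision icosphere subdivision of the added vesicle.
#' @param relax_sweeps tether re-equilibration length.
#' @param seed RNG seed for relaxation.
#' @return a `trimesh` with attributes `"A_ideal"`, `"V_ideal"` (summed
#'   ideal reference values when the host carries them, else host actuals
#'   plus the sphere).
#' @export
fuse_vesicle_to_shape <- function(mesh, radius, attachment_point,
                                  subdivision = 2L, relax_sweeps = 200L,
                                  seed = 1L) {
  if (radius <= 0) return(mesh)  # degenerate: nothing to add
  host_A <- attr(mesh, "A_ideal"); host_V <- attr(mesh, "V_ideal")
  if (is.null(host_A)) host_A <- surface_area(mesh)
  if (is.null(host_V)) host_V <- signed_volume(mesh)
  sp <- build_icosphere(subdivision)
  sc <- radius / sqrt(sum(sp$x[1, ]^2))
  sp_x <- sp$x * sc
  # host vertex nearest the attachment point
  d2 <- rowSums((sweep(mesh$x, 2, attachment_point))^2)
  hv <- which.min(d2)
  # outward direction at host vertex: mean of incident triangle normals
  inc <- which(apply(mesh$tri == hv, 1, any))
  nrm <- colSums(tri_cross(mesh$x, mesh$tri[inc, , drop = FALSE]))
  nrm <- nrm / sqrt(sum(nrm^2))
  # sphere vertex to remove: the one pointing back toward the host
  sv <- which.min(sp_x %*% nrm)
  center <- mesh$x[hv, ] + nrm * (radius * 1.02)
  sp_x <- sweep(sp_x, 2, center, `+`)
  res <- stitch_meshes(mesh$x, mesh$tri, hv, sp_x, sp$tri, sv)
  out <- relax_tether(res$x, res$tri, relax_sweeps = relax_sweeps, seed = seed)
  attr(out, "A_ideal") <- host_A + 4 * pi * radius^2
  attr(out, "V_ideal") <- host_V + 4 / 3 * pi * radius^3
  attr(out, "profile") <- attr(mesh, "profile")
  attr(out, "necks") <- attr(mesh, "necks")
  out
}

# remove vertex v1 from mesh1 and v2 from mesh2 and join the boundary rings
stitch_meshes <- function(x1, t1, v1, x2, t2, v2) {
  ring1 <- boundary_ring(t1, v1)
  ring2 <- boundary_ring(t2, v2)
  keep1 <- !apply(t1 == v1, 1, any)
  keep2 <- !apply(t2 == v2, 1, any)
  t1k <- t1[keep1, , drop = FALSE]
  t2k <- t2[keep2, , drop = FALSE]
  # drop removed vertices, reindex
  n1 <- nrow(x1)
  map1 <- seq_len(n1); map1[v1] <- NA
  map1[!is.na(map1)] <- seq_len(n1 - 1L)
  n2 <- nrow(x2)
  map2 <- seq_len(n2); map2[v2] <- NA
  map2[!is.na(map2)] <- seq_len(n2 - 1L) + (n1 - 1L)
  x <- rbind(x1[-v1, , drop = FALSE], x2[-v2, , drop = FALSE])
  t1k[] <- map1[t1k]; t2k[] <- map2[t2k]
  r1 <- map1[ring1]; r2 <- map2[ring2]
  # the band must traverse the host ring forward and the sphere ring
  # forward in its own order; strip_rings walks its second ring backward,
  # so hand it the reversed sphere ring
  band <- strip_rings(x, r1, rev(r2))
  trimesh(x, rbind(t1k, t2k, band))
}

# ordered boundary ring (neighbors of v in fan order, oriented so that the
# hole left by removing v is on the consistent side)
boundary_ring <- function(tri, v) {
  rows <- which(apply(tri == v, 1, any))
  segs <- lapply(rows, function(r) {
    t <- tri[r, ]; p <- match(v, t)
    c(t[(p %% 3) + 1], t[((p + 1) %% 3) + 1])  # directed edge opposite v
  })
  ring <- segs[[1]]
  segs <- segs[-1]
  while (length(segs)) {
    nxt <- which(vapply(segs, function(s) s[1] == ring[length(ring)], logical(1)))
    if (!length(nxt)) stop("broken vertex star")
    ring <- c(ring, segs[[nxt[1]]][2])
    segs <- segs[-nxt[1]]
  }
  ring[-length(ring)]
}

# greedy triangle strip between two closed rings (indices into x); ring1
# edges are traversed opposite to the host hole boundary, ring2 in stored
# (pre-reversed) order, so every directed edge of the closed result is
# traversed exactly once in each direction.
bridge_rings <- function(x, r1, r2) {
  n1 <- length(r1); n2 <- length(r2)
  i <- 0L; j <- 0L
  tris <- matrix(0L, n1 + n2, 3L); k <- 0L
  while (i < n1 || j < n2) {
    a  <- r1[i %% n1 + 1L]; an <- r1[(i + 1L) %% n1 + 1L]
    b  <- r2[j %% n2 + 1L]; bn <- r2[(j + 1L) %% n2 + 1L]
    adv1 <- i < n1 &&
      (j >= n2 || sum((x[an, ] - x[b, ])^2) <= sum((x[bn, ] - x[a, ])^2))
    k <- k + 1L
    if (adv1) { tris[k, ] <- c(an, a, b); i <- i + 1L }
    else      { tris[k, ] <- c(b, bn, a); j <- j + 1L }
  }
  tris
}

# axisymmetric radius profile measured from a (near-axisymmetric) mesh:
# mean vertex radius in z bins, lightly smoothed, resampled on the template
# profile's z grid and reparameterized by arclength.
empirical_profile <- function(mesh, template, n_bins = 100L) {
  z <- mesh$x[, 3]
  r <- sqrt(mesh$x[, 1]^2 + mesh$x[, 2]^2)
  brk <- seq(min(z) - 1e-9, max(z) + 1e-9, length.out = n_bins + 1L)
  bin <- findInterval(z, brk, all.inside = TRUE)
  zb <- (brk[-1] + brk[-length(brk)]) / 2
  rb <- vapply(seq_len(n_bins), function(k)
    if (any(bin == k)) mean(r[bin == k]) else NA_real_, numeric(1))
  ok <- !is.na(rb)
  sm <- stats::smooth.spline(zb[ok], rb[ok], spar = 0.4)
  zi <- template$z
  ri <- pmax(0.05, stats::predict(sm, pmin(max(zb[ok]), pmax(min(zb[ok]), zi)))$y)
  # close the poles
  ri[1] <- 0; ri[length(ri)] <- 0
  s <- cumsum(c(0, sqrt(diff(zi)^2 + diff(ri)^2)))
  data.frame(s = s, z = zi, r = ri)
}
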