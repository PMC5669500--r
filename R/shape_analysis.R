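#' Geometric descriptors of a vesicle shape
#'
#' Computes the area-weighted gyration-tensor eigenvalues and relative
#' shape anisotropy, reduced volume, area difference, ray-casting pocket
#' descriptors (depth and one-sidedness of the deepest concavity, whether
#' the area centroid lies outside the enclosed volume, fraction of
#' directions whose ray crosses the surface three or more times), and an
#' arm count from the radial-distance field. All descriptors are invariant
#' under rigid motions and uniform scaling.
#'
#' @param mesh a `trimesh`.
#' @param n_dirs number of ray directions (vertex directions of an
#'   icosphere).
#' @return one-row data.frame of descriptors.
#' @export
shape_descriptors <- function(mesh, n_dirs = 162L) {
  geom <- triangle_geometry(mesh)
  cent <- (mesh$x[mesh$tri[, 1], ] + mesh$x[mesh$tri[, 2], ] +
           mesh$x[mesh$tri[, 3], ]) / 3
  w <- geom$area / sum(geom$area)
  com <- colSums(cent * w)
  xc <- sweep(cent, 2, com)
  G <- t(xc * w) %*% xc
  lam <- sort(eigen(G, symmetric = TRUE)$values, decreasing = TRUE)
  lam[lam < 0] <- 0
  tr <- sum(lam)
  asph <- ((lam[1] - lam[2])^2 + (lam[1] - lam[3])^2 + (lam[2] - lam[3])^2) /
    (2 * tr^2)
  st <- shape_state(mesh)
  # ray casting from the area centroid; directions rotated by a generic
  # rotation so rays do not pass exactly through mesh vertices, and
  # coincident hits (edge/vertex grazing counted by both adjacent
  # triangles) collapsed to one
  dirs <- build_icosphere(max(1L, round(log(n_dirs / 10) / log(4))))$x
  dirs <- dirs / sqrt(rowSums(dirs^2))
  a1 <- 0.394; a2 <- 0.716
  R1 <- matrix(c(cos(a1), sin(a1), 0, -sin(a1), cos(a1), 0, 0, 0, 1), 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(a2), sin(a2), 0, -sin(a2), cos(a2)), 3)
  dirs <- dirs %*% R1 %*% R2
  scale_len <- sqrt(max(rowSums(xc^2)))
  hits <- cpp_ray_crossings(com, dirs, mesh$x, mesh$tri - 1L)
  hits <- lapply(hits, function(h) {
    if (length(h) < 2) return(h)
    h[c(TRUE, diff(h) > 1e-7 * scale_len)]
  })
  ncross <- vapply(hits, length, integer(1))
  inside <- mean(ncross %% 2) > 0.5       # odd crossings -> com inside
  frac_multi <- mean(ncross >= 3)
  # support-function concavity depth: h(dir) - distance to last crossing
  hsup <- vapply(seq_len(nrow(dirs)), function(d)
    max(xc %*% dirs[d, ]), numeric(1))
  rout <- vapply(hits, function(h) if (length(h)) max(h) else 0, numeric(1))
  depth <- hsup - rout
  dia <- vapply(seq_len(nrow(dirs)), function(d) {
    opp <- which.max(-(dirs %*% dirs[d, ]))
    hsup[d] + hsup[opp]
  }, numeric(1))
  reldep <- depth / dia
  imax <- which.max(reldep)
  opp <- which.max(-(dirs %*% dirs[imax, ]))
  pocket_depth <- reldep[imax]
  pocket_opposite <- reldep[opp]
  one_sided <- pocket_depth > 2.5 * max(pocket_opposite, 1e-3)
  # arm count: connected components of the high-radial-distance vertex set
  rv <- sqrt(rowSums(sweep(mesh$x, 2, com)^2))
  sel <- rv > 0.7 * max(rv)
  n_arms <- count_components(mesh, sel)
  data.frame(lam1 = lam[1], lam2 = lam[2], lam3 = lam[3],
             asphericity = asph, v = st$v, da = st$da,
             com_inside = inside, frac_multi = frac_multi,
             pocket_depth = pocket_depth, pocket_opposite = pocket_opposite,
             one_sided = one_sided, n_arms = n_arms)
}

count_components <- function(mesh, sel) {
  idx <- which(sel)
  if (!length(idx)) return(0L)
  lab <- integer(nrow(mesh$x))
  comp <- 0L
  adj <- mesh$edges[sel[mesh$edges[, 1]] & sel[mesh$edges[, 2]], , drop = FALSE]
  nbr <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
  for (s in idx) {
    if (lab[s] > 0) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (lab[u] > 0) next
      lab[u] <- comp
      nb <- nbr[[as.character(u)]]
      if (!is.null(nb)) queue <- c(queue, nb[lab[nb] == 0])
    }
  }
  comp
}

#' Classify a vesicle shape
#'
#' Deterministic rule on scale- and rotation-invariant descriptors,
#' calibrated on annealed reference shapes of the shape branch: sphere
#' (vanishing asphericity at v near 1), tube (one dominant gyration axis,
#' no pocket), disk (two dominant axes, shallow symmetric dimples), paddle
#' (mixed tube and disk cross-sections), bowl (single-sided pocket of
#' intermediate depth), cup / phagophore (deep single pocket, or area
#' centroid outside the enclosed volume), starfish (three or more arms).
#' Unrecognized shapes return `"other"`, never an error.
#'
#' @param mesh a `trimesh`.
#' @param desc optional precomputed `shape_descriptors` row.
#' @return list `label` (character) and `descriptors` (data.frame row).
#' @export
classify_shape <- function(mesh, desc = NULL) {
  d <- if (is.null(desc)) shape_descriptors(mesh) else desc
  p <- d$lam1 / max(d$lam2, 1e-12)     # prolateness
  q <- d$lam2 / max(d$lam3, 1e-12)     # oblateness
  # deep-invagination evidence; the centroid-outside test alone is not
  # enough (a bent tube also puts the centroid outside), so it is gated on
  # the shape not being dominated by a single long axis
  deep <- (!d$com_inside && p < 2.2) ||
    (d$one_sided && d$pocket_depth > 0.35) ||
    (d$frac_multi > 0.2 && d$one_sided && d$pocket_depth > 0.25)
  label <-
    if (d$asphericity < 0.01 && d$v > 0.9) "sphere"
    else if (d$n_arms >= 3 && d$asphericity > 0.02) "starfish"
    else if (deep) "cup"
    else if (d$one_sided && d$pocket_depth > 0.12) "bowl"
    else if (p > 2.5 && q < 2.0) "tube"
    else if (p < 2.0 && q > 2.5) "disk"
    else if (p > 2.0 && q > 2.0) "paddle"
    else if (p > 1.6) "tube"
    else if (q > 1.6) "disk"
    else "other"
  list(label = label, descriptors = d)
}

#' Extract barrier heights from a shape-branch table
#'
#' Locates the local minima and maxima of the annealed energy along the
#' area difference and reports `H1` (tube-to-disk barrier: energy at the
#' maximum below the highest-da minimum, minus the tube-minimum energy)
#' and `H2` (disk-to-cup barrier: maximum below the disk minimum minus the
#' disk-minimum energy). A monotone profile reports the corresponding
#' barrier as absent (`NA`), as happens for the disk-to-cup barrier at
#' reduced volumes below about 0.52.
#'
#' @param branch data.frame with columns `da` and either `E_b_8pk` or `E_b`
#'   (energies used as given; report units accordingly).
#' @return list `H1`, `H2`, `stationary` (data.frame of located extrema
#'   with type labels: tube_min, tube_disk_top, disk_min, disk_cup_top,
#'   low_min).
#' @export
extract_barriers <- function(branch) {
  E <- if ("E_b_8pk" %in% names(branch)) branch$E_b_8pk else branch$E_b
  ord <- order(branch$da)
  da <- branch$da[ord]; E <- E[ord]
  n <- length(E)
  if (n < 3) return(list(H1 = NA_real_, H2 = NA_real_,
                         stationary = data.frame()))
  kind <- character(0); idx <- integer(0)
  for (i in seq_len(n)) {
    lo <- if (i > 1) E[i - 1] else Inf
    hi <- if (i < n) E[i + 1] else Inf
    if (E[i] <= lo && E[i] <= hi) { kind <- c(kind, "min"); idx <- c(idx, i) }
    else if (i > 1 && i < n && E[i] >= E[i - 1] && E[i] >= E[i + 1]) {
      kind <- c(kind, "max"); idx <- c(idx, i)
    }
  }
  mins <- idx[kind == "min"]; maxs <- idx[kind == "max"]
  H1 <- H2 <- NA_real_
  stat <- data.frame(da = da[idx], E = E[idx], kind = kind)
  stat$role <- NA_character_
  if (length(mins)) {
    tube <- max(mins)                      # highest-da local minimum
    stat$role[stat$da == da[tube] & stat$kind == "min"] <- "tube_min"
    top1 <- maxs[maxs < tube]
    if (length(top1)) {
      top1 <- max(top1)
      H1 <- E[top1] - E[tube]
      stat$role[stat$da == da[top1]] <- "tube_disk_top"
      disk <- mins[mins < top1]
      if (length(disk)) {
        disk <- max(disk)
        stat$role[stat$da == da[disk]] <- "disk_min"
        top2 <- maxs[maxs < disk]
        if (length(top2)) {
          top2 <- max(top2)
          H2 <- E[top2] - E[disk]
          stat$role[stat$da == da[top2]] <- "disk_cup_top"
          low <- mins[mins < top2]
          if (length(low)) stat$role[stat$da == da[min(low)]] <- "low_min"
        }
      }
    }
  }
  list(H1 = H1, H2 = H2, stationary = stat)
}

#' Success rate of phagophore formation
#'
#' Fraction of runs whose final shape label is `"cup"`; a set of runs is
#' called successful when at least 75% reach the cup within the allotted
#' MC time.
#'
#' @param labels character vector of final shape labels.
#' @param threshold success threshold (default 0.75).
#' @return list `fraction`, `n`, `successful`.
#' @export
success_rate <- function(labels, threshold = 0.75) {
  stopifnot(length(labels) >= 1)
  fr <- mean(labels == "cup")
  list(fraction = fr, n = length(labels), successful = fr >= threshold)
}
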