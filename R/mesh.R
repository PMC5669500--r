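#' @useDynLib phagosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd acf coef dist uniroot approx rnorm runif
#' @importFrom stats smooth.spline predict splinefun
#' @importFrom utils head tail write.table read.table modifyList
NULL

#' Triangulated surface meshes
#'
#' A `trimesh` is a closed, orientable, genus-0 triangulated surface: the
#' discrete membrane of the DTMC model. It stores vertex coordinates (in
#' units of the tether length), consistently outward-oriented triangles, and
#' an edge table derived from the triangles. Edge lengths are kept inside a
#' tether interval `[l_min, l_max]` so that triangles stay non-degenerate
#' while edge flips keep the surface fluid.
#'
#' @param x numeric n_v x 3 matrix of vertex positions.
#' @param tri integer n_t x 3 matrix of vertex indices (1-based), oriented so
#'   that triangle normals point outward.
#' @param l_min,l_max tether bounds on edge lengths. Defaults place the
#'   current mean edge length at the geometric middle of an interval with
#'   ratio `sqrt(3)` (see `tether_bounds`).
#' @return an object of class `trimesh` with components `x`, `tri`, `edges`
#'   (n_e x 2 vertex pairs), `edge_tri` (n_e x 2 adjacent triangles), and the
#'   tether bounds.
#' @export
trimesh <- function(x, tri, l_min = NULL, l_max = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  tri <- as.matrix(tri)
  storage.mode(tri) <- "integer"
  stopifnot(ncol(x) == 3L, ncol(tri) == 3L)
  ed <- edges_from_triangles(tri, n_vertices = nrow(x))
  if (is.null(l_min) || is.null(l_max)) {
    tb <- tether_bounds(mean(edge_lengths_raw(x, ed$edges)))
    if (is.null(l_min)) l_min <- tb[1]
    if (is.null(l_max)) l_max <- tb[2]
  }
  structure(list(x = x, tri = tri, edges = ed$edges, edge_tri = ed$edge_tri,
                 l_min = l_min, l_max = l_max),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d edges, %d triangles (chi = %d)\n",
              nrow(x$x), nrow(x$edges), nrow(x$tri),
              nrow(x$tri) - nrow(x$edges) + nrow(x$x)))
  cat(sprintf("tether [%.4g, %.4g], mean edge %.4g\n",
              x$l_min, x$l_max, mean(edge_lengths(x))))
  invisible(x)
}

#' Tether interval for a given mean edge length
#'
#' The tether interval keeps edges within `[l_low, ratio * l_low]`. The
#' default ratio `sqrt(3)` is the widest interval compatible with
#' non-degenerate triangles on a tethered fluid mesh; `l_low` is chosen so
#' that `l_mean` sits at the geometric middle of the interval. A literal
#' looser interval (e.g. ratio 3) can be requested.
#'
#' @param l_mean mean edge length of the mesh.
#' @param ratio upper/lower bound ratio (default `sqrt(3)`).
#' @return numeric vector `c(l_min, l_max)`.
#' @export
tether_bounds <- function(l_mean, ratio = sqrt(3)) {
  l_low <- l_mean / sqrt(ratio)
  c(l_low, ratio * l_low)
}

edge_lengths_raw <- function(x, edges) {
  d <- x[edges[, 1], , drop = FALSE] - x[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Edge lengths of a mesh
#' @param mesh a `trimesh`.
#' @return numeric vector of length n_e.
#' @export
edge_lengths <- function(mesh) edge_lengths_raw(mesh$x, mesh$edges)

#' Build the edge table of a triangulation
#'
#' Each undirected edge of a closed orientable surface is shared by exactly
#' two triangles and traversed once in each direction. The function errors on
#' boundary or non-manifold edges unless `strict = FALSE`.
#'
#' @param tri integer triangle matrix.
#' @param n_vertices number of vertices (for index validation).
#' @param strict error on non-closed input (default) or return diagnostics.
#' @return list with `edges` (n_e x 2), `edge_tri` (n_e x 2) and, when
#'   `strict = FALSE`, vectors of offending edge indices.
#' @export
edges_from_triangles <- function(tri, n_vertices = max(tri), strict = TRUE) {
  stopifnot(all(tri >= 1L), all(tri <= n_vertices))
  i <- as.vector(t(tri))
  j <- as.vector(t(tri[, c(2, 3, 1)]))
  a <- pmin(i, j); b <- pmax(i, j)
  key <- paste(a, b)
  tri_id <- rep(seq_len(nrow(tri)), each = 3L)
  first <- !duplicated(key)
  edges <- cbind(a[first], b[first])
  idx <- match(key, key[first])
  cnt <- tabulate(idx, nbins = sum(first))
  et <- matrix(NA_integer_, sum(first), 2L)
  ord <- order(idx)
  pos <- c(0L, cumsum(cnt))
  for (e in seq_len(sum(first))) {
    tt <- tri_id[ord[(pos[e] + 1L):pos[e + 1L]]]
    et[e, seq_len(min(2L, length(tt)))] <- tt[seq_len(min(2L, length(tt)))]
  }
  bad_boundary <- which(cnt != 2L)
  if (strict && length(bad_boundary))
    stop("mesh is not a closed 2-manifold: ", length(bad_boundary),
         " edge(s) not shared by exactly two triangles")
  # orientation: each undirected edge must appear once as (i,j) and once (j,i)
  dir_key <- paste(i, j)
  bad_orient <- which(duplicated(dir_key) | duplicated(dir_key, fromLast = TRUE))
  if (strict && length(bad_orient))
    stop("inconsistent triangle orientation: some directed edge repeated")
  out <- list(edges = edges, edge_tri = et)
  if (!strict) {
    out$boundary_edges <- bad_boundary
    out$misoriented <- unique(tri_id[bad_orient])
  }
  out
}

#' Build an icosphere mesh
#'
#' Subdivides a regular icosahedron `subdivision` times, projecting new
#' vertices onto the sphere, giving `10 * 4^L + 2` vertices. Level 3 gives the
#' 642-vertex mesh used for protein runs; level 4 the 2562-vertex mesh used
#' for free-vesicle runs.
#'
#' @param subdivision non-negative integer subdivision level L.
#' @param radius sphere radius; the default chooses the radius at which the
#'   mean edge length equals the unit tether length `l` defined from the mean
#'   triangle area (`l^2 = 4 * Abar / sqrt(3)`).
#' @return a `trimesh`.
#' @export
build_icosphere <- function(subdivision = 3L, radius = NULL) {
  stopifnot(subdivision >= 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision)) {
    res <- subdivide_once(v, f)
    v <- res$v; f <- res$f
  }
  # orient outward: for a sphere about origin, normal . centroid > 0
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  n <- tri_cross(v, f)
  flip <- rowSums(n * cent) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  if (is.null(radius)) {
    # unit tether length: l = sqrt(4*Abar/sqrt(3)); at radius R, A = area of
    # the *polyhedral* surface ~ 4 pi R^2. Solve for mean triangle area = sqrt(3)/4.
    areas <- tri_areas_raw(v, f)
    abar <- mean(areas)                     # at R = 1
    radius <- sqrt((sqrt(3) / 4) / abar)
  }
  trimesh(v * radius, f)
}

subdivide_once <- function(v, f) {
  nv <- nrow(v)
  env_key <- new.env(parent = emptyenv())
  verts <- list(v)
  counter <- nv
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- env_key[[key]]
    if (!is.null(id)) return(id)
    m <- (v[i, ] + v[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    counter <<- counter + 1L
    verts[[length(verts) + 1L]] <<- m
    env_key[[key]] <- counter
    counter
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    newf[4L * t - 3L, ] <- c(a, ab, ca)
    newf[4L * t - 2L, ] <- c(b, bc, ab)
    newf[4L * t - 1L, ] <- c(cc, ca, bc)
    newf[4L * t, ]      <- c(ab, bc, ca)
  }
  vmat <- matrix(0, counter, 3)
  vmat[seq_len(nv), ] <- v
  if (counter > nv)
    vmat[(nv + 1L):counter, ] <- do.call(rbind, verts[-1])
  list(v = vmat, f = newf)
}

tri_cross <- function(x, tri) {
  u <- x[tri[, 2], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  w <- x[tri[, 3], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

tri_areas_raw <- function(x, tri) {
  n <- tri_cross(x, tri)
  0.5 * sqrt(rowSums(n * n))
}

#' Validate mesh invariants
#'
#' Checks the closed-manifold, orientation, Euler-characteristic, tether and
#' non-degeneracy invariants and reports every violation found.
#'
#' @param mesh a `trimesh`.
#' @param area_tol triangles with area below this are reported degenerate.
#' @return character vector of violations; empty when the mesh is valid.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-10) {
  rep_ <- character()
  ed <- tryCatch(edges_from_triangles(mesh$tri, nrow(mesh$x), strict = FALSE),
                 error = function(e) NULL)
  if (is.null(ed)) return("edge table could not be built")
  if (length(ed$boundary_edges))
    rep_ <- c(rep_, sprintf("%d edge(s) not shared by exactly two triangles",
                            length(ed$boundary_edges)))
  if (length(ed$misoriented))
    rep_ <- c(rep_, sprintf("%d triangle(s) with inconsistent orientation",
                            length(ed$misoriented)))
  chi <- nrow(mesh$tri) - nrow(ed$edges) + nrow(mesh$x)
  if (!length(ed$boundary_edges) && chi != 2L)
    rep_ <- c(rep_, sprintf("Euler characteristic %d != 2 (genus 0 required)", chi))
  len <- edge_lengths_raw(mesh$x, ed$edges)
  n_out <- sum(len < mesh$l_min - 1e-12 | len > mesh$l_max + 1e-12)
  if (n_out > 0)
    rep_ <- c(rep_, sprintf("%d edge length(s) outside tether interval [%.4g, %.4g]",
                            n_out, mesh$l_min, mesh$l_max))
  areas <- tri_areas_raw(mesh$x, mesh$tri)
  if (any(areas < area_tol))
    rep_ <- c(rep_, sprintf("%d degenerate triangle(s) below area %g",
                            sum(areas < area_tol), area_tol))
  rep_
}

#' Flip an interior edge
#'
#' Replaces the shared edge of two adjacent triangles by the opposite
#' diagonal of their quadrilateral, the connectivity move that makes the
#' tethered membrane fluid. The flip is *rejected* (not an error) when the
#' new diagonal already exists as an edge, when an endpoint of the old edge
#' would drop below vertex degree 3, when the new edge length falls outside
#' the tether interval, or when either new triangle would be degenerate.
#'
#' @param mesh a `trimesh`.
#' @param edge index into `mesh$edges`.
#' @return list with `accepted` (logical), `mesh` (updated or original), and
#'   `reason` when rejected.
#' @export
flip_edge <- function(mesh, edge) {
  ev <- mesh$edges[edge, ]
  tt <- mesh$edge_tri[edge, ]
  t1 <- mesh$tri[tt[1], ]; t2 <- mesh$tri[tt[2], ]
  i <- ev[1]; j <- ev[2]
  k <- setdiff(t1, ev); m <- setdiff(t2, ev)
  if (length(k) != 1L || length(m) != 1L || k == m)
    return(list(accepted = FALSE, mesh = mesh, reason = "not flippable"))
  # degree check
  deg_i <- sum(mesh$edges == i); deg_j <- sum(mesh$edges == j)
  if (deg_i <= 3L || deg_j <= 3L)
    return(list(accepted = FALSE, mesh = mesh, reason = "degree would drop below 3"))
  # new edge existing?
  a <- min(k, m); b <- max(k, m)
  if (any(mesh$edges[, 1] == a & mesh$edges[, 2] == b))
    return(list(accepted = FALSE, mesh = mesh, reason = "new edge exists"))
  lnew <- sqrt(sum((mesh$x[k, ] - mesh$x[m, ])^2))
  if (lnew < mesh$l_min || lnew > mesh$l_max)
    return(list(accepted = FALSE, mesh = mesh, reason = "tether violated"))
  # build new triangles preserving orientation: t1 contains directed edge i->j
  # or j->i; use order within t1 to keep outward orientation.
  ord1 <- orient_pair(t1, i, j)
  if (ord1) { new1 <- c(i, m, k); new2 <- c(j, k, m) }
  else      { new1 <- c(i, k, m); new2 <- c(j, m, k) }
  tri <- mesh$tri
  tri[tt[1], ] <- new1
  tri[tt[2], ] <- new2
  if (min(tri_areas_raw(mesh$x, rbind(new1, new2))) < 1e-12)
    return(list(accepted = FALSE, mesh = mesh, reason = "degenerate triangle"))
  out <- trimesh(mesh$x, tri, l_min = mesh$l_min, l_max = mesh$l_max)
  list(accepted = TRUE, mesh = out)
}

# TRUE if directed edge i->j occurs in triangle t (cyclically)
orient_pair <- function(t, i, j) {
  p <- match(i, t)
  t[(p %% 3) + 1] == j
}

#' Mesh element counts
#' @param mesh a `trimesh`.
#' @return named integer vector `n_v`, `n_e`, `n_t`.
#' @export
mesh_counts <- function(mesh) {
  c(n_v = nrow(mesh$x), n_e = nrow(mesh$edges), n_t = nrow(mesh$tri))
}
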