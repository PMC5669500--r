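test_that("icosphere counts follow 10*4^L + 2 and the Euler relation", {
  for (L in 0:4) {
    m <- build_icosphere(L)
    cnt <- mesh_counts(m)
    expect_equal(unname(cnt["n_v"]), 10 * 4^L + 2)
    expect_identical(unname(cnt["n_t"] - cnt["n_e"] + cnt["n_v"]), 2L)
  }
  expect_equal(unname(mesh_counts(build_icosphere(3))), c(642L, 1920L, 1280L))
  expect_equal(unname(mesh_counts(build_icosphere(4))), c(2562L, 7680L, 5120L))
})

test_that("icosphere vertices are equidistant from the center", {
  m <- build_icosphere(2, radius = 3.7)
  r <- sqrt(rowSums(m$x^2))
  expect_lt(max(abs(r / 3.7 - 1)), 1e-10)
})

test_that("validate_mesh reports each class of violation", {
  m <- build_icosphere(2)
  expect_length(validate_mesh(m), 0)
  # deleting a triangle opens the surface
  broken <- m
  broken$tri <- m$tri[-1, ]
  expect_true(any(grepl("two triangles", validate_mesh(broken))))
  # stretching one edge beyond the tether bound
  stretched <- m
  v1 <- m$edges[1, 1]
  stretched$x[v1, ] <- stretched$x[v1, ] * 1.8
  expect_true(any(grepl("tether", validate_mesh(stretched))))
})

test_that("edge table round-trips from triangles", {
  m <- build_icosphere(2)
  ed <- edges_from_triangles(m$tri, nrow(m$x))
  expect_identical(ed$edges, m$edges)
  # every edge has two distinct adjacent triangles
  expect_true(all(ed$edge_tri[, 1] != ed$edge_tri[, 2]))
})

test_that("edge flip is an involution and preserves counts", {
  m0 <- build_icosphere(2)
  # a loose tether so that flip diagonals are admissible
  m <- trimesh(m0$x, m0$tri, l_min = m0$l_min,
               l_max = 3 * mean(edge_lengths(m0)))
  # find a flippable edge
  flipped <- NULL
  for (e in seq_len(nrow(m$edges))) {
    r <- flip_edge(m, e)
    if (r$accepted) { flipped <- r$mesh; edge_used <- e; break }
  }
  expect_false(is.null(flipped))
  expect_identical(mesh_counts(flipped), mesh_counts(m))
  expect_length(validate_mesh(flipped), 0)
  # flip the new diagonal back: connectivity returns to the original
  ev_new <- which(apply(flipped$edges, 1, function(p)
    !any(apply(m$edges, 1, function(q) all(p == q)))))
  back <- flip_edge(flipped, ev_new[1])
  expect_true(back$accepted)
  key <- function(tri) sort(apply(t(apply(tri, 1, sort)), 1, paste, collapse = "-"))
  expect_identical(key(back$mesh$tri), key(m$tri))
})

test_that("flips that would violate the tether are rejected, not errors", {
  m <- build_icosphere(2)
  # shrink the allowed interval so every diagonal is too long
  tight <- trimesh(m$x, m$tri, l_min = m$l_min, l_max = mean(edge_lengths(m)))
  res <- vapply(seq_len(nrow(tight$edges)), function(e)
    flip_edge(tight, e)$accepted, logical(1))
  expect_false(any(res))
})

test_that("manifold invariants survive thousands of MC flips and moves", {
  m <- build_icosphere(2)
  mod <- free_vesicle_model(m)
  r <- run_mc(m, mod, mc_schedule(300, temperature = 1, stride = 0, seed = 9))
  expect_length(validate_mesh(r$mesh), 0)
  cnt <- mesh_counts(r$mesh)
  expect_identical(unname(cnt["n_t"] - cnt["n_e"] + cnt["n_v"]), 2L)
})

test_that("tether bounds put the mean edge at the geometric mid-interval", {
  tb <- tether_bounds(1.1)
  expect_equal(sqrt(tb[1] * tb[2]), 1.1, tolerance = 1e-12)
  expect_equal(tb[2] / tb[1], sqrt(3), tolerance = 1e-12)
  wide <- tether_bounds(1, ratio = 3)
  expect_equal(wide[2] / wide[1], 3, tolerance = 1e-12)
})
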