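test_that("rook contiguity on small lattices matches enumeration", {
  g22 <- build_adjacency(grid_geometry(2, 2))
  expect_equal(lengths(g22$nb), rep(2L, 4))
  expect_equal(nrow(g22$edges), 4)

  # 3x3: brute-force oracle from lattice indices
  g33 <- build_adjacency(grid_geometry(3, 3))
  oracle_deg <- function(r, c) sum(c(r > 1, r < 3, c > 1, c < 3))
  expected <- unlist(lapply(1:3, function(cc)
    vapply(1:3, function(r) oracle_deg(r, cc), numeric(1))))
  expect_equal(lengths(g33$nb), as.integer(expected))
  # corners 2, edges 3, center 4
  expect_equal(sort(unique(lengths(g33$nb))), c(2L, 3L, 4L))
})

test_that("adjacency is symmetric, loop-free and handles isolates", {
  g <- build_adjacency(grid_geometry(3, 4))
  for (i in seq_along(g$ids)) {
    expect_false(i %in% g$nb[[i]])
    for (j in g$nb[[i]]) expect_true(i %in% g$nb[[j]])
  }
  # two disjoint squares: no edges, both isolates
  geoms <- geometry_set(list(
    A = matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE),
    B = matrix(c(5, 5, 6, 5, 6, 6, 5, 6), ncol = 2, byrow = TRUE)))
  g2 <- build_adjacency(geoms)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(graph_components(g2), c(1L, 2L))
})

test_that("queen contiguity adds corner-touching neighbors", {
  rook <- build_adjacency(grid_geometry(2, 2), contiguity = "rook")
  queen <- build_adjacency(grid_geometry(2, 2), contiguity = "queen")
  expect_equal(nrow(rook$edges), 4)
  expect_equal(nrow(queen$edges), 6)  # both diagonals included
})

test_that("adjacency is invariant under joint translation and rotation", {
  base <- grid_geometry(3, 3)
  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- geometry_set(lapply(base$areas, function(parts) {
    lapply(parts, function(ring) sweep(ring %*% Rm, 2, c(-13.7, 4.2), "+"))
  }))
  g1 <- build_adjacency(base)
  g2 <- build_adjacency(moved)
  expect_equal(g1$edges, g2$edges)
})

test_that("invalid geometry inputs raise informative errors", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(geometry_set(list(sq)), "named")
  expect_error(geometry_set(list(A = sq, A = sq)), "duplicate")
  bowtie <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(geometry_set(list(B = bowtie)), "self-intersecting")
  degen <- matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)
  expect_error(geometry_set(list(C = degen)), "degenerate")
})

test_that("river adjacency flags crossing, boundary-following and misses", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  crossing <- matrix(c(0.5, -1, 0.5, 2), ncol = 2, byrow = TRUE)
  along_edge <- matrix(c(0, 1, 1, 1), ncol = 2, byrow = TRUE)
  disjoint <- matrix(c(3, 3, 4, 4), ncol = 2, byrow = TRUE)
  inside <- matrix(c(0.2, 0.2, 0.8, 0.8), ncol = 2, byrow = TRUE)

  expect_equal(unname(river_adjacent(
    geometry_set(list(A = sq), list(crossing)))), 1L)
  expect_equal(unname(river_adjacent(
    geometry_set(list(A = sq), list(along_edge)))), 1L)
  expect_equal(unname(river_adjacent(
    geometry_set(list(A = sq), list(disjoint)))), 0L)
  expect_equal(unname(river_adjacent(
    geometry_set(list(A = sq), list(inside)))), 1L)
  expect_error(river_adjacent(geometry_set(list(A = sq))), "river layer")
})

test_that("centroid-to-river distance matches point-segment geometry", {
  # unit square centered at the origin; vertical river at x = 2
  sq <- matrix(c(-0.5, -0.5, 0.5, -0.5, 0.5, 0.5, -0.5, 0.5),
               ncol = 2, byrow = TRUE)
  river <- matrix(c(2, -10, 2, 10), ncol = 2, byrow = TRUE)
  d <- centroid_river_distance(geometry_set(list(A = sq), list(river)))
  expect_equal(unname(d), 2, tolerance = 1e-12)

  # centroid on the river -> 0
  through <- matrix(c(0, -1, 0, 1), ncol = 2, byrow = TRUE)
  d0 <- centroid_river_distance(geometry_set(list(A = sq), list(through)))
  expect_equal(unname(d0), 0, tolerance = 1e-12)

  # adding a farther river leaves the minimum unchanged
  far <- matrix(c(50, 0, 60, 0), ncol = 2, byrow = TRUE)
  d2 <- centroid_river_distance(
    geometry_set(list(A = sq), list(river, far)))
  expect_equal(d2, d)

  # off-segment nearest point: distance to an endpoint
  stub <- matrix(c(3, 4, 3, 9), ncol = 2, byrow = TRUE)
  d3 <- centroid_river_distance(geometry_set(list(A = sq), list(stub)))
  expect_equal(unname(d3), 5, tolerance = 1e-12)
})

test_that("GeoJSON round-trip preserves geometry, adjacency and indicators", {
  sim <- simulate_study(small_config(seed = 9))
  fa <- tempfile(fileext = ".geojson")
  fr <- tempfile(fileext = ".geojson")
  write_geojson(sim$geoms, fa, fr)
  back <- read_geojson(fa, fr)
  expect_equal(names(back$areas), names(sim$geoms$areas))
  g1 <- build_adjacency(sim$geoms)
  g2 <- build_adjacency(back)
  expect_equal(g1$edges, g2$edges)
  expect_equal(river_adjacent(back), river_adjacent(sim$geoms))
  unlink(c(fa, fr))
})

test_that("geometric lattice adjacency equals the index-based constructor", {
  cfg <- small_config(seed = 3, rows = 4, cols = 5)
  sim <- simulate_study(cfg)
  g_geom <- build_adjacency(sim$geoms)
  g_idx <- lattice_adjacency(cfg)
  expect_equal(g_geom$ids, g_idx$ids)
  expect_equal(g_geom$edges, g_idx$edges)
})
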