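test_that("edge-list construction deduplicates, computes degrees and components", {
  g <- build_adjacency_from_edgelist(c("A", "B", "C"),
                                     rbind(c("A", "B"), c("B", "A")))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$degrees, c(1, 1, 0))
  expect_equal(max(g$component_labels), 2)

  path <- build_adjacency_from_edgelist(c("A", "B", "C"),
                                        rbind(c("A", "B"), c("B", "C")))
  expect_equal(path$degrees, c(1, 2, 1))
  expect_equal(max(path$component_labels), 1)

  lone <- build_adjacency_from_edgelist("A", NULL)
  expect_equal(lone$m, 1)
  expect_equal(nrow(lone$edges), 0)
  expect_equal(lone$component_labels, 1L)

  expect_error(build_adjacency_from_edgelist(c("A", "B"), rbind(c("A", "Z"))),
               "Z")
  expect_error(area_graph(c("A", "A"), NULL), "duplicate")
  expect_error(area_graph(c("A", "B"), rbind(c(1, 1))), "self-loop")
})

test_that("queen contiguity from GeoJSON counts edge and corner touches", {
  two <- list(type = "FeatureCollection",
              features = list(square_feature("L", 0, 0),
                              square_feature("R", 1, 0)))
  expect_equal(nrow(build_adjacency_from_geojson(two)$edges), 1)

  block <- grid_geojson(2, 2)
  gq <- build_adjacency_from_geojson(block, rule = "queen")
  expect_equal(nrow(gq$edges), 6)  # 4 sides + 2 corner diagonals
  gr <- build_adjacency_from_geojson(block, rule = "rook")
  expect_equal(nrow(gr$edges), 4)

  apart <- grid_geojson(1, 2, gap = 0.5)
  ga <- build_adjacency_from_geojson(apart)
  expect_equal(nrow(ga$edges), 0)
  expect_equal(max(ga$component_labels), 2)
})

test_that("GeoJSON grids match the closed-form queen/rook edge counts", {
  for (dims in list(c(2, 3), c(3, 4), c(4, 2))) {
    r <- dims[1]; c <- dims[2]
    fc <- grid_geojson(r, c)
    rook_edges <- r * (c - 1) + c * (r - 1)
    diag_edges <- 2 * (r - 1) * (c - 1)
    expect_equal(nrow(build_adjacency_from_geojson(fc, "rook")$edges),
                 rook_edges)
    expect_equal(nrow(build_adjacency_from_geojson(fc, "queen")$edges),
                 rook_edges + diag_edges)
  }
})

test_that("graph construction is invariant to feature order up to relabeling", {
  fc <- grid_geojson(2, 3)
  set.seed(4)
  perm <- sample(6)
  fc2 <- list(type = "FeatureCollection", features = fc$features[perm])
  g1 <- build_adjacency_from_geojson(fc)
  g2 <- build_adjacency_from_geojson(fc2)
  key <- function(g) {
    e <- graph_edges(g)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_equal(key(g1), key(g2))
})

test_that("GeoJSON input validation names the offending feature", {
  dup <- list(type = "FeatureCollection",
              features = list(square_feature("A", 0, 0),
                              square_feature("A", 2, 0)))
  expect_error(build_adjacency_from_geojson(dup), "A")
  expect_error(build_adjacency_from_geojson(
    list(type = "FeatureCollection", features = list())), "empty")
  bad <- list(type = "FeatureCollection",
              features = list(list(type = "Feature",
                                   properties = list(id = "X"),
                                   geometry = list(type = "Point",
                                                   coordinates = list(0, 0)))))
  expect_error(build_adjacency_from_geojson(bad), "X")
})

test_that("ICAR structure matrix is D - W with zero row sums and the right rank", {
  p2 <- build_adjacency_from_edgelist(c("A", "B"), rbind(c("A", "B")))
  expect_equal(unname(icar_structure(p2)),
               matrix(c(1, -1, -1, 1), 2))

  g <- default_study_graph()
  Q <- icar_structure(g)
  expect_equal(Q, t(Q))
  expect_equal(unname(rowSums(Q)), rep(0, g$m))
  expect_equal(qr(Q)$rank, g$m - max(g$component_labels))
})

test_that("the ICAR quadratic form equals the pairwise-difference sum", {
  # 3-node path, u = (0, 1, 3): (0-1)^2 + (1-3)^2 = 5
  p3 <- build_adjacency_from_edgelist(c("A", "B", "C"),
                                      rbind(c("A", "B"), c("B", "C")))
  u <- c(0, 1, 3)
  expect_equal(drop(t(u) %*% icar_structure(p3) %*% u), 5)

  set.seed(7)
  for (rep in 1:20) {
    m <- sample(3:12, 1)
    npairs <- sample.int(m * (m - 1) / 2, 1)
    all_pairs <- t(combn(m, 2))
    e <- all_pairs[sample.int(nrow(all_pairs), npairs), , drop = FALSE]
    g <- area_graph(paste0("a", seq_len(m)), e)
    Q <- icar_structure(g)
    for (k in 1:5) {
      u <- rnorm(m)
      expect_equal(drop(t(u) %*% Q %*% u),
                   sum((u[g$edges[, 1]] - u[g$edges[, 2]])^2),
                   tolerance = 1e-12)
    }
  }
})

test_that("edge-list CSV round-trips through write and read", {
  g <- make_grid_graph(2, 3, "rook")
  f <- tempfile(fileext = ".csv")
  write_adjacency_csv(g, f)
  g2 <- read_adjacency_csv(f, area_ids = g$area_ids)
  expect_equal(g2$edges, g$edges)
})
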