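#' Areal contiguity graph
#'
#' An `area_graph` records which areas of a study region are neighbours.
#' It is the structure behind the intrinsic conditional autoregressive
#' (ICAR) prior of the convolution model: two areas are neighbours when
#' their boundaries share at least one geographic point (queen rule) or a
#' boundary stretch of positive length (rook rule).
#'
#' @param area_ids character vector of unique area labels, in input order.
#' @param edges two-column integer matrix of area indices, one row per
#'   undirected edge. Duplicate rows and reversed duplicates are collapsed;
#'   self-loops are an error.
#'
#' @return An object of class `area_graph` with components `area_ids`,
#'   `edges` (ordered so that `edges[, 1] < edges[, 2]`), `degrees`,
#'   `component_labels` (integers `1..n_components` in order of first
#'   appearance) and `m` (number of areas).
#' @examples
#' g <- area_graph(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
#' g$degrees
#' @export
area_graph <- function(area_ids, edges) {
  area_ids <- as.character(area_ids)
  m <- length(area_ids)
  if (m < 1) stop("an area_graph needs at least one area")
  if (anyDuplicated(area_ids)) {
    stop("duplicate area id: ", area_ids[duplicated(area_ids)][1])
  }
  edges <- if (is.null(edges) || length(edges) == 0) {
    matrix(integer(0), ncol = 2)
  } else {
    matrix(as.integer(edges), ncol = 2)
  }
  if (nrow(edges)) {
    if (any(edges < 1 | edges > m)) stop("edge index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  degrees <- tabulate(c(edges[, 1], edges[, 2]), nbins = m)
  structure(
    list(area_ids = area_ids, edges = edges, degrees = degrees,
         component_labels = connected_components(m, edges), m = m),
    class = "area_graph")
}

# Label connected components 1..k in order of first appearance (BFS).
connected_components <- function(m, edges) {
  nbs <- neighbour_list(m, edges)
  labels <- integer(m)
  comp <- 0L
  for (s in seq_len(m)) {
    if (labels[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      new <- nbs[[i]][labels[nbs[[i]]] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
  }
  labels
}

neighbour_list <- function(m, edges) {
  nbs <- vector("list", m)
  for (i in seq_len(m)) nbs[[i]] <- integer(0)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      nbs[[i]] <- c(nbs[[i]], j)
      nbs[[j]] <- c(nbs[[j]], i)
    }
  }
  lapply(nbs, sort)
}

#' @export
print.area_graph <- function(x, ...) {
  ncomp <- max(x$component_labels)
  cat("area_graph: ", x$m, " areas, ", nrow(x$edges), " edges, ",
      ncomp, if (ncomp == 1) " component" else " components", "\n", sep = "")
  iso <- sum(x$degrees == 0)
  if (iso) cat("  isolated areas (no neighbour): ",
               paste(x$area_ids[x$degrees == 0], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of areas in a graph
#' @param graph an [area_graph()].
#' @return integer count of areas.
#' @export
n_areas <- function(graph) graph$m

#' Edge list of a contiguity graph
#' @param graph an [area_graph()].
#' @return a data.frame with character columns `from` and `to`, one row per
#'   undirected edge.
#' @export
graph_edges <- function(graph) {
  data.frame(from = graph$area_ids[graph$edges[, 1]],
             to = graph$area_ids[graph$edges[, 2]],
             stringsAsFactors = FALSE)
}

#' Build a contiguity graph from an explicit edge list
#'
#' Alternate input path for studies where boundary polygons are not
#' available. Pairs are undirected: `(A,B)` and `(B,A)` identify the same
#' edge and duplicates are collapsed.
#'
#' @param area_ids character vector of all area labels (isolated areas are
#'   kept; they simply have no pairs).
#' @param pairs a two-column matrix or data.frame of area labels, or an
#'   empty object for a graph with no edges.
#' @return an [area_graph()].
#' @examples
#' build_adjacency_from_edgelist(c("A", "B", "C"),
#'                               rbind(c("A", "B"), c("B", "C")))
#' @export
build_adjacency_from_edgelist <- function(area_ids, pairs) {
  area_ids <- as.character(area_ids)
  if (is.null(pairs) || length(pairs) == 0 ||
      (is.data.frame(pairs) && nrow(pairs) == 0)) {
    return(area_graph(area_ids, NULL))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  idx <- matrix(match(as.character(pairs), area_ids), ncol = 2)
  if (anyNA(idx)) {
    bad <- as.character(pairs)[is.na(match(as.character(pairs), area_ids))][1]
    stop("unknown area id in pair: ", bad)
  }
  area_graph(area_ids, idx)
}

#' Read an edge-list CSV (`from,to`) into a contiguity graph
#' @param path CSV file with columns `from` and `to`.
#' @param area_ids optional full set of area labels; defaults to the labels
#'   appearing in the file.
#' @return an [area_graph()].
#' @export
read_adjacency_csv <- function(path, area_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    stop("adjacency CSV needs columns 'from' and 'to'")
  }
  if (is.null(area_ids)) area_ids <- unique(c(df$from, df$to))
  build_adjacency_from_edgelist(area_ids, cbind(df$from, df$to))
}

#' Write a contiguity graph as an edge-list CSV
#' @param graph an [area_graph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(graph, path) {
  utils::write.csv(graph_edges(graph), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Contiguity graph from GeoJSON polygons
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features and
#' links two areas whenever their boundaries touch. Under the queen rule a
#' single shared point (a corner) is enough; under the rook rule the shared
#' boundary must have positive length. Coordinates are compared exactly by
#' default; `snap` sets a tolerance below which nearby points are treated
#' as touching (useful for dirty boundary exports).
#'
#' @param x path to a GeoJSON file, a JSON string, or an already-parsed
#'   FeatureCollection list.
#' @param rule `"queen"` (default) or `"rook"`.
#' @param snap non-negative snapping tolerance in coordinate units.
#' @param id_property name of the feature property holding the unique area
#'   id (a top-level feature `id` member is used as fallback).
#' @return an [area_graph()] whose `area_ids` follow feature order.
#' @export
build_adjacency_from_geojson <- function(x, rule = c("queen", "rook"),
                                         snap = 0, id_property = "id") {
  rule <- match.arg(rule)
  gj <- parse_geojson(x)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0) {
    stop("empty feature collection")
  }
  ids <- vapply(seq_along(feats), function(k) {
    f <- feats[[k]]
    id <- f$properties[[id_property]] %||% f$id
    if (is.null(id)) stop("feature ", k, " has no '", id_property, "' property")
    as.character(id)
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate feature id: ", ids[duplicated(ids)][1])
  }
  segs <- lapply(seq_along(feats), function(k) {
    geometry_segments(feats[[k]]$geometry, ids[k])
  })
  boxes <- t(vapply(segs, function(s) {
    c(min(s[, 1], s[, 3]), max(s[, 1], s[, 3]),
      min(s[, 2], s[, 4]), max(s[, 2], s[, 4]))
  }, numeric(4)))
  m <- length(ids)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (boxes[i, 1] > boxes[j, 2] + snap || boxes[j, 1] > boxes[i, 2] + snap ||
          boxes[i, 3] > boxes[j, 4] + snap || boxes[j, 3] > boxes[i, 4] + snap) next
      if (polygons_touch(segs[[i]], segs[[j]], rule, snap)) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  area_graph(ids, edges)
}

parse_geojson <- function(x) {
  if (is.character(x) && length(x) == 1) {
    gj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else if (is.list(x)) {
    gj <- x
  } else {
    stop("cannot interpret GeoJSON input")
  }
  if (is.null(gj$features) && identical(gj$type, "FeatureCollection")) {
    stop("FeatureCollection has no features")
  }
  gj
}

# Flatten a Polygon/MultiPolygon geometry into a matrix of boundary
# segments (x1, y1, x2, y2), covering exterior rings and holes.
geometry_segments <- function(geom, id) {
  if (is.null(geom) || is.null(geom$type)) {
    stop("feature '", id, "' has an invalid geometry")
  }
  rings <- switch(geom$type,
    Polygon = geom$coordinates,
    MultiPolygon = do.call(c, geom$coordinates),
    stop("feature '", id, "' has unsupported geometry type '", geom$type, "'"))
  if (is.null(rings) || length(rings) == 0) {
    stop("feature '", id, "' has an empty geometry")
  }
  seg_list <- lapply(rings, function(ring) {
    pts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (is.null(pts) || nrow(pts) < 3) {
      stop("feature '", id, "' has a degenerate ring")
    }
    if (any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
    n <- nrow(pts)
    cbind(pts[-n, 1], pts[-n, 2], pts[-1, 1], pts[-1, 2])
  })
  do.call(rbind, seg_list)
}

# Contact between two polygon boundaries, from pairwise segment analysis.
# queen: any shared point. rook: a collinear overlap of positive length
# (or two or more distinct touch points, which on areal boundaries implies
# a shared stretch split across segments).
polygons_touch <- function(sa, sb, rule, snap) {
  tol <- max(snap, 0)
  pts <- NULL
  for (a in seq_len(nrow(sa))) {
    p1 <- sa[a, 1:2]; p2 <- sa[a, 3:4]
    for (b in seq_len(nrow(sb))) {
      p3 <- sb[b, 1:2]; p4 <- sb[b, 3:4]
      ct <- segment_contact(p1, p2, p3, p4, tol)
      if (ct$type == "overlap") {
        if (rule == "rook" || rule == "queen") return(TRUE)
      } else if (ct$type == "point") {
        if (rule == "queen") return(TRUE)
        pts <- rbind(pts, ct$point)
        if (nrow_distinct(pts, tol) >= 2) return(TRUE)
      }
    }
  }
  FALSE
}

nrow_distinct <- function(pts, tol) {
  if (is.null(pts)) return(0L)
  eps <- max(tol, 1e-9)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      for (j in seq(i + 1, nrow(pts))) {
        if (keep[j] && max(abs(pts[i, ] - pts[j, ])) <= eps) keep[j] <- FALSE
      }
    }
  }
  sum(keep)
}

# Classify the contact of two closed segments: "none", a single "point",
# or a positive-length collinear "overlap".  tol = 0 gives the exact
# predicate on input coordinates.
segment_contact <- function(p1, p2, p3, p4, tol) {
  d1 <- p2 - p1
  d2 <- p4 - p3
  r <- p3 - p1
  cross <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- max(abs(c(d1, d2, 1)))
  eps <- max(tol, 1e-12 * scale)
  if (abs(cross) > eps * scale) {
    t <- (r[1] * d2[2] - r[2] * d2[1]) / cross
    s <- (r[1] * d1[2] - r[2] * d1[1]) / cross
    slack_t <- eps / max(sqrt(sum(d1^2)), eps)
    slack_s <- eps / max(sqrt(sum(d2^2)), eps)
    if (t >= -slack_t && t <= 1 + slack_t && s >= -slack_s && s <= 1 + slack_s) {
      return(list(type = "point", point = p1 + t * d1))
    }
    return(list(type = "none"))
  }
  # parallel: collinear iff p3 lies on the line through p1, p2
  if (abs(r[1] * d1[2] - r[2] * d1[1]) > max(eps * scale, eps)) {
    return(list(type = "none"))
  }
  len1 <- sqrt(sum(d1^2))
  if (len1 <= eps) {
    # degenerate first segment: point-vs-segment distance test
    if (point_on_segment(p1, p3, p4, eps)) {
      return(list(type = "point", point = p1))
    }
    return(list(type = "none"))
  }
  u <- d1 / len1
  a0 <- 0; a1 <- len1
  b0 <- sum((p3 - p1) * u); b1 <- sum((p4 - p1) * u)
  lo <- max(a0, min(b0, b1)); hi <- min(a1, max(b0, b1))
  if (hi - lo > eps) {
    return(list(type = "overlap"))
  }
  if (hi - lo >= -eps) {
    return(list(type = "point", point = p1 + u * (lo + hi) / 2))
  }
  list(type = "none")
}

point_on_segment <- function(p, a, b, eps) {
  d <- b - a
  L2 <- sum(d^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * d) / L2))
  sqrt(sum((a + t * d - p)^2)) <= eps
}

#' ICAR structure matrix of a contiguity graph
#'
#' Returns `Q0 = D - W`, where `D` is the diagonal matrix of neighbour
#' counts and `W` the 0/1 adjacency indicator. `Q0` is symmetric with zero
#' row sums and rank `m - c` for `c` connected components; it defines the
#' intrinsic CAR prior density `tau/2 * t(u) %*% Q0 %*% u`, equal to
#' `tau/2 * sum over edges of (u_i - u_j)^2`.
#'
#' @param graph an [area_graph()].
#' @return an `m x m` numeric matrix with `area_ids` as dimnames.
#' @export
icar_structure <- function(graph) {
  m <- graph$m
  Q <- matrix(0, m, m, dimnames = list(graph$area_ids, graph$area_ids))
  e <- graph$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1]; j <- e[r, 2]
      Q[i, j] <- Q[i, j] - 1
      Q[j, i] <- Q[j, i] - 1
    }
  }
  diag(Q) <- graph$degrees
  Q
}

#' Regular grid contiguity graph
#'
#' Test-bench lattice: `rows * cols` square cells, neighbours by side
#' (rook) or by side and corner (queen). Cell ids are `"r<i>c<j>"` in
#' row-major order.
#'
#' @param rows,cols positive integers.
#' @param rule `"queen"` or `"rook"`.
#' @return an [area_graph()].
#' @examples
#' make_grid_graph(2, 2, "queen")$edges
#' @export
make_grid_graph <- function(rows, cols, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  if (rows < 1 || cols < 1) stop("rows and cols must be positive")
  idx <- function(r, c) (r - 1L) * cols + c
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) paste0("r", r, "c", c))))
  edges <- NULL
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) edges <- rbind(edges, c(idx(r, c), idx(r, c + 1)))
      if (r < rows) edges <- rbind(edges, c(idx(r, c), idx(r + 1, c)))
      if (rule == "queen" && r < rows) {
        if (c < cols) edges <- rbind(edges, c(idx(r, c), idx(r + 1, c + 1)))
        if (c > 1) edges <- rbind(edges, c(idx(r, c), idx(r + 1, c - 1)))
      }
    }
  }
  area_graph(ids, edges)
}
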