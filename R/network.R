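# Pedestrian network: an undirected weighted graph with planar node
# coordinates. Off-network points (residential demand points, green-space
# entrances) are snapped to the nearest point on an edge; travel distance is
# then connector + shortest path through the graph + connector. Unreachable
# pairs are Inf, never a capped finite value, so that decay weights cannot
# be silently corrupted.

#' Construct a road network
#'
#' @param nodes data frame with columns `id` (unique character), `x`, `y`
#'   (metres, projected).
#' @param edges data frame with columns `from`, `to` (node ids) and
#'   optionally `length` (metres). Missing lengths are filled with the
#'   straight-line distance. Self-loops are an error; of parallel edges only
#'   the shortest is kept.
#' @return A `road_network`: node and edge tibbles plus the weighted
#'   `igraph` graph used for shortest paths. Edge ids are consecutive
#'   integers in table order.
#' @export
road_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)[, c("id", "x", "y")]
  stopifnot(!anyDuplicated(nodes$id))
  edges <- tibble::as_tibble(edges)
  if (any(edges$from == edges$to)) stop("road network contains a self-loop")
  fi <- match(edges$from, nodes$id)
  ti <- match(edges$to, nodes$id)
  if (anyNA(fi) || anyNA(ti)) stop("edge references a node id absent from the node table")
  straight <- sqrt((nodes$x[ti] - nodes$x[fi])^2 + (nodes$y[ti] - nodes$y[fi])^2)
  if (!"length" %in% names(edges)) edges$length <- straight
  if (any(edges$length <= 0)) stop("all edge lengths must be positive")
  if (any(edges$length < straight - 1e-6)) {
    stop("edge length shorter than the straight-line distance between its endpoints")
  }
  # collapse parallel edges, keeping the shorter
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) {
    edges <- edges[order(key, edges$length), ]
    edges <- edges[!duplicated(paste(pmin(edges$from, edges$to),
                                     pmax(edges$from, edges$to))), ]
  }
  edges$id <- seq_len(nrow(edges))
  edges <- edges[, c("id", "from", "to", "length")]
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  igraph::E(g)$weight <- edges$length
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, total length %.1f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length) / 1000))
  invisible(x)
}

#' Table of walking life-circle travel scopes
#'
#' The three pedestrian travel scopes used throughout the pipeline: the
#' basic (5-min), neighbourhood (15-min) and daily (30-min) life circles,
#' fixed at network distances of 500, 1000 and 2000 m. The nominal 5 km/h
#' walking speed is carried as metadata only; the distances themselves are
#' the operative thresholds.
#'
#' @return Tibble with columns `label`, `d0` (metres) and
#'   `walking_speed_kmh`.
#' @export
travel_scopes <- function() {
  tibble::tibble(
    label = c("5-min", "15-min", "30-min"),
    d0 = c(500, 1000, 2000),
    walking_speed_kmh = 5
  )
}

#' Snap points to the nearest edge of the network
#'
#' Perpendicular projection onto each edge segment, clamped to the segment;
#' the edge minimising the connector (straight-line) distance wins, with
#' ties broken by the smallest edge id.
#'
#' @param points numeric matrix (n x 2) of point coordinates, or a length-2
#'   vector for a single point.
#' @param network a [road_network()].
#' @return Tibble of network locations, one row per point: `edge_id`,
#'   `from`, `to`, `edge_length`, `offset` (metres from the edge's `from`
#'   node), `connector` (straight-line metres from the original point to the
#'   snapped point), `x`, `y` (snapped coordinates).
#' @export
snap_to_network <- function(points, network) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(network$edges) == 0) stop("cannot snap to an empty network")
  e <- network$edges
  fi <- match(e$from, network$nodes$id)
  ti <- match(e$to, network$nodes$id)
  ax <- network$nodes$x[fi]; ay <- network$nodes$y[fi]
  bx <- network$nodes$x[ti]; by <- network$nodes$y[ti]
  dx <- bx - ax; dy <- by - ay
  seg2 <- pmax(dx * dx + dy * dy, 1e-300) # guard degenerate geometry
  n <- nrow(points)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- points[i, 1]; py <- points[i, 2]
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / seg2))
    qx <- ax + t * dx; qy <- ay + t * dy
    conn2 <- (px - qx)^2 + (py - qy)^2
    k <- which.min(conn2) # first minimum = smallest edge id on ties
    out[[i]] <- c(e$id[k], t[k] * e$length[k], sqrt(conn2[k]), qx[k], qy[k])
  }
  m <- do.call(rbind, out)
  k <- match(m[, 1], e$id)
  tibble::tibble(
    edge_id = e$id[k], from = e$from[k], to = e$to[k],
    edge_length = e$length[k],
    offset = m[, 2], connector = m[, 3], x = m[, 4], y = m[, 5]
  )
}

#' Network distances between two sets of snapped locations
#'
#' Shortest-path distance through the graph between the on-edge points,
#' plus both connector lengths when `include_connectors` is TRUE. For two
#' points on the same edge the direct along-edge distance competes with
#' paths leaving through the edge ends. `Inf` marks unreachable pairs.
#'
#' @param origins,dests location tibbles from [snap_to_network()].
#' @param network a [road_network()].
#' @param include_connectors add the off-network connector distances
#'   (default TRUE); switch off to measure the pure on-network metric.
#' @return Numeric matrix, `nrow(origins)` x `nrow(dests)`, metres.
#' @export
network_distance_matrix <- function(origins, dests, network,
                                    include_connectors = TRUE) {
  g <- network$graph
  o_nodes <- unique(c(origins$from, origins$to))
  d_nodes <- unique(c(dests$from, dests$to))
  nd <- igraph::distances(g, v = o_nodes, to = d_nodes,
                          weights = igraph::E(g)$weight)
  oF <- match(origins$from, o_nodes); oT <- match(origins$to, o_nodes)
  dF <- match(dests$from, d_nodes); dT <- match(dests$to, d_nodes)
  o_a <- origins$offset; o_b <- origins$edge_length - origins$offset
  d_a <- dests$offset; d_b <- dests$edge_length - dests$offset
  res <- matrix(Inf, nrow(origins), nrow(dests))
  for (j in seq_len(nrow(dests))) {
    via <- pmin(o_a + nd[oF, dF[j]] + d_a[j],
                o_a + nd[oF, dT[j]] + d_b[j],
                o_b + nd[oT, dF[j]] + d_a[j],
                o_b + nd[oT, dT[j]] + d_b[j])
    same <- origins$edge_id == dests$edge_id[j]
    if (any(same)) {
      via[same] <- pmin(via[same], abs(origins$offset[same] - d_a[j]))
    }
    res[, j] <- via
  }
  if (include_connectors) {
    res <- res + outer(origins$connector, dests$connector, `+`)
  }
  res
}

#' Network distance between two snapped locations
#'
#' @param origin,dest single-row location tibbles from [snap_to_network()].
#' @inheritParams network_distance_matrix
#' @return Distance in metres (`Inf` when no path exists).
#' @export
network_distance <- function(origin, dest, network, include_connectors = TRUE) {
  as.numeric(network_distance_matrix(origin[1, , drop = FALSE],
                                     dest[1, , drop = FALSE],
                                     network, include_connectors))
}

#' Network distance from a demand location to a green space
#'
#' A green space is reached through its nearest entrance: the distance is
#' the minimum network distance over all snapped access points.
#'
#' @param demand single-row location tibble from [snap_to_network()].
#' @param snapped_access location tibble of the green space's entrances.
#' @inheritParams network_distance_matrix
#' @export
distance_to_greenspace <- function(demand, snapped_access, network,
                                   include_connectors = TRUE) {
  if (nrow(snapped_access) == 0) stop("green space has no access points")
  min(network_distance_matrix(demand[1, , drop = FALSE], snapped_access,
                              network, include_connectors))
}

#' Threshold catchment of an origin
#'
#' The targets whose network distance from the origin does not exceed the
#' travel threshold `d0` (boundary included), with the distances used
#' downstream by the accessibility model.
#'
#' @param origin single-row location tibble from [snap_to_network()].
#' @param d0 travel threshold in metres (> 0).
#' @param targets location tibble of candidate targets.
#' @inheritParams network_distance_matrix
#' @return Tibble with columns `target` (row index into `targets`) and
#'   `distance` (metres), rows with `distance <= d0` only.
#' @export
catchment <- function(origin, d0, targets, network, include_connectors = TRUE) {
  stopifnot(d0 > 0)
  d <- as.numeric(network_distance_matrix(origin[1, , drop = FALSE], targets,
                                          network, include_connectors))
  keep <- which(d <= d0)
  tibble::tibble(target = keep, distance = d[keep])
}
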