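# Seeded synthetic-city generator: a perturbed road lattice, a rectangular
# sub-district partition of the extent, residential rectangles with
# area-proportional populations, and green spaces in two size classes with
# tunable spatial clustering. Everything downstream of the generator is
# deterministic in the scenario seed.

#' Generate the pedestrian road network of a scenario
#'
#' Builds a rectangular lattice over the extent at `grid_spacing`, then
#' (optionally) deletes a fraction of edges at random, skipping any deletion
#' that would disconnect the graph. Edge lengths equal the planar distance
#' between endpoint coordinates.
#'
#' @param scenario a [city_scenario()].
#' @return A `road_network` object (see [road_network()]): node table
#'   (id, x, y), edge table (id, from, to, length), and the underlying
#'   weighted graph.
#' @export
generate_road_network <- function(scenario) {
  validate_scenario(scenario)
  nx <- floor(scenario$width / scenario$grid_spacing) + 1L
  ny <- floor(scenario$height / scenario$grid_spacing) + 1L
  if (nx < 2L || ny < 2L) {
    stop("degenerate scenario: extent smaller than one grid cell of the road lattice")
  }
  xs <- seq(0, by = scenario$grid_spacing, length.out = nx)
  ys <- seq(0, by = scenario$grid_spacing, length.out = ny)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  nodes <- tibble::tibble(
    id = sprintf("n%04d", seq_len(nrow(grid))),
    x = xs[grid$ix],
    y = ys[grid$iy]
  )
  node_at <- function(ix, iy) (iy - 1L) * nx + ix
  # horizontal then vertical lattice edges, row-major
  h <- expand.grid(ix = seq_len(nx - 1L), iy = seq_len(ny))
  v <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1L))
  fi <- c(node_at(h$ix, h$iy), node_at(v$ix, v$iy))
  ti <- c(node_at(h$ix + 1L, h$iy), node_at(v$ix, v$iy + 1L))
  edges <- tibble::tibble(
    from = nodes$id[fi], to = nodes$id[ti],
    length = sqrt((nodes$x[ti] - nodes$x[fi])^2 +
                    (nodes$y[ti] - nodes$y[fi])^2)
  )

  n_remove <- floor(scenario$edge_removal * nrow(edges))
  if (n_remove > 0) {
    keep <- with_local_seed(scenario$seed, {
      order_try <- sample.int(nrow(edges))
      g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                         directed = FALSE,
                                         vertices = nodes$id)
      keep <- rep(TRUE, nrow(edges))
      removed <- 0L
      for (e in order_try) {
        if (removed >= n_remove) break
        eid <- igraph::get_edge_ids(g, c(edges$from[e], edges$to[e]))
        g2 <- igraph::delete_edges(g, eid)
        if (igraph::is_connected(g2)) {
          g <- g2
          keep[e] <- FALSE
          removed <- removed + 1L
        }
      }
      keep
    })
    edges <- edges[keep, ]
  }
  edges$id <- seq_len(nrow(edges))
  road_network(nodes, edges[, c("id", "from", "to", "length")])
}

# Split total (an integer-valued target) over shares summing to 1, rounding
# by largest remainder so the parts sum to total exactly.
largest_remainder <- function(shares, total) {
  raw <- shares * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate sub-districts, residential areas and green spaces
#'
#' Sub-district rectangles partition the extent exactly; the total
#' population is split over them by a Dirichlet draw and conserved to the
#' person. Residential areas are random rectangles placed inside their
#' sub-district (demand point = rectangle centre, so containment holds by
#' construction). Green-space areas are drawn log-uniformly from the
#' scenario range; spaces at or above the 5 ha threshold get 2--4 entrances
#' sampled on their boundary, smaller ones a single entrance at the
#' centroid. With probability `clustering` a green space is confined to the
#' north-west quadrant, which concentrates supply and starves the rest of
#' the extent.
#'
#' @param scenario a [city_scenario()].
#' @param network the road network generated from the same scenario
#'   (currently only carried through for interface symmetry; placement does
#'   not depend on it).
#' @return A list with tibbles `subdistricts` (id, name, population,
#'   geometry), `residential` (id, subdistrict_id, area, cx, cy, geometry;
#'   population left NA until [disaggregate_population()]) and `greenspaces`
#'   (id, area, size_class, access, geometry). Geometry columns hold n x 2
#'   coordinate matrices (open rings); `access` holds m x 2 matrices of
#'   entrance points.
#' @export
generate_zones <- function(scenario, network) {
  validate_scenario(scenario)
  with_local_seed(scenario$seed + 1L, {
    subdistricts <- make_subdistricts(scenario)
    residential <- make_residential(scenario, subdistricts)
    greenspaces <- make_greenspaces(scenario)
    list(subdistricts = subdistricts, residential = residential,
         greenspaces = greenspaces)
  })
}

make_subdistricts <- function(scenario) {
  n <- scenario$n_subdistricts
  ncol_ <- ceiling(sqrt(n))
  base <- n %/% ncol_
  counts <- rep(base, ncol_)
  rem <- n - base * ncol_
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  colw <- scenario$width / ncol_
  rings <- vector("list", n)
  k <- 0L
  for (c_ in seq_len(ncol_)) {
    rowh <- scenario$height / counts[c_]
    for (r_ in seq_len(counts[c_])) {
      k <- k + 1L
      rings[[k]] <- .rect_ring((c_ - 1) * colw, (r_ - 1) * rowh,
                               c_ * colw, r_ * rowh)
    }
  }
  shares <- stats::rgamma(n, shape = 1)
  shares <- shares / sum(shares)
  pop <- largest_remainder(shares, scenario$total_population)
  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    name = sprintf("Subdistrict %03d", seq_len(n)),
    population = pop,
    geometry = rings
  )
}

make_residential <- function(scenario, subdistricts) {
  n_sub <- nrow(subdistricts)
  n_res <- scenario$n_residential
  areas <- vapply(subdistricts$geometry, polygon_area, numeric(1))
  # one residential area per sub-district guaranteed, the rest spread
  # proportionally to sub-district area
  extra <- n_res - n_sub
  alloc <- rep(1L, n_sub)
  if (extra > 0) {
    draw <- sample.int(n_sub, extra, replace = TRUE, prob = areas / sum(areas))
    alloc <- alloc + tabulate(draw, nbins = n_sub)
  }
  sub_idx <- rep(seq_len(n_sub), alloc)
  m <- length(sub_idx)
  rings <- vector("list", m)
  cx <- numeric(m); cy <- numeric(m)
  for (i in seq_len(m)) {
    ring <- subdistricts$geometry[[sub_idx[i]]]
    x0 <- min(ring[, 1]); x1 <- max(ring[, 1])
    y0 <- min(ring[, 2]); y1 <- max(ring[, 2])
    w <- min(stats::runif(1, 60, 300), 0.9 * (x1 - x0))
    h <- min(stats::runif(1, 60, 300), 0.9 * (y1 - y0))
    px <- stats::runif(1, x0 + w / 2, x1 - w / 2)
    py <- stats::runif(1, y0 + h / 2, y1 - h / 2)
    rings[[i]] <- .rect_ring(px - w / 2, py - h / 2, px + w / 2, py + h / 2)
    cx[i] <- px; cy[i] <- py
  }
  tibble::tibble(
    id = sprintf("R%04d", seq_len(m)),
    subdistrict_id = subdistricts$id[sub_idx],
    area = vapply(rings, polygon_area, numeric(1)),
    population = NA_real_,
    cx = cx, cy = cy,
    geometry = rings
  )
}

make_greenspaces <- function(scenario) {
  n <- scenario$n_greenspaces
  rng <- scenario$greenspace_area_range
  area <- exp(stats::runif(n, log(rng[1]), log(rng[2])))
  in_cluster <- stats::runif(n) < scenario$clustering
  w <- scenario$width; h <- scenario$height
  # clustered spaces go to the north-west quadrant
  px <- ifelse(in_cluster, stats::runif(n, 0, w / 2), stats::runif(n, 0, w))
  py <- ifelse(in_cluster, stats::runif(n, h / 2, h), stats::runif(n, 0, h))
  aspect <- stats::runif(n, 0.6, 1.6)
  gw <- pmin(sqrt(area * aspect), 0.95 * w)
  gh <- pmin(area / gw, 0.95 * h)
  # keep the rectangle inside the extent by shifting its centre
  px <- pmin(pmax(px, gw / 2), w - gw / 2)
  py <- pmin(pmax(py, gh / 2), h - gh / 2)
  rings <- vector("list", n)
  access <- vector("list", n)
  size_class <- ifelse(gw * gh >= scenario$large_space_threshold,
                       "large", "small")
  for (i in seq_len(n)) {
    ring <- .rect_ring(px[i] - gw[i] / 2, py[i] - gh[i] / 2,
                       px[i] + gw[i] / 2, py[i] + gh[i] / 2)
    rings[[i]] <- ring
    if (size_class[i] == "large") {
      m <- sample(2:4, 1)
      access[[i]] <- boundary_points(ring, stats::runif(m))
    } else {
      access[[i]] <- matrix(polygon_centroid(ring), ncol = 2)
    }
  }
  tibble::tibble(
    id = sprintf("G%03d", seq_len(n)),
    area = vapply(rings, polygon_area, numeric(1)),
    size_class = size_class,
    access = access,
    geometry = rings
  )
}

# Points on a ring's boundary at the given fractions of its perimeter.
boundary_points <- function(ring, fractions) {
  n <- nrow(ring)
  nxt <- c(2:n, 1L)
  seg_len <- sqrt(rowSums((ring[nxt, , drop = FALSE] - ring)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[n + 1L]
  out <- matrix(0, length(fractions), 2)
  for (k in seq_along(fractions)) {
    d <- fractions[k] * total
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    t <- (d - cum[i]) / seg_len[i]
    out[k, ] <- ring[i, ] + t * (ring[nxt[i], ] - ring[i, ])
  }
  out
}

#' Generate a complete synthetic city
#'
#' Road network, zones and disaggregated residential populations in one
#' call; the standard input to the accessibility pipeline.
#'
#' @param scenario a [city_scenario()].
#' @return A `city_layers` object: list with `scenario`, `network`,
#'   `subdistricts`, `residential` (populations filled by Eq-1 areal
#'   weighting) and `greenspaces`.
#' @examples
#' city <- generate_city(city_scenario(seed = 7, width = 2000, height = 2000,
#'                                     grid_spacing = 250, n_subdistricts = 4,
#'                                     n_residential = 30, n_greenspaces = 6,
#'                                     greenspace_area_range = c(2e3, 1e5),
#'                                     total_population = 2e4))
#' @export
generate_city <- function(scenario) {
  network <- generate_road_network(scenario)
  zones <- generate_zones(scenario, network)
  residential <- disaggregate_population(zones$subdistricts, zones$residential)
  structure(
    list(scenario = scenario, network = network,
         subdistricts = zones$subdistricts,
         residential = residential,
         greenspaces = zones$greenspaces),
    class = "city_layers"
  )
}

#' @export
print.city_layers <- function(x, ...) {
  cat("<city_layers>\n")
  cat(sprintf("  %d nodes / %d edges in road network\n",
              nrow(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  %d sub-districts, %d residential areas, %d green spaces\n",
              nrow(x$subdistricts), nrow(x$residential), nrow(x$greenspaces)))
  cat(sprintf("  total population %g, total green area %.1f ha\n",
              sum(x$subdistricts$population), sum(x$greenspaces$area) / 1e4))
  invisible(x)
}
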