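# Layer input/output. All layers are GeoJSON FeatureCollections in a
# projected planar CRS with metre units (the pipeline never reprojects);
# sub-district census populations travel as CSV. Green-space entrances are
# stored in the green-space features' properties so each layer stays a
# single FeatureCollection.

.ring_to_coords <- function(ring) {
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

.coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  # drop the closing vertex
  if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) {
    m <- m[-nrow(m), , drop = FALSE]
  }
  m
}

.feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

.fc <- function(features) list(type = "FeatureCollection", features = features)

.write_geojson <- function(fc, path) {
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' Write the layers of a synthetic or loaded city to disk
#'
#' Emits the four GeoJSON layers (`subdistricts`, `residential`,
#' `greenspaces`, `roads`), the sub-district population CSV
#' (`subdistrict_population.csv`: id, name, population) and, when the city
#' carries a scenario, a flat `scenario.cfg` key=value manifest.
#'
#' @param city a `city_layers` object (from [generate_city()] or
#'   [load_layers()]).
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_city_layers <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subdistricts = file.path(dir, "subdistricts.geojson"),
    residential = file.path(dir, "residential.geojson"),
    greenspaces = file.path(dir, "greenspaces.geojson"),
    roads = file.path(dir, "roads.geojson"),
    population = file.path(dir, "subdistrict_population.csv")
  )

  sd_feats <- lapply(seq_len(nrow(city$subdistricts)), function(i) {
    s <- city$subdistricts[i, ]
    .feature(list(type = "Polygon",
                  coordinates = list(.ring_to_coords(s$geometry[[1]]))),
             list(id = s$id, name = s$name, population = s$population))
  })
  .write_geojson(.fc(sd_feats), paths[["subdistricts"]])

  res_feats <- lapply(seq_len(nrow(city$residential)), function(i) {
    r <- city$residential[i, ]
    .feature(list(type = "Polygon",
                  coordinates = list(.ring_to_coords(r$geometry[[1]]))),
             list(id = r$id, subdistrict_id = r$subdistrict_id,
                  population = r$population))
  })
  .write_geojson(.fc(res_feats), paths[["residential"]])

  gs_feats <- lapply(seq_len(nrow(city$greenspaces)), function(i) {
    g <- city$greenspaces[i, ]
    acc <- g$access[[1]]
    .feature(list(type = "Polygon",
                  coordinates = list(.ring_to_coords(g$geometry[[1]]))),
             list(id = g$id, size_class = g$size_class,
                  access = lapply(seq_len(nrow(acc)),
                                  function(k) c(acc[k, 1], acc[k, 2]))))
  })
  .write_geojson(.fc(gs_feats), paths[["greenspaces"]])

  nodes <- city$network$nodes
  e <- city$network$edges
  fi <- match(e$from, nodes$id); ti <- match(e$to, nodes$id)
  road_feats <- lapply(seq_len(nrow(e)), function(i) {
    .feature(list(type = "LineString",
                  coordinates = list(c(nodes$x[fi[i]], nodes$y[fi[i]]),
                                     c(nodes$x[ti[i]], nodes$y[ti[i]]))),
             list(id = e$id[i], from = e$from[i], to = e$to[i],
                  length_m = e$length[i]))
  })
  .write_geojson(.fc(road_feats), paths[["roads"]])

  utils::write.csv(
    data.frame(id = city$subdistricts$id, name = city$subdistricts$name,
               population = city$subdistricts$population),
    paths[["population"]], row.names = FALSE)

  if (!is.null(city$scenario)) {
    write_scenario_config(city$scenario, file.path(dir, "scenario.cfg"))
    paths <- c(paths, scenario = file.path(dir, "scenario.cfg"))
  }
  invisible(paths)
}

write_scenario_config <- function(scenario, path) {
  vals <- unclass(scenario)
  lines <- vapply(names(vals), function(k) {
    paste0(k, "=", paste(format(vals[[k]], scientific = FALSE, trim = TRUE),
                         collapse = ","))
  }, character(1))
  writeLines(lines, path)
}

read_scenario_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(p[2], ",")[[1]])),
    vapply(kv, `[`, character(1), 1))
  do.call(city_scenario, vals)
}

.check_projected <- function(coords, layer) {
  if (nrow(coords) > 0 &&
      all(abs(coords[, 1]) <= 180) && all(abs(coords[, 2]) <= 90)) {
    stop(sprintf(
      "layer '%s' looks like geographic (degree) coordinates; a projected CRS in metres is required",
      layer))
  }
}

.check_rings <- function(rings, ids, layer) {
  for (i in seq_along(rings)) {
    if (nrow(rings[[i]]) < 3) {
      stop(sprintf("invalid geometry in layer '%s': feature '%s' has fewer than 3 vertices",
                   layer, ids[i]))
    }
    if (polygon_self_intersects(rings[[i]])) {
      stop(sprintf("invalid geometry in layer '%s': feature '%s' is self-intersecting",
                   layer, ids[i]))
    }
  }
}

.read_fc <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop(sprintf("'%s' is not a GeoJSON FeatureCollection", path))
  }
  fc$features
}

.prop <- function(f, name, default = NA) {
  v <- f$properties[[name]]
  if (is.null(v)) default else v
}

#' Load, validate and assemble the pipeline's spatial layers
#'
#' Reads the four GeoJSON layers and the sub-district population CSV
#' written by [write_city_layers()] (or prepared externally in the same
#' schema), validates geometry (no self-intersections, >= 3 vertices),
#' checks that coordinates are projected metres rather than degrees,
#' enforces referential integrity between residential areas and
#' sub-districts, and recomputes derived fields (areas, centroids/demand
#' points, green-space size classes).
#'
#' @param dir directory containing the layer files, or a named character
#'   vector of paths with elements `subdistricts`, `residential`,
#'   `greenspaces`, `roads`, `population`.
#' @param large_space_threshold m^2 boundary between the small and large
#'   green-space classes (used only when re-deriving a missing
#'   `size_class`).
#' @return A `city_layers` object; `scenario` is attached when a
#'   `scenario.cfg` manifest sits next to the layers.
#' @export
load_layers <- function(dir, large_space_threshold = 5e4) {
  if (length(dir) == 1 && is.null(names(dir))) {
    paths <- c(subdistricts = file.path(dir, "subdistricts.geojson"),
               residential = file.path(dir, "residential.geojson"),
               greenspaces = file.path(dir, "greenspaces.geojson"),
               roads = file.path(dir, "roads.geojson"),
               population = file.path(dir, "subdistrict_population.csv"))
    cfg <- file.path(dir, "scenario.cfg")
  } else {
    paths <- dir
    cfg <- ""
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing layer file(s): ", paste(missing, collapse = ", "))
  }

  sd_f <- .read_fc(paths[["subdistricts"]])
  sd_rings <- lapply(sd_f, function(f) .coords_to_ring(f$geometry$coordinates[[1]]))
  subdistricts <- tibble::tibble(
    id = vapply(sd_f, .prop, character(1), "id", NA_character_),
    name = vapply(sd_f, .prop, character(1), "name", NA_character_),
    population = vapply(sd_f, function(f) {
      v <- .prop(f, "population"); if (is.na(v[1])) NA_real_ else as.numeric(v)
    }, numeric(1)),
    geometry = sd_rings
  )

  pop_csv <- utils::read.csv(paths[["population"]], stringsAsFactors = FALSE)
  m <- match(subdistricts$id, pop_csv$id)
  subdistricts$population[!is.na(m)] <- pop_csv$population[m[!is.na(m)]]
  if (anyNA(subdistricts$population)) {
    stop("sub-district(s) without census population: ",
         paste(subdistricts$id[is.na(subdistricts$population)], collapse = ", "))
  }
  if (any(subdistricts$population < 0)) stop("negative sub-district population")

  res_f <- .read_fc(paths[["residential"]])
  res_rings <- lapply(res_f, function(f) .coords_to_ring(f$geometry$coordinates[[1]]))
  centroids <- t(vapply(res_rings, representative_point, numeric(2)))
  residential <- tibble::tibble(
    id = vapply(res_f, .prop, character(1), "id", NA_character_),
    subdistrict_id = vapply(res_f, .prop, character(1), "subdistrict_id",
                            NA_character_),
    area = vapply(res_rings, polygon_area, numeric(1)),
    population = vapply(res_f, function(f) {
      v <- .prop(f, "population"); if (is.na(v[1])) NA_real_ else as.numeric(v)
    }, numeric(1)),
    cx = centroids[, 1], cy = centroids[, 2],
    geometry = res_rings
  )
  unknown <- setdiff(residential$subdistrict_id, subdistricts$id)
  if (length(unknown)) {
    bad <- residential$id[residential$subdistrict_id %in% unknown]
    stop("residential area(s) ", paste(bad, collapse = ", "),
         " reference unknown sub-district(s): ", paste(unknown, collapse = ", "))
  }

  gs_f <- .read_fc(paths[["greenspaces"]])
  gs_rings <- lapply(gs_f, function(f) .coords_to_ring(f$geometry$coordinates[[1]]))
  gs_area <- vapply(gs_rings, polygon_area, numeric(1))
  access <- lapply(seq_along(gs_f), function(i) {
    a <- gs_f[[i]]$properties$access
    if (is.null(a) || length(a) == 0) {
      matrix(polygon_centroid(gs_rings[[i]]), ncol = 2)
    } else {
      do.call(rbind, lapply(a, function(p) c(p[[1]], p[[2]])))
    }
  })
  size_class <- vapply(seq_along(gs_f), function(i) {
    sc <- .prop(gs_f[[i]], "size_class", NA_character_)
    if (is.na(sc)) {
      if (gs_area[i] >= large_space_threshold) "large" else "small"
    } else sc
  }, character(1))
  greenspaces <- tibble::tibble(
    id = vapply(gs_f, .prop, character(1), "id", NA_character_),
    area = gs_area, size_class = size_class,
    access = access, geometry = gs_rings
  )

  road_f <- .read_fc(paths[["roads"]])
  seg <- lapply(road_f, function(f) {
    cc <- f$geometry$coordinates
    do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  })
  endpoints <- do.call(rbind, lapply(seg, function(s) s[c(1, nrow(s)), ]))
  key <- paste(sprintf("%.6f", endpoints[, 1]), sprintf("%.6f", endpoints[, 2]))
  uniq <- !duplicated(key)
  nodes <- tibble::tibble(
    id = paste0("v", seq_len(sum(uniq))),
    x = endpoints[uniq, 1], y = endpoints[uniq, 2]
  )
  node_of <- stats::setNames(nodes$id, key[uniq])
  seg_len <- vapply(seg, function(s) {
    sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
  }, numeric(1))
  given_len <- vapply(road_f, function(f) {
    v <- .prop(f, "length_m"); if (is.na(v[1])) NA_real_ else as.numeric(v)
  }, numeric(1))
  edges <- tibble::tibble(
    from = node_of[key[seq(1, length(key), by = 2)]],
    to = node_of[key[seq(2, length(key), by = 2)]],
    length = ifelse(is.na(given_len), seg_len, given_len)
  )
  network <- road_network(nodes, edges)

  all_coords <- rbind(do.call(rbind, sd_rings), do.call(rbind, res_rings),
                      do.call(rbind, gs_rings), as.matrix(nodes[, c("x", "y")]))
  .check_projected(all_coords, "all layers")
  .check_rings(sd_rings, subdistricts$id, "subdistricts")
  .check_rings(res_rings, residential$id, "residential")
  .check_rings(gs_rings, greenspaces$id, "greenspaces")
  if (any(residential$area <= 0)) {
    stop("residential area(s) with nonpositive polygon area: ",
         paste(residential$id[residential$area <= 0], collapse = ", "))
  }
  if (any(gs_area <= 0)) {
    stop("green space(s) with nonpositive polygon area: ",
         paste(greenspaces$id[gs_area <= 0], collapse = ", "))
  }

  scenario <- if (nzchar(cfg) && file.exists(cfg)) read_scenario_config(cfg)
  structure(
    list(scenario = scenario, network = network, subdistricts = subdistricts,
         residential = residential, greenspaces = greenspaces),
    class = "city_layers"
  )
}

#' Disaggregate sub-district census populations to residential areas
#'
#' Areal-weighting (dasymetric) disaggregation under a uniform-density
#' assumption: within each sub-district the population of residential area
#' k is `D_k = RA_k / RA * SP`, where `RA_k` is the polygon area of unit k,
#' `RA` the summed residential area of the sub-district and `SP` its census
#' population. Populations are kept as real numbers; the split is exactly
#' conservative within each sub-district.
#'
#' @param subdistricts tibble with `id`, `population`, as in
#'   [load_layers()].
#' @param residential tibble with `id`, `subdistrict_id`, `area`.
#' @return `residential` with `population` filled. Sub-districts holding
#'   population but no residential area trigger an orphan-population
#'   warning; the undistributed total is attached as attribute
#'   `unassigned_population`.
#' @export
disaggregate_population <- function(subdistricts, residential) {
  if (any(residential$area <= 0)) stop("residential areas must be positive")
  ra_tot <- tapply(residential$area, residential$subdistrict_id, sum)
  idx <- match(residential$subdistrict_id, subdistricts$id)
  if (anyNA(idx)) stop("residential area references an unknown sub-district")
  sp <- subdistricts$population[idx]
  ra <- as.numeric(ra_tot[residential$subdistrict_id])
  residential$population <- residential$area / ra * sp

  orphan <- !(subdistricts$id %in% residential$subdistrict_id) &
    subdistricts$population > 0
  unassigned <- sum(subdistricts$population[orphan])
  if (unassigned > 0) {
    warning(sprintf(
      "sub-district(s) %s hold %g persons but contain no residential area; population left unassigned",
      paste(subdistricts$id[orphan], collapse = ", "), unassigned))
  }
  attr(residential, "unassigned_population") <- unassigned
  residential
}

#' Check disaggregated populations against surveyed household counts
#'
#' For a sample of residential areas with surveyed household counts, the
#' expected population is `households * persons_per_household` and the
#' per-unit accuracy is the symmetric ratio
#' `min(D_k, expected) / max(D_k, expected)` (1 = perfect agreement, 0 =
#' total disagreement). The mean of these is the average accuracy rate.
#'
#' @param residential tibble with `id` and disaggregated `population`.
#' @param household_counts data frame with columns `id` and `households`.
#' @param persons_per_household average household size (persons), default
#'   3.5.
#' @return List with `per_unit` (tibble: id, population, expected,
#'   accuracy) and `mean_accuracy`.
#' @export
validate_population_estimate <- function(residential, household_counts,
                                         persons_per_household = 3.5) {
  if (is.null(household_counts) || nrow(household_counts) == 0) {
    stop("household_counts is empty")
  }
  idx <- match(household_counts$id, residential$id)
  if (anyNA(idx)) {
    stop("household sample id(s) not in the residential layer: ",
         paste(household_counts$id[is.na(idx)], collapse = ", "))
  }
  d <- residential$population[idx]
  expected <- household_counts$households * persons_per_household
  if (any(household_counts$households == 0)) {
    warning("household sample contains unit(s) with zero households; their accuracy is 0")
  }
  hi <- pmax(d, expected)
  lo <- pmin(d, expected)
  accuracy <- ifelse(hi == 0, 1, lo / hi)
  list(
    per_unit = tibble::tibble(id = household_counts$id, population = d,
                              expected = expected, accuracy = accuracy),
    mean_accuracy = mean(accuracy)
  )
}
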