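#' Define a synthetic city scenario
#'
#' A scenario bundles every knob of the synthetic-city generator: the planar
#' extent, the road-lattice spacing, the number of census sub-districts,
#' residential areas and green spaces, the green-space size distribution and
#' the large-space threshold (5 ha) above which a green space carries several
#' entrances, the spatial clustering of green supply, and the total
#' population to spread over the sub-districts. The defaults emulate a
#' mid-sized, strongly centre-clustered study region: about 2000 residential
#' areas in 39 sub-districts served by 85 green spaces, half of them under
#' 5 ha.
#'
#' @param seed integer seed; the only source of randomness downstream.
#' @param width,height extent of the study region in metres.
#' @param grid_spacing spacing of the pedestrian road lattice in metres.
#' @param n_subdistricts number of census sub-districts (>= 1).
#' @param n_residential number of residential areas (>= n_subdistricts).
#' @param n_greenspaces number of green spaces (>= 1).
#' @param greenspace_area_range length-2 numeric, min and max green-space
#'   polygon area in m^2; areas are drawn log-uniformly so that small
#'   neighbourhood greens and large parks coexist.
#' @param large_space_threshold area (m^2) at or above which a green space is
#'   classed "large" and receives 2--4 boundary entrances; smaller spaces are
#'   entered at their centroid. Default 50,000 m^2 = 5 ha.
#' @param clustering fraction in `[0, 1]`: probability that a green space is
#'   placed in the north-west quadrant rather than uniformly over the whole
#'   extent. 0 gives spatially uniform supply; values near 1 reproduce the
#'   strongly unequal regime in which many residential areas have no green
#'   space within walking reach.
#' @param total_population persons, split over sub-districts by a Dirichlet
#'   draw and conserved exactly.
#' @param edge_removal fraction of lattice edges to delete at random while
#'   keeping the network connected; perturbs the regular grid towards a more
#'   street-like, partly redundant mesh.
#' @return An object of class `city_scenario` (a validated list).
#' @examples
#' sc <- city_scenario(seed = 1, width = 2000, height = 2000,
#'                     grid_spacing = 500, n_subdistricts = 4,
#'                     n_residential = 20, n_greenspaces = 5)
#' @export
city_scenario <- function(seed = 1L,
                          width = 12000, height = 10000,
                          grid_spacing = 250,
                          n_subdistricts = 39L,
                          n_residential = 2020L,
                          n_greenspaces = 85L,
                          greenspace_area_range = c(5e3, 5e5),
                          large_space_threshold = 5e4,
                          clustering = 0.7,
                          total_population = 3e6,
                          edge_removal = 0.1) {
  sc <- list(
    seed = as.integer(seed),
    width = as.numeric(width), height = as.numeric(height),
    grid_spacing = as.numeric(grid_spacing),
    n_subdistricts = as.integer(n_subdistricts),
    n_residential = as.integer(n_residential),
    n_greenspaces = as.integer(n_greenspaces),
    greenspace_area_range = as.numeric(greenspace_area_range),
    large_space_threshold = as.numeric(large_space_threshold),
    clustering = as.numeric(clustering),
    total_population = as.numeric(total_population),
    edge_removal = as.numeric(edge_removal)
  )
  class(sc) <- "city_scenario"
  validate_scenario(sc)
  sc
}

#' @export
print.city_scenario <- function(x, ...) {
  cat("<city_scenario>\n")
  cat(sprintf("  extent: %g x %g m, road spacing %g m\n",
              x$width, x$height, x$grid_spacing))
  cat(sprintf("  %d sub-districts, %d residential areas, %d green spaces\n",
              x$n_subdistricts, x$n_residential, x$n_greenspaces))
  cat(sprintf("  green area %g-%g m^2 (large >= %g), clustering %.2f\n",
              x$greenspace_area_range[1], x$greenspace_area_range[2],
              x$large_space_threshold, x$clustering))
  cat(sprintf("  population %g, seed %d\n", x$total_population, x$seed))
  invisible(x)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "city_scenario"))
  if (!(sc$width > 0 && sc$height > 0 && sc$grid_spacing > 0)) {
    stop("scenario extent and grid spacing must be strictly positive")
  }
  if (sc$n_subdistricts < 1L || sc$n_residential < 1L || sc$n_greenspaces < 1L) {
    stop("scenario counts must all be >= 1")
  }
  if (sc$n_residential < sc$n_subdistricts) {
    stop("n_residential must be >= n_subdistricts ",
         "(every sub-district must contain at least one residential area)")
  }
  if (is.na(sc$clustering) || sc$clustering < 0 || sc$clustering > 1) {
    stop("clustering must lie in [0, 1]")
  }
  r <- sc$greenspace_area_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
    stop("greenspace_area_range must be two positive values with min <= max")
  }
  if (sc$total_population < 0) stop("total_population must be nonnegative")
  if (sc$edge_removal < 0 || sc$edge_removal >= 1) {
    stop("edge_removal must lie in [0, 1)")
  }
  invisible(sc)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
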