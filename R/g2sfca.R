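# Gaussian two-step floating catchment area (G2SFCA).
#
# Step 1 takes each green space j (area S_j, m^2), finds the residential
# demand points k within network distance d0 of its nearest entrance, and
# forms the supply-demand ratio
#     R_j = S_j / sum_k G(d_kj) D_k          (m^2 per person),
# with demand D_k decay-weighted by the bounded Gaussian kernel G. Step 2
# sums, for each demand point, the decay-weighted ratios of the green
# spaces within reach:
#     A_k = sum_j G(d_kj) R_j.
# A_k is interpretable as the effective green-space area per capita at k,
# and the scheme conserves supply in aggregate:
# sum_k D_k A_k = sum over served green spaces of S_j.

#' Bounded Gaussian distance-decay kernel
#'
#' `G(d) = (exp(-(d/d0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2))` on
#' `0 <= d <= d0`: 1 at the origin, 0 at the threshold, strictly
#' decreasing in between. Callers must filter to the catchment first —
#' distances beyond `d0` are a contract violation, not a silent zero.
#'
#' @param d distance(s), metres, in `[0, d0]`.
#' @param d0 travel threshold, metres, > 0.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' gaussian_decay(c(0, 250, 500), 500)
#' @export
gaussian_decay <- function(d, d0) {
  if (d0 <= 0) stop("d0 must be positive")
  if (any(d < 0 | d > d0)) {
    stop("gaussian_decay is defined on [0, d0]; filter by catchment before weighting")
  }
  e0 <- exp(-0.5)
  (exp(-0.5 * (d / d0)^2) - e0) / (1 - e0)
}

#' Demand-to-green-space network distance matrix
#'
#' Snaps every residential demand point and every green-space entrance to
#' the road network and returns, for each (residential, green space) pair,
#' the network distance to the nearest entrance of that green space.
#'
#' @param city a `city_layers` object.
#' @param include_connectors include the straight-line connectors between
#'   off-network points and their snapped locations (default TRUE).
#' @return Numeric matrix, residential areas x green spaces, metres (`Inf`
#'   when unreachable), with the layer ids as dimnames.
#' @export
greenspace_distance_matrix <- function(city, include_connectors = TRUE) {
  demand <- snap_to_network(as.matrix(city$residential[, c("cx", "cy")]),
                            city$network)
  acc_pts <- do.call(rbind, city$greenspaces$access)
  gs_of <- rep(seq_len(nrow(city$greenspaces)),
               vapply(city$greenspaces$access, nrow, integer(1)))
  acc_snap <- snap_to_network(acc_pts, city$network)
  d_all <- network_distance_matrix(demand, acc_snap, city$network,
                                   include_connectors)
  d <- matrix(Inf, nrow(city$residential), nrow(city$greenspaces),
              dimnames = list(city$residential$id, city$greenspaces$id))
  for (j in seq_len(nrow(city$greenspaces))) {
    cols <- which(gs_of == j)
    d[, j] <- if (length(cols) == 1) d_all[, cols]
              else do.call(pmin, as.data.frame(d_all[, cols]))
  }
  d
}

#' Step 1: green-space supply-demand ratios
#'
#' For each green space with at least one weighted demand unit within the
#' travel threshold, `R_j = S_j / sum_k G(d_kj) D_k` (m^2/person). Green
#' spaces whose catchment is empty have an undefined ratio and are excluded
#' with a notice; they contribute nothing downstream.
#'
#' @param greenspaces tibble with `id` and `area` (m^2).
#' @param residential tibble with `id` and `population`.
#' @param distances matrix residential x green spaces (metres), as from
#'   [greenspace_distance_matrix()].
#' @param d0 travel threshold, metres.
#' @param quiet suppress the empty-catchment notice.
#' @return Tibble with `greenspace_id`, `d0`, `served_demand` (the
#'   decay-weighted person sum) and `R` (m^2/person).
#' @export
step1_ratios <- function(greenspaces, residential, distances, d0,
                         quiet = FALSE) {
  w <- decay_weights(distances, d0)
  served <- as.numeric(crossprod(w, residential$population))
  empty <- served <= 0
  if (any(empty) && !quiet) {
    message(sum(empty), " green space(s) with no weighted demand within ",
            d0, " m excluded from step 1: ",
            paste(utils::head(greenspaces$id[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
  }
  tibble::tibble(
    greenspace_id = greenspaces$id[!empty],
    d0 = d0,
    served_demand = served[!empty],
    R = greenspaces$area[!empty] / served[!empty]
  )
}

# Gaussian weights with hard threshold: 0 beyond d0 (the kernel itself is 0
# at exactly d0, so the <= vs < boundary conventions coincide numerically).
decay_weights <- function(distances, d0) {
  w <- matrix(0, nrow(distances), ncol(distances),
              dimnames = dimnames(distances))
  inside <- which(distances <= d0)
  w[inside] <- gaussian_decay(distances[inside], d0)
  w
}

#' Step 2: residential accessibility scores
#'
#' `A_k = sum_j G(d_kj) R_j` over the green spaces within the threshold,
#' in m^2 of (effective) green space per person. Units with no green space
#' strictly within `d0` (or only unserved ones) are inaccessible and score
#' 0.
#'
#' @param residential tibble with `id` and `population`.
#' @param ratios step-1 output ([step1_ratios()]) for the same threshold.
#' @param distances matrix residential x green spaces (metres); columns
#'   named by green-space id.
#' @param d0 travel threshold, metres.
#' @return Tibble with `residential_id`, `d0`, `A` (m^2/person) and
#'   `accessible` (logical).
#' @export
step2_accessibility <- function(residential, ratios, distances, d0) {
  w <- decay_weights(distances, d0)
  cols <- match(ratios$greenspace_id, colnames(distances))
  a <- if (length(cols)) as.numeric(w[, cols, drop = FALSE] %*% ratios$R)
       else rep(0, nrow(residential))
  accessible <- if (length(cols)) {
    rowSums(distances[, cols, drop = FALSE] < d0) > 0
  } else {
    rep(FALSE, nrow(residential))
  }
  tibble::tibble(residential_id = residential$id, d0 = d0,
                 A = a, accessible = accessible)
}

.grade_levels <- c("Inaccessible", "Very low", "Lower", "Medium",
                   "Higher", "Very high")

#' Run the G2SFCA accessibility model over the walking life circles
#'
#' End-to-end accessibility: network distances to nearest entrances, step-1
#' ratios and step-2 scores per travel scope, five-class natural-breaks
#' grading of the accessible units (inaccessible units form their own
#' category and are kept out of the break optimisation), and the comparison
#' of each score against the study-wide per-capita green space baseline
#' `S / P`.
#'
#' @param city a `city_layers` object with disaggregated residential
#'   populations.
#' @param scopes travel-scope tibble (`label`, `d0`), default
#'   [travel_scopes()].
#' @param baseline per-capita green-space baseline in m^2/person; default
#'   computed as total green area over total census population.
#' @param include_connectors passed to [greenspace_distance_matrix()].
#' @param distances optional precomputed distance matrix (to reuse across
#'   calls).
#' @param quiet suppress step-1 notices.
#' @return An `accessibility_run`: list with `results` (one row per
#'   residential area and scope: `residential_id`, `subdistrict_id`,
#'   `scope`, `d0`, `population`, `A`, `accessible`, `grade`,
#'   `above_per_capita`), `ratios`, `breaks` (per-scope break points),
#'   `baseline`, `conservation` (per-scope residual of the supply identity)
#'   and the `scopes` table.
#' @export
compute_accessibility <- function(city, scopes = travel_scopes(),
                                  baseline = NULL,
                                  include_connectors = TRUE,
                                  distances = NULL, quiet = FALSE) {
  stopifnot(nrow(scopes) >= 1, !anyDuplicated(scopes$d0))
  if (anyNA(city$residential$population)) {
    stop("residential populations missing; run disaggregate_population() first")
  }
  if (is.null(baseline)) {
    p <- sum(city$subdistricts$population)
    if (p <= 0) stop("total population must be positive to form the per-capita baseline")
    baseline <- sum(city$greenspaces$area) / p
  }
  if (is.null(distances)) {
    distances <- greenspace_distance_matrix(city, include_connectors)
  }
  res_list <- vector("list", nrow(scopes))
  ratio_list <- vector("list", nrow(scopes))
  breaks <- list()
  conservation <- numeric(nrow(scopes))
  for (s in seq_len(nrow(scopes))) {
    d0 <- scopes$d0[s]
    ratios <- step1_ratios(city$greenspaces, city$residential, distances, d0,
                           quiet = quiet)
    acc <- step2_accessibility(city$residential, ratios, distances, d0)
    acc$scope <- scopes$label[s]
    acc$subdistrict_id <- city$residential$subdistrict_id
    acc$population <- city$residential$population

    grade <- factor(rep("Inaccessible", nrow(acc)), levels = .grade_levels)
    if (any(acc$accessible)) {
      vals <- acc$A[acc$accessible]
      k <- min(5L, length(unique(vals)))
      jb <- grade_natural_breaks(vals, k)
      grade[acc$accessible] <- .grade_levels[-1][jb$classes]
      breaks[[scopes$label[s]]] <- jb$breaks
    } else {
      breaks[[scopes$label[s]]] <- numeric(0)
    }
    acc$grade <- grade
    acc$above_per_capita <- acc$A > baseline

    supplied <- sum(city$greenspaces$area[
      colnames(distances) %in% ratios$greenspace_id])
    conservation[s] <- abs(sum(acc$population * acc$A) - supplied) /
      sum(city$greenspaces$area)

    res_list[[s]] <- acc
    ratio_list[[s]] <- ratios
  }
  results <- do.call(rbind, res_list)
  results <- results[, c("residential_id", "subdistrict_id", "scope", "d0",
                         "population", "A", "accessible", "grade",
                         "above_per_capita")]
  structure(
    list(results = results, ratios = do.call(rbind, ratio_list),
         breaks = breaks, baseline = baseline,
         conservation = stats::setNames(conservation, scopes$label),
         scopes = scopes),
    class = "accessibility_run"
  )
}

#' @export
print.accessibility_run <- function(x, ...) {
  cat("<accessibility_run>\n")
  cat(sprintf("  baseline per-capita green space: %.3f m^2/person\n",
              x$baseline))
  for (lab in x$scopes$label) {
    r <- x$results[x$results$scope == lab, ]
    cat(sprintf("  %s (%g m): %d/%d accessible (%.1f%%), mean A over accessible %.2f\n",
                lab, x$scopes$d0[x$scopes$label == lab],
                sum(r$accessible), nrow(r),
                100 * mean(r$accessible),
                if (any(r$accessible)) mean(r$A[r$accessible]) else NA))
  }
  invisible(x)
}
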