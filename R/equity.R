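# Equity and service-performance statistics over accessibility results:
# Lorenz curve and Gini coefficient of per-capita accessibility, location
# entropy (the per-capita quotient against the study-wide baseline),
# effective service area/population ratios per sub-district, and the
# grading-share summary tables.

#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (0.05 -> 0.1),
#' not the IEEE banker's rounding of [round()].
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Percentage of a count, half-up rounded
#'
#' @param count,total numerator and denominator counts (or measures).
#' @param digits decimal places of the reported percentage (default 1, as
#'   in the grading tables).
#' @return `100 * count / total` rounded half-up; 0 when `total` is 0.
#' @export
share_percent <- function(count, total, digits = 1) {
  out <- round_half_up(100 * count / total, digits)
  out[!is.finite(out)] <- 0 # zero denominator reports as 0%
  out
}

#' Counts-and-percentages table
#'
#' The tabulation core behind [grading_shares()]: category counts with
#' their half-up-rounded percentage of a common denominator.
#'
#' @param counts named numeric vector of category counts.
#' @param total denominator (default the sum of `counts`).
#' @param digits decimal places for the percentage column.
#' @return Tibble with `category`, `count`, `percent`.
#' @export
share_table <- function(counts, total = sum(counts), digits = 1) {
  tibble::tibble(
    category = names(counts),
    count = as.numeric(counts),
    percent = share_percent(as.numeric(counts), total, digits)
  )
}

#' Lorenz curve and Gini coefficient of per-capita accessibility
#'
#' Units are sorted ascending by their per-capita accessibility value; the
#' Lorenz curve plots the cumulative share `W_i` of total accessibility
#' against the cumulative unit fraction `i/n`, and the Gini coefficient is
#' the trapezoidal form `G = 1 - (1/n) * (2 * sum_{i<n} W_i + 1)`: 0 under
#' perfect equality, `(n-1)/n` when a single unit holds everything.
#'
#' @param values nonnegative per-unit values (one observation per unit,
#'   unweighted by default).
#' @param weights optional population weights; when supplied, units still
#'   enter sorted by value but the curve accumulates population fractions
#'   on the x axis and the Gini generalises accordingly.
#' @return List of class `lorenz_gini` with `gini` and `lorenz` (tibble
#'   `p`, `W`, starting at (0,0) and ending at (1,1)).
#' @examples
#' lorenz_gini(c(1, 3))$gini # 0.25
#' @export
lorenz_gini <- function(values, weights = NULL) {
  if (length(values) < 2) stop("at least two units are required")
  if (any(values < 0)) stop("negative per-capita values")
  if (all(values == 0)) stop("Gini undefined: all values are zero")
  o <- order(values)
  x <- values[o]
  if (is.null(weights)) {
    n <- length(x)
    w_cum <- cumsum(x) / sum(x)
    p <- seq_len(n) / n
    gini <- 1 - (2 * sum(w_cum[seq_len(n - 1)]) + 1) / n
  } else {
    stopifnot(length(weights) == length(values), all(weights >= 0))
    wt <- weights[o]
    p <- cumsum(wt) / sum(wt)
    w_cum <- cumsum(x * wt) / sum(x * wt)
    # trapezoid area under the weighted Lorenz curve
    auc <- sum(diff(c(0, p)) * (c(0, utils::head(w_cum, -1)) + w_cum) / 2)
    gini <- 1 - 2 * auc
  }
  structure(
    list(gini = gini,
         lorenz = tibble::tibble(p = c(0, p), W = c(0, w_cum))),
    class = "lorenz_gini"
  )
}

#' @export
print.lorenz_gini <- function(x, ...) {
  cat(sprintf("<lorenz_gini> G = %.3f over %d units\n",
              x$gini, nrow(x$lorenz) - 1L))
  invisible(x)
}

.entropy_levels <- c("Very low", "Lower", "Medium", "Higher", "Very high")

#' Location entropy (per-capita accessibility quotient)
#'
#' `AALQ = A / (S / P)`: a unit's accessibility relative to the study-wide
#' per-capita green space. Values above 1 mark units served better than the
#' regional average. Grades use the fixed bins `[0, 0.5)` very low,
#' `[0.5, 0.75)` lower, `[0.75, 1.2)` medium, `[1.2, 2)` higher and
#' `>= 2` very high.
#'
#' @param A accessibility values, m^2/person (vector).
#' @param total_supply total green-space area S, m^2.
#' @param total_population total population P, persons (> 0).
#' @param unit_id optional unit identifiers.
#' @return Tibble with `unit_id`, `AALQ`, `grade` (ordered factor) and
#'   `above_average` (`AALQ > 1`).
#' @export
location_entropy <- function(A, total_supply, total_population,
                             unit_id = NULL) {
  stopifnot(total_supply > 0, total_population > 0)
  per_capita <- total_supply / total_population
  aalq <- A / per_capita
  grade <- cut(aalq, breaks = c(0, 0.5, 0.75, 1.2, 2, Inf),
               labels = .entropy_levels, right = FALSE,
               include.lowest = TRUE)
  tibble::tibble(
    unit_id = if (is.null(unit_id)) seq_along(A) else unit_id,
    AALQ = aalq, grade = grade, above_average = aalq > 1
  )
}

#' Effective service area and population ratios per sub-district
#'
#' A residential area is covered at a scope when at least one green space
#' lies within its travel threshold. Per sub-district j,
#' `T_j` = (summed polygon area of covered residential areas in j) /
#' (polygon area of j), and `U_j` = (summed population of covered
#' residential areas in j) / (census population of j). `U_j` is reported as
#' `NA` for sub-districts without population.
#'
#' @param subdistricts sub-district tibble (with `geometry` and
#'   `population`).
#' @param residential residential tibble (with `area`, `population`,
#'   `subdistrict_id`).
#' @param results accessibility results table (from
#'   [compute_accessibility()]) carrying `accessible` per unit and scope.
#' @return Tibble with `subdistrict_id`, `scope`, `d0`, `T`, `U`.
#' @export
service_coverage <- function(subdistricts, residential, results) {
  sd_area <- vapply(subdistricts$geometry, polygon_area, numeric(1))
  out <- list()
  for (lab in unique(results$scope)) {
    r <- results[results$scope == lab, ]
    m <- match(residential$id, r$residential_id)
    covered <- r$accessible[m]
    cov_area <- tapply(residential$area * covered,
                       residential$subdistrict_id, sum)
    cov_pop <- tapply(residential$population * covered,
                      residential$subdistrict_id, sum)
    ca <- as.numeric(cov_area[subdistricts$id])
    cp <- as.numeric(cov_pop[subdistricts$id])
    ca[is.na(ca)] <- 0; cp[is.na(cp)] <- 0
    out[[lab]] <- tibble::tibble(
      subdistrict_id = subdistricts$id,
      scope = lab,
      d0 = r$d0[1],
      T = ca / sd_area,
      U = ifelse(subdistricts$population > 0,
                 cp / subdistricts$population, NA_real_)
    )
  }
  do.call(rbind, out)
}

#' Sub-district accessibility from residential results
#'
#' Aggregates residential accessibility to the sub-district level as the
#' population-weighted mean of member units, per scope. Sub-districts with
#' zero assigned population get `NA`.
#'
#' @param results accessibility results table ([compute_accessibility()]).
#' @param subdistricts sub-district tibble.
#' @return Tibble with `subdistrict_id`, `scope`, `d0`, `population`, `A`.
#' @export
subdistrict_accessibility <- function(results, subdistricts) {
  out <- list()
  for (lab in unique(results$scope)) {
    r <- results[results$scope == lab, ]
    pop <- tapply(r$population, r$subdistrict_id, sum)
    wa <- tapply(r$population * r$A, r$subdistrict_id, sum)
    p <- as.numeric(pop[subdistricts$id])
    a <- as.numeric(wa[subdistricts$id]) / p
    out[[lab]] <- tibble::tibble(
      subdistrict_id = subdistricts$id, scope = lab, d0 = r$d0[1],
      population = ifelse(is.na(p), 0, p), A = a
    )
  }
  do.call(rbind, out)
}

#' Grading-share summary tables
#'
#' For each travel scope: count and percentage (of all units, one decimal,
#' half-up) per accessibility grade; the accessible count and share; among
#' the accessible units, the count and share scoring above the per-capita
#' baseline; the location-entropy grade counts with the above-average
#' share; and the mean and standard deviation of the accessibility score
#' over accessible units.
#'
#' @param run an `accessibility_run` from [compute_accessibility()].
#' @param entropy optional precomputed [location_entropy()] table carrying
#'   a `scope` column; computed from the run when omitted.
#' @return List of class `grading_shares` with tibbles `grades` (scope,
#'   category, count, percent), `summary` (scope, accessible count/percent,
#'   above-baseline count/percent-of-accessible, mean_A, sd_A) and
#'   `entropy` (scope, category, count, percent, including
#'   `Above-average`).
#' @export
grading_shares <- function(run, entropy = NULL) {
  res <- run$results
  labs <- run$scopes$label
  grades <- list(); summary <- list(); ent_tab <- list()
  for (lab in labs) {
    r <- res[res$scope == lab, ]
    n <- nrow(r)
    counts <- table(r$grade)
    g <- share_table(stats::setNames(as.numeric(counts), names(counts)),
                     total = n)
    g$scope <- lab
    grades[[lab]] <- g[, c("scope", "category", "count", "percent")]

    n_acc <- sum(r$accessible)
    n_above <- sum(r$accessible & r$above_per_capita)
    summary[[lab]] <- tibble::tibble(
      scope = lab,
      n = n,
      accessible = n_acc,
      accessible_pct = share_percent(n_acc, n),
      above_baseline = n_above,
      above_baseline_pct = share_percent(n_above, n_acc),
      mean_A = if (n_acc) mean(r$A[r$accessible]) else NA_real_,
      sd_A = if (n_acc > 1) stats::sd(r$A[r$accessible]) else NA_real_
    )

    if (is.null(entropy)) {
      le <- location_entropy(r$A, total_supply = run$baseline, # S/P baked in
                             total_population = 1,
                             unit_id = r$residential_id)
    } else {
      le <- entropy[entropy$scope == lab, ]
    }
    ec <- table(le$grade)
    et <- share_table(stats::setNames(as.numeric(ec), names(ec)), total = n)
    et <- rbind(et, tibble::tibble(
      category = "Above-average",
      count = sum(le$above_average),
      percent = share_percent(sum(le$above_average), n)
    ))
    et$scope <- lab
    ent_tab[[lab]] <- et[, c("scope", "category", "count", "percent")]
  }
  structure(
    list(grades = do.call(rbind, grades),
         summary = do.call(rbind, summary),
         entropy = do.call(rbind, ent_tab)),
    class = "grading_shares"
  )
}

#' @export
print.grading_shares <- function(x, ...) {
  cat("<grading_shares>\n")
  print(x$summary)
  invisible(x)
}

#' Plot Lorenz curves
#'
#' Lorenz curves per travel scope against the line of perfect equality,
#' with the Gini coefficient in the legend label.
#'
#' @param curves a named list of [lorenz_gini()] objects (names = scope
#'   labels) or a single such object.
#' @return A ggplot object.
#' @export
plot_lorenz <- function(curves) {
  if (inherits(curves, "lorenz_gini")) curves <- list(Lorenz = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    lz <- curves[[nm]]$lorenz
    data.frame(scope = sprintf("%s (G = %.3f)", nm, curves[[nm]]$gini),
               p = lz$p, W = lz$W)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = p, y = W, colour = scope)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cumulative share of units",
                  y = "Cumulative share of per-capita accessibility",
                  colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
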