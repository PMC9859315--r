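test_that("Gini closed forms: equality, single holder, two-unit case", {
  expect_equal(lorenz_gini(rep(7, 10))$gini, 0, tolerance = 1e-12)
  for (n in c(2, 5, 17)) {
    v <- c(rep(0, n - 1), 42)
    expect_equal(lorenz_gini(v)$gini, (n - 1) / n, tolerance = 1e-12)
  }
  expect_equal(lorenz_gini(c(1, 3))$gini, 0.25, tolerance = 1e-12)
  expect_error(lorenz_gini(rep(0, 5)), "all values are zero")
  expect_error(lorenz_gini(3), "at least two")
  expect_error(lorenz_gini(c(-1, 2)), "negative")
})

test_that("Lorenz curves are valid and match the cumulative-sum oracle", {
  set.seed(5)
  for (trial in 1:5) {
    v <- rexp(30)
    lg <- lorenz_gini(v)
    lz <- lg$lorenz
    expect_equal(lz$p[1], 0); expect_equal(lz$W[1], 0)
    expect_equal(lz$p[nrow(lz)], 1); expect_equal(lz$W[nrow(lz)], 1)
    expect_true(all(diff(lz$W) >= -1e-12))
    expect_true(all(lz$W <= lz$p + 1e-12)) # below the diagonal
    expect_true(all(diff(diff(lz$W)) >= -1e-9)) # convex
    expect_equal(lz$W[-1], oracle_lorenz(v), tolerance = 1e-12)
    # scale invariance and the (n-1)/n bound
    expect_equal(lorenz_gini(v * 1000)$gini, lg$gini, tolerance = 1e-12)
    expect_lt(lg$gini, (length(v) - 1) / length(v) + 1e-12)
  }
})

test_that("population weights shift the Gini the right way", {
  # all accessibility held by a tiny population: weighted inequality is
  # higher than treating units as equal heads would suggest
  v <- c(0, 0, 10)
  w <- c(450, 450, 100)
  unweighted <- lorenz_gini(v)$gini
  weighted <- lorenz_gini(v, weights = w)$gini
  expect_equal(weighted, 0.9, tolerance = 1e-12) # 1 - pop share of holders
  expect_gt(weighted, unweighted)
  # equal values stay perfectly equal under any weighting
  expect_equal(lorenz_gini(rep(2, 4), weights = c(1, 5, 2, 9))$gini, 0,
               tolerance = 1e-12)
})

test_that("location entropy is the per-capita quotient with fixed bins", {
  le <- location_entropy(c(6.95, 0, 13.9, 3.4, 5.3, 8.5, 14.2),
                         total_supply = 6.95, total_population = 1)
  expect_equal(le$AALQ[1], 1)
  expect_false(le$above_average[1]) # strictly greater than 1 required
  expect_equal(le$AALQ[2], 0)
  expect_equal(as.character(le$grade[2]), "Very low")
  expect_equal(le$AALQ[3], 2)
  expect_equal(as.character(le$grade[3]), "Very high") # [2, Inf) bin
  expect_equal(as.character(le$grade[4]), "Very low")  # 0.489 -> [0, 0.5)
  expect_equal(as.character(le$grade[5]), "Medium")    # 0.763
  expect_equal(as.character(le$grade[6]), "Higher")    # 1.223
  expect_true(le$above_average[7])
  # half-open boundaries: 0.5 belongs to "Lower", 1.2 to "Higher"
  lb <- location_entropy(c(0.5, 0.75, 1.2, 2) * 6.95, 6.95, 1)
  expect_equal(as.character(lb$grade),
               c("Lower", "Medium", "Higher", "Very high"))
})

test_that("population-weighted mean AALQ equals the served supply share", {
  city <- generate_city(small_scenario(seed = 41))
  run <- compute_accessibility(city, quiet = TRUE)
  S <- sum(city$greenspaces$area)
  P <- sum(city$subdistricts$population)
  for (lab in run$scopes$label) {
    r <- run$results[run$results$scope == lab, ]
    le <- location_entropy(r$A, S, P, r$residential_id)
    served <- sum(city$greenspaces$area[
      city$greenspaces$id %in%
        run$ratios$greenspace_id[run$ratios$d0 == r$d0[1]]])
    expect_equal(sum(le$AALQ * r$population) / P, served / S,
                 tolerance = 1e-9)
    expect_lte(sum(le$AALQ * r$population) / P, 1 + 1e-12)
  }
})

test_that("service coverage ratios follow the covered-area and population sums", {
  sd <- tibble::tibble(
    id = "S1", population = 400,
    geometry = list(greenaccess:::.rect_ring(0, 0, 1000, 100))) # 100,000 m^2
  res <- tibble::tibble(
    id = c("R1", "R2"), subdistrict_id = "S1",
    area = c(10000, 30000), population = c(100, 300))
  results <- tibble::tibble(
    residential_id = c("R1", "R2"), scope = "15-min", d0 = 1000,
    accessible = c(FALSE, TRUE))
  cov <- service_coverage(sd, res, results)
  expect_equal(cov$T, 0.3)
  expect_equal(cov$U, 0.75)

  all_cov <- results; all_cov$accessible <- TRUE
  cov2 <- service_coverage(sd, res, all_cov)
  expect_equal(cov2$U, 1)
  expect_equal(cov2$T, 0.4)

  none <- results; none$accessible <- FALSE
  cov3 <- service_coverage(sd, res, none)
  expect_equal(cov3$T, 0)
  expect_equal(cov3$U, 0)

  empty_sd <- sd; empty_sd$population <- 0
  expect_true(is.na(service_coverage(empty_sd, res, results)$U))
})

test_that("coverage is monotone in the travel threshold for every sub-district", {
  city <- generate_city(small_scenario(seed = 42))
  run <- compute_accessibility(city, quiet = TRUE)
  cov <- service_coverage(city$subdistricts, city$residential, run$results)
  w <- reshape(as.data.frame(cov[, c("subdistrict_id", "scope", "U")]),
               idvar = "subdistrict_id", timevar = "scope",
               direction = "wide")
  expect_true(all(w[["U.5-min"]] <= w[["U.15-min"]] + 1e-12))
  expect_true(all(w[["U.15-min"]] <= w[["U.30-min"]] + 1e-12))
})

test_that("percentages use half-up rounding at the reported precision", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(share_percent(1, 8), 12.5)
  expect_equal(share_percent(0, 0), 0)
  tab <- share_table(c(a = 1, b = 3))
  expect_equal(tab$percent, c(25, 75))
  expect_equal(tab$count, c(1, 3))
})

test_that("grading shares table has the count/ratio schema per scope", {
  city <- generate_city(small_scenario(seed = 43))
  run <- compute_accessibility(city, quiet = TRUE)
  gs <- grading_shares(run)
  expect_named(gs$grades, c("scope", "category", "count", "percent"))
  expect_setequal(unique(gs$grades$scope), run$scopes$label)
  for (lab in run$scopes$label) {
    g <- gs$grades[gs$grades$scope == lab, ]
    expect_setequal(g$category,
                    c("Inaccessible", "Very low", "Lower", "Medium",
                      "Higher", "Very high"))
    expect_equal(sum(g$count), nrow(city$residential))
  }
  s <- gs$summary
  expect_equal(s$accessible + as.numeric(
    gs$grades$count[gs$grades$category == "Inaccessible"]),
    rep(nrow(city$residential), 3))
  expect_true(all(gs$entropy$category %in%
                    c("Very low", "Lower", "Medium", "Higher", "Very high",
                      "Above-average")))
})
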