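test_that("layers survive a write -> read round trip", {
  city <- generate_city(small_scenario(seed = 21))
  dir <- withr::local_tempdir()
  write_city_layers(city, dir)
  back <- load_layers(dir)

  expect_equal(back$subdistricts$id, city$subdistricts$id)
  expect_equal(back$subdistricts$population, as.numeric(city$subdistricts$population))
  expect_equal(back$residential$id, city$residential$id)
  expect_equal(back$residential$subdistrict_id, city$residential$subdistrict_id)
  expect_equal(back$residential$population, city$residential$population,
               tolerance = 1e-12)
  for (i in seq_len(nrow(city$residential))) {
    expect_equal(back$residential$geometry[[i]], city$residential$geometry[[i]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_equal(back$greenspaces$area, city$greenspaces$area, tolerance = 1e-9)
  for (i in seq_len(nrow(city$greenspaces))) {
    expect_equal(back$greenspaces$access[[i]], city$greenspaces$access[[i]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # the network keeps its metric structure (ids may be renumbered)
  expect_equal(nrow(back$network$nodes), nrow(city$network$nodes))
  expect_equal(sort(back$network$edges$length), sort(city$network$edges$length),
               tolerance = 1e-9)
  # scenario manifest restores the generator settings
  expect_equal(back$scenario$seed, city$scenario$seed)
  expect_equal(back$scenario$total_population, city$scenario$total_population)
})

test_that("referential and geometric validation fails loudly", {
  city <- generate_city(small_scenario(seed = 22, n_residential = 10))
  dir <- withr::local_tempdir()
  write_city_layers(city, dir)

  # unknown sub-district reference
  res <- jsonlite::fromJSON(file.path(dir, "residential.geojson"),
                            simplifyVector = FALSE)
  res$features[[1]]$properties$subdistrict_id <- "Z"
  jsonlite::write_json(res, file.path(dir, "residential.geojson"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_layers(dir), "unknown sub-district")

  # self-intersecting bow-tie polygon, named in the error
  write_city_layers(city, dir)
  gs <- jsonlite::fromJSON(file.path(dir, "greenspaces.geojson"),
                           simplifyVector = FALSE)
  gs$features[[1]]$geometry$coordinates <- list(list(
    c(1000, 1000), c(1200, 1200), c(1200, 1000), c(1000, 1200), c(1000, 1000)))
  bad_id <- gs$features[[1]]$properties$id
  jsonlite::write_json(gs, file.path(dir, "greenspaces.geojson"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(load_layers(dir), bad_id)

  expect_error(load_layers(withr::local_tempdir()), "missing layer")
})

test_that("geographic (degree) coordinates are rejected", {
  sc <- small_scenario(seed = 23, width = 100, height = 80, grid_spacing = 40,
                       n_subdistricts = 2, n_residential = 4,
                       n_greenspaces = 2, greenspace_area_range = c(50, 200))
  city <- generate_city(sc)
  dir <- withr::local_tempdir()
  write_city_layers(city, dir)
  expect_error(load_layers(dir), "degree")
})

test_that("population disaggregation follows areal weighting exactly", {
  sd <- tibble::tibble(id = "S1", population = 3500,
                       geometry = list(greenaccess:::.rect_ring(0, 0, 100, 100)))
  one <- tibble::tibble(id = "R1", subdistrict_id = "S1", area = 500)
  expect_equal(disaggregate_population(sd, one)$population, 3500)

  two <- tibble::tibble(id = c("R1", "R2"), subdistrict_id = "S1",
                        area = c(250, 250))
  expect_equal(disaggregate_population(sd, two)$population, c(1750, 1750))

  uneven <- tibble::tibble(id = c("R1", "R2"), subdistrict_id = "S1",
                           area = c(300, 700))
  d <- disaggregate_population(sd, uneven)
  expect_equal(d$population[1], 300 / 1000 * 3500) # = 1050
  expect_equal(sum(d$population), 3500, tolerance = 1e-9 * 3500)
})

test_that("disaggregation conserves population and is scale-equivariant", {
  city <- generate_city(small_scenario(seed = 24))
  per_sd <- tapply(city$residential$population,
                   city$residential$subdistrict_id, sum)
  expect_equal(as.numeric(per_sd[city$subdistricts$id]),
               as.numeric(city$subdistricts$population),
               tolerance = 1e-9)
  scaled <- city$subdistricts
  scaled$population <- scaled$population * 3
  d2 <- disaggregate_population(scaled, city$residential)
  expect_equal(d2$population, city$residential$population * 3,
               tolerance = 1e-12)
})

test_that("orphan population raises a warning and is tracked", {
  sd <- tibble::tibble(id = c("S1", "S2"), population = c(100, 40),
                       geometry = list(greenaccess:::.rect_ring(0, 0, 1, 1),
                                       greenaccess:::.rect_ring(1, 0, 2, 1)))
  res <- tibble::tibble(id = "R1", subdistrict_id = "S1", area = 10)
  expect_warning(out <- disaggregate_population(sd, res), "unassigned")
  expect_equal(attr(out, "unassigned_population"), 40)
  expect_equal(out$population, 100)
})

test_that("household validation reproduces the stated accuracy ratios", {
  res <- tibble::tibble(id = c("R1", "R2", "R3"),
                        population = c(35, 70, 10))
  perfect <- validate_population_estimate(
    res, data.frame(id = c("R1", "R2"), households = c(10, 20)))
  expect_equal(perfect$mean_accuracy, 1.0)

  half <- validate_population_estimate(
    res, data.frame(id = "R2", households = 10)) # 35 expected vs 70 estimated
  expect_equal(half$per_unit$accuracy, 0.5)
  expect_equal(half$mean_accuracy, 0.5)

  expect_warning(
    zero <- validate_population_estimate(
      res, data.frame(id = c("R1", "R3"), households = c(10, 0))),
    "zero households")
  expect_equal(zero$per_unit$accuracy[2], 0)

  expect_error(validate_population_estimate(res, data.frame()), "empty")
  expect_error(
    validate_population_estimate(res, data.frame(id = "RX", households = 2)),
    "not in the residential layer")
})
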