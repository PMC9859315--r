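# End-to-end orchestration: simulate -> accessibility -> equity. Each stage
# writes plain-text outputs (GeoJSON/CSV/PNG) plus a machine-readable
# manifest, and every source of randomness flows from the single config
# seed.

#' Pipeline configuration
#'
#' @param out_dir output directory; layers land in `out_dir/layers`,
#'   results in `out_dir/results`.
#' @param scenario a [city_scenario()] used by [run_simulate()]; when
#'   layers are supplied externally set `layers_dir` instead.
#' @param layers_dir directory of existing layers (defaults to
#'   `out_dir/layers`).
#' @param scopes travel-scope tibble, default [travel_scopes()].
#' @param baseline optional per-capita baseline override (m^2/person);
#'   default: computed from the layers as total green area / total
#'   population.
#' @param include_connectors include off-network connector distances in
#'   travel distances.
#' @param population_weighted_gini also report population-weighted Gini
#'   variants (the default report is unweighted, one observation per
#'   unit).
#' @param seed integer seed; overrides the scenario's seed so one number
#'   controls the whole run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scenario = city_scenario(),
                            layers_dir = NULL,
                            scopes = travel_scopes(),
                            baseline = NULL,
                            include_connectors = TRUE,
                            population_weighted_gini = FALSE,
                            seed = NULL) {
  stopifnot(nrow(scopes) >= 1, !anyDuplicated(scopes$d0))
  if (!is.null(baseline) && baseline <= 0) stop("baseline override must be positive")
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, scenario = scenario,
         layers_dir = if (is.null(layers_dir)) file.path(out_dir, "layers")
                      else layers_dir,
         scopes = scopes, baseline = baseline,
         include_connectors = include_connectors,
         population_weighted_gini = population_weighted_gini),
    class = "pipeline_config"
  )
}

.write_manifest <- function(config, dir, extra = character()) {
  cfg_file <- file.path(dir, "scenario.cfg")
  lines <- c(
    sprintf("package_version=%s", as.character(utils::packageVersion("greenaccess"))),
    sprintf("r_version=%s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%d", config$scenario$seed),
    sprintf("scopes=%s", paste(config$scopes$d0, collapse = ",")),
    if (file.exists(cfg_file)) {
      sprintf("config_md5=%s", unname(tools::md5sum(cfg_file)))
    },
    extra
  )
  writeLines(lines, file.path(dir, "manifest.txt"))
}

#' Stage 1: generate and write the synthetic layers
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the generated `city_layers`.
#' @export
run_simulate <- function(config) {
  validate_scenario(config$scenario)
  city <- generate_city(config$scenario)
  paths <- write_city_layers(city, config$layers_dir)
  layer_md5 <- tools::md5sum(unname(paths))
  .write_manifest(config, config$layers_dir,
                  sprintf("layer_md5_%s=%s", basename(names(layer_md5)),
                          unname(layer_md5)))
  message(sprintf("simulate: wrote %d layers to %s",
                  length(paths), config$layers_dir))
  invisible(city)
}

#' Stage 2: accessibility per travel scope
#'
#' Loads the layers, fills residential populations by areal disaggregation
#' where missing, runs the G2SFCA model for each scope and writes one
#' result CSV per scope (`accessibility_<label>.csv`), a break-point log
#' and a run log with per-grade counts and the supply-conservation
#' residual.
#'
#' @param config a [pipeline_config()].
#' @param city optional `city_layers` (skips re-reading from disk).
#' @return Invisibly, the `accessibility_run`.
#' @export
run_accessibility <- function(config, city = NULL) {
  if (is.null(city)) city <- load_layers(config$layers_dir)
  if (anyNA(city$residential$population)) {
    city$residential <- disaggregate_population(city$subdistricts,
                                                city$residential)
  }
  run <- compute_accessibility(city, scopes = config$scopes,
                               baseline = config$baseline,
                               include_connectors = config$include_connectors)
  dir <- file.path(config$out_dir, "results")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("baseline_per_capita_m2=%.6f", run$baseline))
  for (lab in run$scopes$label) {
    r <- run$results[run$results$scope == lab, ]
    utils::write.csv(
      r[, c("residential_id", "subdistrict_id", "scope", "d0", "A",
            "grade", "accessible", "above_per_capita")],
      file.path(dir, sprintf("accessibility_%s.csv", lab)),
      row.names = FALSE)
    counts <- table(r$grade)
    log_lines <- c(
      log_lines,
      sprintf("%s_n=%d", lab, nrow(r)),
      sprintf("%s_grade_%s=%d", lab, gsub(" ", "_", names(counts)),
              as.integer(counts)),
      sprintf("%s_conservation_residual=%.3e", lab,
              run$conservation[[lab]]))
  }
  brk <- run$breaks
  brk_df <- do.call(rbind, lapply(names(brk), function(nm) {
    if (!length(brk[[nm]])) return(NULL)
    data.frame(scope = nm, break_index = seq_along(brk[[nm]]) - 1L,
               value = brk[[nm]])
  }))
  if (!is.null(brk_df)) {
    utils::write.csv(brk_df, file.path(dir, "break_points.csv"),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(dir, "accessibility_log.txt"))
  message(sprintf("accessibility: %s",
                  paste(sprintf("%s residual %.1e", run$scopes$label,
                                run$conservation), collapse = "; ")))
  invisible(run)
}

read_accessibility_results <- function(config) {
  dir <- file.path(config$out_dir, "results")
  files <- file.path(dir, sprintf("accessibility_%s.csv",
                                  config$scopes$label))
  if (!all(file.exists(files))) {
    stop("accessibility outputs not found under ", dir,
         "; run run_accessibility() first")
  }
  res <- do.call(rbind, lapply(files, utils::read.csv,
                               stringsAsFactors = FALSE))
  res$grade <- factor(res$grade, levels = .grade_levels)
  log <- readLines(file.path(dir, "accessibility_log.txt"))
  baseline <- as.numeric(sub(".*=", "", log[grepl("^baseline", log)]))
  list(results = tibble::as_tibble(res), baseline = baseline,
       scopes = config$scopes)
}

#' Stage 3: equity and service-performance statistics
#'
#' Consumes the accessibility CSVs and the layers; writes, per scope and
#' for both unit levels (residential and sub-district): Gini summary and
#' Lorenz points, location-entropy tables, sub-district coverage ratios
#' (T_j, U_j), the grading-share tables, and a Lorenz plot (PNG).
#'
#' @param config a [pipeline_config()].
#' @param city optional preloaded `city_layers`.
#' @param run optional in-memory `accessibility_run` (skips re-reading the
#'   CSVs).
#' @return Invisibly, a list with `gini`, `lorenz`, `entropy`, `coverage`,
#'   `shares`.
#' @export
run_equity <- function(config, city = NULL, run = NULL) {
  if (is.null(city)) city <- load_layers(config$layers_dir)
  if (anyNA(city$residential$population)) {
    city$residential <- disaggregate_population(city$subdistricts,
                                                city$residential)
  }
  if (is.null(run)) run <- read_accessibility_results(config)
  res <- run$results
  # population needed for weighted aggregation: take it from the layers
  res$population <- city$residential$population[
    match(res$residential_id, city$residential$id)]
  run$results <- res
  dir <- file.path(config$out_dir, "results")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sub_acc <- subdistrict_accessibility(res, city$subdistricts)
  total_s <- sum(city$greenspaces$area)
  total_p <- sum(city$subdistricts$population)

  gini_rows <- list(); lorenz_pts <- list(); curves_res <- list()
  entropy_rows <- list()
  for (lab in config$scopes$label) {
    r <- res[res$scope == lab, ]
    lg_res <- lorenz_gini(r$A)
    curves_res[[lab]] <- lg_res
    gini_rows[[paste(lab, "res")]] <- tibble::tibble(
      scope = lab, unit_level = "residential", gini = lg_res$gini)
    lorenz_pts[[paste(lab, "res")]] <- tibble::tibble(
      scope = lab, unit_level = "residential",
      p = lg_res$lorenz$p, W = lg_res$lorenz$W)
    if (config$population_weighted_gini) {
      lg_w <- lorenz_gini(r$A, weights = r$population)
      gini_rows[[paste(lab, "res w")]] <- tibble::tibble(
        scope = lab, unit_level = "residential_weighted", gini = lg_w$gini)
    }
    s <- sub_acc[sub_acc$scope == lab & !is.na(sub_acc$A), ]
    if (nrow(s) >= 2 && any(s$A > 0)) {
      lg_sub <- lorenz_gini(s$A)
      gini_rows[[paste(lab, "sub")]] <- tibble::tibble(
        scope = lab, unit_level = "subdistrict", gini = lg_sub$gini)
      lorenz_pts[[paste(lab, "sub")]] <- tibble::tibble(
        scope = lab, unit_level = "subdistrict",
        p = lg_sub$lorenz$p, W = lg_sub$lorenz$W)
    }
    er <- location_entropy(r$A, total_s, total_p, r$residential_id)
    er$scope <- lab; er$unit_level <- "residential"
    es <- location_entropy(s$A, total_s, total_p, s$subdistrict_id)
    es$scope <- lab; es$unit_level <- "subdistrict"
    entropy_rows[[lab]] <- rbind(er, es)
  }
  gini <- do.call(rbind, gini_rows)
  lorenz <- do.call(rbind, lorenz_pts)
  entropy <- do.call(rbind, entropy_rows)
  coverage <- service_coverage(city$subdistricts, city$residential, res)
  shares <- grading_shares(run)

  utils::write.csv(gini, file.path(dir, "gini_summary.csv"), row.names = FALSE)
  utils::write.csv(lorenz, file.path(dir, "lorenz_points.csv"), row.names = FALSE)
  utils::write.csv(entropy, file.path(dir, "entropy.csv"), row.names = FALSE)
  utils::write.csv(coverage, file.path(dir, "coverage.csv"), row.names = FALSE)
  utils::write.csv(shares$grades, file.path(dir, "grading_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(shares$summary, file.path(dir, "grading_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(shares$entropy, file.path(dir, "entropy_shares.csv"),
                   row.names = FALSE)
  p <- plot_lorenz(curves_res)
  grDevices::png(file.path(dir, "lorenz.png"), width = 1200, height = 1000,
                 res = 150)
  print(p)
  grDevices::dev.off()

  message(sprintf("equity: Gini (residential) %s",
                  paste(sprintf("%s=%.3f", config$scopes$label,
                                vapply(config$scopes$label, function(l)
                                  gini$gini[gini$scope == l &
                                              gini$unit_level == "residential"],
                                  numeric(1))),
                        collapse = ", ")))
  invisible(list(gini = gini, lorenz = lorenz, entropy = entropy,
                 coverage = coverage, shares = shares))
}

#' Run the full pipeline: simulate, accessibility, equity
#'
#' @param config a [pipeline_config()].
#' @return List with `city`, `run` (accessibility) and `equity`.
#' @export
run_pipeline <- function(config) {
  city <- run_simulate(config)
  run <- run_accessibility(config, city = city)
  equity <- run_equity(config, city = city, run = run)
  list(city = city, run = run, equity = equity)
}
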