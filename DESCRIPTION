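Package: greenaccess
Title: Walking-Life-Circle Accessibility and Equity of Urban Green Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures pedestrian accessibility to urban green space with the
    Gaussian two-step floating catchment area (G2SFCA) model on a road
    network, at the 5/15/30-minute walking life-circle thresholds
    (500/1000/2000 m), and evaluates the equity and service performance of
    the resulting provision: Gini coefficient and Lorenz curve, location
    entropy (per-capita quotient), effective service area and population
    ratios, and natural-breaks accessibility grading. Includes dasymetric
    population disaggregation from census sub-districts to residential
    areas, GeoJSON/CSV layer input and output, network snapping and
    shortest-path catchments, and a seeded synthetic-city generator so the
    whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    ggplot2,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
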