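# Shared fixtures: a small scenario that exercises every stage quickly, and
# a hand-built network whose geometry is easy to reason about.

small_scenario <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, width = 3000, height = 3000, grid_spacing = 250,
    n_subdistricts = 5, n_residential = 60, n_greenspaces = 10,
    greenspace_area_range = c(2e3, 2e5), total_population = 5e4,
    clustering = 0.8
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(city_scenario, args)
}

# A single horizontal edge from (0,0) to (10,0); the simplest snap target.
single_edge_network <- function() {
  road_network(
    nodes = data.frame(id = c("a", "b"), x = c(0, 10), y = c(0, 0)),
    edges = data.frame(from = "a", to = "b")
  )
}

# Random connected-ish planar graph with n nodes for oracle comparisons.
random_small_network <- function(n, seed, p_extra = 0.3, span = 1000) {
  set.seed(seed)
  nodes <- data.frame(id = paste0("n", seq_len(n)),
                      x = runif(n, 0, span), y = runif(n, 0, span))
  # spanning chain plus random extra edges; no self-loops
  from <- nodes$id[seq_len(n - 1)]
  to <- nodes$id[2:n]
  extra <- which(runif(n * (n - 1) / 2) < p_extra)
  pairs <- utils::combn(n, 2)
  from <- c(from, nodes$id[pairs[1, extra]])
  to <- c(to, nodes$id[pairs[2, extra]])
  keep <- !duplicated(paste(pmin(from, to), pmax(from, to)))
  road_network(nodes, data.frame(from = from[keep], to = to[keep]))
}
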