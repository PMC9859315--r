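# Independent brute-force oracles. These deliberately avoid the package's
# shortest-path machinery: distances come from exhaustive enumeration of
# simple paths in an augmented edge list, and classifications from
# exhaustive search over ordered partitions.

# Minimum-length simple path between two named nodes over an undirected
# edge list (data.frame from, to, length); Inf when unreachable.
brute_force_path <- function(edges, start, goal) {
  if (start == goal) return(0)
  best <- Inf
  visit <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == goal) {
      best <<- acc
      return()
    }
    inc <- which((edges$from == node & !(edges$to %in% visited)) |
                   (edges$to == node & !(edges$from %in% visited)))
    for (e in inc) {
      nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
      visit(nxt, c(visited, nxt), acc + edges$length[e])
    }
  }
  visit(start, start, 0)
  best
}

# Oracle network distance between two snapped locations: splice the snapped
# points into the edge list as explicit nodes, enumerate simple paths, add
# connectors.
oracle_network_distance <- function(a, b, network, include_connectors = TRUE) {
  edges <- as.data.frame(network$edges)
  pts <- data.frame(name = c("PA", "PB"),
                    edge_id = c(a$edge_id, b$edge_id),
                    offset = c(a$offset, b$offset))
  out <- edges[0, c("from", "to", "length")]
  for (i in seq_len(nrow(edges))) {
    on_e <- pts[pts$edge_id == edges$id[i], , drop = FALSE]
    if (nrow(on_e) == 0) {
      out <- rbind(out, edges[i, c("from", "to", "length")])
    } else {
      on_e <- on_e[order(on_e$offset), , drop = FALSE]
      stops <- c(edges$from[i], on_e$name, edges$to[i])
      offs <- c(0, on_e$offset, edges$length[i])
      for (k in seq_len(length(stops) - 1)) {
        seg <- offs[k + 1] - offs[k]
        if (seg > 0 || stops[k] != stops[k + 1]) {
          out <- rbind(out, data.frame(from = stops[k], to = stops[k + 1],
                                       length = seg))
        }
      }
    }
  }
  d <- brute_force_path(out, "PA", "PB")
  if (include_connectors) d <- d + a$connector + b$connector
  d
}

# Exhaustive natural-breaks search: all ordered partitions of the sorted
# values into k non-empty contiguous classes; returns the minimal
# within-class sum of squared deviations.
oracle_jenks_cost <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (c_ in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, c_], n)
    cost <- sum(vapply(seq_len(k), function(m) {
      ssd(x[(bounds[m] + 1):bounds[m + 1]])
    }, numeric(1)))
    best <- min(best, cost)
  }
  best
}

# Direct cumulative-share Lorenz computation for cross-checking.
oracle_lorenz <- function(values) {
  x <- sort(values)
  cumsum(x) / sum(x)
}
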