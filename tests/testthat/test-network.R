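test_that("snapping projects onto the nearest edge with tie-breaking by id", {
  net <- single_edge_network()
  on_edge <- snap_to_network(c(5, 0), net)
  expect_equal(on_edge$connector, 0)
  expect_equal(on_edge$offset, 5)

  off <- snap_to_network(c(5, 3), net)
  expect_equal(off$offset, 5)
  expect_equal(off$connector, 3)
  expect_equal(c(off$x, off$y), c(5, 0))

  # beyond the segment end: clamped projection
  past <- snap_to_network(c(12, 1), net)
  expect_equal(past$offset, 10)
  expect_equal(past$connector, sqrt(2^2 + 1^2))

  # two parallel horizontal edges, point midway: smallest edge id wins
  net2 <- road_network(
    data.frame(id = c("a", "b", "c", "d"),
               x = c(0, 10, 0, 10), y = c(0, 0, 2, 2)),
    data.frame(from = c("a", "c"), to = c("b", "d"))
  )
  mid <- snap_to_network(c(5, 1), net2)
  expect_equal(mid$edge_id, 1L)
  expect_error(snap_to_network(c(0, 0),
                               road_network(data.frame(id = "a", x = 0, y = 0),
                                            data.frame(from = character(),
                                                       to = character(),
                                                       length = numeric()))),
               "empty network")
})

test_that("network construction validates lengths and collapses parallels", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_error(road_network(nodes, data.frame(from = "a", to = "a")),
               "self-loop")
  expect_error(road_network(nodes, data.frame(from = "a", to = "b", length = 2)),
               "straight-line")
  dup <- road_network(nodes, data.frame(from = c("a", "a"), to = c("b", "b"),
                                        length = c(7, 5.5)))
  expect_equal(nrow(dup$edges), 1)
  expect_equal(dup$edges$length, 5.5)
})

test_that("within-edge and identity distances are exact", {
  net <- road_network(
    data.frame(id = c("a", "b"), x = c(0, 500), y = c(0, 0)),
    data.frame(from = "a", to = "b")
  )
  p1 <- snap_to_network(c(100, 0), net)
  p2 <- snap_to_network(c(400, 0), net)
  expect_equal(network_distance(p1, p2, net), 300)
  expect_equal(network_distance(p2, p1, net), 300)
  expect_equal(network_distance(p1, p1, net), 0)
  p3 <- snap_to_network(c(100, 7), net)
  expect_equal(network_distance(p3, p3, net), 14) # both connectors traversed
})

test_that("unreachable pairs are Inf, not a large finite number", {
  net <- road_network(
    data.frame(id = c("a", "b", "c", "d"),
               x = c(0, 100, 1000, 1100), y = 0),
    data.frame(from = c("a", "c"), to = c("b", "d"))
  )
  p1 <- snap_to_network(c(50, 0), net)
  p2 <- snap_to_network(c(1050, 0), net)
  expect_identical(network_distance(p1, p2, net), Inf)
})

test_that("distances match brute-force simple-path enumeration on small graphs", {
  for (seed in 1:8) {
    n <- sample(4:9, 1)
    net <- random_small_network(n, seed = 100 + seed)
    set.seed(200 + seed)
    pts <- matrix(runif(8, 0, 1000), ncol = 2)
    snaps <- snap_to_network(pts, net)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        got <- network_distance(snaps[i, ], snaps[j, ], net)
        want <- oracle_network_distance(snaps[i, ], snaps[j, ], net)
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  net <- random_small_network(8, seed = 42)
  set.seed(43)
  snaps <- snap_to_network(matrix(runif(12, 0, 1000), ncol = 2), net)
  d <- network_distance_matrix(snaps, snaps, net, include_connectors = FALSE)
  expect_equal(d, t(d), tolerance = 1e-9)
  for (a in 1:6) for (b in 1:6) for (c_ in 1:6) {
    expect_lte(d[a, b], d[a, c_] + d[c_, b] + 1e-9)
  }
})

test_that("multi-entrance distance is the minimum over entrances", {
  net <- road_network(
    data.frame(id = c("a", "b", "c"), x = c(0, 1000, 2000), y = 0),
    data.frame(from = c("a", "b"), to = c("b", "c"))
  )
  demand <- snap_to_network(c(0, 0), net)
  acc <- snap_to_network(rbind(c(800, 0), c(450, 0)), net)
  expect_equal(distance_to_greenspace(demand, acc, net), 450)
  expect_equal(distance_to_greenspace(demand, acc[1, ], net), 800)
  # adding entrances can only shorten
  d_multi <- distance_to_greenspace(demand, acc, net)
  for (k in 1:2) {
    expect_lte(d_multi, distance_to_greenspace(demand, acc[k, ], net))
  }
  expect_error(distance_to_greenspace(demand, acc[0, ], net), "no access")
})

test_that("catchments match pairwise oracle distances and are monotone in d0", {
  for (seed in 1:4) {
    net <- random_small_network(7, seed = 300 + seed)
    set.seed(400 + seed)
    origin <- snap_to_network(runif(2, 0, 1000), net)
    targets <- snap_to_network(matrix(runif(12, 0, 1000), ncol = 2), net)
    oracle_d <- vapply(seq_len(nrow(targets)), function(k) {
      oracle_network_distance(origin, targets[k, ], net)
    }, numeric(1))
    prev <- integer(0)
    for (d0 in c(200, 500, 900, 1500, Inf)) {
      got <- catchment(origin, d0, targets, net)
      expect_setequal(got$target, which(oracle_d <= d0))
      expect_equal(got$distance, oracle_d[got$target], tolerance = 1e-9)
      expect_true(all(prev %in% got$target)) # monotone growth
      prev <- got$target
    }
    # saturation: everything reachable at Inf on a connected graph
    expect_setequal(catchment(origin, Inf, targets, net)$target,
                    seq_len(nrow(targets)))
  }
})

test_that("a tight radius around an off-network point yields an empty catchment", {
  net <- single_edge_network()
  origin <- snap_to_network(c(5, 4), net) # connector 4
  targets <- snap_to_network(rbind(c(1, 3), c(9, 3)), net)
  got <- catchment(origin, 3, targets, net)
  expect_equal(nrow(got), 0)
})
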