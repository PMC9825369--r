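test_that("euclidean adjacency gives pairwise mm distances on masked nodes", {
  ct <- contact_table(c("a", "b", "c"), "E", c(0, 3, 10), c(0, 4, 0), 0,
                      soz = c(TRUE, TRUE, FALSE), resected = FALSE)
  g <- euclidean_adjacency(ct)
  expect_equal(g$weights["a", "b"], 5)           # 3-4-5 triangle
  expect_equal(g$weights, t(g$weights))
  expect_equal(unname(diag(g$weights)), rep(0, 3))
  # mask by SOZ keeps two nodes
  g2 <- euclidean_adjacency(ct, ct$soz)
  expect_identical(g2$nodes, c("a", "b"))
  # single node: no edges; empty mask: empty graph
  expect_equal(n_edges(euclidean_adjacency(ct, "a")), 0L)
  expect_equal(n_nodes(euclidean_adjacency(ct, character(0))), 0L)
})

test_that("graph radius matches hand computations and conventions", {
  # path graph a-b-c with unit lengths: ecc a=2, b=1, c=2 -> radius 1
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  r <- graph_radius(fr_graph(c("a", "b", "c"), w, "distance_mm"))
  expect_equal(r$radius, 1)
  expect_equal(unname(r$eccentricities), c(2, 1, 2))
  expect_true(r$connected)

  # complete graph, equal weights 7 on 5 nodes: radius 7
  w5 <- matrix(7, 5, 5); diag(w5) <- 0
  expect_equal(graph_radius(fr_graph(letters[1:5], w5, "distance_mm"))$radius,
               7)

  # single node: radius 0; empty graph: undefined
  expect_equal(graph_radius(fr_graph("a", matrix(0, 1, 1),
                                     "distance_mm"))$radius, 0)
  expect_true(is.na(graph_radius(fr_graph(character(0),
                                          matrix(numeric(0), 0, 0),
                                          "distance_mm"))$radius))

  # disconnected components: unreachable pairs excluded, connected = FALSE
  wd <- matrix(0, 4, 4)
  wd[1, 2] <- wd[2, 1] <- 2; wd[3, 4] <- wd[4, 3] <- 3
  rd <- graph_radius(fr_graph(letters[1:4], wd, "distance_mm"))
  expect_false(rd$connected)
  expect_equal(rd$radius, 2)
})

test_that("graph radius equals the Floyd-Warshall oracle on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.3, 1))
    g <- fr_graph(sprintf("n%d", 1:n), w, "distance_mm")
    expect_equal(graph_radius(g)$radius, oracle_radius(w), tolerance = 1e-9)
  }
})

test_that("SOZ measures follow their definitions", {
  ct <- contact_table(sprintf("c%d", 1:6), "E", c(0, 5, 10, 15, 60, 65),
                      0, 0, soz = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                      resected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  p <- small_patient(ct, event_table(character(0), numeric(0),
                                     character(0), numeric(0)))
  sm <- soz_measures(p)
  expect_equal(sm$soz_rr, 0.75)
  # SOZ at 0,5,10,15 on a line: radius = min ecc; middle nodes see max 10
  expect_equal(sm$soz_radius, 10)
  # resected SOZ at 0,5,10: radius 5; difference 10 - 5
  expect_equal(sm$unresected_soz_radius, 5)

  # all SOZ contacts resected: radii identical, difference 0
  ct2 <- ct; ct2$resected <- ct2$soz
  sm2 <- soz_measures(small_patient(ct2, p$events))
  expect_equal(sm2$unresected_soz_radius, 0)

  # no SOZ: undefined markers
  ct3 <- ct; ct3$soz <- FALSE
  sm3 <- soz_measures(small_patient(ct3, p$events))
  expect_true(all(is.na(unlist(sm3))))
})

test_that("rate-distance weights are mean rate times distance", {
  ct <- contact_table(c("a", "b"), "E", c(0, 10), 0, 0, FALSE,
                      resected = c(TRUE, FALSE))
  # rates 2/min and 4/min over 10 minutes
  ev <- event_table(rep(c("a", "b"), times = c(20, 40)),
                    seq(1, by = 0.5, length.out = 60), "fRonS", 300)
  p <- small_patient(ct, ev, duration_min = 10)
  g <- rate_distance_adjacency(p)
  expect_equal(g$weights["a", "b"], (2 + 4) / 2 * 10)   # 30 mm.events/min
  expect_identical(g$semantics, "rate_distance")

  # a contact without selected events is not a node
  ev2 <- ev[ev$contact_id == "a", ]
  g2 <- rate_distance_adjacency(small_patient(ct, ev2, duration_min = 10))
  expect_identical(g2$nodes, "a")

  # homogeneity: doubling all rates doubles all weights (halve duration)
  p_half <- suppressWarnings(small_patient(ct, ev, duration_min = 5))
  g_half <- rate_distance_adjacency(p_half)
  expect_equal(g_half$weights, g$weights * 2)
})

test_that("radius differences honour their boundary identities", {
  ct <- contact_table(sprintf("c%d", 1:3), "E", c(0, 10, 50), 0, 0, FALSE,
                      resected = c(TRUE, TRUE, TRUE))
  ev <- event_table(rep(sprintf("c%d", 1:3), each = 10),
                    seq(1, by = 1, length.out = 30), "fRonS", 300)
  p_all <- small_patient(ct, ev, duration_min = 10)
  # every FR-generating contact resected -> identical networks -> 0
  expect_equal(rate_distance_radius_difference(p_all), 0)
  expect_equal(distance_radius_difference(p_all), 0)

  # nothing resected -> difference equals the whole-network radius
  ct2 <- ct; ct2$resected <- FALSE
  p_none <- small_patient(ct2, ev, duration_min = 10)
  g <- rate_distance_adjacency(p_none)
  expect_equal(rate_distance_radius_difference(p_none),
               graph_radius(g)$radius)

  # no FR events -> undefined
  p_empty <- small_patient(ct, ev[0, ])
  expect_true(is.na(rate_distance_radius_difference(p_empty)))
  expect_true(is.na(distance_radius_difference(p_empty)))

  # with unit rates the two differences coincide
  ev1 <- event_table(sprintf("c%d", 1:3), c(1, 2, 3), "fRonS", 300)
  ct3 <- ct; ct3$resected <- c(TRUE, TRUE, FALSE)
  p1 <- suppressWarnings(small_patient(ct3, ev1, duration_min = 1))
  expect_equal(rate_distance_radius_difference(p1),
               distance_radius_difference(p1), tolerance = 1e-9)
})

test_that("a distant unresected hot contact raises the radius difference", {
  ct <- contact_table(sprintf("c%d", 1:4), "E", c(0, 5, 10, 80), 0, 0,
                      FALSE, resected = c(TRUE, TRUE, TRUE, FALSE))
  ev <- event_table(rep(sprintf("c%d", 1:4), each = 20),
                    seq(1, by = 0.25, length.out = 80), "fRonS", 300)
  p_unres <- small_patient(ct, ev, duration_min = 10)
  ct2 <- ct; ct2$resected <- rep(TRUE, 4)
  p_res <- small_patient(ct2, ev, duration_min = 10)
  expect_gt(rate_distance_radius_difference(p_unres),
            rate_distance_radius_difference(p_res))
})

test_that("small-graph shortest paths agree with igraph on larger graphs", {
  set.seed(55)
  # the same graph solved by the dense relaxation and by Dijkstra
  n <- 34   # above the internal dense-solver cutoff
  w <- random_weight_matrix(n, density = 0.2)
  g <- fr_graph(sprintf("n%d", 1:n), w, "distance_mm")
  big <- frnet:::shortest_paths_matrix(g)
  dense <- frnet:::minplus_apsp(g$weights)
  expect_equal(big, dense, tolerance = 1e-9, ignore_attr = TRUE)
})
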