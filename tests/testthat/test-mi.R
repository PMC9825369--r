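test_that("MI estimator honours its contracts on degenerate input", {
  expect_equal(mutual_information(c(1, 2), c(1, 2, 3, 4)), 0)
  expect_equal(mutual_information(numeric(0), c(1, 2, 3)), 0)
  expect_error(mutual_information(c(2, 1, 3), c(1, 2, 3)),
               "strictly increasing")
  expect_error(mutual_information(c(1, 1, 2), c(1, 2, 3)),
               "strictly increasing")
})

test_that("independent trains give near-zero MI, coupled trains do not", {
  set.seed(13)
  null_mi <- sapply(1:30, function(s) {
    a <- sort(runif(200, 0, 3000))
    b <- sort(runif(200, 0, 3000))
    mutual_information(a, b)
  })
  expect_lte(median(null_mi), 0.05)
  cp <- make_coupled_pair(6, 0.9, 10, 40, seed = 77)
  expect_gt(mutual_information(cp$a, cp$b), median(null_mi) + 0.2)
})

test_that("self-MI equals the plug-in entropy of the terminal partition", {
  set.seed(31)
  a <- sort(runif(500, 0, 5000))
  mi_self <- mutual_information(a, a)
  counts <- frnet:::mi_partition_counts(a, a)
  p <- counts / sum(counts)
  entropy <- -sum(p * log2(p))
  expect_equal(mi_self, entropy, tolerance = 0.1 * entropy)
  # and self-dependence beats any independent partner
  b <- sort(runif(500, 0, 5000))
  expect_gt(mi_self, mutual_information(a, b))
})

test_that("MI adjacency is symmetric with the coupled edge dominating", {
  set.seed(19)
  cp <- make_coupled_pair(6, 0.9, 10, 30, seed = 5)
  ind <- sort(runif(150, 0, 30 * 60))
  ct <- contact_table(c("x", "y", "z"), "E", c(0, 5, 50), 0, 0, FALSE,
                      resected = c(TRUE, FALSE, FALSE))
  mk_ev <- function(id, t) event_table(rep(id, length(t)), t, "fRonS", 300)
  p <- small_patient(ct, rbind(mk_ev("x", cp$a), mk_ev("y", cp$b),
                               mk_ev("z", ind)), duration_min = 30)
  g <- mi_adjacency(p)
  expect_equal(g$weights, t(g$weights))
  expect_identical(g$semantics, "mutual_information_bits")
  w <- g$weights
  expect_gt(w["x", "y"], max(w["x", "z"], w["y", "z"]))

  # no FR events at all -> empty graph and no_network downstream
  p0 <- small_patient(ct, mk_ev("x", numeric(0)))
  g0 <- mi_adjacency(p0)
  expect_equal(n_nodes(g0), 0L)
  expect_identical(char_path_length_rr(p0, g = g0)$indeterminate_reason,
                   "no_network")
})

test_that("length matrix inverts MI and preserves absent edges", {
  w <- matrix(c(0, 0.5, 0, 0.5, 0, 0, 0, 0, 0), 3, 3)
  g <- fr_graph(c("a", "b", "c"), w, "mutual_information_bits")
  L <- length_matrix(g)
  expect_equal(L["a", "b"], 2)
  expect_equal(L["a", "c"], 0)       # absent stays absent, never length 0
  g2 <- fr_graph(g$nodes, w * 2, "mutual_information_bits")
  expect_equal(length_matrix(g2)["a", "b"], 1)  # doubling MI halves length
  gd <- fr_graph(c("a", "b"), matrix(c(0, 1, 1, 0), 2), "distance_mm")
  expect_error(length_matrix(gd), "mutual_information_bits")
})

test_that("characteristic path length matches closed forms and the oracle", {
  # two nodes, MI 0.5 -> L = 2
  w2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  g2 <- fr_graph(c("a", "b"), w2, "mutual_information_bits")
  expect_equal(char_path_length(g2), 2)
  # triangle with equal MI m -> L = 1/m
  m <- 0.25
  w3 <- matrix(m, 3, 3); diag(w3) <- 0
  g3 <- fr_graph(letters[1:3], w3, "mutual_information_bits")
  expect_equal(char_path_length(g3), 1 / m)
  # random MI graphs vs Floyd-Warshall oracle
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.4, 1), wmin = 0.05,
                              wmax = 2)
    g <- fr_graph(sprintf("n%d", 1:n), w, "mutual_information_bits")
    expect_equal(char_path_length(g), oracle_cpl(w), tolerance = 1e-9)
  }
  # subgraph restriction recomputes paths inside the subgraph only
  sub <- char_path_length(g3, c("a", "b"))
  expect_equal(sub, 1 / m)
})

test_that("cpl resected ratio covers its indeterminate taxonomy", {
  ct <- contact_table(c("a", "b", "c"), "E", c(0, 5, 10), 0, 0, FALSE,
                      resected = c(TRUE, TRUE, FALSE))
  mk_ev <- function(id, t) event_table(rep(id, length(t)), t, "fRonS", 300)
  cp <- make_coupled_pair(6, 0.9, 10, 30, seed = 8)
  # resected subgraph == whole MI-carrying graph -> fully_resected, ratio 1
  p <- small_patient(ct, rbind(mk_ev("a", cp$a), mk_ev("b", cp$b)),
                     duration_min = 30)
  r <- char_path_length_rr(p)
  expect_identical(r$indeterminate_reason, "fully_resected")
  expect_equal(r$value, 1)
  # nothing resected among MI nodes -> no finite resected pair
  ct2 <- ct; ct2$resected <- FALSE
  r2 <- char_path_length_rr(small_patient(ct2, p$events, duration_min = 30))
  expect_false(is.na(r2$indeterminate_reason))
})

test_that("clustering coefficients match closed forms and a triple loop", {
  # binary triangle: all coefficients 1
  w3 <- matrix(1, 3, 3); diag(w3) <- 0
  cc <- clustering_coefficients(fr_graph(letters[1:3], w3, "unweighted"))
  expect_equal(unname(cc), rep(1, 3))
  # star graph: no triangles anywhere
  ws <- matrix(0, 4, 4); ws[1, 2:4] <- ws[2:4, 1] <- 1
  cs <- clustering_coefficients(fr_graph(letters[1:4], ws, "unweighted"))
  expect_equal(unname(cs), rep(0, 4))
  # random weighted graphs vs brute force
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.4, 1))
    g <- fr_graph(sprintf("n%d", 1:n), w, "mutual_information_bits")
    expect_equal(unname(clustering_coefficients(g)), oracle_clustering(w),
                 tolerance = 1e-9)
  }
})

test_that("local efficiencies match closed forms and direct enumeration", {
  # binary K4: every neighborhood is a connected triangle -> LE 1
  w4 <- matrix(1, 4, 4); diag(w4) <- 0
  le <- local_efficiencies(fr_graph(letters[1:4], w4, "unweighted"))
  expect_equal(unname(le), rep(1, 4))
  # node whose two neighbors are unconnected -> LE 0
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 1; wp[2, 3] <- wp[3, 2] <- 1
  lep <- local_efficiencies(fr_graph(letters[1:3], wp, "unweighted"))
  expect_equal(unname(lep[2]), 0)
  # random weighted graphs vs brute force
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.4, 1))
    g <- fr_graph(sprintf("n%d", 1:n), w, "mutual_information_bits")
    expect_equal(unname(local_efficiencies(g)), oracle_local_eff(w),
                 tolerance = 1e-9)
  }
})

test_that("metric panel stratifies by resection and flags indeterminates", {
  set.seed(41)
  co <- generate_cohort(sim_params(n_patients = 2, duration_min = c(30, 45),
                                   seed = 41))
  p <- co$patients[[1]]
  panel <- mi_metric_panel(p)
  if (is.na(panel$indeterminate_reason)) {
    expect_true(panel$cpl_rr > 0)
    expect_true(panel$max_clust_unres >= 0)
    expect_true(panel$zero_le_pct_res >= 0 && panel$zero_le_pct_res <= 100)
    expect_true(panel$zero_le_pct_unres >= 0 &&
                panel$zero_le_pct_unres <= 100)
  }
  # panel values are invariant under node relabeling (contact order)
  perm <- sample(nrow(p$contacts))
  p2 <- patient_record(p$patient_id, p$contacts[perm, ], p$events,
                       p$duration_min, p$engel)
  panel2 <- mi_metric_panel(p2)
  expect_equal(panel$cpl_rr, panel2$cpl_rr, tolerance = 1e-9)
  expect_equal(panel$mean_le_unres_pre, panel2$mean_le_unres_pre,
               tolerance = 1e-9)
})

test_that("unweighted control equals the weighted panel on uniform MI", {
  # equal MI everywhere: binarizing is a pure rescaling
  w <- matrix(0.4, 4, 4); diag(w) <- 0
  ct <- contact_table(letters[1:4], "E", 1:4, 0, 0, FALSE,
                      resected = c(TRUE, TRUE, FALSE, FALSE))
  mk_ev <- function(id) event_table(id, 1, "fRonS", 300)
  p <- small_patient(ct, do.call(rbind, lapply(letters[1:4], mk_ev)))
  g <- fr_graph(letters[1:4], w, "mutual_information_bits")
  pw <- mi_metric_panel(p, g = g)
  pu <- unweighted_control_panel(p, g = g)
  expect_equal(pw$max_clust_unres, pu$max_clust_unres)
  expect_equal(pw$mean_le_unres_pre, pu$mean_le_unres_pre)
  expect_equal(pw$zero_le_pct_res, pu$zero_le_pct_res)
  # binary triangle: whole-network cpl is 1
  wt <- matrix(1, 3, 3); diag(wt) <- 0
  gt <- fr_graph(letters[1:3], wt, "mutual_information_bits")
  expect_equal(char_path_length(gt), 1)
})
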