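# Mutual information between FR event trains
# -------------------------------------------
# The dependency between two contacts' FR trains is estimated from paired
# inter-event intervals (ISIs): events of the sparser train are matched to
# their nearest-in-time events on the other train (each event used at most
# once), and each matched pair contributes the preceding ISI on either
# side as one sample from the joint ISI-ISI distribution. MI of that joint
# sample is estimated by recursive adaptive partitioning (Darbellay-Vajda):
# a cell of the plane is split 2x2 at its conditional medians whenever a
# chi-square test rejects equidistribution of its points over the four
# quadrants (alpha = 0.05, at least 5 samples per candidate subcell), and
# terminal cells contribute p * log2(p / (px * py)). Negative estimates are
# clipped to zero and the estimate is symmetrized over the two argument
# orders.

#' Mutual information between two event trains
#'
#' @param a,b Numeric vectors of sorted onset times (seconds). Trains with
#'   fewer than 3 events give MI 0 by contract.
#' @param alpha Significance level of the chi-square equidistribution test
#'   that drives partition refinement.
#' @param min_cell Minimum samples per candidate subcell for a split.
#' @param symmetrize Average the estimate over both argument orders.
#' @return MI in bits, >= 0.
#' @export
mutual_information <- function(a, b, alpha = 0.05, min_cell = 5,
                               symmetrize = TRUE) {
  check_train(a); check_train(b)
  if (length(a) < 3 || length(b) < 3) return(0)
  m1 <- mi_directed(a, b, alpha, min_cell)
  if (!symmetrize) return(max(0, m1))
  m2 <- mi_directed(b, a, alpha, min_cell)
  max(0, (m1 + m2) / 2)
}

check_train <- function(x) {
  if (length(x) > 1 && any(diff(x) <= 0))
    stop("event train must be strictly increasing", call. = FALSE)
  invisible(x)
}

mi_directed <- function(a, b, alpha, min_cell) {
  # at most min(n_a, n_b) - 1 paired samples can survive (the first event
  # on each side carries no preceding ISI), so short trains cannot reach
  # the 4 * min_cell needed for a first split
  if (min(length(a), length(b)) - 1 < 4 * min_cell) return(0)
  s <- paired_isi(a, b)
  if (is.null(s) || nrow(s) < 4 * min_cell) return(0)
  adaptive_partition_mi(s[, 1], s[, 2], alpha, min_cell)
}

# nearest-in-time matching from the sparser train, one-to-one: candidate
# (i, j) pairs ranked by |dt|, accepted greedily while both ends unused;
# each accepted pair yields (preceding ISI in sparse train, preceding ISI
# in other train), dropping pairs where either event is its train's first.
paired_isi <- function(a, b) {
  if (length(a) <= length(b)) { s <- a; o <- b; swap <- FALSE }
  else { s <- b; o <- a; swap <- TRUE }
  ns <- length(s); no <- length(o)
  # nearest + second-nearest candidates keep the candidate list linear
  idx <- findInterval(s, o)
  ci <- rep.int(seq_len(ns), 2L)
  cj <- c(pmax(idx, 1L), pmin(idx + 1L, no))
  dup <- duplicated(ci * (no + 1) + cj)
  ci <- ci[!dup]; cj <- cj[!dup]
  ord <- order(abs(s[ci] - o[cj]), ci, cj)
  ci <- ci[ord]; cj <- cj[ord]
  used_s <- logical(ns); used_o <- logical(no)
  mi <- integer(ns); mj <- integer(ns); np <- 0L
  for (r in seq_along(ci)) {
    i <- ci[r]; j <- cj[r]
    if (!used_s[i] && !used_o[j]) {
      used_s[i] <- TRUE; used_o[j] <- TRUE
      np <- np + 1L
      mi[np] <- i; mj[np] <- j
    }
  }
  mi <- mi[seq_len(np)]; mj <- mj[seq_len(np)]
  keep <- mi > 1L & mj > 1L
  if (!any(keep)) return(NULL)
  x <- s[mi[keep]] - s[mi[keep] - 1L]
  y <- o[mj[keep]] - o[mj[keep] - 1L]
  if (swap) cbind(y, x) else cbind(x, y)
}

# Darbellay-Vajda recursive adaptive partitioning on ranks of (x, y).
# Working on ranks makes marginals uniform and median splits well defined
# under heavy-tailed ISI distributions; MI is invariant to the monotone
# transform.
adaptive_partition_mi <- function(x, y, alpha, min_cell) {
  n <- length(x)
  rx <- integer(n); rx[order(x)] <- seq_len(n)  # rank, first-come ties
  ry <- integer(n); ry[order(y)] <- seq_len(n)
  crit <- qchisq(1 - alpha, df = 3)
  cells <- dv_cells(rx, ry, seq_len(n), crit, min_cell)
  mi <- 0
  for (cell in cells) {
    p <- length(cell$idx) / n
    # ranks are a permutation of 1..n, so marginal cell masses are the
    # integer count of ranks inside the (lo, hi] bounds
    px <- (floor(min(cell$xhi, n)) - floor(cell$xlo)) / n
    py <- (floor(min(cell$yhi, n)) - floor(cell$ylo)) / n
    if (p > 0 && px > 0 && py > 0)
      mi <- mi + p * log2(p / (px * py))
  }
  mi
}

fast_median <- function(v) {
  n <- length(v)
  s <- sort.int(v, method = "quick")
  if (n %% 2L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

dv_cells <- function(rx, ry, idx, crit, min_cell,
                     xlo = 0, xhi = Inf, ylo = 0, yhi = Inf) {
  n <- length(idx)
  terminal <- list(list(idx = idx, xlo = xlo, xhi = min(xhi, max(rx)),
                        ylo = ylo, yhi = min(yhi, max(ry))))
  if (n < 4 * min_cell) return(terminal)
  mx <- fast_median(rx[idx]); my <- fast_median(ry[idx])
  in_x <- rx[idx] <= mx; in_y <- ry[idx] <= my
  q <- list(idx[in_x & in_y], idx[in_x & !in_y],
            idx[!in_x & in_y], idx[!in_x & !in_y])
  counts <- lengths(q)
  chi2 <- sum((counts - n / 4)^2) / (n / 4)
  if (chi2 <= crit) return(terminal)
  sub <- list(c(xlo, mx, ylo, my), c(xlo, mx, my, yhi),
              c(mx, xhi, ylo, my), c(mx, xhi, my, yhi))
  out <- list()
  for (k in 1:4) {
    if (!counts[k]) next   # empty quadrants carry no probability mass
    b <- sub[[k]]
    out <- c(out, dv_cells(rx, ry, q[[k]], crit, min_cell,
                           b[1], b[2], b[3], b[4]))
  }
  out
}

# exposed for testing: terminal-cell occupancies of one directed run
mi_partition_counts <- function(a, b, alpha = 0.05, min_cell = 5) {
  s <- paired_isi(a, b)
  if (is.null(s)) return(integer(0))
  rx <- rank(s[, 1], ties.method = "first")
  ry <- rank(s[, 2], ties.method = "first")
  crit <- qchisq(1 - alpha, df = 3)
  cells <- dv_cells(rx, ry, seq_along(rx), crit, min_cell)
  vapply(cells, function(cell) length(cell$idx), integer(1))
}

#' FR MI adjacency
#'
#' Builds per-contact FR event trains from the selected events and fills a
#' symmetric matrix with pairwise [mutual_information()]. Nodes are the
#' FR-generating contacts (at least one selected event); edges with MI 0
#' are absent.
#'
#' @inheritParams select_events
#' @param alpha,min_cell Estimator settings, see [mutual_information()].
#' @return An `fr_graph` with `mutual_information_bits` semantics.
#' @export
mi_adjacency <- function(patient, rule = selection_rule("fr_gt350"),
                         alpha = 0.05, min_cell = 5) {
  ev <- select_events(patient, rule)
  ids <- patient$contacts$contact_id
  gen <- ids[ids %in% unique(ev$contact_id)]
  trains <- lapply(gen, function(id)
    unique(sort(ev$onset_s[ev$contact_id == id])))
  n <- length(gen)
  w <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (length(trains[[i]]) < 3) next
      for (j in seq.int(i + 1, n)) {
        if (length(trains[[j]]) < 3) next
        w[i, j] <- w[j, i] <- mutual_information(trains[[i]], trains[[j]],
                                                 alpha, min_cell)
      }
    }
  }
  fr_graph(gen, w, "mutual_information_bits")
}

#' Inverse-MI length matrix
#'
#' Converts an MI adjacency to path lengths: present edges get length
#' 1/MI; absent edges stay absent. Only defined for
#' `mutual_information_bits` graphs.
#'
#' @param g An `fr_graph` with MI semantics.
#' @return A matrix of lengths with 0 marking absent edges (the convention
#'   [fr_graph()] uses), plus attribute `lengths = TRUE`.
#' @export
length_matrix <- function(g) {
  stopifnot(inherits(g, "fr_graph"))
  if (g$semantics != "mutual_information_bits")
    stop("length_matrix is defined for mutual_information_bits graphs",
         call. = FALSE)
  L <- g$weights
  L[L > 0] <- 1 / L[L > 0]
  L
}

mi_length_graph <- function(g) {
  fr_graph(g$nodes, length_matrix(g), "distance_mm")  # lengths-as-weights
}

#' Characteristic path length of an MI network
#'
#' Mean over node pairs of the finite shortest-path lengths computed on
#' the inverse-MI length matrix of the induced subgraph. Pairs with no
#' connecting path are excluded from the mean; when no finite pair exists
#' the value is indeterminate (`NA`).
#'
#' @param g An `fr_graph` with `mutual_information_bits` semantics.
#' @param node_subset Optional character vector restricting to an induced
#'   subgraph (paths may then only use subgraph edges).
#' @return Mean shortest path length, or `NA_real_`.
#' @export
char_path_length <- function(g, node_subset = NULL) {
  if (!is.null(node_subset)) g <- induced_fr_graph(g, node_subset)
  if (n_nodes(g) < 2) return(NA_real_)
  d <- shortest_paths_matrix(mi_length_graph(g))
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Characteristic path length resected ratio
#'
#' Characteristic path length of the FR MI network induced on resected
#' FR-generating contacts divided by that of the whole FR MI network.
#' Indeterminate when the whole network has no MI edges (`no_network`) or
#' when every node carrying an MI edge is resected (`fully_resected`; the
#' ratio is then 1 but flagged, mirroring patients whose entire FR MI
#' network lay inside the resection).
#'
#' @inheritParams mi_adjacency
#' @param g Optional precomputed [mi_adjacency()] graph.
#' @return List with `value` (ratio or `NA`) and `indeterminate_reason`
#'   (`NA`, `"no_network"` or `"fully_resected"`).
#' @export
char_path_length_rr <- function(patient, rule = selection_rule("fr_gt350"),
                                g = NULL) {
  if (is.null(g)) g <- mi_adjacency(patient, rule)
  net_nodes <- mi_network_nodes(g)
  if (!length(net_nodes))
    return(list(value = NA_real_, indeterminate_reason = "no_network"))
  res_ids <- patient$contacts$contact_id[patient$contacts$resected]
  if (all(net_nodes %in% res_ids))
    return(list(value = 1, indeterminate_reason = "fully_resected"))
  whole <- char_path_length(g)
  res <- char_path_length(g, intersect(g$nodes, res_ids))
  if (is.na(res) || is.na(whole))
    return(list(value = NA_real_, indeterminate_reason = "no_network"))
  list(value = res / whole, indeterminate_reason = NA_character_)
}

# nodes that carry at least one MI edge
mi_network_nodes <- function(g) {
  if (n_nodes(g) == 0) return(character(0))
  g$nodes[rowSums(g$weights > 0) > 0]
}

normalize_weights <- function(w) {
  mx <- max(w)
  if (mx > 0) w / mx else w
}

#' Weighted clustering coefficients (geometric triangle mean)
#'
#' Weights are first normalized by the within-graph maximum; node i's
#' coefficient is the sum over neighbor pairs of the geometric mean of the
#' three normalized triangle weights, divided by k_i (k_i - 1) with k_i the
#' node degree. Nodes of degree < 2 get 0.
#'
#' @param g An `fr_graph`.
#' @return Named numeric vector over nodes.
#' @export
clustering_coefficients <- function(g) {
  w <- normalize_weights(g$weights)
  if (n_nodes(g) == 0) return(setNames(numeric(0), character(0)))
  w3 <- w^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  setNames(as.numeric(cc), g$nodes)
}

#' Weighted local efficiencies
#'
#' For each node, the efficiency of the subgraph induced on its neighbors:
#' the mean over neighbor pairs of the inverse shortest-path length, paths
#' computed on inverse normalized weights within that subgraph (pairs with
#' no path contribute 0). Nodes of degree < 2 get 0.
#'
#' @param g An `fr_graph`.
#' @return Named numeric vector over nodes.
#' @export
local_efficiencies <- function(g) {
  n <- n_nodes(g)
  if (n == 0) return(setNames(numeric(0), character(0)))
  w <- normalize_weights(g$weights)
  L <- w
  L[L > 0] <- 1 / L[L > 0]
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    sub <- fr_graph(g$nodes[nb], L[nb, nb, drop = FALSE], "distance_mm")
    d <- shortest_paths_matrix(sub)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    le[i] <- mean(inv)
  }
  setNames(le, g$nodes)
}

#' FR MI graph-metric panel for one patient
#'
#' The per-patient summary of the FR MI network relative to the resection:
#' * `cpl_rr`: characteristic path length resected ratio
#'   ([char_path_length_rr()]);
#' * `max_clust_unres`: maximum clustering coefficient over unresected
#'   nodes on the whole (pre-resection) network;
#' * `mean_le_unres_pre`: mean local efficiency over unresected nodes on
#'   the whole network;
#' * `mean_le_unres_post`: mean local efficiency over the nodes of the
#'   post-resection network (the subgraph induced on unresected nodes,
#'   re-normalized within itself);
#' * `zero_le_pct_res`, `zero_le_pct_unres`: percentage of resected
#'   (respectively unresected) FR nodes with local efficiency 0 on the
#'   whole network.
#'
#' @inheritParams char_path_length_rr
#' @param unweighted Binarize MI > 0 edges to weight 1 before computing
#'   every metric (the node/edge-structure control network).
#' @return Named list with the panel values and `indeterminate_reason`
#'   (`NA`, `"no_network"` or `"fully_resected"`; metrics are `NA` when
#'   indeterminate).
#' @export
mi_metric_panel <- function(patient, rule = selection_rule("fr_gt350"),
                            g = NULL, unweighted = FALSE) {
  if (is.null(g)) g <- mi_adjacency(patient, rule)
  if (unweighted) {
    w <- (g$weights > 0) * 1
    g <- fr_graph(g$nodes, w, "mutual_information_bits")
  }
  empty <- list(cpl_rr = NA_real_, max_clust_unres = NA_real_,
                mean_le_unres_pre = NA_real_, mean_le_unres_post = NA_real_,
                zero_le_pct_res = NA_real_, zero_le_pct_unres = NA_real_)
  cpl <- char_path_length_rr(patient, rule, g = g)
  if (!is.na(cpl$indeterminate_reason))
    return(c(empty, list(indeterminate_reason = cpl$indeterminate_reason)))
  res_ids <- patient$contacts$contact_id[patient$contacts$resected]
  resected <- g$nodes %in% res_ids
  cc <- clustering_coefficients(g)
  le <- local_efficiencies(g)
  unres <- !resected
  post <- induced_fr_graph(g, g$nodes[unres])
  le_post <- local_efficiencies(post)
  list(
    cpl_rr = cpl$value,
    max_clust_unres = if (any(unres)) max(cc[unres]) else NA_real_,
    mean_le_unres_pre = if (any(unres)) mean(le[unres]) else NA_real_,
    mean_le_unres_post = if (n_nodes(post) > 0) mean(le_post) else NA_real_,
    zero_le_pct_res = if (any(resected))
      100 * mean(le[resected] == 0) else NA_real_,
    zero_le_pct_unres = if (any(unres))
      100 * mean(le[unres] == 0) else NA_real_,
    indeterminate_reason = NA_character_
  )
}

#' @rdname mi_metric_panel
#' @export
unweighted_control_panel <- function(patient,
                                     rule = selection_rule("fr_gt350"),
                                     g = NULL) {
  mi_metric_panel(patient, rule, g = g, unweighted = TRUE)
}
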