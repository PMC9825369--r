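# Spatial networks: complete Euclidean-distance graphs on masked contact
# sets, rate-weighted distance graphs on FR-generating contacts, and the
# graph radius (minimum node eccentricity under shortest-path lengths).
# Distance-type weights ARE path lengths; no inversion. Excluded contact
# pairs are represented by absent nodes rather than infinite entries.

#' Complete Euclidean-distance graph on a contact subset
#'
#' @param contacts A contact table ([contact_table()]).
#' @param node_mask Logical vector over rows of `contacts`, or a character
#'   vector of contact ids; default keeps all contacts.
#' @return An `fr_graph` with `distance_mm` semantics; the empty graph when
#'   no contact passes the mask.
#' @export
euclidean_adjacency <- function(contacts, node_mask = NULL) {
  keep <- resolve_mask(contacts, node_mask)
  sub <- contacts[keep, , drop = FALSE]
  d <- as.matrix(dist(sub[, c("x", "y", "z")]))
  fr_graph(sub$contact_id, d, "distance_mm")
}

resolve_mask <- function(contacts, node_mask) {
  if (is.null(node_mask)) return(rep(TRUE, nrow(contacts)))
  if (is.character(node_mask)) return(contacts$contact_id %in% node_mask)
  if (is.logical(node_mask) && length(node_mask) == nrow(contacts))
    return(node_mask)
  stop("node_mask must be NULL, a logical vector over contacts, ",
       "or contact ids", call. = FALSE)
}

igraph_from_fr <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# all-pairs shortest path matrix; weights are lengths, Inf = unreachable.
# Small dense graphs use an in-R min-plus relaxation; larger ones go
# through igraph's Dijkstra.
shortest_paths_matrix <- function(g) {
  n <- n_nodes(g)
  if (n == 0) return(matrix(numeric(0), 0, 0))
  if (n <= 30) return(minplus_apsp(g$weights))
  ig <- igraph_from_fr(g)
  d <- igraph::distances(ig, algorithm = "dijkstra")
  d[g$nodes, g$nodes, drop = FALSE]
}

# vectorized Floyd-Warshall relaxation on a dense length matrix
minplus_apsp <- function(w) {
  D <- w
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(nrow(D))) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  D
}

#' Graph radius
#'
#' Treats edge weights as path lengths, computes all-pairs shortest paths,
#' takes each node's eccentricity (its maximum finite shortest-path length
#' to any reachable node) and returns the minimum eccentricity. On
#' disconnected graphs unreachable pairs are excluded from eccentricities
#' and `connected` is `FALSE`; an isolated node's eccentricity is `NA` and
#' does not enter the radius. A single-node graph has radius 0; the empty
#' graph gives `NA` (undefined).
#'
#' @param g An `fr_graph`.
#' @return A list with `radius`, named `eccentricities`, `n_nodes`,
#'   `connected`.
#' @export
graph_radius <- function(g) {
  stopifnot(inherits(g, "fr_graph"))
  n <- n_nodes(g)
  if (n == 0)
    return(list(radius = NA_real_, eccentricities = numeric(0),
                n_nodes = 0L, connected = FALSE))
  if (n == 1)
    return(list(radius = 0, eccentricities = setNames(0, g$nodes),
                n_nodes = 1L, connected = TRUE))
  d <- shortest_paths_matrix(g)
  diag(d) <- NA
  ecc <- apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (!length(fin)) NA_real_ else max(fin)
  })
  connected <- all(is.finite(d[upper.tri(d)]))
  radius <- if (all(is.na(ecc))) NA_real_ else min(ecc, na.rm = TRUE)
  list(radius = radius, eccentricities = ecc, n_nodes = as.integer(n),
       connected = connected)
}

# radius with the `< 2 nodes -> 0` convention used by resection differences
radius_or_zero <- function(g) {
  if (n_nodes(g) < 2) return(0)
  graph_radius(g)$radius
}

#' SOZ resection measures
#'
#' Three measures of the seizure onset zone relative to the resection:
#' * `soz_rr`: fraction of SOZ contacts inside the resection margins;
#' * `soz_radius`: radius of the complete Euclidean-distance network on all
#'   SOZ contacts (mm);
#' * `unresected_soz_radius`: `soz_radius` minus the radius of the network
#'   restricted to resected SOZ contacts (that restricted radius is 0 when
#'   fewer than two SOZ contacts were resected).
#'
#' @param patient An `fr_patient`.
#' @return Named list; all `NA` when the patient has no SOZ contacts.
#' @export
soz_measures <- function(patient) {
  ct <- patient$contacts
  soz <- ct[ct$soz, , drop = FALSE]
  if (nrow(soz) == 0)
    return(list(soz_rr = NA_real_, soz_radius = NA_real_,
                unresected_soz_radius = NA_real_))
  soz_rr <- sum(soz$resected) / nrow(soz)
  g_all <- euclidean_adjacency(ct, ct$soz)
  g_res <- euclidean_adjacency(ct, ct$soz & ct$resected)
  soz_radius <- radius_or_zero(g_all)
  list(soz_rr = soz_rr, soz_radius = soz_radius,
       unresected_soz_radius = soz_radius - radius_or_zero(g_res))
}

#' FR rate-distance adjacency
#'
#' Complete graph on the patient's FR-generating contacts (at least one
#' selected event) passing `node_mask`; the weight of edge (i, j) is the
#' mean of the two contacts' FR rates (events/min) times their Euclidean
#' distance (mm).
#'
#' @inheritParams select_events
#' @param node_mask As in [euclidean_adjacency()], applied on top of the
#'   FR-generating requirement.
#' @return An `fr_graph` with `rate_distance` semantics; empty when no
#'   FR-generating contact passes.
#' @export
rate_distance_adjacency <- function(patient,
                                    rule = selection_rule("fr_gt350"),
                                    node_mask = NULL) {
  cr <- contact_rates(patient, rule)
  keep <- cr$n_events > 0 & resolve_mask(patient$contacts, node_mask)
  sub <- patient$contacts[keep, , drop = FALSE]
  rates <- cr$rate_per_min[keep]
  d <- as.matrix(dist(sub[, c("x", "y", "z")]))
  w <- d * outer(rates, rates, function(a, b) (a + b) / 2)
  fr_graph(sub$contact_id, w, "rate_distance")
}

#' FR rate-distance radius difference
#'
#' Radius of the whole FR rate-distance network minus the radius of the
#' same network restricted to resected FR-generating contacts (restricted
#' radius 0 when fewer than two such contacts). An estimate of the residual
#' FR-generating tissue activity left outside the resection.
#'
#' @inheritParams select_events
#' @return Nonnegative number; `NA` when the patient has no FR-generating
#'   contact.
#' @export
rate_distance_radius_difference <- function(patient,
                                            rule = selection_rule("fr_gt350")) {
  g <- rate_distance_adjacency(patient, rule)
  if (n_nodes(g) == 0) return(NA_real_)
  res_ids <- patient$contacts$contact_id[patient$contacts$resected]
  radius_or_zero(g) - radius_or_zero(induced_fr_graph(g, res_ids))
}

#' FR distance radius difference (rate-unweighted control)
#'
#' As [rate_distance_radius_difference()] but with pure Euclidean distances
#' (mm) as edge weights, removing the rate weighting.
#'
#' @inheritParams select_events
#' @return Nonnegative number in mm; `NA` when no FR-generating contact.
#' @export
distance_radius_difference <- function(patient,
                                       rule = selection_rule("fr_gt350")) {
  cr <- contact_rates(patient, rule)
  keep <- cr$n_events > 0
  if (!any(keep)) return(NA_real_)
  g <- euclidean_adjacency(patient$contacts, keep)
  res_ids <- patient$contacts$contact_id[patient$contacts$resected]
  radius_or_zero(g) - radius_or_zero(induced_fr_graph(g, res_ids))
}
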