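#' @keywords internal
"_PACKAGE"

#' @importFrom stats median qchisq quantile rnorm rpois runif sd cor cor.test
#'   binom.test kmeans setNames dist
#' @importFrom utils write.csv read.csv head
NULL

EVENT_CLASSES <- c("fRonO", "fRonS", "RonO", "RonS")
GRAPH_SEMANTICS <- c("distance_mm", "rate_distance", "mutual_information_bits",
                     "unweighted")

#' Construct a contact table
#'
#' A contact is one SEEG recording site: a string id unique within the
#' patient, its electrode label, 3-D coordinates in millimetres
#' (normalized-atlas convention), and flags marking membership in the
#' clinically defined seizure onset zone (SOZ) and in the surgical
#' resection/ablation cavity.
#'
#' @param contact_id Character vector of per-patient-unique contact ids.
#' @param electrode Character vector of electrode labels.
#' @param x,y,z Numeric coordinates in mm.
#' @param soz Logical, contact in the seizure onset zone.
#' @param resected Logical, contact inside the resection margins.
#' @param anat_label Optional character anatomical label.
#' @return A `data.frame` with columns `contact_id`, `electrode`, `x`, `y`,
#'   `z`, `soz`, `resected`, `anat_label`.
#' @export
contact_table <- function(contact_id, electrode, x, y, z, soz, resected,
                          anat_label = NA_character_) {
  df <- data.frame(
    contact_id = as.character(contact_id),
    electrode = as.character(electrode),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    soz = as.logical(soz), resected = as.logical(resected),
    anat_label = as.character(anat_label),
    stringsAsFactors = FALSE
  )
  validate_contacts(df)
  df
}

validate_contacts <- function(df, who = "contacts") {
  req <- c("contact_id", "electrode", "x", "y", "z", "soz", "resected")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing columns: %s", who,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$contact_id))
    stop(sprintf("%s: duplicated contact_id: %s", who,
                 paste(unique(df$contact_id[duplicated(df$contact_id)]),
                       collapse = ", ")), call. = FALSE)
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) > 0 && !all(is.finite(coords)))
    stop(sprintf("%s: non-finite coordinates", who), call. = FALSE)
  if (any(is.na(df$soz)) || any(is.na(df$resected)))
    stop(sprintf("%s: soz/resected flags must be TRUE/FALSE", who),
         call. = FALSE)
  invisible(df)
}

#' Construct an event table
#'
#' One row per detected high-frequency oscillation: the contact that
#' recorded it, its onset time in seconds from recording start, its class
#' (fast ripple or ripple, on a background oscillation or on an epileptiform
#' spike), and its spectral frequency in Hz.
#'
#' @param contact_id Character vector.
#' @param onset_s Numeric onset times, seconds, non-negative.
#' @param event_class One of `"fRonO"`, `"fRonS"`, `"RonO"`, `"RonS"`.
#' @param freq_hz Positive spectral frequency in Hz.
#' @return A `data.frame` with those four columns.
#' @export
event_table <- function(contact_id, onset_s, event_class, freq_hz) {
  n <- length(onset_s)
  df <- data.frame(
    contact_id = rep_len(as.character(contact_id), n),
    onset_s = as.numeric(onset_s),
    event_class = rep_len(as.character(event_class), n),
    freq_hz = rep_len(as.numeric(freq_hz), n),
    stringsAsFactors = FALSE
  )
  validate_events(df)
  df
}

validate_events <- function(df, who = "events") {
  req <- c("contact_id", "onset_s", "event_class", "freq_hz")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing columns: %s", who,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  bad_class <- setdiff(unique(df$event_class), EVENT_CLASSES)
  if (length(bad_class))
    stop(sprintf("%s: unknown event_class: %s", who,
                 paste(bad_class, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(df$onset_s)) || any(df$onset_s < 0))
    stop(sprintf("%s: onset_s must be finite and >= 0", who), call. = FALSE)
  if (any(!is.finite(df$freq_hz)) || any(df$freq_hz <= 0))
    stop(sprintf("%s: freq_hz must be finite and > 0", who), call. = FALSE)
  invisible(df)
}

#' Construct a patient record
#'
#' Bundles one patient's contact table, event catalog, analyzed recording
#' duration and Engel post-operative outcome class. Validation enforces
#' referential integrity (every event's contact exists), event times inside
#' the recording, and warns when the analyzed duration falls outside the
#' 10-60 minute window typical of artifact-free non-REM sleep epochs.
#'
#' @param patient_id Character scalar.
#' @param contacts Contact table as from [contact_table()].
#' @param events Event table as from [event_table()].
#' @param duration_min Analyzed recording duration, minutes, > 0.
#' @param engel Integer Engel outcome class 1-4 (subclasses collapsed).
#' @param follow_up_months Optional follow-up length in months.
#' @return An object of class `fr_patient`.
#' @export
patient_record <- function(patient_id, contacts, events, duration_min, engel,
                           follow_up_months = NA_real_) {
  stopifnot(is.character(patient_id), length(patient_id) == 1)
  validate_contacts(contacts, who = paste0(patient_id, " contacts"))
  validate_events(events, who = paste0(patient_id, " events"))
  if (!is.numeric(duration_min) || length(duration_min) != 1 ||
      !is.finite(duration_min) || duration_min <= 0)
    stop(sprintf("%s: duration_min must be a positive number", patient_id),
         call. = FALSE)
  engel <- as.integer(engel)
  if (is.na(engel) || engel < 1L || engel > 4L)
    stop(sprintf("%s: engel must be an integer in 1..4", patient_id),
         call. = FALSE)
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(events$contact_id), contacts$contact_id)
    if (length(unknown))
      stop(sprintf("%s: events reference unknown contact_id: %s", patient_id,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    if (any(events$onset_s >= duration_min * 60))
      stop(sprintf("%s: event onset_s at or beyond recording end", patient_id),
           call. = FALSE)
  }
  if (duration_min < 10 || duration_min > 60)
    warning(sprintf("%s: duration_min = %g outside the usual 10-60 min window",
                    patient_id, duration_min), call. = FALSE)
  structure(
    list(patient_id = patient_id, contacts = contacts, events = events,
         duration_min = as.numeric(duration_min), engel = engel,
         follow_up_months = as.numeric(follow_up_months)),
    class = "fr_patient"
  )
}

#' Construct a cohort
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @return An object of class `fr_cohort` (a list of `fr_patient`).
#' @export
fr_cohort <- function(patients) {
  stopifnot(is.list(patients))
  ok <- vapply(patients, inherits, logical(1), what = "fr_patient")
  if (!all(ok)) stop("all elements must be fr_patient objects", call. = FALSE)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated patient_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  structure(list(patients = patients), class = "fr_cohort")
}

#' @export
print.fr_patient <- function(x, ...) {
  cat(sprintf("<fr_patient %s: %d contacts (%d SOZ, %d resected), %d events, %.1f min, Engel %d>\n",
              x$patient_id, nrow(x$contacts), sum(x$contacts$soz),
              sum(x$contacts$resected), nrow(x$events), x$duration_min,
              x$engel))
  invisible(x)
}

#' @export
print.fr_cohort <- function(x, ...) {
  cat(sprintf("<fr_cohort: %d patients>\n", length(x$patients)))
  invisible(x)
}

#' @export
length.fr_cohort <- function(x) length(x$patients)

#' Construct a weighted graph
#'
#' The package's one graph container: an ordered node set of contact ids
#' and a symmetric nonnegative weight matrix with a zero diagonal. A zero
#' weight means the edge is absent. `semantics` declares the units:
#' Euclidean distance in mm, rate-distance (mm x events/min), mutual
#' information in bits, or unweighted (0/1).
#'
#' @param nodes Character vector of node (contact) ids.
#' @param weights Numeric symmetric matrix, `length(nodes)` square.
#' @param semantics One of `"distance_mm"`, `"rate_distance"`,
#'   `"mutual_information_bits"`, `"unweighted"`.
#' @return An object of class `fr_graph`.
#' @export
fr_graph <- function(nodes, weights, semantics) {
  if (length(semantics) != 1 || !semantics %in% GRAPH_SEMANTICS)
    stop("semantics must be one of: ", paste(GRAPH_SEMANTICS, collapse = ", "),
         call. = FALSE)
  nodes <- as.character(nodes)
  n <- length(nodes)
  weights <- as.matrix(weights)
  if (n == 0) weights <- matrix(numeric(0), 0, 0)
  if (!all(dim(weights) == c(n, n)))
    stop("weights must be a square matrix matching nodes", call. = FALSE)
  if (n > 0) {
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and nonnegative", call. = FALSE)
    if (max(abs(weights - t(weights))) > 1e-9 * max(1, max(abs(weights))))
      stop("weights must be symmetric", call. = FALSE)
    weights <- (weights + t(weights)) / 2
    diag(weights) <- 0
  }
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, semantics = semantics),
            class = "fr_graph")
}

#' @export
print.fr_graph <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<fr_graph [%s]: %d nodes, %d edges>\n", x$semantics,
              length(x$nodes), n_edges))
  invisible(x)
}

#' Number of nodes / edges of an fr_graph
#' @param g An `fr_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) {
  if (n_nodes(g) < 2) return(0L)
  sum(g$weights[upper.tri(g$weights)] > 0)
}

#' Induced subgraph on a node subset
#'
#' @param g An `fr_graph`.
#' @param keep Character vector of node ids to keep.
#' @return An `fr_graph` on `intersect(g$nodes, keep)` preserving order and
#'   weights.
#' @export
induced_fr_graph <- function(g, keep) {
  idx <- g$nodes %in% keep
  fr_graph(g$nodes[idx], g$weights[idx, idx, drop = FALSE], g$semantics)
}
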