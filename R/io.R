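# On-disk cohort layout
# ---------------------
# dir/
#   cohort_manifest.json  {patients: [{patient_id, contacts, events,
#                                      duration_min, engel, follow_up_months}]}
#   <id>_contacts.csv     patient_id,contact_id,electrode,x_mm,y_mm,z_mm,
#                         soz,resected,anat_label
#   <id>_events.json      [{contact_id, onset_s, event_class, freq_hz}, ...]
# Field ordering and number formatting are fixed so that re-serialization of
# the same cohort is byte-stable.

CONTACT_CSV_COLS <- c("patient_id", "contact_id", "electrode", "x_mm", "y_mm",
                      "z_mm", "soz", "resected", "anat_label")

DEFAULT_EVENT_FIELD_MAP <- c(contact_id = "contact_id", onset_s = "onset_s",
                             event_class = "event_class", freq_hz = "freq_hz")

#' Write a cohort to a directory
#'
#' Serializes every patient to a contacts CSV and an events JSON, plus a
#' manifest listing the files and the per-patient metadata. The output is
#' byte-stable: writing the same cohort twice produces identical files.
#'
#' @param cohort An `fr_cohort`.
#' @param dir Output directory (created if absent).
#' @return Path to the written `cohort_manifest.json`, invisibly usable by
#'   [read_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  entries <- lapply(cohort$patients, function(p) {
    cfile <- paste0(p$patient_id, "_contacts.csv")
    efile <- paste0(p$patient_id, "_events.json")
    cdf <- data.frame(
      patient_id = rep(p$patient_id, nrow(p$contacts)),
      contact_id = p$contacts$contact_id,
      electrode = p$contacts$electrode,
      x_mm = fmt_num(p$contacts$x), y_mm = fmt_num(p$contacts$y),
      z_mm = fmt_num(p$contacts$z),
      soz = p$contacts$soz, resected = p$contacts$resected,
      anat_label = p$contacts$anat_label,
      stringsAsFactors = FALSE
    )
    write.csv(cdf, file.path(dir, cfile), row.names = FALSE, quote = TRUE,
              eol = "\n")
    ev <- p$events[, c("contact_id", "onset_s", "event_class", "freq_hz"),
                   drop = FALSE]
    jsonlite::write_json(ev, file.path(dir, efile), dataframe = "rows",
                         digits = NA, auto_unbox = FALSE, pretty = FALSE)
    list(patient_id = p$patient_id, contacts = cfile, events = efile,
         duration_min = p$duration_min, engel = p$engel,
         follow_up_months = p$follow_up_months)
  })
  manifest <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(list(patients = entries), manifest, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(manifest)
}

fmt_num <- function(x) {
  # shortest round-trip decimal representation, locale-independent
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE), character(1))
}

#' Read a cohort from a manifest
#'
#' Reads and validates a cohort written by [write_cohort()], or any
#' directory following the same layout. Catalogs exported from
#' document-style (e.g. MongoDB JSON) stores with different field names can
#' be ingested by supplying `event_field_map`, a named character vector
#' mapping the canonical names (`contact_id`, `onset_s`, `event_class`,
#' `freq_hz`) to the names found in the files.
#'
#' @param manifest_path Path to `cohort_manifest.json`.
#' @param event_field_map Named character vector; see Details.
#' @return An `fr_cohort`; schema violations abort with the offending
#'   patient and record named.
#' @export
read_cohort <- function(manifest_path,
                        event_field_map = DEFAULT_EVENT_FIELD_MAP) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  patients <- lapply(man$patients, function(e) {
    cpath <- file.path(dir, e$contacts)
    epath <- file.path(dir, e$events)
    for (f in c(cpath, epath))
      if (!file.exists(f))
        stop(sprintf("patient %s: missing file %s", e$patient_id, f),
             call. = FALSE)
    cdf <- read.csv(cpath, stringsAsFactors = FALSE,
                    colClasses = c(contact_id = "character",
                                   electrode = "character"))
    contacts <- data.frame(
      contact_id = cdf$contact_id, electrode = cdf$electrode,
      x = as.numeric(cdf$x_mm), y = as.numeric(cdf$y_mm),
      z = as.numeric(cdf$z_mm),
      soz = as.logical(cdf$soz), resected = as.logical(cdf$resected),
      anat_label = as.character(cdf$anat_label),
      stringsAsFactors = FALSE
    )
    ev_raw <- jsonlite::read_json(epath, simplifyVector = TRUE)
    events <- remap_events(ev_raw, event_field_map, e$patient_id)
    fup <- if (is.null(e$follow_up_months)) NA_real_
           else as.numeric(e$follow_up_months)
    patient_record(as.character(e$patient_id), contacts, events,
                   as.numeric(e$duration_min), as.integer(e$engel),
                   follow_up_months = fup)
  })
  fr_cohort(patients)
}

remap_events <- function(ev_raw, field_map, patient_id) {
  canon <- names(DEFAULT_EVENT_FIELD_MAP)
  if (!all(canon %in% names(field_map)))
    stop("event_field_map must name all of: ", paste(canon, collapse = ", "),
         call. = FALSE)
  if (is.null(ev_raw) || length(ev_raw) == 0 ||
      (is.data.frame(ev_raw) && nrow(ev_raw) == 0))
    return(event_table(character(0), numeric(0), character(0), numeric(0)))
  if (!is.data.frame(ev_raw))
    ev_raw <- as.data.frame(ev_raw, stringsAsFactors = FALSE)
  missing_fields <- setdiff(unname(field_map), names(ev_raw))
  if (length(missing_fields))
    stop(sprintf("patient %s: events missing fields: %s", patient_id,
                 paste(missing_fields, collapse = ", ")), call. = FALSE)
  event_table(ev_raw[[field_map[["contact_id"]]]],
              ev_raw[[field_map[["onset_s"]]]],
              ev_raw[[field_map[["event_class"]]]],
              ev_raw[[field_map[["freq_hz"]]]])
}
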