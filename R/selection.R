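SELECTION_MODES <- c("fr_gt350", "all_fr", "fr_on_ripples")

#' Event selection rules
#'
#' The analysis runs on fast-ripple events only; ripples (RonO/RonS) are
#' never selected. Two rules are supported:
#' * `fr_gt350`: fRonO with spectral frequency strictly above 350 Hz plus
#'   every fRonS regardless of frequency (fRonS are not frequency-filtered).
#' * `all_fr`: all fRonO and fRonS irrespective of frequency.
#'
#' `fr_on_ripples` (fast ripples superimposed on ripples) would require a
#' per-event co-occurrence annotation that plain catalogs do not carry, and
#' requesting it raises an error.
#'
#' @param mode One of `"fr_gt350"`, `"all_fr"`, `"fr_on_ripples"`.
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(mode = c("fr_gt350", "all_fr", "fr_on_ripples")) {
  if (length(mode) > 1) mode <- mode[1]
  if (!mode %in% SELECTION_MODES)
    stop("unknown selection mode: ", mode, call. = FALSE)
  structure(list(mode = mode), class = "selection_rule")
}

as_rule <- function(rule) {
  if (inherits(rule, "selection_rule")) rule else selection_rule(rule)
}

#' Select events under a rule
#'
#' @param patient An `fr_patient`.
#' @param rule A [selection_rule()] or its mode string.
#' @return The subset of `patient$events` satisfying the rule.
#' @export
select_events <- function(patient, rule = selection_rule("fr_gt350")) {
  rule <- as_rule(rule)
  ev <- patient$events
  if (rule$mode == "fr_on_ripples")
    stop("fr_on_ripples requires event co-occurrence annotations, ",
         "which plain catalogs do not carry", call. = FALSE)
  keep <- switch(rule$mode,
    fr_gt350 = (ev$event_class == "fRonO" & ev$freq_hz > 350) |
               ev$event_class == "fRonS",
    all_fr = ev$event_class %in% c("fRonO", "fRonS")
  )
  ev[keep, , drop = FALSE]
}

#' Fast ripple resection ratio
#'
#' The number of selected FR events on resected contacts divided by the
#' total number of selected FR events. Undefined (`NA`) when the patient
#' has no selected events.
#'
#' @inheritParams select_events
#' @return A fraction in \[0,1\], or `NA_real_` when undefined.
#' @export
resection_ratio <- function(patient, rule = selection_rule("fr_gt350")) {
  ev <- select_events(patient, rule)
  if (nrow(ev) == 0) return(NA_real_)
  res_ids <- patient$contacts$contact_id[patient$contacts$resected]
  sum(ev$contact_id %in% res_ids) / nrow(ev)
}

#' Per-contact FR event counts and rates
#'
#' @inheritParams select_events
#' @return A data.frame with one row per contact: `contact_id`, `n_events`,
#'   `rate_per_min` (= n_events / duration), `resected`, `soz`.
#' @export
contact_rates <- function(patient, rule = selection_rule("fr_gt350")) {
  ev <- select_events(patient, rule)
  counts <- table(factor(ev$contact_id,
                         levels = patient$contacts$contact_id))
  data.frame(
    contact_id = patient$contacts$contact_id,
    n_events = as.integer(counts),
    rate_per_min = as.numeric(counts) / patient$duration_min,
    resected = patient$contacts$resected,
    soz = patient$contacts$soz,
    stringsAsFactors = FALSE
  )
}

#' Spatial undersampling flag
#'
#' Flags patients whose implant may have missed the dominant FR generator:
#' among contacts with at least one selected event, no contact's FR rate
#' exceeds the mean rate plus three standard deviations. Rates are divided
#' by their within-patient maximum first (`normalize = TRUE`, the default);
#' the criterion is scale-invariant, so the raw-rate variant
#' (`normalize = FALSE`) gives the same answer and is kept only to make
#' that explicit.
#'
#' @inheritParams select_events
#' @param normalize Divide rates by their maximum before mean/SD.
#' @return `TRUE` when undersampling is suspected. Patients with fewer than
#'   two FR-generating contacts are flagged `TRUE` with a `reason`
#'   attribute.
#' @export
undersampling_flag <- function(patient, rule = selection_rule("fr_gt350"),
                               normalize = TRUE) {
  cr <- contact_rates(patient, rule)
  r <- cr$rate_per_min[cr$n_events > 0]
  if (length(r) < 2)
    return(structure(TRUE, reason = "fewer than 2 FR-generating contacts"))
  if (normalize) r <- r / max(r)
  !any(r > mean(r) + 3 * sd(r))
}

#' Within-patient rate percentile (linear interpolation)
#'
#' Percentile of per-contact FR rates with linear interpolation between
#' order statistics (the convention of MATLAB's `prctile`, equivalent to
#' `quantile(type = 5)`): the k-th of n sorted values sits at percentile
#' 100*(k - 0.5)/n and values between are interpolated linearly, clamped at
#' the extremes.
#'
#' @param x Numeric vector.
#' @param pct Percentile in \[0,100\].
#' @return The percentile value.
#' @export
rate_percentile <- function(x, pct) {
  stopifnot(pct >= 0, pct <= 100)
  as.numeric(quantile(x, pct / 100, type = 5, names = FALSE))
}

#' Percentile-removal outcome test
#'
#' `TRUE` iff every contact whose FR rate strictly exceeds the
#' within-patient `pct`-th percentile of contact rates (over FR-generating
#' contacts) was resected — i.e. the high-rate tail was completely removed.
#'
#' @inheritParams select_events
#' @param pct Percentile in \[0,100\].
#' @return Logical; `NA` when the patient has no FR-generating contact.
#' @export
percentile_removal_test <- function(patient,
                                    rule = selection_rule("fr_gt350"),
                                    pct = 95) {
  cr <- contact_rates(patient, rule)
  cr <- cr[cr$n_events > 0, , drop = FALSE]
  if (nrow(cr) == 0) return(NA)
  cutoff <- rate_percentile(cr$rate_per_min, pct)
  above <- cr$rate_per_min > cutoff
  all(cr$resected[above])
}
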