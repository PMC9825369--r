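# Directed FR propagation between contact pairs: collect all cross-pair
# onset delays closer than a window (full cross product, not one-to-one
# matching), then ask with an exact two-sided sign test whether the delays
# are systematically one-sided.

#' Cross-pair onset delays between two trains
#'
#' Every ordered pair (i from `a`, j from `b`) whose onsets differ by less
#' than `window_ms` contributes the signed delay `b[j] - a[i]` in
#' milliseconds. A positive delay means the `b` event follows the `a`
#' event.
#'
#' @param a,b Sorted onset-time vectors (seconds).
#' @param window_ms Pairing window, default 250 ms.
#' @return Numeric vector of signed delays (ms), possibly empty.
#' @export
onset_delays <- function(a, b, window_ms = 250) {
  check_train(a); check_train(b)
  if (!length(a) || !length(b)) return(numeric(0))
  d <- outer(a, b, function(x, y) (y - x) * 1000)
  as.numeric(d[abs(d) < window_ms])
}

#' Exact sign test for a propagation delay
#'
#' Two-sided exact binomial sign test on the signs of the delays (zero
#' delays discarded, following the usual sign-test convention).
#' `direction = "a_leads"` when positive delays are the majority.
#'
#' @param delays Signed delays in ms.
#' @param alpha Significance level, default 0.005.
#' @return List with `significant`, `p`, `direction`, `n`,
#'   `median_delay_ms`; or with `insufficient = TRUE` when no nonzero delay
#'   exists.
#' @export
sign_test_propagation <- function(delays, alpha = 0.005) {
  nz <- delays[delays != 0]
  if (!length(nz))
    return(list(insufficient = TRUE, significant = FALSE, p = NA_real_,
                direction = NA_character_, n = 0L,
                median_delay_ms = NA_real_))
  n_pos <- sum(nz > 0)
  p <- binom.test(n_pos, length(nz), p = 0.5)$p.value
  list(insufficient = FALSE,
       significant = p < alpha,
       p = p,
       direction = if (n_pos * 2 > length(nz)) "a_leads" else "b_leads",
       n = length(nz),
       median_delay_ms = median(nz))
}

#' Significant FR propagation edges in a patient
#'
#' Builds per-contact fRonO trains (after applying the selection rule and
#' keeping only fRonO events), tests every unordered contact pair once,
#' and returns the pairs whose delay distribution is significant. The
#' leading contact becomes `out_node`.
#'
#' @inheritParams select_events
#' @param alpha Sign-test threshold, default 0.005 (no multiple-comparison
#'   correction; the fixed threshold is the test).
#' @param window_ms Pairing window in ms.
#' @param soz_only Restrict tested contacts to SOZ members.
#' @return data.frame with columns `out_node`, `in_node`, `n_pairs`,
#'   `median_delay_ms`, `p_value`, `out_resected` (zero rows when nothing
#'   is significant).
#' @export
propagation_edges <- function(patient, rule = selection_rule("fr_gt350"),
                              alpha = 0.005, window_ms = 250,
                              soz_only = FALSE) {
  ev <- select_events(patient, rule)
  ev <- ev[ev$event_class == "fRonO", , drop = FALSE]
  ct <- patient$contacts
  ids <- ct$contact_id
  if (soz_only) ids <- ids[ct$soz]
  ids <- ids[ids %in% unique(ev$contact_id)]
  trains <- lapply(ids, function(id)
    unique(sort(ev$onset_s[ev$contact_id == id])))
  out <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        delays <- onset_delays(trains[[i]], trains[[j]], window_ms)
        st <- sign_test_propagation(delays, alpha)
        if (isTRUE(st$significant) && st$median_delay_ms != 0) {
          lead <- if (st$direction == "a_leads") ids[i] else ids[j]
          folw <- if (st$direction == "a_leads") ids[j] else ids[i]
          out[[length(out) + 1L]] <- data.frame(
            out_node = lead, in_node = folw, n_pairs = st$n,
            median_delay_ms = abs(st$median_delay_ms), p_value = st$p,
            out_resected = ct$resected[match(lead, ct$contact_id)],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(out_node = character(0), in_node = character(0),
                      n_pairs = integer(0), median_delay_ms = numeric(0),
                      p_value = numeric(0), out_resected = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cohort propagation resection coverage
#'
#' Per patient: the number of significant propagation edges, how many of
#' their leading (out) contacts were resected, and the coverage fraction
#' (undefined, `NA`, when the patient has no edge — most patients, since
#' propagation that survives the sign test is rare).
#'
#' @param cohort An `fr_cohort`.
#' @inheritParams propagation_edges
#' @return data.frame with one row per patient: `patient_id`, `engel`,
#'   `n_edges`, `n_out_resected`, `coverage`.
#' @export
propagation_resection_summary <- function(cohort,
                                          rule = selection_rule("fr_gt350"),
                                          alpha = 0.005, window_ms = 250,
                                          soz_only = FALSE) {
  rows <- lapply(cohort$patients, function(p) {
    e <- propagation_edges(p, rule, alpha, window_ms, soz_only)
    n <- nrow(e)
    data.frame(patient_id = p$patient_id, engel = p$engel,
               n_edges = n, n_out_resected = sum(e$out_resected),
               coverage = if (n > 0) sum(e$out_resected) / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
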