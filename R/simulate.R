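# Synthetic SEEG cohort generator
#
# Emulates the statistical structure the downstream analysis assumes:
# linear depth-electrode arrays (5 mm contact pitch) placed randomly in a
# 140 mm cube, background contacts emitting sparse homogeneous Poisson FR
# trains, a spatially clustered minority of "hot" pathological contacts
# with high heterogeneous rates, temporal coupling of hot contacts through
# a shared mother point process with Gaussian timing jitter, optional
# directed propagation pairs with a fixed lag, a resection mask removing
# the highest-rate hot contacts first, and Engel outcome classes optionally
# tied to the residual (unresected) hot-contact rate mass.

#' Simulation parameters for a synthetic SEEG cohort
#'
#' @param n_patients Number of patients.
#' @param n_electrodes Electrodes per patient; scalar or range, default 8-16.
#' @param contacts_per_electrode Contacts per electrode; scalar or range,
#'   default 7-15.
#' @param duration_min Analyzed recording minutes; scalar or range,
#'   default 10-60.
#' @param base_rate_per_min FR rate of background contacts (events/min).
#' @param hot_rate_per_min Geometric-mean FR rate of pathological ("hot")
#'   contacts; per-contact rates are log-normally dispersed around it.
#' @param n_hot Number of hot contacts per patient.
#' @param n_periphery Moderate-rate contacts adjacent to the focus that
#'   share the mother process (at `periphery_rho_factor` times the hot
#'   coupling, `periphery_rate_factor` times the hot rate) but carry no
#'   pathological rate mass and are not resection targets; they give the
#'   MI network its unresected fringe.
#' @param periphery_rate_factor,periphery_rho_factor See `n_periphery`.
#' @param coupling_rho Fraction in \[0,1\] of mother-process events shared by
#'   the most strongly coupled hot contact; coupling decays toward the
#'   lowest-rate hot contact.
#' @param jitter_ms SD of the Gaussian timing jitter (truncated at 3 SD)
#'   applied to shared events, milliseconds.
#' @param prop_lag_ms Propagation lag for directed pairs, ms (< 250).
#' @param prop_jitter_ms SD of the lag jitter, ms.
#' @param n_prop_pairs Directed propagation pairs per patient (among hot
#'   contacts), default 0.
#' @param secondary_focus_frac Fraction of hot contacts forming a second,
#'   spatially distant focus of desynchronized (uncoupled) high-rate FR
#'   generators; resection reaches them last, so they dominate the
#'   residual burden of incomplete resections.
#' @param resect_coverage Fraction of hot contacts inside the resection;
#'   scalar or per-patient sampling range, default 0.3-0.95.
#' @param outcome_rule `"coupled"` assigns Engel class by cohort quartile of
#'   residual unresected hot-contact rate mass; `"random"` assigns Engel
#'   uniformly.
#' @param freq_mix Fraction of fRonO events with spectral frequency
#'   above 350 Hz.
#' @param seed Integer RNG seed (mandatory).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_patients = 20,
                       n_electrodes = c(8, 16),
                       contacts_per_electrode = c(7, 15),
                       duration_min = c(10, 60),
                       base_rate_per_min = 0.005,
                       hot_rate_per_min = 8,
                       n_hot = 15,
                       n_periphery = 5,
                       periphery_rate_factor = 0.45,
                       periphery_rho_factor = 0.5,
                       coupling_rho = 0.8,
                       jitter_ms = 15,
                       prop_lag_ms = 30,
                       prop_jitter_ms = 5,
                       n_prop_pairs = 0,
                       secondary_focus_frac = 0.2,
                       resect_coverage = c(0.3, 0.95),
                       outcome_rule = c("coupled", "random"),
                       freq_mix = 0.6,
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  outcome_rule <- match.arg(outcome_rule)
  as_range <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      stop(nm, " must be a scalar or an increasing length-2 range",
           call. = FALSE)
    x
  }
  p <- list(
    n_patients = as.integer(n_patients),
    n_electrodes = as_range(n_electrodes, "n_electrodes"),
    contacts_per_electrode = as_range(contacts_per_electrode,
                                      "contacts_per_electrode"),
    duration_min = as_range(duration_min, "duration_min"),
    base_rate_per_min = as.numeric(base_rate_per_min),
    hot_rate_per_min = as.numeric(hot_rate_per_min),
    n_hot = as.integer(n_hot),
    n_periphery = as.integer(n_periphery),
    periphery_rate_factor = as.numeric(periphery_rate_factor),
    periphery_rho_factor = as.numeric(periphery_rho_factor),
    coupling_rho = as.numeric(coupling_rho),
    jitter_ms = as.numeric(jitter_ms),
    prop_lag_ms = as.numeric(prop_lag_ms),
    prop_jitter_ms = as.numeric(prop_jitter_ms),
    n_prop_pairs = as.integer(n_prop_pairs),
    secondary_focus_frac = as.numeric(secondary_focus_frac),
    resect_coverage = as_range(resect_coverage, "resect_coverage"),
    outcome_rule = outcome_rule,
    freq_mix = as.numeric(freq_mix),
    seed = as.integer(seed)
  )
  for (nm in c("coupling_rho", "freq_mix", "secondary_focus_frac"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be in [0,1]", call. = FALSE)
  if (any(p$resect_coverage < 0) || any(p$resect_coverage > 1))
    stop("resect_coverage must be in [0,1]", call. = FALSE)
  if (p$base_rate_per_min < 0 || p$hot_rate_per_min < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (p$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (p$prop_lag_ms >= 250)
    stop("prop_lag_ms must be < 250", call. = FALSE)
  class(p) <- "sim_params"
  p
}

rint <- function(rng) {
  if (rng[1] == rng[2]) as.integer(rng[1])
  else sample(seq.int(rng[1], rng[2]), 1L)
}

# truncated (3 SD) Gaussian jitter, seconds
jitter_s <- function(n, sd_ms) {
  if (sd_ms <= 0 || n == 0) return(rep(0, n))
  z <- rnorm(n)
  z[z > 3] <- 3; z[z < -3] <- -3
  z * sd_ms / 1000
}

pois_train <- function(rate_per_min, duration_min) {
  n <- rpois(1, rate_per_min * duration_min)
  sort(runif(n, 0, duration_min * 60))
}

# freq draw: fRonO spectral frequency, `p_hi` above 350 Hz
draw_freq <- function(n, p_hi) {
  hi <- runif(n) < p_hi
  ifelse(hi, runif(n, 351, 600), runif(n, 200, 349))
}

#' Generate a synthetic cohort
#'
#' Fully reproducible: the same `sim_params` (same seed) gives an identical
#' cohort. Geometry, rates, coupling and the resection mask follow the
#' scheme described in the package vignette; see [sim_params()] for the
#' knobs.
#'
#' @param params A [sim_params()] object.
#' @return An `fr_cohort`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  patients <- lapply(seq_len(params$n_patients), function(i)
    generate_patient(params, sprintf("P%03d", i)))
  residual <- vapply(patients, function(p) attr(p, "residual_mass"),
                     numeric(1))
  engel <- switch(params$outcome_rule,
    coupled = engel_by_quartile(residual),
    random = sample(1:4, length(patients), replace = TRUE)
  )
  patients <- Map(function(p, e) { p$engel <- as.integer(e); p },
                  patients, engel)
  fr_cohort(patients)
}

engel_by_quartile <- function(residual) {
  # rank-quartile assignment; ties broken by order so classes stay
  # near-balanced even for small cohorts
  r <- rank(residual, ties.method = "first")
  pmin(4L, pmax(1L, as.integer(ceiling(4 * r / length(r)))))
}

generate_patient <- function(params, patient_id) {
  n_e <- rint(params$n_electrodes)
  dur <- runif(1, params$duration_min[1], params$duration_min[2])
  # linear electrode arrays, 5 mm pitch, random entry and direction
  contacts <- do.call(rbind, lapply(seq_len(n_e), function(e) {
    n_c <- rint(params$contacts_per_electrode)
    entry <- runif(3, 0, 140)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    depth <- (seq_len(n_c) - 1) * 5
    data.frame(
      contact_id = sprintf("E%02d-%02d", e, seq_len(n_c)),
      electrode = sprintf("E%02d", e),
      x = entry[1] + depth * dirv[1],
      y = entry[2] + depth * dirv[2],
      z = entry[3] + depth * dirv[3],
      stringsAsFactors = FALSE
    )
  }))
  n_total <- nrow(contacts)
  n_hot <- params$n_hot
  if (n_hot > n_total)
    stop(sprintf("%s: n_hot (%d) exceeds total contacts (%d)", patient_id,
                 n_hot, n_total), call. = FALSE)

  # primary focus: a compact coupled pathological zone; secondary focus: a
  # distant set of desynchronized high-rate generators (uncoupled trains)
  # that the resection reaches last; periphery: the contacts just outside
  # the primary zone, sharing the mother process at moderate strength
  n_hot2 <- min(round(params$secondary_focus_frac * n_hot), n_hot - 1L)
  n_hot2 <- max(n_hot2, 0L)
  n_hot1 <- n_hot - n_hot2
  xyz <- as.matrix(contacts[, c("x", "y", "z")])
  focus <- xyz[sample.int(n_total, 1), ]
  d_focus <- sqrt(colSums((t(xyz) - focus)^2))
  hot1_idx <- order(d_focus)[seq_len(n_hot1)]
  hot2_idx <- integer(0)
  if (n_hot2 > 0) {
    far <- which(d_focus >= median(d_focus))
    focus2 <- xyz[far[sample.int(length(far), 1)], ]
    d_focus2 <- sqrt(colSums((t(xyz) - focus2)^2))
    d_focus2[hot1_idx] <- Inf
    hot2_idx <- order(d_focus2)[seq_len(n_hot2)]
  }
  hot_idx <- c(hot1_idx, hot2_idx)   # resection order: primary zone first
  is_hot <- seq_len(n_total) %in% hot_idx
  n_per <- min(params$n_periphery, n_total - n_hot)
  d_per <- d_focus; d_per[hot_idx] <- Inf
  per_idx <- order(d_per)[seq_len(n_per)]

  # primary-zone rates arise from the coupling itself: each contact
  # re-emits a thinned copy of the mother process (participation rho_i
  # decaying away from the focus) plus a small independent background, so
  # the strongest coupled generators are also the most synchronized;
  # secondary-zone contacts fire at comparable rates but independently
  rank_frac <- if (n_hot1 > 1) (n_hot1 - seq_len(n_hot1)) / (n_hot1 - 1)
               else rep(1, n_hot1)
  rho_i <- pmin(1, params$coupling_rho * (0.5 + 0.5 * rank_frac) *
                  exp(rnorm(n_hot1, 0, 0.1)))
  indep1 <- 0.1 * params$hot_rate_per_min * exp(rnorm(n_hot1, 0, 0.3))
  rates1 <- rho_i * params$hot_rate_per_min + indep1
  rates2 <- params$hot_rate_per_min * runif(n_hot2, 0.4, 0.6)
  hot_rates <- c(rates1, rates2)     # aligned with hot_idx

  # events carry (onset, class, frequency); shared mother events keep one
  # class/frequency draw at every contact that re-emits them, since a
  # synchronized FR event has coherent spectral content across sites
  draw_marks <- function(n) {
    is_ono <- runif(n) < 0.8
    freq <- numeric(n)
    freq[is_ono] <- draw_freq(sum(is_ono), params$freq_mix)
    freq[!is_ono] <- runif(sum(!is_ono), 200, 600)
    data.frame(event_class = ifelse(is_ono, "fRonO", "fRonS"),
               freq_hz = freq, stringsAsFactors = FALSE)
  }
  marked_train <- function(onsets, marks) {
    data.frame(onset_s = onsets, marks, stringsAsFactors = FALSE)
  }
  rand_train <- function(rate) {
    t <- pois_train(rate, dur)
    marked_train(t, draw_marks(length(t)))
  }
  clip_sort <- function(tr) {
    tr <- tr[tr$onset_s > 0 & tr$onset_s < dur * 60, , drop = FALSE]
    tr[order(tr$onset_s), , drop = FALSE]
  }

  mother <- pois_train(params$hot_rate_per_min, dur)
  mother_marks <- draw_marks(length(mother))
  trains <- vector("list", n_total)
  empty_tr <- marked_train(numeric(0), draw_marks(0))
  for (k in seq_len(n_total)) trains[[k]] <- empty_tr
  # timing jitter grows away from the core: the strongest generators are
  # the most tightly synchronized, outer hot contacts progressively less
  jit_i <- params$jitter_ms * (1 + 3 * (1 - rank_frac))
  for (j in seq_len(n_hot1)) {
    k <- hot1_idx[j]
    keep <- runif(length(mother)) < rho_i[j]
    shared <- marked_train(mother[keep] + jitter_s(sum(keep), jit_i[j]),
                           mother_marks[keep, , drop = FALSE])
    trains[[k]] <- clip_sort(rbind(shared, rand_train(indep1[j])))
  }
  for (j in seq_len(n_hot2))
    trains[[hot2_idx[j]]] <- clip_sort(rand_train(rates2[j]))
  per_rate <- params$hot_rate_per_min * params$periphery_rate_factor
  # shared fraction capped so the periphery rate stays at per_rate
  rho_p <- min(params$coupling_rho * params$periphery_rho_factor,
               per_rate / max(params$hot_rate_per_min, 1e-12))
  for (k in per_idx) {
    keep <- runif(length(mother)) < rho_p
    shared <- marked_train(mother[keep] + jitter_s(sum(keep),
                                                   params$jitter_ms),
                           mother_marks[keep, , drop = FALSE])
    indep_rate <- max(0, per_rate - rho_p * params$hot_rate_per_min)
    trains[[k]] <- clip_sort(rbind(shared, rand_train(indep_rate)))
  }
  bg_idx <- which(!is_hot & !(seq_len(n_total) %in% per_idx))
  for (k in bg_idx) trains[[k]] <- clip_sort(rand_train(params$base_rate_per_min))

  # directed propagation pairs: follower re-emits the leader's train
  prop_pairs <- list()
  if (params$n_prop_pairs > 0 && n_hot >= 2) {
    n_pp <- min(params$n_prop_pairs, floor(n_hot / 2))
    perm <- sample(hot_idx)
    for (q in seq_len(n_pp)) {
      a <- perm[2 * q - 1]; b <- perm[2 * q]
      fol <- trains[[a]]
      fol$onset_s <- fol$onset_s + params$prop_lag_ms / 1000 +
        jitter_s(nrow(fol), params$prop_jitter_ms)
      trains[[b]] <- clip_sort(fol)
      prop_pairs[[q]] <- c(contacts$contact_id[a], contacts$contact_id[b])
    }
  }

  # resection: coverage drives both zones at once — the primary zone is
  # resected proportionally (strongest, focus-nearest contacts first) and
  # each secondary-zone contact falls once coverage clears its own
  # threshold, so more extensive surgeries progressively reach the distant
  # generators; each resected contact drags in its nearest neighbor
  coverage <- runif(1, params$resect_coverage[1], params$resect_coverage[2])
  k1 <- floor(coverage * n_hot1)
  res_hot <- hot1_idx[seq_len(k1)]
  if (n_hot2 > 0) {
    tau <- runif(n_hot2, 0.55, 0.95)
    res_hot <- c(res_hot, hot2_idx[coverage >= tau])
  }
  resected <- rep(FALSE, n_total)
  if (length(res_hot) > 0) {
    resected[res_hot] <- TRUE
    for (k in res_hot) {
      d <- sqrt(colSums((t(xyz) - xyz[k, ])^2))
      d[k] <- Inf
      resected[which.min(d)] <- TRUE
    }
  }

  events <- do.call(rbind, lapply(seq_len(n_total), function(k) {
    tr <- trains[[k]]
    if (!nrow(tr)) return(NULL)
    data.frame(contact_id = contacts$contact_id[k], tr,
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- event_table(character(0), numeric(0), character(0), numeric(0))
  events <- events[order(events$onset_s, events$contact_id), , drop = FALSE]
  rownames(events) <- NULL

  ctab <- data.frame(contacts,
                     soz = is_hot, resected = resected,
                     anat_label = NA_character_, stringsAsFactors = FALSE)
  rec <- patient_record(patient_id, ctab, events, dur, engel = 1L)
  attr(rec, "residual_mass") <- sum(hot_rates[!resected[hot_idx]])
  attr(rec, "prop_pairs") <- prop_pairs
  rec
}

#' Generate one coupled event-train pair
#'
#' Train A is a homogeneous Poisson mother process; train B re-emits a
#' fraction `coupling_rho` of A's events with truncated-Gaussian timing
#' jitter plus an independent Poisson background that keeps B's total rate
#' near `rate_per_min`. `coupling_rho = 1, jitter_ms = 0` gives identical
#' trains; `coupling_rho = 0` gives independent trains.
#'
#' @param rate_per_min Event rate per minute.
#' @param coupling_rho Shared-event fraction in \[0,1\].
#' @param jitter_ms Jitter SD in ms.
#' @param duration_min Duration in minutes.
#' @param seed Integer seed.
#' @return List with sorted onset vectors `a` and `b` (seconds).
#' @export
make_coupled_pair <- function(rate_per_min, coupling_rho, jitter_ms,
                              duration_min, seed) {
  stopifnot(coupling_rho >= 0, coupling_rho <= 1, rate_per_min >= 0,
            duration_min > 0)
  set.seed(as.integer(seed))
  a <- pois_train(rate_per_min, duration_min)
  keep <- runif(length(a)) < coupling_rho
  shared <- a[keep] + jitter_s(sum(keep), jitter_ms)
  b <- sort(c(shared, pois_train(rate_per_min * (1 - coupling_rho),
                                 duration_min)))
  b <- b[b > 0 & b < duration_min * 60]
  list(a = a, b = b)
}

#' Generate one propagating event-train pair
#'
#' Train B repeats train A's events after a fixed lag with truncated
#' Gaussian jitter, emulating directed FR propagation between two contacts.
#'
#' @param rate_per_min Event rate per minute.
#' @param lag_ms Propagation lag in ms (must be < 250).
#' @param lag_jitter_ms Jitter SD of the lag in ms.
#' @param duration_min Duration in minutes.
#' @param seed Integer seed.
#' @return List with sorted onset vectors `a` (leading) and `b` (following).
#' @export
make_propagating_pair <- function(rate_per_min, lag_ms, lag_jitter_ms,
                                  duration_min, seed) {
  stopifnot(lag_ms < 250, rate_per_min >= 0, duration_min > 0)
  set.seed(as.integer(seed))
  a <- pois_train(rate_per_min, duration_min)
  b <- a + lag_ms / 1000 + jitter_s(length(a), lag_jitter_ms)
  b <- sort(b[b > 0 & b < duration_min * 60])
  list(a = a, b = b)
}
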