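# Outcome statistics: Spearman correlation with merged Engel classes, ROC
# analysis with Youden's J operating point and exact binomial CIs,
# imputation of indeterminate patients, reflex (two-stage) testing, and
# k-means clustering of (rate, local efficiency) node features.

#' Measure specification
#'
#' Declares, before any ROC is computed, which direction of a measure
#' predicts the positive outcome (e.g. a larger FR resection ratio, a
#' lower rate-distance radius difference, a larger MI graph metric all
#' predict seizure freedom).
#'
#' @param name Measure name.
#' @param polarity `"higher_predicts_positive"` or
#'   `"lower_predicts_positive"`.
#' @return A `measure_spec` object.
#' @export
measure_spec <- function(name,
                         polarity = c("higher_predicts_positive",
                                      "lower_predicts_positive")) {
  polarity <- match.arg(polarity)
  structure(list(name = name, polarity = polarity), class = "measure_spec")
}

#' Outcome labels from Engel classes
#'
#' Two binary definitions: `seizure_free` (Engel 1 vs 2-4) and `improved`
#' (Engel 1-3 vs 4).
#'
#' @param engel Integer vector of Engel classes 1-4.
#' @param definition `"seizure_free"` or `"improved"`.
#' @return Logical vector, `TRUE` = positive outcome.
#' @export
outcome_labels <- function(engel, definition = c("seizure_free", "improved")) {
  definition <- match.arg(definition)
  stopifnot(all(engel %in% 1:4))
  if (definition == "seizure_free") engel == 1 else engel <= 3
}

#' Spearman correlation of a measure with Engel outcome
#'
#' Engel 2 and 3 are merged into one ordinal level (1 < 2/3 < 4) before
#' ranking. Reports the tie-corrected Spearman rho with its two-sided
#' asymptotic p value, plus the squared Pearson correlation of the same
#' pairs as `r2`.
#'
#' @param values Per-patient measure values (`NA` allowed; dropped).
#' @param engel Per-patient Engel classes 1-4.
#' @return List with `rho`, `p`, `r2`, `n`; `rho` is `NA` for constant
#'   values or fewer than 3 usable patients.
#' @export
spearman_outcome <- function(values, engel) {
  stopifnot(length(values) == length(engel))
  ok <- !is.na(values) & !is.na(engel)
  v <- values[ok]
  e <- engel[ok]
  e <- ifelse(e %in% c(2, 3), 2.5, as.numeric(e))  # merge E2/E3
  if (length(v) < 3 || length(unique(v)) < 2 || length(unique(e)) < 2)
    return(list(rho = NA_real_, p = NA_real_, r2 = NA_real_,
                n = length(v)))
  ct <- suppressWarnings(cor.test(v, e, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       r2 = cor(v, e)^2, n = length(v))
}

#' ROC analysis with Youden operating point
#'
#' Orients the values by the declared polarity, sweeps every threshold,
#' and reports the empirical ROC, its trapezoidal AUC (identical to the
#' all-pairs concordance statistic with ties counted 1/2), the Youden
#' threshold (maximum sensitivity + specificity - 1; ties broken toward
#' higher specificity), and the confusion matrix at that threshold with
#' exact Clopper-Pearson 95% CIs on sensitivity, specificity, PPV, NPV and
#' accuracy. Patients with `NA` values are indeterminate: they never enter
#' the ROC and are folded into the confusion matrix according to
#' `impute_rule` (see [impute_indeterminate()]).
#'
#' @param values Per-patient measure values (`NA` = indeterminate).
#' @param labels Logical outcome labels (`TRUE` = positive).
#' @param spec A [measure_spec()].
#' @param impute_rule `"as_misclassified"`, `"as_test_negative"` or
#'   `"exclude"`.
#' @return A `diagnostic_result` list: `auc`, `roc` (data.frame fpr, tpr,
#'   threshold), `youden_threshold`, `youden_j`, `confusion` (tp, fp, fn,
#'   tn), `metrics` (point estimates and CIs), `n_indeterminate`,
#'   `impute_rule`, `spec`.
#' @export
roc_analysis <- function(values, labels, spec,
                         impute_rule = c("as_misclassified",
                                         "as_test_negative", "exclude")) {
  stopifnot(inherits(spec, "measure_spec"),
            length(values) == length(labels))
  impute_rule <- match.arg(impute_rule)
  labels <- as.logical(labels)
  det <- !is.na(values)
  v <- values[det]
  l <- labels[det]
  if (length(unique(l)) < 2)
    stop("both outcome classes must be present among determinate patients",
         call. = FALSE)
  flip <- spec$polarity == "lower_predicts_positive"
  ov <- if (flip) -v else v

  # empirical ROC over all thresholds (call positive when oriented value
  # >= threshold), descending thresholds
  thr <- c(Inf, sort(unique(ov), decreasing = TRUE))
  n_pos <- sum(l); n_neg <- sum(!l)
  tpr <- vapply(thr, function(t) sum(ov >= t & l) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(ov >= t & !l) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)

  j <- tpr - fpr
  best <- which(j == max(j))[1]  # thresholds descend, so the first maximum
                                 # is the highest threshold = fewest
                                 # positives = highest specificity
  youden_thr_oriented <- thr[best]
  youden_threshold <- if (flip) -youden_thr_oriented else youden_thr_oriented

  pos_call <- ov >= youden_thr_oriented
  conf <- list(tp = sum(pos_call & l), fp = sum(pos_call & !l),
               fn = sum(!pos_call & l), tn = sum(!pos_call & !l))
  n_ind <- sum(!det)
  conf <- impute_indeterminate(conf, labels[!det], impute_rule)

  metrics <- confusion_metrics(conf)
  structure(list(
    auc = auc,
    roc = data.frame(fpr = fpr, tpr = tpr, threshold = if (flip) -thr else thr),
    youden_threshold = youden_threshold,
    youden_j = max(j),
    confusion = conf,
    metrics = metrics,
    n_indeterminate = n_ind,
    impute_rule = impute_rule,
    spec = spec
  ), class = "diagnostic_result")
}

#' Fold indeterminate patients into a confusion matrix
#'
#' * `as_misclassified`: indeterminate positives count as false negatives
#'   and indeterminate negatives as false positives (conservative);
#' * `as_test_negative`: indeterminates are called test-negative
#'   (positives become FN, negatives TN);
#' * `exclude`: indeterminates are dropped (the denominator shrinks).
#'
#' @param conf List with counts `tp`, `fp`, `fn`, `tn`.
#' @param ind_labels Logical outcome labels of the indeterminate patients.
#' @param rule Imputation rule.
#' @return Adjusted counts list with an `n_excluded` element.
#' @export
impute_indeterminate <- function(conf, ind_labels,
                                 rule = c("as_misclassified",
                                          "as_test_negative", "exclude")) {
  rule <- match.arg(rule)
  n_pos <- sum(ind_labels); n_neg <- sum(!ind_labels)
  conf$n_excluded <- 0L
  if (rule == "as_misclassified") {
    conf$fn <- conf$fn + n_pos
    conf$fp <- conf$fp + n_neg
  } else if (rule == "as_test_negative") {
    conf$fn <- conf$fn + n_pos
    conf$tn <- conf$tn + n_neg
  } else {
    conf$n_excluded <- n_pos + n_neg
  }
  conf
}

clopper_pearson <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n)$conf.int)
}

confusion_metrics <- function(conf) {
  with(conf, {
    one <- function(x, n) {
      ci <- clopper_pearson(x, n)
      list(estimate = if (n > 0) x / n else NA_real_,
           ci_lo = ci[1], ci_hi = ci[2])
    }
    list(sensitivity = one(tp, tp + fn),
         specificity = one(tn, tn + fp),
         ppv = one(tp, tp + fp),
         npv = one(tn, tn + fn),
         accuracy = one(tp + tn, tp + fp + fn + tn))
  })
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic_result %s: AUC %.3f, Youden threshold %g (J = %.3f)>\n",
              x$spec$name, x$auc, x$youden_threshold, x$youden_j))
  m <- x$metrics
  for (nm in names(m))
    cat(sprintf("  %-12s %.3f [%.2f %.2f]\n", nm, m[[nm]]$estimate,
                m[[nm]]$ci_lo, m[[nm]]$ci_hi))
  invisible(x)
}

classify_at <- function(values, threshold, polarity) {
  if (polarity == "lower_predicts_positive") values <= threshold
  else values >= threshold
}

#' Reflex testing of primary-positive patients
#'
#' Two-stage classification: patients negative on the primary test keep
#' that call; patients positive on the primary test are re-classified by
#' the reflex test (final positive iff also reflex-positive). Patients
#' with a missing reflex value among primary positives are indeterminate
#' and handled per `impute_rule` when counting.
#'
#' @param primary,reflex Lists with `values`, `threshold` and `spec`
#'   (a [measure_spec()]); thresholds typically come from each measure's
#'   own Youden operating point.
#' @param labels Logical outcome labels.
#' @param impute_rule As in [roc_analysis()].
#' @return List with `per_patient` (data.frame: primary_positive,
#'   final_positive, label, category), `confusion_before`,
#'   `confusion_after`, `misclass_before`, `misclass_after` (counts) and
#'   `misclass_rate_before/after` (fractions of n).
#' @export
reflex_test <- function(primary, reflex, labels,
                        impute_rule = c("as_misclassified",
                                        "as_test_negative", "exclude")) {
  impute_rule <- match.arg(impute_rule)
  stopifnot(length(primary$values) == length(labels),
            length(reflex$values) == length(labels))
  labels <- as.logical(labels)
  prim_pos <- classify_at(primary$values, primary$threshold,
                          primary$spec$polarity)
  refl_pos <- classify_at(reflex$values, reflex$threshold,
                          reflex$spec$polarity)
  final <- prim_pos & refl_pos
  # primary positives lacking a reflex value are indeterminate
  ind <- !is.na(prim_pos) & prim_pos & is.na(refl_pos)
  final[ind] <- NA

  count_conf <- function(calls) {
    det <- !is.na(calls)
    conf <- list(tp = sum(calls[det] & labels[det]),
                 fp = sum(calls[det] & !labels[det]),
                 fn = sum(!calls[det] & labels[det]),
                 tn = sum(!calls[det] & !labels[det]))
    impute_indeterminate(conf, labels[!det], impute_rule)
  }
  cb <- count_conf(prim_pos)
  ca <- count_conf(final)
  n <- length(labels)
  per_patient <- data.frame(
    primary_positive = prim_pos, final_positive = final, label = labels,
    category = ifelse(is.na(final), "indeterminate",
                      ifelse(final & labels, "TP",
                             ifelse(final & !labels, "FP",
                                    ifelse(!final & labels, "FN", "TN")))),
    stringsAsFactors = FALSE
  )
  list(per_patient = per_patient,
       confusion_before = cb, confusion_after = ca,
       misclass_before = cb$fp + cb$fn,
       misclass_after = ca$fp + ca$fn,
       misclass_rate_before = (cb$fp + cb$fn) / (n - cb$n_excluded),
       misclass_rate_after = (ca$fp + ca$fn) / (n - ca$n_excluded))
}

#' K-means clusters of (FR rate, local efficiency) node features
#'
#' Pools FR-generating nodes with positive local efficiency across the
#' cohort, z-scores the two features, and partitions them with k-means
#' (k-means++-style multiple restarts via `nstart`, fixed seed). Reports
#' per-patient percentages of resected and unresected nodes in each
#' cluster (zero-LE nodes tallied separately) and the Spearman correlation
#' of each percentage with Engel class.
#'
#' @param node_table data.frame with columns `patient_id`, `contact_id`,
#'   `rate_per_min`, `local_efficiency`, `resected`, `engel`.
#' @param k Number of clusters, default 3.
#' @param seed RNG seed for the restarts.
#' @param nstart Random restarts, default 50.
#' @return List with `assignments` (node_table plus `cluster`, 0 = zero-LE),
#'   `centers` (on the z-scored scale), `percentages` (per patient x
#'   region x cluster), `spearman` (per region x cluster vs Engel); `NULL`
#'   when fewer than `k` positive-LE nodes exist.
#' @export
rate_efficiency_clusters <- function(node_table, k = 3, seed = 1,
                                     nstart = 50) {
  req <- c("patient_id", "contact_id", "rate_per_min", "local_efficiency",
           "resected", "engel")
  stopifnot(all(req %in% names(node_table)))
  pos <- node_table$local_efficiency > 0
  if (sum(pos) < k) return(NULL)
  feat <- scale(cbind(rate = node_table$rate_per_min[pos],
                      le = node_table$local_efficiency[pos]))
  set.seed(as.integer(seed))
  km <- kmeans(feat, centers = k, nstart = nstart)
  # stable cluster identity: order clusters by center rate (descending)
  ord <- order(km$centers[, "rate"], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  node_table$cluster <- 0L
  node_table$cluster[pos] <- relabel[km$cluster]

  pats <- unique(node_table$patient_id)
  pct_rows <- list()
  for (pid in pats) {
    sub <- node_table[node_table$patient_id == pid, , drop = FALSE]
    for (region in c(TRUE, FALSE)) {
      rsub <- sub[sub$resected == region, , drop = FALSE]
      n <- nrow(rsub)
      for (cl in 0:k) {
        pct_rows[[length(pct_rows) + 1L]] <- data.frame(
          patient_id = pid, engel = sub$engel[1],
          region = if (region) "resected" else "unresected",
          cluster = cl,
          pct = if (n > 0) 100 * mean(rsub$cluster == cl) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  percentages <- do.call(rbind, pct_rows)
  sp_rows <- list()
  for (region in c("resected", "unresected")) {
    for (cl in 0:k) {
      sub <- percentages[percentages$region == region &
                         percentages$cluster == cl, , drop = FALSE]
      sp <- spearman_outcome(sub$pct, sub$engel)
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        region = region, cluster = cl, rho = sp$rho, p = sp$p, n = sp$n,
        stringsAsFactors = FALSE)
    }
  }
  list(assignments = node_table,
       centers = km$centers[ord, , drop = FALSE],
       percentages = percentages,
       spearman = do.call(rbind, sp_rows))
}
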