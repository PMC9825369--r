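test_that("spearman outcome merges Engel 2/3 and matches a rank oracle", {
  engel <- c(1, 1, 2, 3, 4, 4)
  values <- c(1, 2, 3, 4, 5, 6)
  s <- spearman_outcome(values, engel)
  # oracle: ranks of values against merged ordinal levels
  merged <- c(1, 1, 2.5, 2.5, 4, 4)
  expect_equal(s$rho, cor(rank(values), rank(merged)), tolerance = 1e-9)
  expect_gt(s$rho, 0.9)
  expect_equal(s$r2, cor(values, merged)^2, tolerance = 1e-9)

  # monotone with the merged classes (tie pattern matched): rho = 1
  expect_equal(spearman_outcome(c(1, 2, 2, 3), c(1, 2, 3, 4))$rho, 1)
  # strictly increasing values still correlate near-perfectly
  expect_gt(spearman_outcome(c(1, 2, 3, 4), c(1, 2, 3, 4))$rho, 0.94)
  # constant measure: undefined
  expect_true(is.na(spearman_outcome(rep(2, 5), c(1, 2, 3, 4, 4))$rho))
  # NA values dropped, not propagated
  s2 <- spearman_outcome(c(1, NA, 3, 4, 5), c(1, 2, 2, 3, 4))
  expect_equal(s2$n, 4)

  # permuted values show no systematic correlation
  set.seed(71)
  ps <- replicate(40, {
    spearman_outcome(rnorm(20), sample(1:4, 20, replace = TRUE))$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("ROC analysis matches closed forms, concordance, and Youden", {
  spec_hi <- measure_spec("m", "higher_predicts_positive")
  # perfectly separated values
  v <- c(1, 2, 3, 10, 11, 12)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  d <- roc_analysis(v, l, spec_hi)
  expect_equal(d$auc, 1)
  expect_equal(d$youden_j, 1)
  expect_equal(d$confusion$tp, 3)
  expect_equal(d$confusion$fp, 0)
  expect_equal(d$metrics$sensitivity$estimate, 1)
  # CI bounds contain the estimate (Clopper-Pearson)
  expect_true(d$metrics$sensitivity$ci_lo <= 1 &
              d$metrics$sensitivity$ci_hi >= 1)

  # identical values for everyone: chance
  expect_equal(roc_analysis(rep(5, 6), l, spec_hi)$auc, 0.5)

  # polarity flip mirrors the AUC
  spec_lo <- measure_spec("m", "lower_predicts_positive")
  expect_equal(roc_analysis(v, l, spec_lo)$auc, 0)

  # AUC equals all-pairs concordance on random data, ties included
  set.seed(83)
  for (rep in 1:30) {
    vv <- sample(1:8, 20, replace = TRUE)   # forces ties
    ll <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(ll)) < 2) next
    dd <- roc_analysis(vv, ll, spec_hi)
    expect_equal(dd$auc, oracle_auc(vv, ll), tolerance = 1e-12)
    # Youden threshold maximizes J over an exhaustive sweep
    js <- sapply(unique(vv), function(t) {
      sens <- sum(vv >= t & ll) / sum(ll)
      spec <- sum(vv < t & !ll) / sum(!ll)
      sens + spec - 1
    })
    expect_equal(dd$youden_j, max(js), tolerance = 1e-12)
  }

  expect_error(roc_analysis(v, rep(TRUE, 6), spec_hi), "both outcome")
})

test_that("indeterminate imputation preserves patient counts", {
  conf <- list(tp = 3, fp = 1, fn = 2, tn = 4)
  ind <- c(TRUE, TRUE, FALSE)   # two positive, one negative indeterminate
  m <- impute_indeterminate(conf, ind, "as_misclassified")
  expect_equal(m$fn, 4); expect_equal(m$fp, 2)
  tn <- impute_indeterminate(conf, ind, "as_test_negative")
  expect_equal(tn$fn, 4); expect_equal(tn$tn, 5)
  ex <- impute_indeterminate(conf, ind, "exclude")
  expect_equal(ex$n_excluded, 3)
  # conservation: counted cells plus exclusions always cover all patients
  for (rule in c("as_misclassified", "as_test_negative", "exclude")) {
    r <- impute_indeterminate(conf, ind, rule)
    expect_equal(r$tp + r$fp + r$fn + r$tn + r$n_excluded, 13)
  }
  # NA-valued patients feed the confusion matrix but never the ROC
  v <- c(1, 2, 3, 10, 11, NA)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  d <- roc_analysis(v, l, measure_spec("m", "higher_predicts_positive"))
  expect_equal(d$n_indeterminate, 1)
  expect_equal(d$confusion$fn, 1)   # as_misclassified default
  expect_equal(d$auc, 1)            # ROC on the 5 determinate patients
})

test_that("reflex testing corrects false positives and is idempotent", {
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  primary <- list(values = c(9, 8, 7, 6, 5, 6, 7, 1),
                  threshold = 5,
                  spec = measure_spec("p", "higher_predicts_positive"))
  # primary calls everyone but the last positive: 4 FP
  # reflex separates perfectly among primary positives
  reflex <- list(values = c(10, 10, 10, 0, 0, 0, 0, 0),
                 threshold = 5,
                 spec = measure_spec("r", "higher_predicts_positive"))
  rt <- reflex_test(primary, reflex, labels)
  expect_equal(rt$misclass_before, 4)
  expect_equal(rt$misclass_after, 0)
  expect_equal(rt$confusion_after$tp, 3)
  expect_equal(rt$confusion_after$tn, 5)
  # reflex identical to primary changes nothing
  rt_same <- reflex_test(primary, primary, labels)
  expect_equal(rt_same$misclass_after, rt_same$misclass_before)
  # a primary-negative patient is never re-classified
  expect_false(rt$per_patient$final_positive[8])
  # missing reflex value on a primary positive becomes indeterminate
  reflex_na <- reflex; reflex_na$values[1] <- NA
  rt_na <- reflex_test(primary, reflex_na, labels)
  expect_identical(rt_na$per_patient$category[1], "indeterminate")
  expect_equal(rt_na$confusion_after$fn, 1)   # imputed as misclassified
})

test_that("k-means recovers planted rate/efficiency clusters", {
  set.seed(97)
  centers <- rbind(c(8, 0.05), c(2, 0.7), c(0.5, 0.2))
  n_per <- 30
  pts <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], 0.2), rnorm(n_per, centers[k, 2], 0.02))
  }))
  node_table <- data.frame(
    patient_id = rep(sprintf("P%d", 1:6), length.out = 3 * n_per),
    contact_id = sprintf("c%d", seq_len(3 * n_per)),
    rate_per_min = pmax(pts[, 1], 0.01),
    local_efficiency = pmax(pts[, 2], 1e-4),
    resected = rep(c(TRUE, FALSE), length.out = 3 * n_per),
    engel = rep(c(1L, 2L, 3L, 4L, 1L, 4L), length.out = 3 * n_per)
  )
  res <- rate_efficiency_clusters(node_table, k = 3, seed = 1)
  truth <- rep(1:3, each = n_per)
  tab <- table(res$assignments$cluster, truth)
  # each planted cluster maps to one recovered label
  expect_equal(sum(apply(tab, 2, max)), 3 * n_per)
  # deterministic under the seed
  res2 <- rate_efficiency_clusters(node_table, k = 3, seed = 1)
  expect_identical(res$assignments$cluster, res2$assignments$cluster)
  # percentages partition each patient region (clusters 0..k sum to 100)
  pct <- res$percentages
  for (pid in unique(pct$patient_id)) for (reg in c("resected", "unresected")) {
    s <- sum(pct$pct[pct$patient_id == pid & pct$region == reg])
    if (!is.na(s)) expect_equal(s, 100, tolerance = 1e-9)
  }
  # fewer than k positive-LE nodes: undefined
  tiny <- node_table[1:2, ]
  expect_null(rate_efficiency_clusters(tiny, k = 3, seed = 1))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  spec <- measure_spec("m", "higher_predicts_positive")
  for (rep in 1:10) {
    v <- rnorm(25)
    l <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = v,
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_analysis(v, l, spec)$auc, ref, tolerance = 1e-12)
  }
})
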