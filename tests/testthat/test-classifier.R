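# quickly built gaussian feature matrices with a controllable number of
# informative columns (avoids running the simulator for protocol tests)
toy_features <- function(n_td = 40, n_d = 20, p_noise = 30,
                         informative = "planted", shift = 3, seed = 1,
                         duplicate = FALSE) {
  set.seed(seed)
  n <- n_td + n_d
  m <- matrix(rnorm(n * p_noise), n,
              dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  lab <- factor(rep(c("TD", "D"), c(n_td, n_d)), levels = c("TD", "D"))
  x <- rnorm(n) + shift * (lab == "D")
  m <- cbind(m, matrix(x, ncol = 1, dimnames = list(NULL, informative)))
  if (duplicate)
    m <- cbind(m, matrix(x, ncol = 1,
                         dimnames = list(NULL, paste0(informative, "_copy"))))
  rownames(m) <- sprintf("w%03d", seq_len(n))
  list(m = m, labels = lab)
}

test_that("F1 follows the harmonic-mean definition", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(0, 3, 5), 0)
  expect_equal(f1_score(29, 2, 1),
               2 * (29 / 31 * 29 / 30) / (29 / 31 + 29 / 30))
  expect_equal(f1_score(29, 2, 1), 0.95082, tolerance = 1e-4)
  expect_error(f1_score(0, 3, 0), "undefined")
})

test_that("training is deterministic and refuses degenerate input", {
  toy <- toy_features()
  cfg <- cv_config(seed = 5)
  fit1 <- dysgraphia_rf(toy$m, toy$labels, cfg)
  fit2 <- dysgraphia_rf(toy$m, toy$labels, cfg)
  p1 <- predict(fit1, toy$m)
  p2 <- predict(fit2, toy$m)
  expect_identical(p1, p2)

  # separable training data is memorized
  expect_true(all(p1$label == as.character(toy$labels)))
  expect_identical(p1$label, ifelse(p1$score > 0.5, "D", "TD"))

  expect_error(dysgraphia_rf(toy$m[toy$labels == "TD", ],
                             toy$labels[toy$labels == "TD"], cfg),
               "both classes")
})

test_that("prediction refuses incomplete or misnamed feature vectors", {
  toy <- toy_features()
  fit <- dysgraphia_rf(toy$m, toy$labels, cv_config(seed = 2))
  fv <- toy$m[1, ]
  expect_error(predict(fit, fv[-1]), "lacks")
  fv_na <- fv; fv_na[3] <- NA
  expect_error(predict(fit, fv_na), "missing")
  one <- predict(fit, fv)
  expect_true(one$label %in% c("TD", "D"))
  expect_gte(one$score, 0); expect_lte(one$score, 1)
})

test_that("evaluation reports are internally consistent", {
  toy <- toy_features(seed = 3)
  ev <- evaluate_cohort(toy$m, toy$labels, cv_config(k = 8, seed = 7))
  pr <- ev$per_repeat
  expect_equal(pr$f1,
               mapply(f1_score, pr$tp, pr$fp, pr$fn))
  expect_equal(pr$sensitivity, pr$tp / (pr$tp + pr$fn))
  expect_equal(pr$specificity + pr$fpr, rep(1, nrow(pr)))
  expect_true(all(pr[c("f1", "sensitivity", "specificity", "fpr")] >= 0 &
                    pr[c("f1", "sensitivity", "specificity", "fpr")] <= 1))
  expect_equal(ev$mean[["f1"]], mean(pr$f1))
  # test sets are 30% of each class
  expect_equal(unique(pr$tp + pr$fn), round(0.3 * 20))
  expect_equal(unique(pr$fp + pr$tn), round(0.3 * 40))
})

test_that("evaluation with a fixed seed is bit-stable", {
  toy <- toy_features(seed = 4)
  cfg <- cv_config(k = 5, seed = 11)
  ev1 <- evaluate_cohort(toy$m, toy$labels, cfg)
  ev2 <- evaluate_cohort(toy$m, toy$labels, cfg)
  expect_identical(ev1$per_repeat, ev2$per_repeat)
  expect_identical(ev1$importances, ev2$importances)
})

test_that("Gini importances are normalized and find planted features", {
  toy <- toy_features(seed = 5)
  ev <- evaluate_cohort(toy$m, toy$labels, cv_config(k = 6, seed = 13))
  imp <- feature_importances(ev)
  expect_equal(sum(imp$mean_importance), 1, tolerance = 1e-9)
  expect_equal(imp$name[1], "planted")

  dup <- toy_features(seed = 5, duplicate = TRUE)
  ev2 <- evaluate_cohort(dup$m, dup$labels, cv_config(k = 6, seed = 13))
  imp2 <- feature_importances(ev2)
  single <- imp$mean_importance[imp$name == "planted"]
  both <- imp2$mean_importance[imp2$name %in% c("planted", "planted_copy")]
  expect_length(both, 2)
  expect_true(all(both < single))        # importance is shared
  expect_gt(sum(both), 0.5 * single)
})

test_that("feature subsetting and k-fold mode work", {
  toy <- toy_features(seed = 6)
  cfg <- cv_config(k = 4, seed = 3, feature_subset = c("planted", "noise1"))
  ev <- evaluate_cohort(toy$m, toy$labels, cfg)
  expect_setequal(ev$importances$name, c("planted", "noise1"))
  expect_gt(ev$mean[["f1"]], 0.8)
  expect_error(
    evaluate_cohort(toy$m, toy$labels,
                    cv_config(feature_subset = "no_such_feature")),
    "unknown features")

  cfg_kf <- cv_config(k = 5, seed = 3, mode = "kfold")
  ev_kf <- evaluate_cohort(toy$m, toy$labels, cfg_kf)
  expect_equal(nrow(ev_kf$per_repeat), 5)
  # disjoint folds partition the cohort: test totals sum to n
  expect_equal(sum(ev_kf$per_repeat$tp + ev_kf$per_repeat$fp +
                     ev_kf$per_repeat$fn + ev_kf$per_repeat$tn), 60)
})

test_that("distance features are referenced to the training split only", {
  sc <- small_cohort()
  fc <- sc$fc
  # build a reference from an explicit subset and check the distances
  # equal hand-computed L2 distances to that subset's mean spectrum
  train_ix <- 1:9
  ref <- graphokin:::reference_from_spectra(fc$spectra[train_ix],
                                            fc$packets)
  feats <- graphokin:::recompute_distances(fc, ref)
  fam_sp <- lapply(fc$spectra[train_ix], `[[`, "speed")
  fam_sp <- fam_sp[!vapply(fam_sp, is.null, TRUE)]
  pw <- rowMeans(sapply(fam_sp, `[[`, "power"))
  pw <- pw / sum(pw)
  for (i in c(1, 12, 18)) {
    s <- fc$spectra[[i]]$speed
    expect_equal(feats[i, "speed_freq_distance"],
                 sqrt(sum((s$power - pw)^2)), tolerance = 1e-12)
  }
  # changing the reference subset changes the distances
  ref2 <- graphokin:::reference_from_spectra(fc$spectra[10:18], fc$packets)
  feats2 <- graphokin:::recompute_distances(fc, ref2)
  expect_false(isTRUE(all.equal(feats[, "speed_freq_distance"],
                                feats2[, "speed_freq_distance"])))
})

test_that("the end-to-end protocol separates simulated groups", {
  sc <- small_cohort()
  ev <- evaluate_cohort(sc$fc, sc$coh$labels,
                        cv_config(k = 6, seed = 21))
  expect_gt(ev$mean[["f1"]], 0.8)
  m <- dysgraphia_rf(sc$fc, sc$coh$labels, cv_config(seed = 21))
  pr <- predict(m, sc$fc)
  expect_gt(mean(pr$label == as.character(sc$coh$labels)), 0.9)
})

test_that("robustness curve handles durations beyond the recording", {
  sc <- small_cohort()
  short <- lapply(sc$coh$recordings[c(1:6, 11:16)],
                  truncate_recording, 40)
  labs <- sc$coh$labels[c(1:6, 11:16)]
  rc <- robustness_curve(short, labs, c(30, 1e5),
                         cv_config(k = 3, seed = 2))
  expect_equal(nrow(rc), 2)
  # beyond-length duration equals the full recordings
  fc_full <- extract_cohort(short)
  ev_full <- evaluate_cohort(fc_full, labs, cv_config(k = 3, seed = 2))
  expect_equal(rc$f1_mean[2], ev_full$mean[["f1"]])
})
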