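#' F1 score from confusion counts
#'
#' `recall = tp / (tp + fn)`, `precision = tp / (tp + fp)` (taken as 0
#' when nothing was predicted positive), and
#' `F1 = 2 * precision * recall / (precision + recall)`, defined as 0 when
#' both are 0.
#'
#' @param tp,fp,fn confusion counts; `tp + fn` must be positive (there
#'   must be at least one positive truth, else the metric is undefined).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(tp, fp, fn) {
  if (tp + fn <= 0) stop("undefined metric: no positive ground truths")
  recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Cross-validation / evaluation configuration
#'
#' The evaluation protocol is k repeated stratified shuffle-splits: per
#' repeat, `train_fraction` of each class is drawn for training and the
#' rest scored. Reporting a mean and std of F1 over repeats requires
#' repeated splits rather than disjoint folds; a plain k-fold mode is
#' available via `mode = "kfold"`.
#'
#' @param k number of repeats (default 25).
#' @param train_fraction per-class training fraction (default 0.70).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed driving every split and forest.
#' @param feature_subset optional character vector restricting the model
#'   to named features (see [feature_names()]).
#' @param mode `"shuffle"` (repeated stratified 70/30 splits, default) or
#'   `"kfold"` (stratified k disjoint folds).
#' @param threshold vote fraction above which a writer is labelled `D`
#'   (default 0.5).
#' @return a list of class `cv_config`.
#' @export
cv_config <- function(k = 25, train_fraction = 0.70, n_trees = 100,
                      seed = 1L, feature_subset = NULL,
                      mode = c("shuffle", "kfold"), threshold = 0.5) {
  stopifnot(k >= 1, train_fraction > 0, train_fraction < 1, n_trees >= 1,
            threshold > 0, threshold < 1)
  structure(list(k = as.integer(k), train_fraction = train_fraction,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 feature_subset = feature_subset,
                 mode = match.arg(mode), threshold = threshold),
            class = "cv_config")
}

feature_matrix <- function(x) {
  if (inherits(x, "handwriting_features")) x$features
  else as.matrix(x)
}

select_complete <- function(feats, cfg, quiet = FALSE) {
  cols <- if (!is.null(cfg$feature_subset)) {
    missing_cols <- setdiff(cfg$feature_subset, colnames(feats))
    if (length(missing_cols))
      stop("unknown features requested: ",
           paste(missing_cols, collapse = ", "))
    cfg$feature_subset
  } else colnames(feats)
  m <- feats[, cols, drop = FALSE]
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    if (!quiet)
      message("feature(s) missing for every recording, excluded: ",
              paste(colnames(m)[all_na], collapse = ", "))
    m <- m[, !all_na, drop = FALSE]
    cols <- colnames(m)
  }
  ok <- stats::complete.cases(m)
  if (!quiet && any(!ok))
    message(sum(!ok), " recording(s) dropped for missing features")
  list(m = m, ok = ok, cols = cols)
}

#' Fit a Random Forest dysgraphia screen
#'
#' The single fitting entry point: trains a Random Forest on a feature
#' table and binary labels (`TD`/`D`), storing the feature-name order, the
#' cohort reference used at extraction and the configuration so that
#' prediction can refuse incompatible feature vectors. Deterministic given
#' `cfg$seed`. Rows with missing values in the selected features are
#' dropped with a message.
#'
#' @param x a `handwriting_features` object from [extract_cohort()], or a
#'   numeric feature matrix with named columns.
#' @param labels factor (or character) with levels `TD` and `D`; `D` is
#'   the positive class.
#' @param cfg a [cv_config()] (only `n_trees`, `seed` and
#'   `feature_subset` are used here).
#' @return an object of class `dysgraphia_rf` with `forest`, `features`
#'   (column order), `ref`, `cfg` and `levels`.
#' @export
dysgraphia_rf <- function(x, labels, cfg = cv_config()) {
  feats <- feature_matrix(x)
  labels <- factor(as.character(labels), levels = c("TD", "D"))
  if (nrow(feats) != length(labels))
    stop("labels do not match the feature rows")
  sel <- select_complete(feats, cfg)
  y <- labels[sel$ok]
  if (nlevels(droplevels(y)) < 2)
    stop("training requires both classes to be present")
  with_seed(cfg$seed, {
    forest <- randomForest::randomForest(
      x = sel$m[sel$ok, , drop = FALSE], y = y, ntree = cfg$n_trees)
  })
  structure(list(forest = forest, features = sel$cols,
                 ref = if (inherits(x, "handwriting_features")) x$ref,
                 cfg = cfg, levels = c("TD", "D"),
                 n_train = sum(sel$ok)),
            class = "dysgraphia_rf")
}

#' @export
print.dysgraphia_rf <- function(x, ...) {
  cat(sprintf(
    "Dysgraphia Random Forest screen: %d trees, %d features, %d writers\n",
    x$cfg$n_trees, length(x$features), x$n_train))
  invisible(x)
}

#' @export
summary.dysgraphia_rf <- function(object, n = 10, ...) {
  imp <- randomForest::importance(object$forest, type = 2)[, 1L]
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  cat(sprintf("Top %d features by Gini importance:\n", min(n, length(imp))))
  for (i in seq_len(min(n, length(imp))))
    cat(sprintf("  %2d. %-26s %.3f\n", i, names(imp)[i], imp[i]))
  invisible(imp)
}

#' Predict dysgraphia for new feature vectors
#'
#' @param object a [dysgraphia_rf()] model.
#' @param newdata named numeric vector (one writer), matrix, or
#'   `handwriting_features` object. Feature names must cover the model's
#'   feature set and contain no missing values in it.
#' @param ... unused.
#' @return data frame with `label` (`TD`/`D`) and `score` (forest vote
#'   fraction for `D`).
#' @export
predict.dysgraphia_rf <- function(object, newdata, ...) {
  m <- if (is.null(dim(newdata)) && is.numeric(newdata))
    matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  else feature_matrix(newdata)
  missing_cols <- setdiff(object$features, colnames(m))
  if (length(missing_cols))
    stop("feature vector lacks model features: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  m <- m[, object$features, drop = FALSE]
  if (anyNA(m))
    stop("missing values in required features; cannot predict")
  votes <- stats::predict(object$forest, m, type = "vote", norm.votes = TRUE)
  score <- votes[, "D"]
  data.frame(label = ifelse(score > object$cfg$threshold, "D", "TD"),
             score = as.numeric(score), row.names = rownames(m))
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == "D" & pred == "D")
  fp <- sum(truth == "TD" & pred == "D")
  fn <- sum(truth == "D" & pred == "TD")
  tn <- sum(truth == "TD" & pred == "TD")
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       f1 = f1_score(tp, fp, fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       fpr = fp / (fp + tn))
}

split_indices <- function(labels, cfg, repeat_seed) {
  with_seed(repeat_seed, {
    train <- logical(length(labels))
    for (lv in levels(labels)) {
      ix <- which(labels == lv)
      n_tr <- round(cfg$train_fraction * length(ix))
      n_tr <- min(max(n_tr, 1L), length(ix) - 1L)
      train[sample(ix, n_tr)] <- TRUE
    }
    train
  })
}

kfold_assignment <- function(labels, cfg) {
  with_seed(cfg$seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      ix <- sample(which(labels == lv))
      fold[ix] <- rep_len(seq_len(cfg$k), length(ix))
    }
    fold
  })
}

#' Evaluate the screen under the repeated-split protocol
#'
#' Runs `cfg$k` independent stratified splits (70% of each class for
#' training by default), fits a forest per split, scores the held-out 30%,
#' and reports per-repeat F1, sensitivity (recall on `D`), specificity and
#' false-positive rate with their means and stds, pooled confusion totals,
#' and Gini importances averaged over repeats (normalized to sum to 1 per
#' repeat).
#'
#' When `x` is a `handwriting_features` object, the five distance-to-mean
#' features are recomputed per repeat against a cohort reference built
#' from that repeat's training split only, so no test-set information
#' enters the reference.
#'
#' @param x a `handwriting_features` object (preferred) or numeric feature
#'   matrix. A plain matrix is used as-is, including any distances already
#'   in it.
#' @param labels factor/character `TD`/`D` per row.
#' @param cfg a [cv_config()].
#' @return object of class `dysgraphia_eval`: list with `per_repeat` (data
#'   frame), `mean`, `std`, `confusion` (pooled totals), `importances`
#'   (data frame, descending mean importance), `cfg`, `n`.
#' @export
evaluate_cohort <- function(x, labels, cfg = cv_config()) {
  labels <- factor(as.character(labels), levels = c("TD", "D"))
  feats <- feature_matrix(x)
  if (any(table(labels) < 2))
    stop("both classes need at least 2 members to split")
  has_spectra <- inherits(x, "handwriting_features")
  # rows with missing required features are excluded before splitting (the
  # exclusion is part of the protocol, not of any one split); the usable
  # column set is fixed once so importances align across repeats.
  # Distance-feature missingness does not depend on which recordings enter
  # the reference, so the base selection is stable across repeats.
  base <- if (has_spectra) recompute_distances(x, x$ref) else feats
  sel0 <- select_complete(base, cfg)
  usable <- which(sel0$ok)
  if (any(table(labels[usable]) < 2))
    stop("both classes need at least 2 members with complete features")
  cfg_cols <- cfg
  cfg_cols$feature_subset <- sel0$cols
  per <- vector("list", cfg$k)
  imps <- vector("list", cfg$k)
  fold <- if (cfg$mode == "kfold") kfold_assignment(labels[usable], cfg)
  for (r in seq_len(cfg$k)) {
    train_u <- if (cfg$mode == "kfold") fold != r
               else split_indices(labels[usable], cfg,
                                  writer_seed(cfg$seed, r))
    train <- logical(length(labels))
    train[usable[train_u]] <- TRUE
    feats_r <- feats
    if (has_spectra) {
      ref_r <- reference_from_spectra(x$spectra[train], x$packets)
      feats_r <- recompute_distances(x, ref_r)
    }
    sel <- select_complete(feats_r, cfg_cols, quiet = TRUE)
    tr <- train & sel$ok
    te <- !train & sel$ok & seq_along(labels) %in% usable
    if (nlevels(droplevels(labels[tr])) < 2 || !any(labels[te] == "D"))
      stop("a split lost one class entirely; increase group sizes")
    with_seed(writer_seed(cfg$seed, 1000L + r), {
      forest <- randomForest::randomForest(
        x = sel$m[tr, , drop = FALSE], y = labels[tr], ntree = cfg$n_trees)
    })
    votes <- stats::predict(forest, sel$m[te, , drop = FALSE],
                            type = "vote", norm.votes = TRUE)
    pred <- ifelse(votes[, "D"] > cfg$threshold, "D", "TD")
    cm <- confusion_metrics(labels[te], pred)
    per[[r]] <- data.frame(repeat_ = r, f1 = cm$f1,
                           sensitivity = cm$sensitivity,
                           specificity = cm$specificity, fpr = cm$fpr,
                           tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
                           n_dropped = sum(!sel$ok))
    gi <- randomForest::importance(forest, type = 2)[, 1L]
    row <- stats::setNames(rep(NA_real_, length(cfg_cols$feature_subset)),
                           cfg_cols$feature_subset)
    row[names(gi)] <- gi / sum(gi)
    imps[[r]] <- row
  }
  per <- do.call(rbind, per)
  imp_m <- do.call(rbind, imps)
  importances <- data.frame(
    name = colnames(imp_m),
    mean_importance = colMeans(imp_m, na.rm = TRUE),
    std_importance = apply(imp_m, 2L, pop_sd), row.names = NULL)
  importances <- importances[order(-importances$mean_importance), ]
  rownames(importances) <- NULL
  metrics <- c("f1", "sensitivity", "specificity", "fpr")
  structure(list(
    per_repeat = per,
    mean = vapply(per[metrics], mean, 0),
    std = vapply(per[metrics], stats::sd, 0),
    confusion = colSums(per[c("tp", "fp", "fn", "tn")]),
    importances = importances,
    cfg = cfg, n = length(labels)),
    class = "dysgraphia_eval")
}

#' @export
print.dysgraphia_eval <- function(x, ...) {
  cat(sprintf(
    "Dysgraphia screen evaluation: %d repeats, %d writers (%s mode)\n",
    x$cfg$k, x$n, x$cfg$mode))
  cat(sprintf("  F1          %.4f (std %.4f)\n", x$mean["f1"], x$std["f1"]))
  cat(sprintf("  sensitivity %.4f (std %.4f)\n",
              x$mean["sensitivity"], x$std["sensitivity"]))
  cat(sprintf("  specificity %.4f (std %.4f)\n",
              x$mean["specificity"], x$std["specificity"]))
  cat(sprintf("  FPR         %.4f (std %.4f)\n", x$mean["fpr"], x$std["fpr"]))
  cat("Top 5 features by mean Gini importance:\n")
  top <- utils::head(x$importances, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %-26s %.3f (std %.3f)\n", i, top$name[i],
                top$mean_importance[i], top$std_importance[i]))
  invisible(x)
}

#' @export
plot.dysgraphia_eval <- function(x, ...) {
  graphics::boxplot(x$per_repeat$f1, ylab = "F1 score",
                    main = sprintf("F1 over %d repeats", x$cfg$k), ...)
  invisible(x)
}

#' Ranked Gini feature importances of an evaluation
#'
#' @param eval a `dysgraphia_eval` from [evaluate_cohort()].
#' @return data frame `name`, `mean_importance`, `std_importance`, sorted
#'   descending; importances sum to 1 within each repeat.
#' @export
feature_importances <- function(eval) {
  stopifnot(inherits(eval, "dysgraphia_eval"))
  eval$importances
}

#' F1 robustness against recording duration
#'
#' Truncates every recording to each requested duration, re-extracts the
#' full feature bank (spectral packet sizes shrink automatically on short
#' recordings), and runs [evaluate_cohort()] per duration — the classic
#' "how many seconds of writing are enough" curve. Durations longer than a
#' recording leave it untouched.
#'
#' @param recordings list of [recording()] objects.
#' @param labels `TD`/`D` per recording.
#' @param durations numeric vector of seconds (use `Inf` for the full
#'   recordings).
#' @param cfg a [cv_config()].
#' @param static_cfg,dyn_cfg feature extraction configurations.
#' @return object of class `robustness_curve`: data frame with `duration`,
#'   `f1_mean`, `f1_std`, plus the per-duration evaluations in
#'   `attr(, "evaluations")`.
#' @export
robustness_curve <- function(recordings, labels, durations,
                             cfg = cv_config(),
                             static_cfg = static_config(),
                             dyn_cfg = dynamics_config()) {
  stopifnot(all(durations > 0))
  evals <- list()
  rows <- vector("list", length(durations))
  for (i in seq_along(durations)) {
    d <- durations[i]
    recs <- lapply(recordings, function(r)
      if (is.finite(d) && max(r$t) >= d) truncate_recording(r, d) else r)
    fc <- extract_cohort(recs, static_cfg = static_cfg, dyn_cfg = dyn_cfg)
    ev <- evaluate_cohort(fc, labels, cfg)
    evals[[as.character(d)]] <- ev
    rows[[i]] <- data.frame(duration = d, f1_mean = ev$mean["f1"],
                            f1_std = ev$std["f1"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evaluations") <- evals
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' @export
plot.robustness_curve <- function(x, ...) {
  d <- x$duration
  d[!is.finite(d)] <- max(d[is.finite(d)], 0) * 1.2
  graphics::plot(d, x$f1_mean, type = "b", ylim = c(0, 1),
                 xlab = "duration used (s)", ylab = "mean F1", ...)
  graphics::arrows(d, x$f1_mean - x$f1_std, d, x$f1_mean + x$f1_std,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
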