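# Single-trial pain prediction from selected patterns: linear SVC/SVR under
# leave-one-out cross-validation, with the confusion-matrix and MAE metrics
# computed per trial and re-aggregated.

#' Sensitivity and specificity from a confusion table
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, with
#' high-pain trials as the positive class.
#'
#' @param tp,fn,tn,fp Confusion-table counts.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fn + tn + fp))
}

#' Mean absolute error
#'
#' `MAE = (1/P) * sum_p |R_p - Rhat_p|` over the P trials of one subject.
#'
#' @param ratings True ratings.
#' @param predicted Predicted ratings.
#' @return The MAE.
#' @export
mae <- function(ratings, predicted) {
  stopifnot(length(ratings) == length(predicted))
  mean(abs(ratings - predicted))
}

new_prediction_result <- function(trials, feature_set, target_mode, type) {
  metrics <- if (type == "classification") {
    tp <- sum(trials$true_class == "high" & trials$pred_class == "high")
    fn <- sum(trials$true_class == "high" & trials$pred_class == "low")
    tn <- sum(trials$true_class == "low" & trials$pred_class == "low")
    fp <- sum(trials$true_class == "low" & trials$pred_class == "high")
    c(classification_metrics(tp, fn, tn, fp),
      list(tp = tp, fn = fn, tn = tn, fp = fp))
  } else {
    list(mae = mae(trials$true_value, trials$pred_value))
  }
  structure(
    list(trials = trials, metrics = metrics, n_trials = nrow(trials),
         feature_set = feature_set, target_mode = target_mode, type = type),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  if (x$type == "classification") {
    cat(sprintf("<prediction_result> SVC %s: accuracy %.3f, sens %.3f, spec %.3f (%d trials)\n",
                x$feature_set, x$metrics$accuracy, x$metrics$sensitivity,
                x$metrics$specificity, x$n_trials))
  } else {
    cat(sprintf("<prediction_result> SVR %s (%s): MAE %.3f (%d trials)\n",
                x$feature_set, x$target_mode, x$metrics$mae, x$n_trials))
  }
  invisible(x)
}

#' Aggregate pattern features into SVM predictors
#'
#' Builds the trials x predictors matrix fed to the decoders. In `"mean"`
#' mode each pattern contributes one predictor, the mean feature value over
#' its coordinates (stabilizes the SVM at ~40 trials per subject); in
#' `"pixels"` mode every pattern coordinate is its own predictor. Column
#' order follows the pattern list and, within a pattern, feature order.
#'
#' @param fm A `feature_matrix` (normally energy-normalized).
#' @param patterns Non-empty list of `pattern`s from [extract_patterns()].
#' @param mode `"mean"` or `"pixels"`.
#' @param scale `"as-is"` uses the stored (typically normalized) values;
#'   `"raw"` adds back the energy-group means first (see [raw_values()]) —
#'   the scale on which the classifier operates.
#' @return Numeric matrix with named columns.
#' @export
aggregate_pattern_features <- function(fm, patterns, mode = c("mean", "pixels"),
                                       scale = c("as-is", "raw")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(patterns) == 0L) stop("no patterns selected")
  values <- if (scale == "raw") raw_values(fm) else fm$values
  cols <- list()
  for (p in patterns) {
    if (any(p$features > ncol(values)))
      stop("pattern '", p$name, "' refers to features outside the matrix")
    block <- values[, p$features, drop = FALSE]
    if (mode == "mean") {
      cols[[p$name]] <- rowMeans(block)
    } else {
      colnames(block) <- paste0(p$name, "_", seq_len(ncol(block)))
      cols[[p$name]] <- block
    }
  }
  out <- do.call(cbind, cols)
  if (mode == "mean") colnames(out) <- vapply(patterns, `[[`, "", "name")
  out
}

# z-score by training-fold statistics; zero-sd columns pass through unscaled.
fold_zscore <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, `/`),
       test = sweep(sweep(test, 2L, mu, `-`), 2L, sd, `/`))
}

#' Leave-one-out SVC prediction of high versus low pain
#'
#' Classifies trials into low pain (VAS < 5) and high pain (VAS >= 5) with a
#' linear support vector classifier. For each fold the remaining trials are
#' z-scored by their own statistics, the model is trained on them, and the
#' held-out trial is predicted; nothing from the held-out trial enters
#' training. Aggregates follow the confusion-table definitions with high pain
#' as the positive class.
#'
#' @param Xp Trials x predictors matrix (see [aggregate_pattern_features()]).
#' @param ratings Raw 0-10 ratings; labels are derived via `threshold`.
#' @param threshold Class boundary on the VAS scale (default 5; a rating of
#'   exactly 5 is high pain).
#' @param cost SVM cost parameter C (default 1).
#' @param feature_set Label stored in the result.
#' @return A `prediction_result` (classification).
#' @export
loocv_classify <- function(Xp, ratings, threshold = 5, cost = 1,
                           feature_set = "features") {
  Xp <- as.matrix(Xp)
  stopifnot(nrow(Xp) == length(ratings))
  labels <- factor(ifelse(ratings >= threshold, "high", "low"),
                   levels = c("low", "high"))
  if (min(table(labels)) < 2L)
    stop("class with fewer than 2 trials; subject must be skipped",
         call. = FALSE)
  n <- nrow(Xp)
  pred <- character(n)
  for (p in seq_len(n)) {
    z <- fold_zscore(Xp[-p, , drop = FALSE], Xp[p, , drop = FALSE])
    fit <- e1071::svm(z$train, labels[-p], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[p] <- as.character(stats::predict(fit, z$test))
  }
  trials <- data.frame(rating = ratings,
                       true_class = as.character(labels), pred_class = pred)
  new_prediction_result(trials, feature_set, target_mode = "raw",
                        type = "classification")
}

#' Leave-one-out SVR prediction of pain intensity
#'
#' Predicts the continuous 0-10 rating (or its within-energy fluctuation)
#' with linear epsilon-support-vector regression. The training target is the
#' rating minus the training-fold mean rating of that trial's energy group,
#' so energy-group means are re-estimated inside every fold and never use the
#' held-out trial. With `target_mode = "raw"` the training-fold mean of the
#' held-out trial's energy is added back to the prediction and the error is
#' measured on the 0-10 scale; with `"normalized"` both prediction and truth
#' stay on the fluctuation scale (the only scale on which pre-stimulus state
#' can carry information, since stimulus energy is randomized).
#'
#' @param Xp Trials x predictors matrix.
#' @param ratings Raw 0-10 ratings.
#' @param energies Energy labels (`E1`-`E4`), one per trial.
#' @param cost,epsilon Linear SVR hyperparameters (defaults 1 and 0.1).
#' @param target_mode `"raw"` or `"normalized"`.
#' @param feature_set Label stored in the result.
#' @return A `prediction_result` (regression) whose MAE follows the mean
#'   absolute error definition on the requested scale.
#' @export
loocv_regress <- function(Xp, ratings, energies, cost = 1, epsilon = 0.1,
                          target_mode = c("raw", "normalized"),
                          feature_set = "features") {
  target_mode <- match.arg(target_mode)
  Xp <- as.matrix(Xp)
  n <- nrow(Xp)
  stopifnot(n == length(ratings), n == length(energies))
  if (n < 3L) stop("need at least 3 trials")
  energies <- as.character(energies)
  pred <- numeric(n)
  truth <- numeric(n)
  for (p in seq_len(n)) {
    tr_rat <- ratings[-p]
    tr_en <- energies[-p]
    if (!(energies[p] %in% tr_en))
      stop("energy ", energies[p], " of the held-out trial is absent from training")
    gmeans <- tapply(tr_rat, tr_en, mean)
    y_tr <- tr_rat - gmeans[tr_en]
    z <- fold_zscore(Xp[-p, , drop = FALSE], Xp[p, , drop = FALSE])
    fit <- e1071::svm(z$train, as.numeric(y_tr), type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    # a degenerate fit with no support vectors (all targets inside the
    # epsilon tube) predicts the training-target mean
    yhat <- if (fit$tot.nSV == 0) mean(y_tr) else as.numeric(stats::predict(fit, z$test))
    if (target_mode == "raw") {
      pred[p] <- yhat + gmeans[[energies[p]]]
      truth[p] <- ratings[p]
    } else {
      pred[p] <- yhat
      truth[p] <- ratings[p] - gmeans[[energies[p]]]
    }
  }
  trials <- data.frame(rating = ratings, energy = energies,
                       true_value = truth, pred_value = pred)
  new_prediction_result(trials, feature_set, target_mode, type = "regression")
}

#' Paired comparison of two feature sets across subjects
#'
#' Two-tailed paired t-test on per-subject metric values (e.g. accuracy of
#' "Pre+Post" versus "Post"). Degenerate cases are flagged rather than
#' silently tested: identical per-subject values give p = 1 with flag
#' `"identical"`; a constant nonzero difference has zero variance, so no t
#' statistic exists and the result carries flag `"constant-difference"` with
#' p = NA.
#'
#' @param values_a,values_b Per-subject metric values, same subjects and order.
#' @param subjects Optional subject identifiers (checked for agreement when
#'   both sets carry names).
#' @param metric Name of the metric being compared.
#' @return Object of class `comparison_result`: `metric`, `mean_diff`,
#'   `t`, `p`, `n`, `flag`, and the per-subject `diff` vector.
#' @export
compare_feature_sets <- function(values_a, values_b, subjects = NULL,
                                 metric = "accuracy") {
  if (length(values_a) != length(values_b))
    stop("subject mismatch between the two result sets")
  if (!is.null(names(values_a)) && !is.null(names(values_b)) &&
      !identical(names(values_a), names(values_b)))
    stop("subject mismatch between the two result sets")
  d <- values_a - values_b
  n <- length(d)
  flag <- "ok"
  if (n < 2L) {
    return(structure(
      list(metric = metric, mean_diff = if (n) mean(d) else NA_real_,
           t = NA_real_, p = NA_real_, n = n, flag = "insufficient-subjects",
           diff = d, subjects = subjects %||% names(values_a)),
      class = "comparison_result"))
  }
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      tstat <- 0; p <- 1; flag <- "identical"
    } else {
      tstat <- NA_real_; p <- NA_real_; flag <- "constant-difference"
    }
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    tstat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(metric = metric, mean_diff = mean(d), t = tstat, p = p, n = n,
         flag = flag, diff = d,
         subjects = subjects %||% names(values_a)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: mean diff %+.4f, t = %s, p = %s (n = %d%s)\n",
              x$metric, x$mean_diff,
              ifelse(is.na(x$t), "NA", sprintf("%.3f", x$t)),
              ifelse(is.na(x$p), "NA", format.pval(x$p, digits = 3)), x$n,
              if (x$flag != "ok") paste0(", ", x$flag) else ""))
  invisible(x)
}

#' Rank individual patterns by predictive power
#'
#' Evaluates each pattern alone: per subject, its aggregated feature is fed to
#' [loocv_classify()] (labels always from raw ratings) and [loocv_regress()].
#' Pre-stimulus patterns predict the normalized rating — the pre-stimulus
#' brain state can only modulate fluctuation within identical stimuli, as
#' stimulus energies are randomized — whereas post-stimulus patterns predict
#' the raw 0-10 rating. Significance above chance is a one-sample t-test of
#' per-subject accuracies against 0.5; optionally the MAE is tested against a
#' permuted-rating baseline (`n_mae_null` label permutations per subject).
#'
#' @param fms List of normalized per-subject `feature_matrix` objects.
#' @param patterns List of `pattern`s (>= 2 for a meaningful ranking).
#' @param threshold,cost,epsilon Decoder settings.
#' @param n_mae_null Permutations per subject for the MAE chance baseline
#'   (0 disables the baseline columns).
#' @param seed Seed for the MAE permutation baseline.
#' @return A data.frame, one row per pattern, ordered by decreasing mean
#'   accuracy: `pattern`, `phase`, `mean_accuracy`, `t_vs_chance`,
#'   `p_vs_chance`, `mean_mae`, and when `n_mae_null > 0` also
#'   `mean_mae_null` and `p_mae_vs_null`. The per-subject accuracy and MAE
#'   vectors are attached as the `"per_subject"` attribute.
#' @export
rank_patterns <- function(fms, patterns, threshold = 5, cost = 1,
                          epsilon = 0.1, n_mae_null = 0L, seed = 1L) {
  if (length(patterns) < 2L) stop("need at least 2 patterns to rank")
  rows <- list()
  per_subject <- list()
  for (pat in patterns) {
    target_mode <- if (pat$phase == "pre") "normalized" else "raw"
    accs <- c(); maes <- c(); mae_null <- c()
    for (fm in fms) {
      Xp_cls <- aggregate_pattern_features(fm, list(pat), mode = "mean",
                                           scale = "raw")
      Xp <- aggregate_pattern_features(fm, list(pat), mode = "mean")
      cls <- tryCatch(
        loocv_classify(Xp_cls, fm$meta$rating, threshold, cost, pat$name),
        error = function(e) NULL)
      if (is.null(cls)) next
      reg <- loocv_regress(Xp, fm$meta$rating, fm$meta$energy, cost, epsilon,
                           target_mode, pat$name)
      accs <- c(accs, cls$metrics$accuracy)
      maes <- c(maes, reg$metrics$mae)
      if (n_mae_null > 0L) {
        set.seed(derive_seed(seed, length(mae_null)))
        nulls <- replicate(n_mae_null, {
          perm <- sample(nrow(Xp))
          loocv_regress(Xp, fm$meta$rating[perm], fm$meta$energy[perm],
                        cost, epsilon, target_mode, pat$name)$metrics$mae
        })
        mae_null <- c(mae_null, mean(nulls))
      }
    }
    tt <- tryCatch(stats::t.test(accs, mu = 0.5, alternative = "greater"),
                   error = function(e) NULL)   # degenerate: constant accuracies
    row <- data.frame(pattern = pat$name, phase = pat$phase,
                      n_subjects = length(accs),
                      mean_accuracy = mean(accs),
                      t_vs_chance = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                      p_vs_chance = if (is.null(tt)) NA_real_ else tt$p.value,
                      mean_mae = mean(maes))
    if (n_mae_null > 0L) {
      mt <- stats::t.test(maes, mae_null, paired = TRUE,
                          alternative = "less")
      row$mean_mae_null <- mean(mae_null)
      row$p_mae_vs_null <- mt$p.value
    }
    rows[[length(rows) + 1L]] <- row
    per_subject[[pat$name]] <- list(accuracy = accs, mae = maes)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_accuracy), , drop = FALSE]
  attr(out, "per_subject") <- per_subject
  out
}
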