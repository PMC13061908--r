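#' Area under the ROC curve
#'
#' Concordance form: the fraction of positive-negative pairs in which the
#' positive sample scores higher, counting ties one half. Identical to the
#' Mann-Whitney U statistic divided by \code{n1 * n0}.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (1 = high-stress) or logical.
#' @return the AUC.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a threshold classifier by the Youden index
#'
#' Searches all candidate cutoffs (midpoints between consecutive distinct
#' sorted scores plus the infinite boundaries) and both orientations for the
#' maximum of J = sensitivity + specificity - 1. Ties are broken by higher
#' specificity, then the smaller cutoff, then the high-scores-predict-stress
#' orientation, so the fit is exactly deterministic.
#'
#' @param scores numeric scores, one per unit.
#' @param labels 0/1 (1 = high-stress) or logical.
#' @return list with \code{orientation} (+1: scores at or above the cutoff
#'   predict high stress; -1: scores below the cutoff do), \code{cutoff},
#'   \code{J}, \code{sensitivity}, \code{specificity}, \code{degenerate}.
#' @export
youden_fit <- function(scores, labels) {
  labels <- as.integer(labels)
  f <- cpp_youden(as.numeric(scores), labels)
  f$degenerate <- length(unique(scores)) == 1L
  if (f$degenerate)
    warning("all scores identical; returning a degenerate model with J = 0")
  f
}

#' DeLong test of AUC = 0.5
#'
#' Placement-value estimator of the AUC variance and a one-sided Z-test of
#' the null AUC = 0.5 against AUC > 0.5.
#'
#' @param scores numeric scores (oriented so that higher predicts
#'   high-stress when testing a fitted model).
#' @param labels 0/1 (1 = high-stress) or logical.
#' @return list with \code{auc}, \code{variance}, \code{z}, \code{p}
#'   (one-sided) and \code{degenerate} (TRUE when the placement variance is
#'   zero, e.g. perfect separation; \code{p} is then reported as 0 for
#'   AUC > 0.5).
#' @export
delong_test <- function(scores, labels) {
  labels <- as.integer(labels)
  s1 <- scores[labels == 1L]
  s0 <- scores[labels == 0L]
  n1 <- length(s1); n0 <- length(s0)
  if (n1 < 2L || n0 < 2L) stop("need at least two units per class")
  v10 <- vapply(s1, function(s) (sum(s0 < s) + 0.5 * sum(s0 == s)) / n0,
                numeric(1))
  v01 <- vapply(s0, function(s) (sum(s1 > s) + 0.5 * sum(s1 == s)) / n1,
                numeric(1))
  a <- mean(v10)
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (v <= 0) {
    p <- if (a > 0.5) 0 else if (a < 0.5) 1 else 0.5
    return(list(auc = a, variance = 0, z = if (a == 0.5) 0 else Inf * sign(a - 0.5),
                p = p, degenerate = TRUE))
  }
  z <- (a - 0.5) / sqrt(v)
  list(auc = a, variance = v, z = z, p = stats::pnorm(z, lower.tail = FALSE),
       degenerate = FALSE)
}

## internal: per-sample scores for a single-feature or ratio candidate
candidate_scores <- function(table, feature, denominator = NULL,
                             rows = seq_len(nrow(table$values))) {
  j <- match(feature, table$features$feature_id)
  if (is.na(j)) stop("feature '", feature, "' not found in the table")
  s <- table$values[rows, j]
  if (!is.null(denominator)) {
    if (identical(denominator, feature))
      stop("ratio numerator and denominator must differ")
    jd <- match(denominator, table$features$feature_id)
    if (is.na(jd)) stop("feature '", denominator, "' not found in the table")
    den <- table$values[rows, jd]
    if (any(den == 0, na.rm = TRUE))
      stop("zero denominator in ratio ", feature, "/", denominator)
    s <- s / den
  }
  if (anyNA(s)) stop("candidate scores contain NA; impute below-LOD first")
  s
}

## internal: resampling design of a stratum. Units are participants; for the
## pooled "All" stratum each unit owns its four samples and is scored by the
## median of their values.
stratum_design <- function(table, stratum) {
  rows <- stratum_samples(table, stratum)
  s <- table$samples[rows, , drop = FALSE]
  unit_ids <- unique(s$participant_id)
  unit <- match(s$participant_id, unit_ids) - 1L
  unit_label <- group_indicator(s[match(unit_ids, s$participant_id), ,
                                  drop = FALSE])
  if (all(unit_label == unit_label[1L]))
    stop("stratum '", stratum, "' contains a single group")
  list(rows = rows, unit = unit, unit_ids = unit_ids,
       unit_label = unit_label)
}

## internal: stratified (within-group) bootstrap of units; m x B matrix of
## 0-based unit indices, deterministic given seed
make_boot_units <- function(unit_label, n_boot, seed) {
  if (n_boot < 2L) stop("'n_boot' must be at least 2")
  idx1 <- which(unit_label == 1L) - 1L
  idx0 <- which(unit_label == 0L) - 1L
  set.seed(seed)
  vapply(seq_len(n_boot), function(b)
    c(sample(idx0, length(idx0), replace = TRUE),
      sample(idx1, length(idx1), replace = TRUE)),
    integer(length(unit_label)))
}

#' Fit a threshold model on a feature table
#'
#' Fits a single-feature or two-feature-ratio threshold classifier on one
#' stratum (a collection point, or \code{"All"} for the pooled samples) by
#' the Youden index, and attaches full-data AUC and DeLong inference.
#'
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param feature feature id used as the score (or ratio numerator).
#' @param denominator optional feature id; when given the score is the
#'   concentration ratio \code{feature / denominator}.
#' @param stratum a time-point label or \code{"All"}.
#' @return an object of class \code{threshold_model}.
#' @export
threshold_model <- function(table, feature, denominator = NULL,
                            stratum = "Rest") {
  des <- stratum_design(table, stratum)
  scores <- candidate_scores(table, feature, denominator, des$rows)
  labels <- group_indicator(table$samples[des$rows, , drop = FALSE])
  fit <- youden_fit(scores, labels)
  oriented <- fit$orientation * scores
  dl <- delong_test(oriented, labels)
  structure(list(feature = feature, denominator = denominator,
                 stratum = stratum, orientation = fit$orientation,
                 cutoff = fit$cutoff, J = fit$J,
                 sensitivity = fit$sensitivity,
                 specificity = fit$specificity,
                 auc = dl$auc, delong = dl,
                 direction = if (fit$orientation == 1L) "up" else "down",
                 n = length(labels), n1 = sum(labels == 1L),
                 scores = scores, labels = labels,
                 call = match.call()),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  spec <- if (is.null(x$denominator)) x$feature
  else paste0(x$feature, "/", x$denominator)
  cat("threshold_model:", spec, "@", x$stratum, "\n")
  cat(sprintf("  predict high-stress iff score %s %.4g\n",
              if (x$orientation == 1L) ">=" else "<", x$cutoff))
  cat(sprintf("  J = %.3f (sens %.3f, spec %.3f); full-data AUC = %.3f\n",
              x$J, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  DeLong one-sided p (AUC > 0.5) = %.4g%s\n", x$delong$p,
              if (isTRUE(x$delong$degenerate)) " [degenerate variance]"
              else ""))
  cat("  association with high stress:",
      if (x$direction == "up") "higher score" else "lower score", "\n")
  invisible(x)
}

#' @export
coef.threshold_model <- function(object, ...) {
  c(cutoff = object$cutoff, orientation = object$orientation)
}

#' @export
summary.threshold_model <- function(object, ...) {
  print(object)
  pred <- predict(object)
  tab <- table(predicted = pred, actual = object$labels)
  cat("\nfull-data confusion (training stratum):\n")
  print(tab)
  invisible(object)
}

#' Predict from a threshold model
#'
#' @param object a \code{\link{threshold_model}}.
#' @param table optional \code{feature_table}; defaults to the training
#'   scores.
#' @param stratum stratum of \code{table} to predict on.
#' @param type \code{"class"} (0/1 high-stress indicator) or \code{"score"}.
#' @param ... ignored.
#' @return integer predictions or numeric scores, one per sample.
#' @export
predict.threshold_model <- function(object, table = NULL,
                                    stratum = object$stratum,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- if (is.null(table)) object$scores
  else candidate_scores(table, object$feature, object$denominator,
                        stratum_samples(table, stratum))
  if (type == "score") return(scores)
  if (object$orientation == 1L) as.integer(scores >= object$cutoff)
  else as.integer(scores < object$cutoff)
}

#' ROC curve of a threshold model
#'
#' Plots the full-data ROC curve of the model's oriented scores and marks
#' the fitted Youden cutoff.
#'
#' @param x a \code{\link{threshold_model}}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.threshold_model <- function(x, ...) {
  s <- x$orientation * x$scores
  y <- x$labels
  thr <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(s[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[y == 0L] >= t), numeric(1))
  plot(c(0, fpr, 1), c(0, sens, 1), type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  cut_or <- x$orientation * x$cutoff
  graphics::points(mean(s[y == 0L] >= cut_or), mean(s[y == 1L] >= cut_or),
                   pch = 19)
  invisible(x)
}

#' Leave-one-out cross-validation of a candidate
#'
#' Leaves out one participant at a time, refits the Youden threshold on the
#' remainder and predicts the held-out participant (for the pooled
#' \code{"All"} stratum a participant's four samples enter training together
#' and the participant is scored by their median, preventing
#' within-participant leakage). Held-out AUC is computed on the raw held-out
#' scores with the single orientation of the full-data fit.
#'
#' @inheritParams threshold_model
#' @return list with per-unit held-out \code{score}, \code{prediction} and
#'   \code{label}, and pooled \code{auc}, \code{accuracy}, \code{f1}.
#' @export
loocv_evaluate <- function(table, feature, denominator = NULL,
                           stratum = "Rest") {
  des <- stratum_design(table, stratum)
  scores <- candidate_scores(table, feature, denominator, des$rows)
  res <- cpp_loocv(scores, des$unit, des$unit_label)
  skipped <- sum(is.na(res$prediction))
  if (skipped > 0L)
    warning(skipped, " fold(s) skipped: training set had a single class")
  list(participant_id = des$unit_ids, score = res$heldout_score,
       prediction = res$prediction, label = des$unit_label,
       auc = res$auc, accuracy = res$accuracy, f1 = res$f1,
       orientation = res$orientation)
}

#' Bootstrap-nested LOOCV evaluation
#'
#' The study's evaluation protocol: participants are resampled with
#' replacement within each group (duplicates kept as distinct units), a full
#' leave-one-participant-out cross-validation is run inside each bootstrap
#' replicate, and AUC, accuracy and F1 are summarised across replicates by
#' their means and percentile confidence intervals.
#'
#' @inheritParams threshold_model
#' @param n_boot number of bootstrap iterations (study setting: 100).
#' @param seed integer seed; the same seed always reproduces the evaluation.
#' @param ci_level confidence level of the percentile intervals.
#' @return an object of class \code{resampled_evaluation}.
#' @export
bootstrap_loocv <- function(table, feature, denominator = NULL,
                            stratum = "Rest", n_boot = 100L, seed = 1L,
                            ci_level = 0.95) {
  des <- stratum_design(table, stratum)
  scores <- candidate_scores(table, feature, denominator, des$rows)
  boot <- make_boot_units(des$unit_label, n_boot, seed)
  res <- cpp_eval_candidates(matrix(scores, ncol = 1L), des$unit,
                             des$unit_label, boot)
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                        stats::quantile(v, probs, na.rm = TRUE, names = FALSE))
  full <- threshold_model(table, feature, denominator, stratum)
  structure(list(feature = feature, denominator = denominator,
                 stratum = stratum, n_boot = n_boot, seed = seed,
                 ci_level = ci_level,
                 auc = summ(res$auc[, 1L]),
                 accuracy = summ(res$accuracy[, 1L]),
                 f1 = summ(res$f1[, 1L]),
                 delong_p = full$delong$p,
                 direction = full$direction,
                 full_auc = full$auc),
            class = "resampled_evaluation")
}

#' @export
print.resampled_evaluation <- function(x, ...) {
  spec <- if (is.null(x$denominator)) x$feature
  else paste0(x$feature, "/", x$denominator)
  cat("resampled_evaluation:", spec, "@", x$stratum,
      sprintf("(%d bootstrap iterations, LOOCV inside each)\n", x$n_boot))
  fmt <- function(nm, v) cat(sprintf("  %-9s %.3f [%.3f - %.3f]\n",
                                     nm, v[1L], v[2L], v[3L]))
  fmt("AUC", x$auc); fmt("accuracy", x$accuracy); fmt("F1", x$f1)
  cat(sprintf("  DeLong one-sided p = %.4g; association: %s with stress\n",
              x$delong_p, x$direction))
  invisible(x)
}

#' Exhaustive threshold-model search
#'
#' Evaluates every feature (\code{family = "single"}) or every unordered
#' feature pair as one canonical ratio, numerator before denominator in the
#' table's feature order (\code{family = "ratio"}; the reciprocal is
#' redundant under a threshold model, only the orientation flips), by
#' \code{\link{bootstrap_loocv}}, and ranks candidates by mean bootstrap
#' AUC.
#'
#' @inheritParams bootstrap_loocv
#' @param family \code{"single"} or \code{"ratio"}.
#' @param features optional feature-id subset to restrict the search to.
#' @return a \code{model_search} data.frame, one row per candidate, ranked
#'   by mean AUC, with mean and CI columns for AUC/accuracy/F1, the
#'   full-data AUC, DeLong p and association direction.
#' @export
search_models <- function(table, stratum = "Rest",
                          family = c("single", "ratio"), n_boot = 100L,
                          seed = 1L, ci_level = 0.95, features = NULL) {
  family <- match.arg(family)
  des <- stratum_design(table, stratum)
  feats <- table$features$feature_id
  if (!is.null(features)) {
    miss <- setdiff(features, feats)
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    feats <- features
  }
  vals <- table$values[des$rows, match(feats, table$features$feature_id),
                       drop = FALSE]
  if (anyNA(vals)) stop("table contains below-LOD cells; impute first")
  if (family == "single") {
    scoremat <- vals
    num <- feats; den <- rep(NA_character_, length(feats))
  } else {
    pr <- utils::combn(length(feats), 2L)
    scoremat <- vals[, pr[1L, ], drop = FALSE] / vals[, pr[2L, ], drop = FALSE]
    num <- feats[pr[1L, ]]; den <- feats[pr[2L, ]]
  }
  labels <- group_indicator(table$samples[des$rows, , drop = FALSE])

  boot <- make_boot_units(des$unit_label, n_boot, seed)
  res <- cpp_eval_candidates(scoremat, des$unit, des$unit_label, boot)
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  qlo <- function(m) cpp_col_quantiles(m, probs)[1L, ]
  qhi <- function(m) cpp_col_quantiles(m, probs)[2L, ]

  C <- ncol(scoremat)
  full_auc <- numeric(C); delong_p <- numeric(C); dir <- character(C)
  for (cc in seq_len(C)) {
    f <- cpp_youden(scoremat[, cc], labels)
    oriented <- f$orientation * scoremat[, cc]
    dl <- delong_test(oriented, labels)
    full_auc[cc] <- dl$auc
    delong_p[cc] <- dl$p
    dir[cc] <- if (f$orientation == 1L) "up" else "down"
  }

  out <- data.frame(
    feature = num, denominator = den,
    spec = ifelse(is.na(den), num, paste0(num, "/", den)),
    stratum = stratum,
    auc_mean = colMeans(res$auc, na.rm = TRUE),
    auc_lo = qlo(res$auc), auc_hi = qhi(res$auc),
    accuracy_mean = colMeans(res$accuracy, na.rm = TRUE),
    accuracy_lo = qlo(res$accuracy), accuracy_hi = qhi(res$accuracy),
    f1_mean = colMeans(res$f1, na.rm = TRUE),
    f1_lo = qlo(res$f1), f1_hi = qhi(res$f1),
    full_auc = full_auc, delong_p = delong_p, direction = dir,
    stringsAsFactors = FALSE)
  out <- out[order(-out$auc_mean, out$spec), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family") <- family
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "stratum") <- stratum
  class(out) <- c("model_search", "data.frame")
  out
}

#' @export
print.model_search <- function(x, n = 10L, ...) {
  cat("model_search:", nrow(x), attr(x, "family"), "candidates @",
      attr(x, "stratum"), sprintf("(n_boot = %d)\n", attr(x, "n_boot")))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("spec", "auc_mean", "auc_lo", "auc_hi",
                           "accuracy_mean", "f1_mean", "delong_p",
                           "direction")]
  print(df, digits = 3)
  invisible(x)
}

#' Per-stratum CI-lower-bound selection thresholds
#'
#' The selection bar applied to ranked candidates: a model is kept only when
#' the lower bounds of its 95 percent bootstrap CIs strictly exceed
#' AUC 0.60 (0.65 at the final collection point, where candidates are more
#' numerous and stronger; 0.50 for the pooled stratum), accuracy 0.50 and
#' F1 0.50.
#'
#' @param stratum stratum label.
#' @param time_points the study's collection points, in order.
#' @return named vector with \code{auc}, \code{accuracy}, \code{f1}.
#' @export
selection_thresholds <- function(stratum,
                                 time_points = c("Rest", "Post-UK",
                                                 "Recover", "Post-WM")) {
  k <- length(time_points)
  auc_thr <- if (identical(stratum, "All")) 0.50
  else if (identical(stratum, time_points[k])) 0.65
  else if (stratum %in% time_points) 0.60
  else stop("unknown stratum '", stratum, "'")
  c(auc = auc_thr, accuracy = 0.50, f1 = 0.50)
}

#' Select models by CI lower bounds
#'
#' Applies the per-stratum strict CI-lower-bound thresholds of
#' \code{\link{selection_thresholds}} to a \code{\link{search_models}}
#' result.
#'
#' @param ranked a \code{model_search} data.frame.
#' @param stratum stratum label (defaults to the search's stratum).
#' @param thresholds optional named vector overriding
#'   \code{\link{selection_thresholds}}.
#' @param time_points collection-point labels used to resolve the default
#'   thresholds.
#' @return the selected subset, ordered by mean AUC.
#' @export
select_models <- function(ranked, stratum = attr(ranked, "stratum"),
                          thresholds = NULL,
                          time_points = c("Rest", "Post-UK", "Recover",
                                          "Post-WM")) {
  if (is.null(thresholds))
    thresholds <- selection_thresholds(stratum, time_points)
  keep <- ranked$auc_lo > thresholds["auc"] &
    ranked$accuracy_lo > thresholds["accuracy"] &
    ranked$f1_lo > thresholds["f1"]
  out <- ranked[keep, , drop = FALSE]
  out <- out[order(-out$auc_mean, out$spec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a fitted model to other collection points
#'
#' Keeps the cutoff and orientation fixed at their training-stratum values
#' and evaluates classification of each target stratum's participants.
#'
#' @param model a \code{\link{threshold_model}}.
#' @param table a filtered, imputed \code{\link{feature_table}}.
#' @param strata character vector of target strata (time points or
#'   \code{"All"}).
#' @return data.frame with one row per stratum: \code{accuracy}, \code{f1},
#'   \code{auc} (of the oriented scores).
#' @export
transfer_evaluate <- function(model, table,
                              strata = levels(table$samples$time_point)) {
  res <- lapply(strata, function(st) {
    des <- stratum_design(table, st)
    scores <- candidate_scores(table, model$feature, model$denominator,
                               des$rows)
    unit_score <- vapply(split(scores, des$unit), stats::median, numeric(1))
    unit_score <- unit_score[order(as.integer(names(unit_score)))]
    pred <- if (model$orientation == 1L) unit_score >= model$cutoff
    else unit_score < model$cutoff
    lab <- des$unit_label
    tp <- sum(pred & lab == 1L); tn <- sum(!pred & lab == 0L)
    fp <- sum(pred & lab == 0L); fn <- sum(!pred & lab == 1L)
    data.frame(stratum = st,
               accuracy = (tp + tn) / length(lab),
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
               else 1,
               auc = auc(model$orientation * unit_score, lab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
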