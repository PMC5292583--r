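#' Leave-one-out linear SVM classification with per-fold screening
#'
#' Each subject is held out once; on the remaining subjects features
#' are optionally screened by a two-sample t-test (keep p < alpha),
#' standardized (training mean/sd only — no statistic ever sees the
#' held-out subject), and a linear soft-margin SVM (fixed cost) is
#' trained to predict the held-out subject. Folds with no surviving
#' features predict the training-set majority class. Missing feature
#' values are imputed with the training-fold column mean.
#'
#' Sensitivity is the correct-classification rate of the first factor
#' level, specificity that of the second.
#'
#' @param features subject x feature numeric matrix.
#' @param labels two-level factor (or coercible); first level is the
#'   "positive" class for sensitivity.
#' @param screen logical, per-fold univariate feature screening.
#' @param alpha screening threshold.
#' @param cost SVM regularization constant.
#' @return list with accuracy, sensitivity, specificity, per-fold
#'   predictions and per-fold surviving-feature counts.
#' @export
loocvSVM <- function(features, labels, screen = TRUE, alpha = 0.05,
                     cost = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) .stopf("exactly two classes required")
  if (min(table(labels)) < 2) .stopf("need >= 2 subjects per class")
  n <- nrow(features)
  pred <- factor(rep(NA, n), levels = levels(labels))
  nfeat <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- features[-i, , drop = FALSE]
    ytr <- labels[-i]
    # training-fold imputation of missing values
    if (anyNA(Xtr) || anyNA(features[i, ])) {
      mu <- apply(Xtr, 2, function(x) mean(x, na.rm = TRUE))
      for (j in which(colSums(is.na(Xtr)) > 0))
        Xtr[is.na(Xtr[, j]), j] <- mu[j]
      xte <- features[i, ]
      xte[is.na(xte)] <- mu[is.na(xte)]
    } else xte <- features[i, ]
    keep <- rep(TRUE, ncol(Xtr))
    if (screen) {
      tt <- .colWelchT(Xtr[ytr == levels(labels)[1], , drop = FALSE],
                       Xtr[ytr == levels(labels)[2], , drop = FALSE])
      keep <- !is.na(tt$p) & tt$p < alpha
    }
    sds <- apply(Xtr, 2, stats::sd)
    keep <- keep & sds > 0
    nfeat[i] <- sum(keep)
    if (!any(keep)) {
      maj <- names(which.max(table(ytr)))
      pred[i] <- maj
      .noticef("fold %d: no surviving features; predicting training majority '%s'",
               i, maj)
      next
    }
    mu <- colMeans(Xtr[, keep, drop = FALSE])
    sd <- sds[keep]
    Ztr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu), 2, sd, "/")
    zte <- (xte[keep] - mu) / sd
    fit <- e1071::svm(Ztr, ytr, kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[i] <- stats::predict(fit, matrix(zte, nrow = 1))
  }
  correct <- pred == labels
  pos <- labels == levels(labels)[1]
  list(accuracy = mean(correct),
       sensitivity = mean(correct[pos]),
       specificity = mean(correct[!pos]),
       perFold = data.frame(truth = labels, predicted = pred,
                            correct = correct),
       nFeaturesPerFold = nfeat,
       levels = levels(labels))
}

#' Permutation test of LOOCV classification accuracy
#'
#' Re-runs the full leave-one-out procedure (including per-fold
#' screening) under \code{R} random relabelings and reports the
#' add-one permutation p-value \code{(1 + #{null >= observed}) /
#' (1 + R)}, which can never be exactly zero.
#'
#' @inheritParams loocvSVM
#' @param R number of permutations (10000 in the full analysis
#'   profile).
#' @param seed integer seed.
#' @return list with observed accuracy, null accuracies and p-value.
#' @export
permutationTest <- function(features, labels, R = 10000, screen = TRUE,
                            alpha = 0.05, cost = 1, seed = 1) {
  obs <- loocvSVM(features, labels, screen = screen, alpha = alpha,
                  cost = cost)$accuracy
  null <- .withSeed(seed, vapply(seq_len(R), function(r) {
    suppressMessages(
      loocvSVM(features, sample(labels), screen = screen, alpha = alpha,
               cost = cost)$accuracy)
  }, numeric(1)))
  list(observed = obs, null = null,
       p.value = (1 + sum(null >= obs)) / (1 + R))
}

#' Validate the sliding-window width by classification accuracy
#'
#' For each candidate width, windowed trajectories are computed for the
#' two contrasted groups, summarised per subject as
#' amplitude-of-low-frequency-fluctuation maps (\code{\link{alffFC}}),
#' and fed to \code{\link{loocvSVM}} with per-fold screening. The
#' selected width maximises accuracy, with ties broken towards 44 s and
#' then towards the smaller width; a maximum accuracy below 0.6 flags
#' the selection as low-confidence.
#'
#' @param cohort named list of filtered
#'   \code{\linkS4class{SubjectTimecourses}}.
#' @param groups character(2), the two group labels to contrast (the
#'   first is the sensitivity class).
#' @param widths candidate widths in seconds.
#' @param lambda graphical-LASSO penalty.
#' @param sigmaTr taper sd in TRs.
#' @param band,normConst passed to \code{\link{alffFC}}.
#' @param cost,alpha passed to \code{\link{loocvSVM}}.
#' @return list with per-width CV results and accuracies, the selected
#'   width, a low-confidence flag, and the per-width windowed
#'   trajectories (reusable downstream).
#' @export
windowValidation <- function(cohort, groups, widths = c(30, 40, 44, 50, 60),
                             lambda = 0.1, sigmaTr = 3,
                             band = c(0.01, 0.08), normConst = 0.5,
                             cost = 1, alpha = 0.05) {
  sel <- Filter(function(s) s@group %in% groups, cohort)
  if (!length(sel)) .stopf("no subjects in groups %s", paste(groups, collapse = "/"))
  labels <- factor(vapply(sel, function(s) s@group, ""), levels = groups)
  results <- list(); wfncAll <- list()
  acc <- numeric(length(widths))
  for (wi in seq_along(widths)) {
    win <- makeTaperedWindow(widths[wi], sel[[1]]@TR, sigmaTr)
    wf <- lapply(sel, windowedFNC, window = win, lambda = lambda)
    feats <- do.call(rbind, lapply(wf, alffFC, band = band,
                                   normConst = normConst))
    cv <- loocvSVM(feats, labels, screen = TRUE, alpha = alpha, cost = cost)
    results[[as.character(widths[wi])]] <- cv
    wfncAll[[as.character(widths[wi])]] <- wf
    acc[wi] <- cv$accuracy
  }
  best <- which(acc == max(acc))
  if (length(best) > 1) {
    best <- if (any(widths[best] == 44)) best[widths[best] == 44]
            else best[which.min(widths[best])]
  }
  list(results = results, accuracies = stats::setNames(acc, widths),
       selectedWidth = widths[best[1]],
       lowConfidence = max(acc) < 0.6,
       wfnc = wfncAll)
}

#' Classification from static, dynamic and combined predictors
#'
#' Three leave-one-out runs of the linear SVM — static-only,
#' dynamic-only and combined feature tables — with screening off (the
#' features are pre-selected summaries: significant static pairs, and
#' per-state fraction of time and mean dwell). Missing dynamic entries
#' (a subject never visiting a state has no dwell) are imputed with
#' training-fold means and flagged.
#'
#' @param staticFeatures subject x feature matrix (e.g. the 7
#'   significant static pairs).
#' @param dynamicFeatures subject x feature matrix (e.g. 3 fractions +
#'   3 dwells).
#' @param labels two-level factor aligned with the rows.
#' @param cost SVM regularization constant.
#' @return list of three CV results: \code{static}, \code{dynamic},
#'   \code{combined}.
#' @export
combinedClassification <- function(staticFeatures, dynamicFeatures, labels,
                                   cost = 1) {
  staticFeatures <- as.matrix(staticFeatures)
  dynamicFeatures <- as.matrix(dynamicFeatures)
  if (nrow(staticFeatures) != nrow(dynamicFeatures))
    .stopf("feature tables are not aligned by subject")
  if (anyNA(dynamicFeatures))
    .noticef("%d missing dynamic feature value(s); imputed per training fold",
             sum(is.na(dynamicFeatures)))
  list(static = loocvSVM(staticFeatures, labels, screen = FALSE, cost = cost),
       dynamic = loocvSVM(dynamicFeatures, labels, screen = FALSE, cost = cost),
       combined = loocvSVM(cbind(staticFeatures, dynamicFeatures), labels,
                           screen = FALSE, cost = cost))
}
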