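#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis with the defaults
#' used throughout the package: 0.01-0.15 Hz band, despike threshold 4
#' robust sds, window grid {30, 40, 44, 50, 60} s with a sigma = 3 TR
#' taper, graphical-LASSO penalty 0.1, k grid 2..8 (or a fixed k),
#' 10 k-means replicates, FDR alpha 0.05, and named seeds per
#' stochastic stage.
#'
#' @param band band-pass edges, Hz.
#' @param despikeThresh despike threshold, robust sds.
#' @param widths sliding-window grid, seconds.
#' @param sigmaTr taper sd, TRs.
#' @param lambda graphical-LASSO penalty.
#' @param k fixed state count, or NULL to select via \code{kGrid}.
#' @param kGrid elbow grid.
#' @param replicates k-means restarts.
#' @param nBoot bootstrap resamples for state-contrast stability.
#' @param permReps permutation-test iterations (0 disables).
#' @param alpha FDR significance level.
#' @param classifyGroups character(2): the groups contrasted by the
#'   window validation and classification stages.
#' @param contrasts list of \code{list(A=, B=, paired=)} group
#'   contrasts; when NULL, a two-sample contrast of
#'   \code{classifyGroups} is used.
#' @param nStaticFeatures static predictors for classification.
#' @param seeds named list of integer seeds per stage.
#' @return validated configuration list (class \code{dfncConfig}).
#' @export
runConfig <- function(band = c(0.01, 0.15), despikeThresh = 4,
                      widths = c(30, 40, 44, 50, 60), sigmaTr = 3,
                      lambda = 0.1, k = NULL, kGrid = 2:8,
                      replicates = 10, nBoot = 10000, permReps = 0,
                      alpha = 0.05, classifyGroups = NULL,
                      contrasts = NULL, nStaticFeatures = 7,
                      seeds = list(cluster = 11L, boot = 12L, perm = 13L)) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            despikeThresh > 0, all(widths > 0), sigmaTr > 0, lambda >= 0,
            replicates >= 1, nBoot >= 0, permReps >= 0,
            alpha > 0, alpha < 1)
  cfg <- list(band = band, despikeThresh = despikeThresh, widths = widths,
              sigmaTr = sigmaTr, lambda = lambda, k = k, kGrid = kGrid,
              replicates = replicates, nBoot = nBoot, permReps = permReps,
              alpha = alpha, classifyGroups = classifyGroups,
              contrasts = contrasts, nStaticFeatures = nStaticFeatures,
              seeds = seeds)
  class(cfg) <- "dfncConfig"
  cfg
}

.writeTSV <- function(x, path, rowNames = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
}

#' Run the full dynamic-connectivity pipeline
#'
#' Executes, in order: postprocessing (FD regression, detrend, despike,
#' band-pass), static connectivity with group contrasts, sliding-window
#' connectivity over the width grid with SVM window validation, state
#' clustering at the selected width (elbow k selection unless a fixed k
#' is configured), state occupancy statistics with group contrasts,
#' transition and clinical tests, bootstrap-screened state connectivity
#' contrasts, and static/dynamic/combined classification. All artifacts
#' are written as delimited text under \code{outDir}, stamped with the
#' configuration (serialized and md5-hashed) and the per-stage seeds; a
#' machine-readable \code{summary.yaml} and human-readable
#' \code{report.txt} close the run. Any stage failure halts with the
#' stage and subject named; single-group cohorts skip between-group
#' stages with explicit "skipped" records.
#'
#' @param cohort named list of raw
#'   \code{\linkS4class{SubjectTimecourses}} (e.g. from
#'   \code{\link{simulateCohort}} or \code{\link{readCohort}}).
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory.
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(cohort, config = runConfig(), outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  stageError <- function(stage, e, subject = NULL)
    .stopf("pipeline stage '%s' failed%s: %s", stage,
           if (is.null(subject)) "" else paste0(" for subject ", subject),
           conditionMessage(e))

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  summary$config_md5 <- cfgHash
  summary$seeds <- config$seeds

  groups <- unique(vapply(cohort, function(s) s@group, ""))
  classifyGroups <- config$classifyGroups
  if (is.null(classifyGroups) && length(groups) >= 2)
    classifyGroups <- groups[1:2]
  twoGroup <- length(groups) >= 2

  ## -- postprocess -------------------------------------------------------
  filtered <- lapply(cohort, function(s) {
    tryCatch(postprocessSubject(s, band = config$band,
                                despikeThresh = config$despikeThresh),
             error = function(e) stageError("postprocess", e, s@subject))
  })

  ## -- static FNC --------------------------------------------------------
  fnc <- tryCatch(lapply(filtered, staticFNC),
                  error = function(e) stageError("static_fnc", e))
  for (g in groups) {
    gm <- groupMeanFNC(fnc[vapply(filtered, function(s) s@group == g, TRUE)])
    .writeTSV(round(gm, 10), file.path(outDir, sprintf("static_mean_%s.tsv", g)),
              rowNames = TRUE)
  }
  contrasts <- config$contrasts
  if (is.null(contrasts) && twoGroup)
    contrasts <- list(list(A = classifyGroups[1], B = classifyGroups[2],
                           paired = FALSE))
  staticContrasts <- list()
  if (is.null(contrasts)) {
    summary$static_contrasts <- "skipped: fewer than two groups"
  } else {
    for (ct in contrasts) {
      nm <- sprintf("%s_vs_%s", ct$A, ct$B)
      subA <- fnc[vapply(filtered, function(s) s@group == ct$A, TRUE)]
      subB <- fnc[vapply(filtered, function(s) s@group == ct$B, TRUE)]
      if (isTRUE(ct$paired)) {
        names(subA) <- vapply(filtered[names(subA)], function(s) s@pairKey, "")
        names(subB) <- vapply(filtered[names(subB)], function(s) s@pairKey, "")
        common <- intersect(names(subA), names(subB))
        subA <- subA[common]; subB <- subB[common]
      }
      res <- tryCatch(groupContrast(subA, subB, paired = isTRUE(ct$paired),
                                    alpha = config$alpha),
                      error = function(e) stageError("static_fnc", e))
      staticContrasts[[nm]] <- res
      .writeTSV(res, file.path(outDir, sprintf("static_contrast_%s.tsv", nm)))
    }
    summary$static_significant <- lapply(staticContrasts, function(r)
      r$pair[r$significant])
  }

  ## -- window validation -------------------------------------------------
  if (twoGroup) {
    wv <- tryCatch(
      windowValidation(filtered, classifyGroups, widths = config$widths,
                       lambda = config$lambda, sigmaTr = config$sigmaTr,
                       cost = 1, alpha = config$alpha),
      error = function(e) stageError("window_validation", e))
    .writeTSV(data.frame(width_s = as.numeric(names(wv$accuracies)),
                         accuracy = unname(wv$accuracies)),
              file.path(outDir, "window_validation.tsv"))
    selectedWidth <- wv$selectedWidth
    summary$window_validation <- list(
      selected_width_s = selectedWidth,
      accuracies = as.list(wv$accuracies),
      low_confidence = wv$lowConfidence)
    if (config$permReps > 0) {
      win <- makeTaperedWindow(selectedWidth, filtered[[1]]@TR, config$sigmaTr)
      sel <- Filter(function(s) s@group %in% classifyGroups, filtered)
      feats <- do.call(rbind, lapply(wv$wfnc[[as.character(selectedWidth)]],
                                     alffFC))
      labs <- factor(vapply(sel, function(s) s@group, ""),
                     levels = classifyGroups)
      pt <- permutationTest(feats, labs, R = config$permReps,
                            seed = config$seeds$perm)
      summary$window_validation$permutation_p <- pt$p.value
    }
  } else {
    selectedWidth <- 44
    summary$window_validation <- "skipped: fewer than two groups; width 44 s used"
  }

  ## -- clustering at the selected width ---------------------------------
  win <- makeTaperedWindow(selectedWidth, filtered[[1]]@TR, config$sigmaTr)
  wfnc <- lapply(filtered, function(s)
    tryCatch(windowedFNC(s, win, lambda = config$lambda),
             error = function(e) stageError("dynamic_fnc", e, s@subject)))
  exemplars <- tryCatch(selectExemplars(wfnc),
                        error = function(e) stageError("clustering", e))
  if (is.null(config$k)) {
    elbow <- chooseK(exemplars, kGrid = config$kGrid,
                     replicates = config$replicates,
                     seed = config$seeds$cluster)
    .writeTSV(data.frame(k = elbow@kValues, ratio = elbow@ratio),
              file.path(outDir, "elbow_curve.tsv"))
    kUse <- elbow@kSelected
    summary$clustering <- list(k_selected = kUse, flagged = elbow@flagged)
  } else {
    kUse <- config$k
    summary$clustering <- list(k_fixed = kUse)
  }
  exModel <- fitStates(exemplars, kUse, replicates = config$replicates,
                       seed = config$seeds$cluster)
  model <- orderStatesByConnectivity(assignAllWindows(wfnc, exModel))
  .writeTSV(round(centroids(model), 10), file.path(outDir, "state_centroids.tsv"))
  assignTab <- data.frame(
    subject = rep(names(assignments(model)),
                  vapply(assignments(model), length, 1L)),
    state = unlist(assignments(model), use.names = FALSE))
  .writeTSV(assignTab, file.path(outDir, "state_assignments.tsv"))

  ## -- state statistics --------------------------------------------------
  occ <- occupancyOfModel(model, wfnc)
  occTab <- do.call(rbind, lapply(occ, function(o)
    data.frame(subject = o@subject, group = o@group, session = o@session,
               state = seq_len(kUse), mean_dwell_windows = o@meanDwell,
               mean_dwell_s = o@meanDwell * o@TR, fraction = o@fraction)))
  .writeTSV(occTab, file.path(outDir, "occupancy.tsv"), rowNames = FALSE)

  medians <- lapply(names(wfnc), function(id)
    subjectStateMedians(wfnc[[id]], assignments(model)[[id]], kUse))
  names(medians) <- names(wfnc)

  occContrasts <- list(); stateContrasts <- list(); transTests <- list()
  if (is.null(contrasts)) {
    summary$occupancy_contrasts <- "skipped: fewer than two groups"
    summary$state_contrasts <- "skipped: fewer than two groups"
    summary$transition_tests <- "skipped: fewer than two groups"
  } else {
    for (ct in contrasts) {
      nm <- sprintf("%s_vs_%s", ct$A, ct$B)
      inA <- vapply(filtered, function(s) s@group == ct$A, TRUE)
      inB <- vapply(filtered, function(s) s@group == ct$B, TRUE)
      oc <- occupancyContrast(occ[inA], occ[inB], paired = isTRUE(ct$paired))
      occContrasts[[nm]] <- oc
      .writeTSV(oc, file.path(outDir, sprintf("occupancy_contrast_%s.tsv", nm)))
      transTests[[nm]] <- transitionTest(occ[inA], occ[inB])
      medA <- medians[inA]; medB <- medians[inB]
      if (isTRUE(ct$paired)) {
        names(medA) <- vapply(filtered[names(medians)[inA]],
                              function(s) s@pairKey, "")
        names(medB) <- vapply(filtered[names(medians)[inB]],
                              function(s) s@pairKey, "")
        common <- intersect(names(medA), names(medB))
        medA <- medA[common]; medB <- medB[common]
      }
      sc <- do.call(rbind, lapply(seq_len(kUse), function(s)
        stateContrast(medA, medB, s, paired = isTRUE(ct$paired),
                      nBoot = config$nBoot, alpha = config$alpha,
                      seed = config$seeds$boot)))
      stateContrasts[[nm]] <- sc
      if (!is.null(sc))
        .writeTSV(sc, file.path(outDir, sprintf("state_contrast_%s.tsv", nm)))
    }
    summary$occupancy_contrasts <- lapply(occContrasts, function(oc)
      lapply(seq_len(nrow(oc)), function(i)
        list(state = oc$state[i], metric = oc$metric[i], p = oc$p[i])))
    summary$stable_state_pairs <- lapply(stateContrasts, function(sc)
      if (is.null(sc)) character(0) else paste(sc$state[sc$stable],
                                               sc$pair[sc$stable]))
    summary$transition_tests <- lapply(transTests, function(tt)
      list(statistic = tt$statistic, df = tt$df, p = tt$p.value))
  }

  ## clinical correlation where follow-up scores exist
  clin <- do.call(rbind, lapply(filtered, function(s)
    data.frame(pairKey = s@pairKey, baseline = s@clinicalScores[["baseline"]],
               followup = s@clinicalScores[["followup"]])))
  clin <- unique(clin[stats::complete.cases(clin), , drop = FALSE])
  if (nrow(clin) >= 3 && twoGroup) {
    baseGroup <- classifyGroups[2]
    occBase <- occ[vapply(filtered, function(s) s@group == baseGroup, TRUE)]
    cc <- clinicalCorrelation(occBase, clin)
    .writeTSV(cc, file.path(outDir, "clinical_correlation.tsv"))
    summary$clinical_correlation <- "written"
  } else {
    summary$clinical_correlation <- "skipped: no usable clinical scores"
  }

  ## -- classification ----------------------------------------------------
  if (twoGroup && length(staticContrasts)) {
    sel <- vapply(filtered, function(s) s@group %in% classifyGroups, TRUE)
    labs <- factor(vapply(filtered[sel], function(s) s@group, ""),
                   levels = classifyGroups)
    ctab <- staticContrasts[[1]]
    topPairs <- utils::head(ctab[order(ctab$p_raw), ], config$nStaticFeatures)
    staticFeat <- do.call(rbind, lapply(fnc[sel], function(m)
      m[cbind(topPairs$i, topPairs$j)]))
    colnames(staticFeat) <- topPairs$pair
    dynFeat <- do.call(rbind, lapply(occ[sel], function(o)
      c(stats::setNames(o@fraction, paste0("fraction_s", seq_len(kUse))),
        stats::setNames(o@meanDwell, paste0("dwell_s", seq_len(kUse))))))
    cls <- tryCatch(combinedClassification(staticFeat, dynFeat, labs),
                    error = function(e) stageError("classification", e))
    clsTab <- data.frame(
      features = c("static", "dynamic", "combined"),
      accuracy = vapply(cls, `[[`, numeric(1), "accuracy"),
      sensitivity = vapply(cls, `[[`, numeric(1), "sensitivity"),
      specificity = vapply(cls, `[[`, numeric(1), "specificity"))
    .writeTSV(clsTab, file.path(outDir, "classification.tsv"))
    summary$classification <- lapply(cls, function(x)
      list(accuracy = x$accuracy, sensitivity = x$sensitivity,
           specificity = x$specificity))
  } else {
    summary$classification <- "skipped: fewer than two groups"
  }

  yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
  rep <- c(sprintf("dynFNC pipeline run (config md5 %s)", cfgHash),
           sprintf("subjects: %d in groups %s", length(cohort),
                   paste(groups, collapse = ", ")),
           sprintf("selected window: %s s", selectedWidth),
           sprintf("states: k = %d", kUse))
  writeLines(rep, file.path(outDir, "report.txt"))
  invisible(list(filtered = filtered, fnc = fnc,
                 staticContrasts = staticContrasts,
                 selectedWidth = selectedWidth, wfnc = wfnc, model = model,
                 occ = occ, occContrasts = occContrasts,
                 stateContrasts = stateContrasts, summary = summary))
}
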