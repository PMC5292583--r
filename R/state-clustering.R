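# Perpendicular distance of each curve point to the chord joining the
# endpoints, both axes scaled to [0, 1]; the knee maximises it.
.chordDistance <- function(k, ratio) {
  x <- (k - k[1]) / max(diff(range(k)), 1L)
  y <- (ratio - min(ratio)) / max(diff(range(ratio)), .Machine$double.eps)
  n <- length(x)
  len <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  abs((y[n] - y[1]) * x - (x[n] - x[1]) * y + x[n] * y[1] - y[n] * x[1]) / len
}

# L1 k-means core: assignment by sum of absolute differences, centroid
# update by element-wise median. `centroids` supplies the initial
# positions; no randomness inside.
.kmeansL1 <- function(X, centroids, maxIter = 150) {
  M <- nrow(X)
  k <- nrow(centroids)
  assign <- integer(M)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    D <- vapply(seq_len(k),
                function(c) rowSums(abs(X - rep(centroids[c, ], each = M))),
                numeric(M))
    if (M == 1) D <- matrix(D, nrow = 1)
    newAssign <- max.col(-D, ties.method = "first")
    for (c in which(tabulate(newAssign, k) == 0L)) {
      # empty cluster: reseed at the point farthest (L1) from its centroid
      far <- which.max(D[cbind(seq_len(M), newAssign)])
      .noticef("k-means: cluster %d emptied; reseeding at point %d", c, far)
      centroids[c, ] <- X[far, ]
      D[, c] <- rowSums(abs(X - rep(centroids[c, ], each = M)))
      newAssign[far] <- c
    }
    inertia <- sum(D[cbind(seq_len(M), newAssign)])
    trace <- c(trace, inertia)
    if (it > 1 && all(newAssign == assign)) break
    assign <- newAssign
    for (c in seq_len(k))
      centroids[c, ] <- .colMedians(X[assign == c, , drop = FALSE])
  }
  list(centroids = centroids, assign = assign, inertia = inertia,
       iterations = it, inertiaTrace = trace)
}

#' Select exemplar windows at variance maxima
#'
#' For each subject, the variance across the P connectivity values of
#' every window defines a series over window starts; windows at strict
#' local maxima of this series (one-sided comparison at the endpoints)
#' are kept as exemplars for the initial clustering stage. A subject
#' with a constant variance series contributes its single
#' maximum-variance window (earliest on ties) with a notice.
#'
#' @param wfncList named list of \code{\linkS4class{WindowedFNC}}.
#' @return an \code{\linkS4class{ExemplarSet}}.
#' @export
selectExemplars <- function(wfncList) {
  rows <- list(); prov <- list()
  for (w in wfncList) {
    v <- apply(w@trajectory, 1, stats::var)
    n <- length(v)
    if (n < 3) .stopf("subject %s has only %d windows; need >= 3", w@subject, n)
    hits <- which(c(v[1] > v[2],
                    v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
                    v[n] > v[n - 1]))
    if (!length(hits)) {
      hits <- which.max(v)
      .noticef("subject %s: no strict variance maxima; keeping max-variance window %d",
               w@subject, hits)
    }
    rows[[w@subject]] <- w@trajectory[hits, , drop = FALSE]
    prov[[w@subject]] <- data.frame(subject = w@subject,
                                    windowStart = w@windowStarts[hits],
                                    stringsAsFactors = FALSE)
  }
  new("ExemplarSet", rows = do.call(rbind, unname(rows)),
      provenance = do.call(rbind, unname(prov)))
}

#' Cluster exemplar windows into connectivity states
#'
#' k-means with L1 (sum of absolute differences) distance and
#' element-wise median centroid updates, capped at \code{maxIter}
#' iterations; the best of \code{replicates} seeded random
#' initialisations (by total L1 inertia) is returned. Deterministic
#' given \code{seed}.
#'
#' @param exemplars an \code{\linkS4class{ExemplarSet}} (or a plain
#'   numeric matrix of points).
#' @param k number of states.
#' @param maxIter iteration cap per replicate.
#' @param replicates random restarts.
#' @param seed integer seed.
#' @param pairNames optional connectivity-pair labels.
#' @return a \code{\linkS4class{StateModel}} at the exemplar stage; the
#'   exemplar labels are in \code{assignments(model)$.exemplars}.
#' @export
fitStates <- function(exemplars, k, maxIter = 150, replicates = 10, seed = 1,
                      pairNames = NULL) {
  X <- if (is(exemplars, "ExemplarSet")) exemplars@rows else as.matrix(exemplars)
  M <- nrow(X)
  if (M < k) .stopf("only %d exemplars for k = %d states", M, k)
  if (is.null(pairNames)) pairNames <- colnames(X)
  if (is.null(pairNames)) pairNames <- paste0("p", seq_len(ncol(X)))
  fits <- .withSeed(seed, lapply(seq_len(replicates), function(r) {
    init <- X[sample.int(M, k), , drop = FALSE]
    .kmeansL1(X, init, maxIter)
  }))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
  new("StateModel", k = as.integer(k), centroids = unname(best$centroids),
      assignments = list(.exemplars = best$assign), inertia = best$inertia,
      stage = "exemplar", pairNames = pairNames)
}

#' Choose the number of states by the elbow criterion
#'
#' Fits the exemplar-stage clustering over a grid of candidate k and
#' computes, per k, the ratio of within-cluster to between-cluster
#' sum-of-squares distance (squared Euclidean, per the criterion's
#' definition, while the clustering itself uses L1). The selected k is
#' the point of maximum perpendicular distance to the chord joining the
#' curve's endpoints, after scaling both axes to [0, 1]. Non-monotone
#' or nearly flat curves are flagged rather than rejected.
#'
#' @param exemplars an \code{\linkS4class{ExemplarSet}} or matrix.
#' @param kGrid candidate state counts.
#' @param maxIter,replicates,seed passed to \code{\link{fitStates}}.
#' @return an \code{\linkS4class{ElbowCurve}}.
#' @export
chooseK <- function(exemplars, kGrid = 2:8, maxIter = 150, replicates = 10,
                    seed = 1) {
  X <- if (is(exemplars, "ExemplarSet")) exemplars@rows else as.matrix(exemplars)
  kGrid <- as.integer(kGrid)
  if (max(kGrid) > nrow(X) - 1) .stopf("k grid exceeds M - 1 = %d", nrow(X) - 1)
  mu <- colMeans(X)
  ratio <- vapply(kGrid, function(k) {
    fit <- fitStates(X, k, maxIter = maxIter, replicates = replicates,
                     seed = seed + k)
    a <- fit@assignments$.exemplars
    cen <- centroids(fit)
    within <- sum((X - cen[a, , drop = FALSE])^2)
    nc <- tabulate(a, k)
    between <- sum(nc * rowSums((cen - rep(mu, each = k))^2))
    within / between
  }, numeric(1))
  d <- .chordDistance(kGrid, ratio)
  kSel <- kGrid[which.max(d)]
  flagged <- FALSE; note <- ""
  if (any(diff(ratio) > 0)) {
    flagged <- TRUE
    note <- "ratio curve is not monotonically decreasing"
    .noticef("elbow: %s", note)
  }
  # a confident knee is a drop followed by a plateau: relative ratio drops
  # after the knee should be small next to the steepest drop before it
  drops <- -diff(ratio) / ratio[-length(ratio)]
  knee <- which.max(d)
  pre <- drops[seq_len(knee - 1)]
  post <- if (knee <= length(drops)) drops[knee:length(drops)] else numeric(0)
  if (!length(pre) || !length(post) || max(post) > 0.4 * max(pre)) {
    flagged <- TRUE
    note <- paste0(note, if (nzchar(note)) "; ",
                   "no clear plateau after the knee; k selection is low-confidence")
    .noticef("elbow: weak knee at k = %d", kSel)
  }
  new("ElbowCurve", kValues = kGrid, ratio = ratio,
      kSelected = as.integer(kSel), flagged = flagged, note = note)
}

#' Assign every window to a connectivity state
#'
#' Runs the same L1/median k-means on all subjects' windows, warm
#' started at the exemplar-stage centroids. No randomness: the result
#' is a deterministic function of the windows and the warm start, and
#' state labels are carried over from the warm start.
#'
#' @param wfncList named list of \code{\linkS4class{WindowedFNC}}.
#' @param exemplarModel \code{\linkS4class{StateModel}} from
#'   \code{\link{fitStates}}.
#' @param maxIter iteration cap.
#' @return a \code{\linkS4class{StateModel}} at the full stage with
#'   per-subject window assignments.
#' @export
assignAllWindows <- function(wfncList, exemplarModel, maxIter = 150) {
  P <- ncol(centroids(exemplarModel))
  X <- do.call(rbind, lapply(wfncList, trajectory))
  if (ncol(X) != P) .stopf("windows have %d pairs but the model expects %d",
                           ncol(X), P)
  fit <- .kmeansL1(X, centroids(exemplarModel), maxIter)
  nW <- vapply(wfncList, function(w) nrow(w@trajectory), 1L)
  split_idx <- rep(seq_along(wfncList), nW)
  assignments <- split(fit$assign, split_idx)
  names(assignments) <- names(wfncList)
  new("StateModel", k = exemplarModel@k, centroids = unname(fit$centroids),
      assignments = assignments, inertia = fit$inertia, stage = "full",
      pairNames = exemplarModel@pairNames)
}

#' Relabel states by total connectivity
#'
#' Reorders states so label 1 is the most sparsely connected state and
#' label k the most abundantly connected (ascending mean centroid
#' value), making sparse/intermediate/abundant labels reproducible
#' across runs.
#'
#' @param model a \code{\linkS4class{StateModel}}.
#' @return the relabelled model.
#' @export
orderStatesByConnectivity <- function(model) {
  ord <- order(rowMeans(centroids(model)))
  remap <- integer(model@k)
  remap[ord] <- seq_len(model@k)
  initialize(model,
             centroids = centroids(model)[ord, , drop = FALSE],
             assignments = lapply(assignments(model),
                                  function(a) remap[a]))
}
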