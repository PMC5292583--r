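#' @title Core S4 classes for dynamic functional network connectivity
#' @name dynFNC-classes
#' @description
#' S4 containers used across the pipeline: cohort simulation specs,
#' per-subject component time courses, tapered windows, windowed
#' connectivity trajectories, connectivity-state models and per-subject
#' state occupancy summaries.
NULL

#' Connectivity state specification
#'
#' A discrete connectivity state of the generative model: a label and a
#' correlation-scale covariance matrix. The constructor rescales any
#' symmetric positive-definite covariance to a correlation matrix.
#'
#' @slot label integer state index (1..k).
#' @slot covariance C x C symmetric positive-definite correlation matrix.
#' @export
setClass("StateSpec", representation(label = "integer", covariance = "matrix"))

setValidity("StateSpec", function(object) {
  m <- object@covariance
  if (!.isSquareNumeric(m)) return("covariance must be a square numeric matrix")
  if (max(abs(m - t(m))) > 1e-10)
    return(sprintf("state %d covariance is not symmetric", object@label))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    return(sprintf("state %d covariance is not positive definite (min eigenvalue %.3g)",
                   object@label, min(ev)))
  if (max(abs(diag(m) - 1)) > 1e-8)
    return(sprintf("state %d covariance diagonal must be 1 after correlation scaling",
                   object@label))
  TRUE
})

#' @rdname StateSpec-class
#' @param label integer state index.
#' @param covariance symmetric positive-definite matrix; rescaled to
#'   correlation form.
#' @return a \code{StateSpec}.
#' @export
StateSpec <- function(label, covariance) {
  covariance <- as.matrix(covariance)
  if (!.isSquareNumeric(covariance))
    .stopf("state %s: covariance must be a square numeric matrix", label)
  if (any(diag(covariance) <= 0))
    .stopf("state %s: covariance has non-positive diagonal entries", label)
  new("StateSpec", label = as.integer(label),
      covariance = stats::cov2cor(covariance))
}

#' Group / session cell of a simulated cohort
#'
#' @slot name group label (e.g. "HCb", "SZb", "SZ6").
#' @slot nSubjects number of subjects in the cell.
#' @slot transitionMatrix k x k row-stochastic matrix governing state
#'   switching.
#' @slot initialDistribution length-k probability vector for the first
#'   timepoint's state.
#' @slot clinicalMean,clinicalSd positive-symptom score distribution
#'   (scale units) at baseline; follow-up scores are drawn around an
#'   improved mean.
#' @slot session session label of this cell (e.g. "baseline", "week6").
#' @slot cohort underlying population label; two cells sharing a
#'   \code{cohort} contain the same people at different sessions, and
#'   subjects with the same index share a \code{pairKey}.
#' @export
setClass("GroupSpec", representation(
  name = "character", nSubjects = "integer",
  transitionMatrix = "matrix", initialDistribution = "numeric",
  clinicalMean = "numeric", clinicalSd = "numeric",
  session = "character", cohort = "character"))

setValidity("GroupSpec", function(object) {
  P <- object@transitionMatrix
  if (!.isSquareNumeric(P)) return("transitionMatrix must be square numeric")
  if (any(P < 0) || any(P > 1)) return("transition probabilities must lie in [0,1]")
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad))
    return(sprintf("transitionMatrix row %s does not sum to 1",
                   paste(bad, collapse = ", ")))
  pi0 <- object@initialDistribution
  if (length(pi0) != nrow(P)) return("initialDistribution length must equal k")
  if (any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-12)
    return("initialDistribution must be a probability vector")
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  TRUE
})

#' @rdname GroupSpec-class
#' @param name,nSubjects,transitionMatrix,initialDistribution,clinicalMean,clinicalSd
#'   see slots.
#' @return a \code{GroupSpec}.
#' @export
GroupSpec <- function(name, nSubjects, transitionMatrix,
                      initialDistribution = NULL,
                      clinicalMean = 9.5, clinicalSd = 3,
                      session = "1", cohort = name) {
  transitionMatrix <- as.matrix(transitionMatrix)
  if (is.null(initialDistribution))
    initialDistribution <- rep(1 / nrow(transitionMatrix), nrow(transitionMatrix))
  bad <- which(abs(rowSums(transitionMatrix) - 1) > 1e-12)
  if (length(bad))
    .stopf("group %s: transition matrix row %s does not sum to 1",
           name, paste(bad, collapse = ", "))
  new("GroupSpec", name = name, nSubjects = as.integer(nSubjects),
      transitionMatrix = transitionMatrix,
      initialDistribution = initialDistribution,
      clinicalMean = clinicalMean, clinicalSd = clinicalSd,
      session = session, cohort = cohort)
}

#' Full parameterization of the synthetic cohort generator
#'
#' @slot groups list of \code{\linkS4class{GroupSpec}}.
#' @slot states list of \code{\linkS4class{StateSpec}} sharing one
#'   component count.
#' @slot nComponents component count C.
#' @slot T timepoints per scan.
#' @slot TR sampling interval, seconds.
#' @slot observationNoiseSd additive white-noise sd.
#' @slot motionWalkSd random-walk step sd of the six realignment
#'   parameters (mm / radians).
#' @slot spikeRate per-timepoint, per-component probability of an
#'   artifactual spike.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec", representation(
  groups = "list", states = "list", nComponents = "integer", T = "integer",
  TR = "numeric", observationNoiseSd = "numeric", motionWalkSd = "numeric",
  spikeRate = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (!length(object@states)) return("at least one state is required")
  k <- length(object@states)
  Cs <- vapply(object@states, function(s) nrow(s@covariance), 1L)
  if (any(Cs != object@nComponents))
    return("all state covariances must be C x C for the spec's C")
  for (g in object@groups) {
    v <- validObject(g, test = TRUE)
    if (!isTRUE(v)) return(v)
    if (nrow(g@transitionMatrix) != k)
      return(sprintf("group %s transition matrix is %dx%d but there are %d states",
                     g@name, nrow(g@transitionMatrix), ncol(g@transitionMatrix), k))
  }
  if (object@T < 2L) return("T must be >= 2")
  if (object@TR <= 0) return("TR must be > 0")
  if (object@observationNoiseSd < 0 || object@motionWalkSd < 0 ||
      object@spikeRate < 0 || object@spikeRate > 1)
    return("noise sds must be >= 0 and spikeRate in [0,1]")
  TRUE
})

#' One subject's component time courses
#'
#' Holds a T x C matrix of component time courses, the subject's
#' realignment parameters, provenance labels and (for synthetic
#' subjects) the generating state path. The \code{stage} slot tracks the
#' postprocessing chain \code{raw -> fd_regressed -> detrended ->
#' despiked -> filtered}; each stage refuses to run out of order or
#' twice.
#'
#' @slot subject subject identifier.
#' @slot data T x C numeric matrix.
#' @slot realignment T x 6 matrix (translations mm, rotations radians),
#'   or a 0-row matrix when absent.
#' @slot TR seconds per timepoint.
#' @slot group,session,pairKey provenance labels; \code{pairKey}
#'   identifies the same person across sessions for paired contrasts.
#' @slot stage postprocessing stage flag.
#' @slot clinicalScores named numeric, \code{baseline} and
#'   \code{followup} positive-symptom scores (NA when not simulated).
#' @slot trueStatePath length-T generating state labels (integer(0) for
#'   real data).
#' @export
setClass("SubjectTimecourses", representation(
  subject = "character", data = "matrix", realignment = "matrix",
  TR = "numeric", group = "character", session = "character",
  pairKey = "character", stage = "character", clinicalScores = "numeric",
  trueStatePath = "integer"))

.STAGES <- c("raw", "fd_regressed", "detrended", "despiked", "filtered")

setValidity("SubjectTimecourses", function(object) {
  if (!all(is.finite(object@data))) return("time courses contain non-finite values")
  if (nrow(object@realignment) &&
      (ncol(object@realignment) != 6L ||
       nrow(object@realignment) != nrow(object@data)))
    return("realignment must be T x 6 (3 translations mm, 3 rotations rad)")
  if (!object@stage %in% .STAGES)
    return(sprintf("unknown stage '%s'", object@stage))
  if (length(object@trueStatePath) &&
      length(object@trueStatePath) != nrow(object@data))
    return("trueStatePath must have one label per timepoint")
  TRUE
})

#' @rdname SubjectTimecourses-class
#' @param subject,data,TR,realignment,group,session,pairKey,stage,clinicalScores,trueStatePath
#'   see slots.
#' @return a \code{SubjectTimecourses}.
#' @export
SubjectTimecourses <- function(subject, data, TR,
                               realignment = matrix(0, 0, 6),
                               group = "A", session = "1",
                               pairKey = subject, stage = "raw",
                               clinicalScores = c(baseline = NA_real_,
                                                  followup = NA_real_),
                               trueStatePath = integer(0)) {
  new("SubjectTimecourses", subject = subject, data = as.matrix(data),
      realignment = as.matrix(realignment), TR = TR, group = group,
      session = session, pairKey = pairKey, stage = stage,
      clinicalScores = clinicalScores,
      trueStatePath = as.integer(trueStatePath))
}

#' Gaussian-tapered sliding window
#'
#' A rectangle of the requested width convolved with a Gaussian
#' (sd \code{sigmaTr} timepoints), truncated to the width and normalised
#' to sum 1.
#'
#' @slot widthS window width in seconds.
#' @slot widthTr window width in timepoints (\code{round(widthS / TR)}).
#' @slot sigmaTr Gaussian sd in timepoints.
#' @slot TR seconds per timepoint.
#' @slot weights length-\code{widthTr} nonnegative taper, sums to 1,
#'   symmetric about the centre.
#' @export
setClass("TaperedWindow", representation(
  widthS = "numeric", widthTr = "integer", sigmaTr = "numeric",
  TR = "numeric", weights = "numeric"))

setValidity("TaperedWindow", function(object) {
  w <- object@weights
  if (length(w) != object@widthTr) return("weights length must equal widthTr")
  if (any(w < 0)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-10) return("weights must sum to 1")
  if (max(abs(w - rev(w))) > 1e-10) return("weights must be symmetric")
  TRUE
})

#' Windowed connectivity trajectory of one subject
#'
#' Each row is the vectorized upper triangle (Fisher z) of one window's
#' regularised correlation matrix; rows advance by one TR.
#'
#' @slot subject,group,session,pairKey provenance (copied from the
#'   input time courses).
#' @slot TR seconds per timepoint.
#' @slot widthTr window width in timepoints.
#' @slot lambda graphical-LASSO penalty used.
#' @slot windowStarts 1-based first timepoint of each window.
#' @slot trajectory N_w x P matrix, P = C(C-1)/2.
#' @slot pairNames length-P component-pair labels.
#' @export
setClass("WindowedFNC", representation(
  subject = "character", group = "character", session = "character",
  pairKey = "character", TR = "numeric", widthTr = "integer",
  lambda = "numeric", windowStarts = "integer", trajectory = "matrix",
  pairNames = "character"))

setValidity("WindowedFNC", function(object) {
  if (nrow(object@trajectory) != length(object@windowStarts))
    return("one windowStart per trajectory row required")
  if (!all(is.finite(object@trajectory)))
    return("trajectory contains non-finite values")
  TRUE
})

#' Exemplar windows used to initialise state clustering
#'
#' @slot rows M x P matrix of exemplar windows (local maxima of the
#'   per-subject window-variance series).
#' @slot provenance data.frame with columns \code{subject} and
#'   \code{windowStart}, one row per exemplar.
#' @export
setClass("ExemplarSet", representation(rows = "matrix", provenance = "data.frame"))

setValidity("ExemplarSet", function(object) {
  if (nrow(object@rows) != nrow(object@provenance))
    return("provenance must have one row per exemplar")
  TRUE
})

#' Connectivity-state model
#'
#' Result of L1 k-means: k centroids over connectivity space (element-wise
#' medians) plus, after the full-assignment stage, per-subject window
#' state labels.
#'
#' @slot k number of states.
#' @slot centroids k x P matrix.
#' @slot assignments named list (by subject) of length-N_w integer
#'   state labels; empty at the exemplar stage.
#' @slot inertia total L1 distance of clustered points to their
#'   centroids.
#' @slot stage \code{"exemplar"} or \code{"full"}.
#' @slot pairNames connectivity-pair labels for centroid columns.
#' @export
setClass("StateModel", representation(
  k = "integer", centroids = "matrix", assignments = "list",
  inertia = "numeric", stage = "character", pairNames = "character"))

setValidity("StateModel", function(object) {
  if (nrow(object@centroids) != object@k) return("one centroid row per state required")
  if (!object@stage %in% c("exemplar", "full")) return("stage must be exemplar or full")
  TRUE
})

#' Elbow curve for state-count selection
#'
#' @slot kValues candidate state counts.
#' @slot ratio within- to between-cluster sum-of-squares ratio per k.
#' @slot kSelected k at the knee (maximum perpendicular distance to the
#'   chord joining the curve's endpoints).
#' @slot flagged TRUE when the curve is non-monotone or too flat to
#'   define a confident knee.
#' @slot note human-readable flag explanation.
#' @export
setClass("ElbowCurve", representation(
  kValues = "integer", ratio = "numeric", kSelected = "integer",
  flagged = "logical", note = "character"))

#' Per-subject state occupancy statistics
#'
#' @slot subject,group,session,pairKey provenance.
#' @slot TR seconds per timepoint (dwell in windows times TR gives
#'   seconds).
#' @slot nWindows number of windows in the subject's assignment.
#' @slot meanDwell length-k mean sojourn length in windows; NA for
#'   states never visited.
#' @slot fraction length-k fraction of windows spent in each state.
#' @slot transitions k x k row-stochastic matrix of empirical
#'   transition probabilities (self-transitions included); rows of
#'   unvisited states are NaN.
#' @slot counts k x k raw transition counts.
#' @slot visited length-k logical.
#' @export
setClass("StateOccupancy", representation(
  subject = "character", group = "character", session = "character",
  pairKey = "character", TR = "numeric", nWindows = "integer",
  meanDwell = "numeric", fraction = "numeric", transitions = "matrix",
  counts = "matrix", visited = "logical"))

setValidity("StateOccupancy", function(object) {
  if (abs(sum(object@fraction) - 1) > 1e-12)
    return("state fractions must sum to 1")
  if (any(!is.na(object@meanDwell[!object@visited])))
    return("mean dwell must be NA for unvisited states")
  TRUE
})
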