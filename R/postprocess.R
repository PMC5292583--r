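#' Framewise displacement from realignment parameters
#'
#' Scalar head-motion summary per timepoint: the sum of absolute
#' frame-to-frame changes of the three translations (mm) plus the three
#' rotations (radians) converted to arc displacement on a 50 mm radius.
#' The first value is 0 by convention.
#'
#' @param realignment T x 6 numeric matrix; columns 1-3 translations in
#'   mm, columns 4-6 rotations in radians.
#' @param radius head radius in mm used to convert rotations.
#' @return numeric length-T vector of displacements (mm).
#' @export
computeFD <- function(realignment, radius = 50) {
  realignment <- as.matrix(realignment)
  if (ncol(realignment) != 6L)
    .stopf("realignment must have 6 columns (3 translations mm, 3 rotations rad), got %d",
           ncol(realignment))
  d <- abs(diff(realignment))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

.requireStage <- function(tc, needed, op) {
  if (tc@stage != needed)
    .stopf("%s expects stage '%s' but subject %s is at stage '%s'",
           op, needed, tc@subject, tc@stage)
}

#' Regress framewise displacement from component time courses
#'
#' Replaces each component series by the residual of an ordinary
#' least-squares fit on an intercept and the FD series, removing
#' motion-locked variance. A constant FD series degenerates to
#' demeaning (a notice is logged, not an error).
#'
#' @param tc a \code{\linkS4class{SubjectTimecourses}} at stage
#'   \code{"raw"}.
#' @param fd length-T framewise-displacement vector; computed from the
#'   subject's realignment parameters when omitted.
#' @return the subject at stage \code{"fd_regressed"}.
#' @export
regressFD <- function(tc, fd = NULL) {
  .requireStage(tc, "raw", "regressFD")
  if (is.null(fd)) {
    if (!nrow(tc@realignment))
      .stopf("subject %s has no realignment parameters and no fd was given",
             tc@subject)
    fd <- computeFD(tc@realignment)
  }
  if (length(fd) != nrow(tc@data))
    .stopf("fd length %d does not match T = %d", length(fd), nrow(tc@data))
  if (stats::sd(fd) == 0) {
    .noticef("subject %s: constant FD series; FD regression reduces to demeaning",
             tc@subject)
    res <- sweep(tc@data, 2, colMeans(tc@data))
  } else {
    X <- cbind(1, fd)
    res <- tc@data - X %*% solve(crossprod(X), crossprod(X, tc@data))
  }
  initialize(tc, data = unname(res), stage = "fd_regressed")
}

#' Linear detrend of component time courses
#'
#' Removes the per-component best-fit line (intercept and slope).
#'
#' @param tc subject at stage \code{"fd_regressed"}.
#' @return the subject at stage \code{"detrended"}.
#' @export
detrendTimecourses <- function(tc) {
  .requireStage(tc, "fd_regressed", "detrendTimecourses")
  T <- nrow(tc@data)
  X <- cbind(1, seq_len(T))
  res <- tc@data - X %*% solve(crossprod(X), crossprod(X, tc@data))
  initialize(tc, data = unname(res), stage = "detrended")
}

#' Despike component time courses
#'
#' Samples deviating more than \code{thresh} robust standard deviations
#' (1.4826 x the median absolute deviation of the residual from a
#' running median) from a centred running median are replaced by the
#' running-median value.
#'
#' @param tc subject at stage \code{"detrended"}.
#' @param window running-median width in timepoints (odd).
#' @param thresh threshold in robust sds.
#' @return the subject at stage \code{"despiked"}.
#' @export
despikeTimecourses <- function(tc, window = 5, thresh = 4) {
  .requireStage(tc, "detrended", "despikeTimecourses")
  out <- apply(tc@data, 2, function(x) {
    med <- stats::runmed(x, k = window, endrule = "median")
    dev <- x - med
    sigma <- 1.4826 * stats::median(abs(dev))
    bad <- if (sigma > 0) abs(dev) > thresh * sigma else dev != 0
    x[bad] <- med[bad]
    x
  })
  initialize(tc, data = unname(out), stage = "despiked")
}

#' Band-pass filter component time courses
#'
#' Fifth-order Butterworth band-pass (0.01-0.15 Hz by default), applied
#' forward and backward (zero phase) so state boundaries are not
#' shifted in time. Series length is preserved.
#'
#' @param tc subject at stage \code{"despiked"}.
#' @param band length-2 numeric, pass-band edges in Hz.
#' @param order filter order.
#' @return the subject at stage \code{"filtered"}.
#' @export
bandpassTimecourses <- function(tc, band = c(0.01, 0.15), order = 5) {
  .requireStage(tc, "despiked", "bandpassTimecourses")
  nyq <- 1 / (2 * tc@TR)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    .stopf("band (%g, %g) Hz incompatible with Nyquist %g Hz at TR = %gs",
           band[1], band[2], nyq, tc@TR)
  if (nrow(tc@data) < 3 * order)
    .stopf("need T >= %d for an order-%d filter, got %d",
           3 * order, order, nrow(tc@data))
  bf <- signal::butter(order, band / nyq, type = "pass")
  out <- apply(tc@data, 2, function(x) signal::filtfilt(bf, x))
  if (!all(is.finite(out)))
    .stopf("band-pass produced non-finite values for subject %s", tc@subject)
  initialize(tc, data = unname(out), stage = "filtered")
}

#' Run the full postprocessing chain
#'
#' FD regression, linear detrend, despike and zero-phase band-pass, in
#' that order.
#'
#' @param tc subject at stage \code{"raw"}.
#' @param band pass-band edges in Hz.
#' @param despikeThresh despike threshold in robust sds.
#' @param fd optional FD series overriding the subject's realignment
#'   parameters.
#' @return the subject at stage \code{"filtered"}.
#' @export
postprocessSubject <- function(tc, band = c(0.01, 0.15), despikeThresh = 4,
                               fd = NULL) {
  tc <- regressFD(tc, fd = fd)
  tc <- detrendTimecourses(tc)
  tc <- despikeTimecourses(tc, thresh = despikeThresh)
  bandpassTimecourses(tc, band = band)
}
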