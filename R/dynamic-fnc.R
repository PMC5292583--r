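#' Sparse inverse covariance by graphical LASSO
#'
#' Estimates an L1-penalised precision matrix from a covariance (or
#' correlation) matrix by blockwise coordinate descent, penalising
#' off-diagonal precision entries only, and returns both the precision
#' estimate and its inverse (the regularised covariance). With
#' \code{rho = 0} the problem is the unpenalised maximum-likelihood fit
#' and is solved directly.
#'
#' @param S symmetric positive-definite covariance matrix.
#' @param rho nonnegative L1 penalty.
#' @param maxit maximum outer sweeps.
#' @param tol relative convergence tolerance on the working covariance.
#' @return list with \code{w} (regularised covariance), \code{wi}
#'   (precision), \code{niter} and \code{converged}.
#' @export
graphicalLasso <- function(S, rho, maxit = 200, tol = 1e-7) {
  S <- as.matrix(S)
  if (!.isSquareNumeric(S) || max(abs(S - t(S))) > 1e-8)
    .stopf("S must be a symmetric numeric matrix")
  if (rho < 0) .stopf("rho must be >= 0")
  if (rho == 0) {
    wi <- solve(S)
    return(list(w = S, wi = 0.5 * (wi + t(wi)), niter = 0L, converged = TRUE))
  }
  glasso_cd(S, rho, as.integer(maxit), tol, 2000L)
}

#' Construct a Gaussian-tapered sliding window
#'
#' A rectangle of \code{round(widthS / TR)} timepoints convolved with a
#' Gaussian of sd \code{sigmaTr} timepoints, truncated back to the
#' rectangle's width and renormalised to sum 1. As \code{sigmaTr}
#' approaches 0 the taper tends to the plain rectangle.
#'
#' @param widthS window width in seconds (the study grid is 30, 40, 44,
#'   50 and 60 s).
#' @param TR sampling interval in seconds.
#' @param sigmaTr Gaussian sd in timepoints.
#' @return a \code{\linkS4class{TaperedWindow}}.
#' @export
makeTaperedWindow <- function(widthS, TR, sigmaTr = 3) {
  if (sigmaTr <= 0) .stopf("sigmaTr must be > 0")
  widthTr <- as.integer(round(widthS / TR))
  if (widthTr < 3L) .stopf("window of %gs is only %d timepoints at TR = %gs; need >= 3",
                           widthS, widthTr, TR)
  half <- max(1L, as.integer(ceiling(4 * sigmaTr)))
  g <- stats::dnorm(seq(-half, half), sd = sigmaTr)
  w <- stats::convolve(rep(1, widthTr), rev(g), type = "open")
  w <- w[(half + 1):(half + widthTr)]   # central widthTr taps
  w <- w / sum(w)
  new("TaperedWindow", widthS = widthS, widthTr = widthTr,
      sigmaTr = sigmaTr, TR = TR, weights = w)
}

# Weighted covariance of a window: demean with taper weights, scale rows
# by sqrt(weight).
.weightedCov <- function(X, w) {
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu) * sqrt(w)
  crossprod(Xc)
}

#' Sliding-window regularised connectivity trajectory
#'
#' Slides the tapered window through a subject's filtered time courses
#' in steps of one TR. For each window the taper-weighted sample
#' covariance is scaled to a correlation matrix and the sparse inverse
#' is estimated by graphical LASSO; the inverse of that precision,
#' rescaled to correlation and Fisher-z transformed, gives one row of
#' the trajectory (vectorized upper triangle). A window where the
#' solver fails to converge is retried once with the penalty doubled,
#' then reported as an error naming the window.
#'
#' @param tc a \code{\linkS4class{SubjectTimecourses}} at stage
#'   \code{"filtered"}.
#' @param window a \code{\linkS4class{TaperedWindow}}.
#' @param lambda L1 penalty (unitless, on the correlation scale).
#' @param componentLabels optional component names.
#' @return a \code{\linkS4class{WindowedFNC}}.
#' @export
windowedFNC <- function(tc, window, lambda = 0.1,
                        componentLabels = paste0("IC", seq_len(ncol(timecourses(tc))))) {
  .requireStage(tc, "filtered", "windowedFNC")
  X <- tc@data
  T <- nrow(X); C <- ncol(X)
  W <- window@widthTr
  if (W > T) .stopf("window of %d TRs exceeds the %d available timepoints", W, T)
  nW <- T - W + 1L
  P <- C * (C - 1L) / 2L
  traj <- matrix(0, nW, P)
  for (s in seq_len(nW)) {
    Sw <- .weightedCov(X[s:(s + W - 1L), , drop = FALSE], window@weights)
    v <- diag(Sw)
    if (any(v <= 0))
      .stopf("subject %s window %d: zero-variance component %s",
             tc@subject, s, paste(which(v <= 0), collapse = ","))
    Rw <- stats::cov2cor(Sw)
    if (lambda == 0) {
      # unpenalised: the regularised covariance is the sample correlation
      # itself, so no inversion is needed (and rank-deficient windows with
      # exactly collinear components remain representable)
      Sig <- Rw
    } else {
      fit <- graphicalLasso(Rw, lambda)
      if (!fit$converged) {
        fit <- graphicalLasso(Rw, 2 * lambda)
        if (!fit$converged)
          .stopf("graphical LASSO did not converge for subject %s window %d (lambda %g and %g)",
                 tc@subject, s, lambda, 2 * lambda)
      }
      Sig <- solve(fit$wi)
    }
    traj[s, ] <- fisherZ(.vecUT(stats::cov2cor(Sig)))
  }
  new("WindowedFNC", subject = tc@subject, group = tc@group,
      session = tc@session, pairKey = tc@pairKey, TR = tc@TR,
      widthTr = W, lambda = lambda, windowStarts = seq_len(nW),
      trajectory = traj, pairNames = .pairNames(componentLabels))
}

#' Amplitude of low-frequency fluctuation of windowed connectivity
#'
#' Summarises how much each connectivity pair fluctuates over the scan:
#' per pair, the windowed-correlation series is demeaned, its discrete
#' Fourier amplitude spectrum taken (series sampled at one TR), the
#' amplitudes at frequencies inside \code{band} are summed and the sum
#' divided by \code{normConst}.
#'
#' The default normalisation constant is the literal 0.5 (Hz) used by
#' the ALFF-FC convention this summary follows; note a TR-sampled
#' window series has Nyquist \code{1/(2 TR)} (0.25 Hz at TR = 2 s), so
#' \code{normConst = "nyquist"} is available as an alternative.
#'
#' @param wfnc a \code{\linkS4class{WindowedFNC}}.
#' @param band length-2 Hz band, default \code{c(0.01, 0.08)}.
#' @param normConst positive number, or \code{"nyquist"}.
#' @return numeric length-P nonnegative vector, named by pair.
#' @export
alffFC <- function(wfnc, band = c(0.01, 0.08), normConst = 0.5) {
  Y <- wfnc@trajectory
  nW <- nrow(Y)
  if (nW < 8) .stopf("need at least 8 windows for a spectrum, got %d", nW)
  fs <- 1 / wfnc@TR
  nyq <- fs / 2
  if (band[2] > nyq)
    .stopf("band upper edge %g Hz exceeds the windowed-series Nyquist %g Hz",
           band[2], nyq)
  if (identical(normConst, "nyquist")) normConst <- nyq
  # one-sided amplitude spectrum over positive frequencies
  pos <- seq_len(floor(nW / 2)) + 1L
  freqs <- (pos - 1) / (nW * wfnc@TR)
  keep <- freqs >= band[1] & freqs <= band[2]
  Yc <- sweep(Y, 2, colMeans(Y))
  amp <- abs(stats::mvfft(Yc))[pos, , drop = FALSE] / nW
  vals <- colSums(amp[keep, , drop = FALSE]) / normConst
  names(vals) <- wfnc@pairNames
  vals
}
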