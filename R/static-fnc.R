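#' Static functional network connectivity of one subject
#'
#' Pairwise Pearson correlation between whole component time courses,
#' Fisher-z transformed (with correlations clipped to +/-(1 - 1e-12) so
#' identical components give a large finite z rather than infinity).
#' The diagonal is stored as 0 by convention; self-connectivity is
#' excluded from all tests. Zero-variance components yield NA pairs and
#' a warning naming the component.
#'
#' @param tc a \code{\linkS4class{SubjectTimecourses}} at stage
#'   \code{"filtered"}.
#' @param componentLabels optional component names.
#' @return C x C symmetric numeric matrix of Fisher-z correlations.
#' @export
staticFNC <- function(tc, componentLabels = paste0("IC", seq_len(ncol(timecourses(tc))))) {
  .requireStage(tc, "filtered", "staticFNC")
  X <- tc@data
  if (nrow(X) < 3) .stopf("need at least 3 timepoints, got %d", nrow(X))
  v <- apply(X, 2, stats::sd)
  dead <- which(v == 0)
  if (length(dead))
    warning(sprintf("subject %s: zero-variance component(s) %s; their pairs are NA",
                    tc@subject, paste(dead, collapse = ", ")), call. = FALSE)
  suppressWarnings(r <- stats::cor(X))
  z <- fisherZ(r)
  diag(z) <- 0
  dimnames(z) <- list(componentLabels, componentLabels)
  z
}

#' Element-wise group contrast of connectivity matrices
#'
#' Per unique component pair (C(C-1)/2 tests), a two-sample Welch or
#' paired t-test on the subjects' Fisher-z values, with
#' Benjamini-Hochberg FDR correction across all pairs. Paired contrasts
#' match subjects by pair key and reject the contrast if any key is
#' unmatched.
#'
#' @param matricesA,matricesB named lists of subject connectivity
#'   matrices (names are pair keys for paired contrasts).
#' @param paired logical.
#' @param alpha FDR significance level, for the \code{significant}
#'   column.
#' @return data.frame with one row per pair: indices, labels, t, df,
#'   p_raw, p_fdr, direction (sign of mean A - B) and significance
#'   flag, ordered by p_fdr.
#' @export
groupContrast <- function(matricesA, matricesB, paired = FALSE, alpha = 0.05) {
  if (length(matricesA) < 2 || length(matricesB) < 2)
    .stopf("need at least 2 subjects per group (got %d and %d)",
           length(matricesA), length(matricesB))
  C <- nrow(matricesA[[1]])
  labels <- rownames(matricesA[[1]])
  if (is.null(labels)) labels <- paste0("IC", seq_len(C))
  A <- do.call(rbind, lapply(matricesA, .vecUT))
  B <- do.call(rbind, lapply(matricesB, .vecUT))
  if (ncol(A) != ncol(B)) .stopf("groups have different component counts")
  if (paired) {
    ka <- names(matricesA); kb <- names(matricesB)
    if (is.null(ka) || is.null(kb))
      .stopf("paired contrast requires named (pair-keyed) matrix lists")
    un <- c(setdiff(ka, kb), setdiff(kb, ka))
    if (length(un))
      .stopf("paired contrast requested but keys are unmatched: %s",
             paste(un, collapse = ", "))
    B <- B[match(ka, kb), , drop = FALSE]
    tt <- .colPairedT(A - B)
  } else {
    tt <- .colWelchT(A, B)
  }
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  res <- data.frame(
    i = idx[, 1], j = idx[, 2],
    pair = paste0(labels[idx[, 1]], "-", labels[idx[, 2]]),
    t = tt$t, df = tt$df, p_raw = tt$p,
    p_fdr = stats::p.adjust(tt$p, method = "BH"),
    direction = sign(colMeans(A) - colMeans(B)),
    stringsAsFactors = FALSE)
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res[order(res$p_fdr, res$p_raw), ]
}

#' Group-mean connectivity matrix
#'
#' Arithmetic mean of subject Fisher-z matrices.
#'
#' @param matrices list of subject connectivity matrices.
#' @return mean matrix.
#' @export
groupMeanFNC <- function(matrices) {
  Reduce(`+`, matrices) / length(matrices)
}
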