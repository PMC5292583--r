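#' State occupancy statistics of one assignment sequence
#'
#' Runs of identical labels define sojourns. Mean dwell time of a state
#' is the mean sojourn length (in windows; multiply by TR for seconds),
#' the fraction of time is the share of windows assigned to the state,
#' and the transition matrix is the row-normalised table of consecutive
#' label pairs, self-transitions included. States never visited get NA
#' dwell (absence is not brevity) and NaN transition rows.
#'
#' @param labels integer vector of per-window state labels (1..k).
#' @param k number of states.
#' @param TR seconds per timepoint.
#' @param subject,group,session,pairKey provenance labels.
#' @return a \code{\linkS4class{StateOccupancy}}.
#' @export
stateOccupancy <- function(labels, k, TR = NA_real_, subject = "s",
                           group = "A", session = "1", pairKey = subject) {
  labels <- as.integer(labels)
  N <- length(labels)
  if (N == 0) .stopf("empty assignment sequence")
  if (any(labels < 1 | labels > k))
    .stopf("labels outside 1..%d", k)
  runs <- rle(labels)
  meanDwell <- vapply(seq_len(k), function(s) {
    l <- runs$lengths[runs$values == s]
    if (length(l)) mean(l) else NA_real_
  }, numeric(1))
  fraction <- tabulate(labels, k) / N
  counts <- matrix(0, k, k)
  if (N > 1) {
    tab <- table(factor(labels[-N], levels = seq_len(k)),
                 factor(labels[-1], levels = seq_len(k)))
    counts <- matrix(as.numeric(tab), k, k)
  }
  transitions <- counts / rowSums(counts) # 0/0 -> NaN marks unvisited rows
  new("StateOccupancy", subject = subject, group = group, session = session,
      pairKey = pairKey, TR = TR, nWindows = as.integer(N),
      meanDwell = meanDwell, fraction = fraction,
      transitions = transitions, counts = counts,
      visited = fraction > 0)
}

#' Occupancy statistics for every subject of a fitted state model
#'
#' @param model full-stage \code{\linkS4class{StateModel}}.
#' @param wfncList the windowed trajectories the model was fitted to
#'   (provenance source); optional.
#' @return named list of \code{\linkS4class{StateOccupancy}}.
#' @export
occupancyOfModel <- function(model, wfncList = NULL) {
  if (model@stage != "full")
    .stopf("occupancy needs a full-stage model with per-subject assignments")
  out <- lapply(names(assignments(model)), function(id) {
    w <- wfncList[[id]]
    stateOccupancy(assignments(model)[[id]], model@k,
                   TR = if (is.null(w)) NA_real_ else w@TR,
                   subject = id,
                   group = if (is.null(w)) "A" else w@group,
                   session = if (is.null(w)) "1" else w@session,
                   pairKey = if (is.null(w)) id else w@pairKey)
  })
  names(out) <- names(assignments(model))
  out
}

#' Per-subject state median connectivity
#'
#' Element-wise median over the subject's windows assigned to each
#' state; states the subject never occupies yield NA rows, which group
#' tests exclude rather than zero-fill.
#'
#' @param wfnc a \code{\linkS4class{WindowedFNC}}.
#' @param assignment the subject's window state labels.
#' @param k number of states.
#' @return k x P matrix (NA rows for unvisited states).
#' @export
subjectStateMedians <- function(wfnc, assignment, k) {
  Y <- wfnc@trajectory
  if (nrow(Y) != length(assignment))
    .stopf("assignment length %d does not match %d windows",
           length(assignment), nrow(Y))
  out <- matrix(NA_real_, k, ncol(Y))
  for (s in seq_len(k)) {
    rows <- which(assignment == s)
    if (length(rows))
      out[s, ] <- .colMedians(Y[rows, , drop = FALSE])
  }
  rownames(out) <- paste0("state", seq_len(k))
  colnames(out) <- wfnc@pairNames
  out
}

# subject-median rows for one state, dropping subjects lacking the state
.stateRows <- function(medianList, state) {
  rows <- lapply(medianList, function(m) m[state, ])
  keep <- !vapply(rows, function(r) any(is.na(r)), TRUE)
  do.call(rbind, rows[keep])
}

#' Group contrast of state connectivity with bootstrap stability
#'
#' Element-wise t-tests (Benjamini-Hochberg FDR across pairs) on the
#' subjects' state-median connectivity, followed by bootstrap
#' resampling of subjects with replacement within each group: the tests
#' are recomputed per resample and a pair is called stable when it is
#' significant in at least \code{stableAt} of the resamples (and in the
#' original sample). With \code{nBoot = 0} the original tests are
#' returned with support undefined.
#'
#' @param mediansA,mediansB named lists of k x P subject state-median
#'   matrices (see \code{\link{subjectStateMedians}}).
#' @param state state label to contrast.
#' @param paired logical; subjects matched by list names.
#' @param nBoot number of bootstrap resamples (10000 in the full
#'   analysis profile).
#' @param alpha FDR level.
#' @param stableAt required fraction of significant resamples.
#' @param seed integer seed for the resampling.
#' @return data.frame per pair: t, p_raw, p_fdr, bootstrap support and
#'   stability flag; or NULL (with a message) when fewer than two
#'   subjects per group express the state.
#' @export
stateContrast <- function(mediansA, mediansB, state, paired = FALSE,
                          nBoot = 10000, alpha = 0.05, stableAt = 0.95,
                          seed = 1) {
  if (paired) {
    common <- intersect(names(mediansA), names(mediansB))
    un <- c(setdiff(names(mediansA), common), setdiff(names(mediansB), common))
    if (length(un))
      .stopf("paired contrast requested but keys are unmatched: %s",
             paste(un, collapse = ", "))
    mediansA <- mediansA[common]; mediansB <- mediansB[common]
    ok <- vapply(common, function(id)
      !any(is.na(mediansA[[id]][state, ])) &&
        !any(is.na(mediansB[[id]][state, ])), TRUE)
    A <- do.call(rbind, lapply(mediansA[ok], function(m) m[state, ]))
    B <- do.call(rbind, lapply(mediansB[ok], function(m) m[state, ]))
  } else {
    A <- .stateRows(mediansA, state)
    B <- .stateRows(mediansB, state)
  }
  if (is.null(A) || is.null(B) || nrow(A) < 2 || nrow(B) < 2) {
    .noticef("state %d expressed by < 2 subjects in a group; contrast skipped",
             state)
    return(NULL)
  }
  tt <- if (paired) .colPairedT(A - B) else .colWelchT(A, B)
  pf <- stats::p.adjust(tt$p, method = "BH")
  support <- rep(NA_real_, ncol(A))
  if (nBoot > 0) {
    hits <- numeric(ncol(A))
    .withSeed(seed, {
      for (b in seq_len(nBoot)) {
        if (paired) {
          ii <- sample.int(nrow(A), replace = TRUE)
          bt <- .colPairedT(A[ii, , drop = FALSE] - B[ii, , drop = FALSE])
        } else {
          ia <- sample.int(nrow(A), replace = TRUE)
          ib <- sample.int(nrow(B), replace = TRUE)
          bt <- .colWelchT(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
        }
        bp <- stats::p.adjust(bt$p, method = "BH")
        hits <- hits + (!is.na(bp) & bp < alpha)
      }
    })
    support <- hits / nBoot
  }
  pairs <- colnames(A)
  if (is.null(pairs)) pairs <- paste0("p", seq_len(ncol(A)))
  data.frame(state = state, pair = pairs, t = tt$t, df = tt$df,
             p_raw = tt$p, p_fdr = pf, support = support,
             stable = !is.na(support) & support >= stableAt &
               !is.na(pf) & pf < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group contrasts of occupancy statistics
#'
#' Per state and metric (mean dwell time, fraction of time), a
#' two-sample Welch or paired t-test between groups. Subjects with
#' undefined dwell for a state (never visited) are excluded from that
#' state's dwell test and counted in the output; zero-variance
#' degenerate tests are reported as NA with a note, never as p = 0.
#'
#' @param occA,occB lists of \code{\linkS4class{StateOccupancy}}; for
#'   paired contrasts subjects are matched by \code{pairKey}.
#' @param paired logical.
#' @return data.frame: state, metric, group sizes used, excluded
#'   counts, t, df, p, note.
#' @export
occupancyContrast <- function(occA, occB, paired = FALSE) {
  k <- length(occA[[1]]@fraction)
  if (paired) {
    ka <- vapply(occA, function(o) o@pairKey, "")
    kb <- vapply(occB, function(o) o@pairKey, "")
    common <- intersect(ka, kb)
    un <- c(setdiff(ka, common), setdiff(kb, common))
    if (length(un))
      .stopf("paired contrast requested but pair keys are unmatched: %s",
             paste(un, collapse = ", "))
    occA <- occA[match(common, ka)]
    occB <- occB[match(common, kb)]
  }
  grab <- function(occ, metric, s)
    vapply(occ, function(o)
      if (metric == "dwell") o@meanDwell[s] else o@fraction[s], numeric(1))
  out <- list()
  for (s in seq_len(k)) {
    for (metric in c("dwell", "fraction")) {
      a <- grab(occA, metric, s); b <- grab(occB, metric, s)
      if (paired) {
        keep <- !is.na(a) & !is.na(b)
        d <- a[keep] - b[keep]
        excl <- sum(!keep)
        nA <- nB <- length(d)
        if (length(d) < 2) {
          res <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                      note = "fewer than 2 usable pairs; skipped")
        } else if (stats::sd(d) == 0) {
          res <- list(t = if (all(d == 0)) 0 else NA_real_, df = NA_real_,
                      p = NA_real_, note = "zero-variance differences; degenerate")
        } else {
          tt <- .colPairedT(matrix(d, ncol = 1))
          res <- list(t = tt$t, df = tt$df, p = tt$p, note = "")
        }
      } else {
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        excl <- (length(occA) - length(a)) + (length(occB) - length(b))
        nA <- length(a); nB <- length(b)
        if (nA < 2 || nB < 2) {
          res <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                      note = "fewer than 2 usable subjects; skipped")
        } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          res <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                      note = "zero variance in both groups; degenerate")
        } else {
          tt <- .colWelchT(matrix(a, ncol = 1), matrix(b, ncol = 1))
          res <- list(t = tt$t, df = tt$df, p = tt$p, note = "")
        }
      }
      out[[length(out) + 1]] <- data.frame(
        state = s, metric = metric, nA = nA, nB = nB, excluded = excl,
        t = res$t, df = res$df, p = res$p, note = res$note,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Chi-square homogeneity test of transition structure
#'
#' Pools raw transition counts per group and compares the two pooled
#' k x k tables row by row (each origin state contributes a 2 x k
#' homogeneity table); row statistics and degrees of freedom are
#' summed. Origin states never entered in one of the groups are dropped
#' from both tables with a notice, and cells with expected counts below
#' 5 are reported in a warning but still used.
#'
#' @param occA,occB lists of \code{\linkS4class{StateOccupancy}}.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{dropped} origin states and \code{smallCells}.
#' @export
transitionTest <- function(occA, occB) {
  CA <- Reduce(`+`, lapply(occA, function(o) o@counts))
  CB <- Reduce(`+`, lapply(occB, function(o) o@counts))
  k <- nrow(CA)
  dropped <- which(rowSums(CA) == 0 | rowSums(CB) == 0)
  if (length(dropped))
    .noticef("transition test: origin state(s) %s never entered in one group; dropped",
             paste(dropped, collapse = ", "))
  stat <- 0; df <- 0; small <- character(0)
  for (i in setdiff(seq_len(k), dropped)) {
    O <- rbind(CA[i, ], CB[i, ])
    colkeep <- colSums(O) > 0
    O <- O[, colkeep, drop = FALSE]
    if (ncol(O) < 2) next
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    if (any(E < 5))
      small <- c(small, sprintf("row %d cells: %s", i,
                                paste(which(E < 5), collapse = ",")))
    stat <- stat + sum((O - E)^2 / E)
    df <- df + (nrow(O) - 1) * (ncol(O) - 1)
  }
  if (length(small))
    warning(sprintf("transition test: expected counts < 5 in %s",
                    paste(small, collapse = "; ")), call. = FALSE)
  list(statistic = stat, df = df,
       p.value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
                 else NA_real_,
       dropped = dropped, smallCells = small)
}

#' Correlation of occupancy statistics with treatment response
#'
#' Treatment response is the percent change in positive-symptom score,
#' \code{100 (baseline - followup) / baseline}. Per state and metric,
#' the Pearson correlation of response with mean dwell time and
#' fraction of time. Subjects with a zero or missing baseline are
#' excluded and counted; degenerate inputs (constant response or
#' metric) are reported as NA with a note.
#'
#' @param occ list of \code{\linkS4class{StateOccupancy}}.
#' @param clinical data.frame with columns \code{pairKey},
#'   \code{baseline} and \code{followup}, matched to the occupancy
#'   objects by pair key.
#' @return data.frame: state, metric, n, excluded, r, p, note.
#' @export
clinicalCorrelation <- function(occ, clinical) {
  keys <- vapply(occ, function(o) o@pairKey, "")
  m <- match(keys, clinical$pairKey)
  base <- clinical$baseline[m]; fup <- clinical$followup[m]
  usable <- !is.na(base) & !is.na(fup) & base != 0
  nExcl <- sum(!usable)
  if (nExcl)
    .noticef("clinical correlation: %d subject(s) excluded (zero or missing baseline)",
             nExcl)
  response <- 100 * (base - fup) / base
  k <- length(occ[[1]]@fraction)
  out <- list()
  for (s in seq_len(k)) {
    for (metric in c("dwell", "fraction")) {
      v <- vapply(occ, function(o)
        if (metric == "dwell") o@meanDwell[s] else o@fraction[s], numeric(1))
      keep <- usable & !is.na(v)
      n <- sum(keep)
      if (n < 3 || stats::sd(response[keep]) == 0 || stats::sd(v[keep]) == 0) {
        r <- NA_real_; p <- NA_real_
        note <- if (n < 3) "fewer than 3 usable subjects"
                else "constant response or metric; correlation undefined"
      } else {
        ct <- stats::cor.test(response[keep], v[keep])
        r <- unname(ct$estimate); p <- ct$p.value; note <- ""
      }
      out[[length(out) + 1]] <- data.frame(
        state = s, metric = metric, n = n, excluded = nExcl, r = r, p = p,
        note = note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
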