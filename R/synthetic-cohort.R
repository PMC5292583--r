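#' Block-template connectivity states
#'
#' Builds k correlation matrices with graded off-diagonal mass —
#' sparsely, abundantly and intermediately connected patterns — by
#' partitioning the C components into blocks and filling each block
#' with a constant within-block correlation. Block structure guarantees
#' positive definiteness for \code{strength} < 1; density is controlled
#' by the number of blocks.
#'
#' With the default \code{k = 3}: state 1 splits the components into
#' pairs with graded strengths (sparse off-diagonal mass), state 2 is a
#' dense single-factor pattern with graded loadings (abundant), state 3
#' uses two blocks of different strength (intermediate). Strengths are
#' graded within each template so every state has a non-constant
#' connectivity pattern.
#'
#' @param C component count.
#' @param strength baseline within-block correlation in (0, 1).
#' @param k number of states (the default templates define 3; larger k
#'   adds further block partitions).
#' @return list of \code{\linkS4class{StateSpec}}.
#' @export
connectivityStateTemplates <- function(C, strength = 0.5, k = 3) {
  stopifnot(C >= 4, strength > 0, strength < 1, k >= 1)
  blockState <- function(label, nb, strengths) {
    blocks <- sort(rep_len(seq_len(nb), C))
    s <- strengths[blocks]
    m <- outer(blocks, blocks, "==") * sqrt(outer(s, s))
    diag(m) <- 1
    StateSpec(label, m)
  }
  out <- vector("list", k)
  for (s in seq_len(k)) {
    out[[s]] <- if (s == 1) {
      # sparse: isolated pairs, strengths graded across pairs
      nb <- floor(C / 2)
      blockState(1, nb, strength * seq(1.3, 0.7, length.out = nb))
    } else if (s == 2) {
      # abundant: dense single-factor pattern, graded loadings
      load <- pmin(sqrt(strength) * seq(1.25, 0.8, length.out = C), 0.95)
      m <- tcrossprod(load)
      diag(m) <- 1
      StateSpec(2, m)
    } else {
      # intermediate and beyond: s - 1 blocks of graded strength
      nb <- s - 1
      blockState(s, nb, strength * seq(1.2, 0.8, length.out = nb))
    }
  }
  out
}

#' Construct a cohort specification
#'
#' @param groups list of \code{\linkS4class{GroupSpec}}.
#' @param states list of \code{\linkS4class{StateSpec}}; default three
#'   block-template states over \code{C} components.
#' @param C component count.
#' @param T timepoints per scan (150 volumes by default).
#' @param TR sampling interval in seconds (2 s by default).
#' @param observationNoiseSd additive white-noise sd.
#' @param motionWalkSd realignment random-walk step sd.
#' @param spikeRate per-timepoint per-component spike probability.
#' @param seed master seed.
#' @return a \code{\linkS4class{CohortSpec}}.
#' @export
CohortSpec <- function(groups, states = connectivityStateTemplates(C),
                       C = 10, T = 150, TR = 2,
                       observationNoiseSd = 0.5, motionWalkSd = 0.02,
                       spikeRate = 0.01, seed = 1L) {
  new("CohortSpec", groups = groups, states = states, nComponents = as.integer(C),
      T = as.integer(T), TR = TR, observationNoiseSd = observationNoiseSd,
      motionWalkSd = motionWalkSd, spikeRate = spikeRate,
      seed = as.integer(seed))
}

#' Default five-cell study specification
#'
#' A cohort shaped like a two-group longitudinal resting-state study:
#' controls at baseline (HCb, n = 35) and week 6 (HC6, n = 19), patients
#' unmedicated (SZb, n = 33) and after one (SZ1, n = 29) and six (SZ6,
#' n = 24) weeks of treatment, with 150 volumes at TR = 2 s. Patients
#' dwell less in the sparse state and more in the intermediate state
#' than controls, recovering towards the control transition structure by
#' week 6; positive-symptom scores improve between sessions.
#'
#' @param C component count for the three template states.
#' @param seed master seed.
#' @param strength within-block correlation of the state templates.
#' @return a \code{\linkS4class{CohortSpec}}.
#' @export
defaultCohortSpec <- function(C = 10, seed = 1L, strength = 0.5) {
  states <- connectivityStateTemplates(C, strength = strength, k = 3)
  # controls favour the sparse state 1; unmedicated patients shift sojourn
  # mass towards the intermediate state 3
  Phc <- matrix(c(0.95, 0.02, 0.03,
                  0.05, 0.90, 0.05,
                  0.06, 0.04, 0.90), 3, 3, byrow = TRUE)
  Psz <- matrix(c(0.88, 0.02, 0.10,
                  0.05, 0.90, 0.05,
                  0.02, 0.03, 0.95), 3, 3, byrow = TRUE)
  Psz6 <- matrix(c(0.92, 0.02, 0.06,
                   0.05, 0.90, 0.05,
                   0.04, 0.03, 0.93), 3, 3, byrow = TRUE)
  groups <- list(
    GroupSpec("HCb", 35, Phc, clinicalMean = NA_real_, clinicalSd = NA_real_,
              session = "baseline", cohort = "HC"),
    GroupSpec("HC6", 19, Phc, clinicalMean = NA_real_, clinicalSd = NA_real_,
              session = "week6", cohort = "HC"),
    GroupSpec("SZb", 33, Psz, clinicalMean = 9.53, clinicalSd = 3.04,
              session = "baseline", cohort = "SZ"),
    GroupSpec("SZ1", 29, Psz, clinicalMean = 9.53, clinicalSd = 3.04,
              session = "week1", cohort = "SZ"),
    GroupSpec("SZ6", 24, Psz6, clinicalMean = 9.53, clinicalSd = 3.04,
              session = "week6", cohort = "SZ"))
  CohortSpec(groups, states, C = C, T = 150, TR = 2, seed = seed)
}

#' Recovery-benchmark cohort specification
#'
#' The noise-free, well-separated regime used for state-recovery
#' studies: two groups of \code{nPerGroup} subjects, three block
#' template states at strength 0.7, uniform symmetric switching with
#' expected sojourns of 100 timepoints (diagonal 0.99), 150 volumes at
#' TR = 2 s, no observation noise or spikes. Under these conditions
#' windowed correlations separate cleanly by generating state, which is
#' the premise of recovery checks (window-level agreement with the true
#' state paths, elbow selection of k = 3, centroid pattern
#' correlation).
#'
#' @param seed master seed.
#' @param nPerGroup subjects per group.
#' @param C component count.
#' @return a \code{\linkS4class{CohortSpec}}.
#' @export
recoveryCohortSpec <- function(seed = 1L, nPerGroup = 20, C = 10) {
  P <- matrix(0.005, 3, 3)
  diag(P) <- 0.99
  CohortSpec(list(GroupSpec("A", nPerGroup, P), GroupSpec("B", nPerGroup, P)),
             connectivityStateTemplates(C, strength = 0.7),
             C = C, T = 150, TR = 2,
             observationNoiseSd = 0, spikeRate = 0, seed = seed)
}

#' Simulate a Markov-switching multivariate Gaussian cohort
#'
#' For each subject a discrete state path is sampled from the group's
#' initial distribution and transition matrix; at each timepoint the
#' observation is a zero-mean multivariate Gaussian draw with the
#' current state's correlation matrix, plus white noise and occasional
#' artifactual spikes (magnitude five times the observation noise sd,
#' random sign). Realignment parameters are a six-dimensional Gaussian
#' random walk starting at zero. Subjects sharing a \code{cohort} label
#' across cells share \code{pairKey}s and clinical scores, so paired
#' longitudinal contrasts are well defined. Identical spec and seed
#' yield identical output.
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @return named list of \code{\linkS4class{SubjectTimecourses}}.
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  k <- length(spec@states)
  chols <- lapply(spec@states, function(s) chol(s@covariance))
  .withSeed(spec@seed, {
    # one clinical (baseline, follow-up) pair per person in each cohort,
    # reused across that person's sessions
    cohorts <- unique(vapply(spec@groups, function(g) g@cohort, ""))
    clin <- list()
    for (co in cohorts) {
      cells <- Filter(function(g) g@cohort == co, spec@groups)
      nmax <- max(vapply(cells, function(g) g@nSubjects, 1L))
      mu <- cells[[1]]@clinicalMean; sd <- cells[[1]]@clinicalSd
      if (is.na(mu)) {
        clin[[co]] <- cbind(rep(NA_real_, nmax), rep(NA_real_, nmax))
      } else {
        base <- pmax(stats::rnorm(nmax, mu, sd), 1)
        # follow-up improves; ratios mirror a ~50% positive-symptom reduction
        fup <- pmax(stats::rnorm(nmax, 0.51 * mu, 0.78 * sd), 0)
        clin[[co]] <- cbind(base, fup)
      }
    }
    subjects <- list()
    for (g in spec@groups) {
      for (i in seq_len(g@nSubjects)) {
        path <- .sampleChain(g@transitionMatrix, g@initialDistribution, spec@T)
        Z <- matrix(stats::rnorm(spec@T * spec@nComponents), spec@T, spec@nComponents)
        X <- matrix(0, spec@T, spec@nComponents)
        for (s in seq_len(k)) {
          rows <- which(path == s)
          if (length(rows)) X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
        }
        if (spec@observationNoiseSd > 0)
          X <- X + matrix(stats::rnorm(spec@T * spec@nComponents, 0,
                                       spec@observationNoiseSd),
                          spec@T, spec@nComponents)
        if (spec@spikeRate > 0) {
          hits <- matrix(stats::runif(spec@T * spec@nComponents) < spec@spikeRate,
                         spec@T, spec@nComponents)
          signs <- matrix(sample(c(-1, 1), spec@T * spec@nComponents, replace = TRUE),
                          spec@T, spec@nComponents)
          X <- X + hits * signs * 5 * spec@observationNoiseSd
        }
        steps <- matrix(stats::rnorm(spec@T * 6, 0, spec@motionWalkSd),
                        spec@T, 6)
        steps[1, ] <- 0
        rp <- apply(steps, 2, cumsum)
        id <- sprintf("%s_%02d", g@name, i)
        subjects[[id]] <- SubjectTimecourses(
          subject = id, data = X, TR = spec@TR, realignment = rp,
          group = g@name, session = g@session,
          pairKey = sprintf("%s_%02d", g@cohort, i),
          clinicalScores = c(baseline = unname(clin[[g@cohort]][i, 1]),
                             followup = unname(clin[[g@cohort]][i, 2])),
          trueStatePath = path)
      }
    }
    subjects
  })
}

.sampleChain <- function(P, pi0, T) {
  k <- nrow(P)
  path <- integer(T)
  path[1] <- sample.int(k, 1, prob = pi0)
  for (t in 2:T) path[t] <- sample.int(k, 1, prob = P[path[t - 1], ])
  path
}

#' Expected state occupancy of a Markov chain
#'
#' Ground truth for parameter-recovery tests: the stationary fraction of
#' time per state (or, for non-ergodic chains, the occupancy averaged
#' over \code{T} steps from \code{initial}) and the expected dwell time
#' \code{1 / (1 - P[i,i])} in timepoints. A diagonal entry of 1 yields
#' an explicit infinite dwell.
#'
#' @param P k x k row-stochastic transition matrix.
#' @param initial length-k initial distribution (uniform by default);
#'   used only for non-ergodic chains.
#' @param T horizon for the non-ergodic time average.
#' @return list with elements \code{fraction} and \code{dwell}.
#' @export
expectedOccupancy <- function(P, initial = NULL, T = 150) {
  P <- as.matrix(P)
  if (!.isSquareNumeric(P)) .stopf("P must be a square numeric matrix")
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad))
    .stopf("transition matrix row %s does not sum to 1",
           paste(bad, collapse = ", "))
  k <- nrow(P)
  if (is.null(initial)) initial <- rep(1 / k, k)
  dwell <- ifelse(diag(P) >= 1, Inf, 1 / (1 - diag(P)))
  e <- eigen(t(P))
  one <- which(abs(e$values - 1) < 1e-9)
  ergodic <- length(one) == 1 &&
    sum(abs(abs(e$values) - 1) < 1e-9) == 1
  if (ergodic) {
    v <- Re(e$vectors[, one])
    fraction <- v / sum(v)
    if (any(fraction < -1e-12)) ergodic <- FALSE else fraction <- pmax(fraction, 0)
  }
  if (!ergodic) {
    # time-averaged occupancy over T steps
    pi_t <- initial
    acc <- pi_t
    for (t in seq_len(T - 1)) {
      pi_t <- as.numeric(pi_t %*% P)
      acc <- acc + pi_t
    }
    fraction <- acc / T
  }
  list(fraction = as.numeric(fraction), dwell = as.numeric(dwell))
}

#' Write a cohort to delimited text files
#'
#' One TSV of time courses and one of realignment parameters per
#' subject, a tab-separated manifest listing files, group, session,
#' pair key, clinical scores and the postprocessing stage, and (for
#' synthetic subjects) the generating state path in a
#' \code{*_true_states.tsv} file.
#'
#' @param cohort named list of \code{\linkS4class{SubjectTimecourses}}.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    tcf <- file.path(dir, paste0(s@subject, "_timecourses.tsv"))
    utils::write.table(format(s@data, digits = 17, trim = TRUE), tcf,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    rpf <- ""
    if (nrow(s@realignment)) {
      rpf <- file.path(dir, paste0(s@subject, "_realignment.tsv"))
      utils::write.table(format(s@realignment, digits = 17, trim = TRUE), rpf,
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
    if (length(s@trueStatePath))
      utils::write.table(s@trueStatePath,
                         file.path(dir, paste0(s@subject, "_true_states.tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    data.frame(subject = s@subject, group = s@group, session = s@session,
               pair_key = s@pairKey, TR = s@TR,
               tc_file = basename(tcf), rp_file = basename(rpf),
               clinical_baseline = s@clinicalScores[["baseline"]],
               clinical_followup = s@clinicalScores[["followup"]],
               stage = s@stage, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mf)
}

#' Read a cohort written by \code{writeCohort}
#'
#' @param dir directory containing \code{manifest.tsv}.
#' @return named list of \code{\linkS4class{SubjectTimecourses}}.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) .stopf("no manifest.tsv under %s", dir)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    X <- as.matrix(utils::read.table(file.path(dir, m$tc_file), sep = "\t"))
    dimnames(X) <- NULL
    rp <- matrix(0, 0, 6)
    if (nzchar(m$rp_file) && !is.na(m$rp_file)) {
      rp <- as.matrix(utils::read.table(file.path(dir, m$rp_file), sep = "\t"))
      dimnames(rp) <- NULL
    }
    tsf <- file.path(dir, paste0(m$subject, "_true_states.tsv"))
    path <- if (file.exists(tsf))
      utils::read.table(tsf, sep = "\t")[[1]] else integer(0)
    SubjectTimecourses(subject = m$subject, data = X, TR = m$TR,
                       realignment = rp, group = m$group,
                       session = m$session, pairKey = m$pair_key,
                       stage = m$stage,
                       clinicalScores = c(baseline = m$clinical_baseline,
                                          followup = m$clinical_followup),
                       trueStatePath = path)
  })
  names(cohort) <- manifest$subject
  cohort
}
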