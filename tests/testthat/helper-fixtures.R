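# Fixture builders shared across test files.

filteredSubject <- function(X, TR = 2, subject = "s", group = "A",
                            session = "1", pairKey = subject) {
  SubjectTimecourses(subject, as.matrix(X), TR = TR, group = group,
                     session = session, pairKey = pairKey, stage = "filtered")
}

rawSubject <- function(X, TR = 2, subject = "s", realignment = matrix(0, 0, 6),
                       group = "A") {
  SubjectTimecourses(subject, as.matrix(X), TR = TR,
                     realignment = realignment, group = group)
}

syntheticWFNC <- function(traj, TR = 2, subject = "s", group = "A",
                          widthTr = 22L, lambda = 0.1) {
  traj <- as.matrix(traj)
  new("WindowedFNC", subject = subject, group = group, session = "1",
      pairKey = subject, TR = TR, widthTr = as.integer(widthTr),
      lambda = lambda, windowStarts = seq_len(nrow(traj)),
      trajectory = traj, pairNames = paste0("p", seq_len(ncol(traj))))
}

# mode generating state of each sliding window, per subject, concatenated
windowModeTruth <- function(cohort, widthTr, k) {
  unlist(lapply(cohort, function(s) {
    p <- trueStatePath(s)
    nW <- length(p) - widthTr + 1
    vapply(seq_len(nW), function(i)
      which.max(tabulate(p[i:(i + widthTr - 1)], k)), 1L)
  }), use.names = FALSE)
}

# small two-cloud exemplar matrix with known labels
twoClouds <- function(n = 20, P = 10, sep = 20, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * P), n, P),
             matrix(rnorm(n * P, mean = sep), n, P))
  list(X = X, labels = rep(1:2, each = n))
}
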