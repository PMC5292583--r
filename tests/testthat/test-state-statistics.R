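test_that("occupancy statistics match hand counts on worked sequences", {
  o <- stateOccupancy(c(1, 1, 1, 2, 2, 3), 3)
  expect_equal(meanDwell(o), c(3, 2, 1))
  expect_equal(fractionTime(o), c(0.5, 1 / 3, 1 / 6))

  o2 <- stateOccupancy(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(meanDwell(o2)[1], 1.5)           # sojourns of 2 and 1
  expect_equal(o2@counts, matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE))
  expect_equal(transitionMatrix(o2)[1, ], c(0.5, 0.5))
  expect_equal(transitionMatrix(o2)[2, ], c(1 / 3, 2 / 3))

  o3 <- stateOccupancy(rep(2, 8), 3)
  expect_equal(fractionTime(o3), c(0, 1, 0))
  expect_equal(meanDwell(o3)[2], 8)
  expect_true(is.na(meanDwell(o3)[1]) && is.na(meanDwell(o3)[3]))
  expect_true(all(is.nan(transitionMatrix(o3)[1, ])))
  expect_error(stateOccupancy(integer(0), 3), "empty")
})

test_that("occupancy bookkeeping identities hold on random sequences", {
  set.seed(44)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    lab <- sample.int(k, sample(5:60, 1), replace = TRUE)
    o <- stateOccupancy(lab, k)
    expect_equal(sum(fractionTime(o)), 1)
    runs <- rle(lab)
    nSojourn <- vapply(seq_len(k), function(s) sum(runs$values == s), 1L)
    dwell <- meanDwell(o); dwell[is.na(dwell)] <- 0
    expect_equal(sum(nSojourn * dwell), length(lab))
    expect_equal(sum(o@counts), length(lab) - 1)
  }
})

test_that("subject state medians respect missing states and group means", {
  traj <- rbind(c(0.1, 1), c(0.5, 2), c(0.9, 3))
  w <- syntheticWFNC(traj)
  m <- subjectStateMedians(w, c(1, 1, 1), 2)
  expect_equal(unname(m[1, ]), c(0.5, 2))
  expect_true(all(is.na(m[2, ])))

  m2 <- subjectStateMedians(w, c(2, 1, 1), 2)
  expect_equal(unname(m2[2, ]), c(0.1, 1))      # single window: that window

  # group mean centroid equals the flat mean of present subject rows
  subs <- lapply(1:4, function(i) {
    tr <- matrix(rnorm(12), 4, 3)
    subjectStateMedians(syntheticWFNC(tr), c(1, 1, 2, 2), 2)
  })
  gm <- Reduce(`+`, lapply(subs, function(m) m[1, ])) / 4
  flat <- colMeans(do.call(rbind, lapply(subs, function(m) m[1, ])))
  expect_equal(gm, flat)
})

test_that("state contrasts flag only reliably shifted pairs as stable", {
  set.seed(55)
  planted <- 0; spurious <- 0
  for (rep in 1:5) {
    A <- lapply(1:20, function(i) {
      m <- matrix(rnorm(2 * 6, 0, 0.1), 2, 6); m[1, 3] <- m[1, 3] + 1
      rownames(m) <- c("state1", "state2"); m
    })
    B <- lapply(1:20, function(i) {
      m <- matrix(rnorm(2 * 6, 0, 0.1), 2, 6)
      rownames(m) <- c("state1", "state2"); m
    })
    names(A) <- paste0("a", 1:20); names(B) <- paste0("b", 1:20)
    res <- stateContrast(A, B, state = 1, nBoot = 200, seed = rep)
    planted <- planted + res$stable[3]
    spurious <- spurious + sum(res$stable[-3])
    # stability implies original significance by construction
    expect_true(all(res$p_fdr[res$stable] < 0.05))
  }
  expect_gte(planted, 4)
  expect_lte(spurious, 1)
})

test_that("identical groups yield no stable pairs and disabled bootstraps report NA", {
  set.seed(8)
  A <- lapply(1:6, function(i) matrix(rnorm(12), 2, 6))
  names(A) <- paste0("s", 1:6)
  res <- stateContrast(A, A, state = 1, nBoot = 100, seed = 1)
  expect_false(any(res$stable))

  res0 <- stateContrast(A, A, state = 1, nBoot = 0)
  expect_true(all(is.na(res0$support)))
  expect_false(any(res0$stable))

  # a state expressed by too few subjects skips the contrast with a message
  B <- lapply(1:6, function(i) {
    m <- matrix(rnorm(12), 2, 6); m[1, ] <- NA; m
  })
  names(B) <- paste0("t", 1:6)
  expect_message(out <- stateContrast(A, B, state = 1, nBoot = 0), "skipped")
  expect_null(out)
})

test_that("occupancy contrasts exclude undefined dwells and guard degeneracy", {
  mkOcc <- function(lab, id, grp) stateOccupancy(lab, 3, subject = id,
                                                 group = grp, pairKey = id)
  A <- lapply(1:5, function(i) mkOcc(c(1, 1, 2, 2, 2, 1, 3, 3), paste0("a", i), "A"))
  res <- occupancyContrast(A, A)
  expect_true(all(res$note != "" | res$p == 1 | is.na(res$p)))

  # deterministic disjoint fractions: degenerate, not p = 0
  B1 <- lapply(1:4, function(i) mkOcc(rep(1, 6), paste0("a", i), "A"))
  B2 <- lapply(1:4, function(i) mkOcc(rep(2, 6), paste0("b", i), "B"))
  res2 <- occupancyContrast(B1, B2)
  frac1 <- res2[res2$state == 1 & res2$metric == "fraction", ]
  expect_true(is.na(frac1$p))
  expect_match(frac1$note, "degenerate|skipped")
  # dwell for a state visited by neither group is skipped with counts reported
  dwell3 <- res2[res2$state == 3 & res2$metric == "dwell", ]
  expect_equal(dwell3$excluded, 8)
})

test_that("transition homogeneity testing matches the chi-square oracle", {
  mkOcc <- function(lab) stateOccupancy(lab, 2)
  A <- list(mkOcc(c(rep(1, 91), rep(2, 10))))
  # identical pooled tables: statistic exactly 0
  same <- suppressWarnings(transitionTest(A, A))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  TA <- matrix(c(90, 10, 10, 90), 2, 2, byrow = TRUE)
  TB <- matrix(c(50, 50, 50, 50), 2, 2, byrow = TRUE)
  oA <- stateOccupancy(c(1, 2), 2); oA@counts <- TA
  oB <- stateOccupancy(c(1, 2), 2); oB@counts <- TB
  got <- transitionTest(list(oA), list(oB))
  ref <- transitionChisqOracle(TA, TB)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(got$df, ref$df)

  # a never-entered origin state is dropped from both tables
  T3A <- rbind(c(40, 10, 0), c(5, 45, 0), c(0, 0, 0))
  T3B <- rbind(c(30, 20, 0), c(15, 35, 0), c(0, 0, 0))
  o3A <- stateOccupancy(c(1, 2, 1), 3); o3A@counts <- T3A
  o3B <- stateOccupancy(c(1, 2, 1), 3); o3B@counts <- T3B
  expect_message(got3 <- transitionTest(list(o3A), list(o3B)), "dropped")
  ref3 <- transitionChisqOracle(T3A[1:2, 1:2], T3B[1:2, 1:2])
  expect_equal(got3$statistic, ref3$statistic, tolerance = 1e-12)
  expect_equal(got3$df, ref3$df)
})

test_that("clinical correlations handle exact, degenerate and excluded cases", {
  mkOcc <- function(counts, id) {
    stateOccupancy(rep(1:3, counts), 3, subject = id, pairKey = id)
  }
  occ <- lapply(1:8, function(i) mkOcc(c(i, 8, 16 - i), paste0("s", i)))
  # response exactly linear in the state-1 fraction
  clin <- data.frame(pairKey = paste0("s", 1:8),
                     baseline = 10, followup = 10 - (1:8))
  res <- clinicalCorrelation(occ, clin)
  r1 <- res[res$state == 1 & res$metric == "fraction", "r"]
  expect_equal(r1, 1, tolerance = 1e-10)

  # constant response: undefined, reported as such
  clinC <- data.frame(pairKey = paste0("s", 1:8), baseline = 10, followup = 5)
  resC <- clinicalCorrelation(occ, clinC)
  expect_true(all(is.na(resC$r)))
  expect_true(all(nzchar(resC$note)))

  # zero baseline excluded with a notice
  clinZ <- clin; clinZ$baseline[1] <- 0
  expect_message(resZ <- clinicalCorrelation(occ, clinZ), "excluded")
  expect_true(all(resZ$excluded == 1))
})
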