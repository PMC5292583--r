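test_that("state templates are valid correlation matrices with graded density", {
  tmpl <- connectivityStateTemplates(10)
  expect_length(tmpl, 3)
  for (s in tmpl) {
    m <- s@covariance
    expect_equal(diag(m), rep(1, 10))
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  mass <- vapply(tmpl, function(s) mean(abs(s@covariance[upper.tri(s@covariance)])),
                 numeric(1))
  # sparse < intermediate < abundant off-diagonal mass
  expect_lt(mass[1], mass[3])
  expect_lt(mass[3], mass[2])
  # every template has a non-constant connectivity pattern
  for (s in tmpl)
    expect_gt(stats::sd(s@covariance[upper.tri(s@covariance)]), 0)
})

test_that("identity transition matrix freezes every subject in its initial state", {
  P <- diag(3)
  spec <- CohortSpec(list(GroupSpec("A", 5, P)), connectivityStateTemplates(6),
                     C = 6, T = 50, seed = 4)
  co <- simulateCohort(spec)
  for (s in co)
    expect_length(unique(trueStatePath(s)), 1)
})

test_that("empirical correlation converges to the single state's correlation", {
  tmpl <- connectivityStateTemplates(6)[2]
  tmpl[[1]]@label <- 1L
  spec <- CohortSpec(list(GroupSpec("A", 1, matrix(1))), tmpl,
                     C = 6, T = 10000, observationNoiseSd = 0, spikeRate = 0,
                     seed = 9)
  co <- simulateCohort(spec)
  emp <- cor(timecourses(co[[1]]))
  expect_lt(max(abs(emp - tmpl[[1]]@covariance)), 0.05)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  spec <- CohortSpec(list(GroupSpec("A", 3, diag(3))), connectivityStateTemplates(5),
                     C = 5, T = 40, seed = 11)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(lapply(a, timecourses), lapply(b, timecourses))
  expect_identical(lapply(a, realignment), lapply(b, realignment))
  spec2 <- CohortSpec(list(GroupSpec("A", 3, diag(3))), connectivityStateTemplates(5),
                      C = 5, T = 40, seed = 12)
  c <- simulateCohort(spec2)
  expect_false(identical(timecourses(a[[1]]), timecourses(c[[1]])))
})

test_that("invalid specifications are rejected with informative messages", {
  P <- matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2, byrow = TRUE) # row 1 sums to 1.1
  expect_error(GroupSpec("A", 3, P), "row 1")
  bad <- matrix(c(1, 2, 2, 1), 2, 2) # not PD
  expect_error(StateSpec(2, bad), "positive definite")
})

test_that("expected occupancy matches hand values and an eigen oracle", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  eo <- expectedOccupancy(P)
  expect_equal(eo$dwell, c(10, 10))
  expect_equal(eo$fraction, c(0.5, 0.5))

  P <- matrix(0.5, 2, 2)
  eo <- expectedOccupancy(P)
  expect_equal(eo$fraction, c(0.5, 0.5))
  expect_equal(eo$dwell, c(2, 2))

  P3 <- matrix(c(.8, .1, .1, .2, .7, .1, .1, .1, .8), 3, 3, byrow = TRUE)
  eo <- expectedOccupancy(P3)
  expect_equal(eo$fraction, stationaryOracle(P3), tolerance = 1e-10)

  # absorbing diagonal entry reports infinite dwell explicitly
  Pa <- matrix(c(1, 0, 0.3, 0.7), 2, 2, byrow = TRUE)
  eo <- expectedOccupancy(Pa, initial = c(0.5, 0.5), T = 100)
  expect_identical(eo$dwell[1], Inf)
})

test_that("empirical state fractions recover the stationary distribution", {
  P <- matrix(c(.85, .1, .05, .1, .8, .1, .05, .15, .8), 3, 3, byrow = TRUE)
  spec <- CohortSpec(list(GroupSpec("A", 1, P)), connectivityStateTemplates(4),
                     C = 4, T = 5000, seed = 21)
  co <- simulateCohort(spec)
  emp <- tabulate(trueStatePath(co[[1]]), 3) / 5000
  expect_lt(max(abs(emp - expectedOccupancy(P)$fraction)), 0.03)
})

test_that("cohorts survive a text round trip", {
  spec <- CohortSpec(list(GroupSpec("A", 2, diag(2), session = "b")),
                     connectivityStateTemplates(5, k = 2), C = 5, T = 30,
                     seed = 5)
  co <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(names(back), names(co))
  expect_equal(timecourses(back[[1]]), timecourses(co[[1]]), tolerance = 1e-12)
  expect_identical(trueStatePath(back[[1]]), trueStatePath(co[[1]]))
  expect_identical(back[[1]]@session, "b")
})

test_that("paired sessions share pair keys and clinical scores", {
  P <- diag(3)
  groups <- list(
    GroupSpec("Gb", 4, P, clinicalMean = 9.5, clinicalSd = 3,
              session = "baseline", cohort = "G"),
    GroupSpec("G6", 3, P, clinicalMean = 9.5, clinicalSd = 3,
              session = "week6", cohort = "G"))
  co <- simulateCohort(CohortSpec(groups, connectivityStateTemplates(5),
                                  C = 5, T = 30, seed = 2))
  expect_identical(co[["Gb_02"]]@pairKey, co[["G6_02"]]@pairKey)
  expect_identical(co[["Gb_02"]]@clinicalScores, co[["G6_02"]]@clinicalScores)
  expect_true(co[["Gb_01"]]@clinicalScores[["baseline"]] > 0)
})
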