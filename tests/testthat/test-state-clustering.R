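test_that("exemplars sit at strict variance maxima with one-sided endpoints", {
  # construct windows whose across-pair variance is exactly (1, 3, 2, 5, 4)
  v <- c(1, 3, 2, 5, 4)
  traj <- t(vapply(v, function(s) c(sqrt(s), -sqrt(s), 0, 0), numeric(4)))
  ex <- selectExemplars(list(s1 = syntheticWFNC(traj)))
  expect_identical(ex@provenance$windowStart, c(2L, 4L))

  vInc <- 1:6
  trajInc <- t(vapply(vInc, function(s) c(sqrt(s), -sqrt(s), 0, 0), numeric(4)))
  ex2 <- selectExemplars(list(s1 = syntheticWFNC(trajInc)))
  expect_identical(ex2@provenance$windowStart, 6L)

  flat <- matrix(rep(c(1, -1, 0, 0), each = 5), 5, 4)
  expect_message(ex3 <- selectExemplars(list(s1 = syntheticWFNC(flat))),
                 "max-variance")
  expect_identical(nrow(ex3@rows), 1L)
})

test_that("L1 k-means recovers separated clouds and honours median centroids", {
  tc <- twoClouds(seed = 41)
  fit <- fitStates(tc$X, 2, replicates = 5, seed = 1)
  a <- assignments(fit)$.exemplars
  expect_equal(mclust::adjustedRandIndex(a, tc$labels), 1)

  # all points identical
  one <- matrix(1, 5, 3)
  f1 <- fitStates(one, 1, replicates = 2, seed = 1)
  expect_equal(unname(centroids(f1)[1, ]), rep(1, 3))
  expect_equal(f1@inertia, 0)

  # the L1 centroid is the median, not the mean
  pts <- matrix(c(0, 0, 10), ncol = 1)
  fm <- fitStates(pts, 1, replicates = 2, seed = 1)
  expect_equal(unname(centroids(fm)[1, 1]), 0)
})

test_that("k-means inertia never increases across iterations", {
  set.seed(7)
  X <- matrix(rnorm(300), 100, 3)
  fit <- dynFNC:::.kmeansL1(X, X[1:4, ], maxIter = 150)
  expect_true(all(diff(fit$inertiaTrace) <= 1e-10))
})

test_that("clustering is deterministic given a seed and ignores caller RNG", {
  tc <- twoClouds(seed = 3)
  f1 <- fitStates(tc$X, 2, seed = 99)
  set.seed(12345); runif(10)
  f2 <- fitStates(tc$X, 2, seed = 99)
  expect_identical(centroids(f1), centroids(f2))
  expect_identical(assignments(f1), assignments(f2))
})

test_that("the chord rule finds a constructed sharp knee", {
  k <- 2:8
  ratio <- c(4, 2.5, 1.6, 1.5, 1.45, 1.42, 1.4) # sharp knee at k = 4
  d <- dynFNC:::.chordDistance(k, ratio)
  expect_identical(k[which.max(d)], 4L)
})

test_that("the elbow recovers three well-separated clusters and flags flat curves", {
  set.seed(19)
  centers <- matrix(rnorm(3 * 20, sd = 4), 3, 20)
  hits <- 0
  for (s in 1:5) {
    X <- do.call(rbind, lapply(1:3, function(c)
      matrix(rnorm(30 * 20, mean = rep(centers[c, ], each = 30), sd = 1), 30, 20)))
    eb <- chooseK(X, kGrid = 2:6, replicates = 5, seed = s)
    hits <- hits + (eb@kSelected == 3)
  }
  expect_gte(hits, 4)

  # structureless data: selection still returned but flagged low-confidence
  X0 <- matrix(rnorm(100 * 10), 100, 10)
  expect_message(eb0 <- chooseK(X0, kGrid = 2:6, replicates = 3, seed = 1))
  expect_true(eb0@flagged)
  expect_true(eb0@kSelected %in% 2:6)
})

test_that("warm-started full assignment is a fixed point on the exemplar set", {
  tc <- twoClouds(seed = 5)
  em <- fitStates(tc$X, 2, replicates = 5, seed = 1)
  wf <- list(s1 = syntheticWFNC(tc$X[1:20, ]), s2 = syntheticWFNC(tc$X[21:40, ]))
  full <- assignAllWindows(wf, em)
  expect_equal(centroids(full), centroids(em))
  expect_identical(unname(unlist(assignments(full))),
                   assignments(em)$.exemplars)
})

test_that("full assignment is order-invariant and label-equivariant", {
  set.seed(33)
  X <- rbind(matrix(rnorm(200), 50, 4), matrix(rnorm(200, 5), 50, 4))
  wf <- list(a = syntheticWFNC(X[1:25, ]), b = syntheticWFNC(X[26:75, ]),
             c = syntheticWFNC(X[76:100, ]))
  em <- fitStates(X, 2, replicates = 5, seed = 2)
  f1 <- assignAllWindows(wf, em)
  f2 <- assignAllWindows(wf[c("c", "a", "b")], em)
  expect_equal(centroids(f1), centroids(f2))
  expect_identical(assignments(f1)$a, assignments(f2)$a)

  # permuting warm-start labels permutes the output consistently
  emSwap <- em
  emSwap@centroids <- em@centroids[2:1, , drop = FALSE]
  fSwap <- assignAllWindows(wf, emSwap)
  expect_identical(assignments(fSwap)$a, 3L - assignments(f1)$a)
  expect_equal(centroids(fSwap), centroids(f1)[2:1, , drop = FALSE])
})

test_that("states reorder by ascending total connectivity", {
  m <- new("StateModel", k = 2L,
           centroids = rbind(c(5, 5), c(-1, -1)),
           assignments = list(s = c(1L, 1L, 2L)), inertia = 0,
           stage = "full", pairNames = c("p1", "p2"))
  o <- orderStatesByConnectivity(m)
  expect_equal(centroids(o)[1, ], c(-1, -1))
  expect_identical(assignments(o)$s, c(2L, 2L, 1L))
})
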