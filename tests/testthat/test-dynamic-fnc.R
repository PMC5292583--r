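test_that("tapered windows have the documented width, mass and symmetry", {
  w <- makeTaperedWindow(44, 2)
  expect_identical(w@widthTr, 22L)      # 44 s at TR = 2 s
  for (width in c(30, 40, 44, 50, 60)) {
    w <- makeTaperedWindow(width, 2)
    expect_identical(w@widthTr, as.integer(round(width / 2)))
    expect_equal(sum(w@weights), 1, tolerance = 1e-12)
    expect_equal(w@weights, rev(w@weights), tolerance = 1e-12)
    expect_true(all(w@weights >= 0))
  }
  # vanishing taper sd approaches the plain rectangle
  w0 <- makeTaperedWindow(44, 2, sigmaTr = 1e-6)
  expect_equal(w0@weights, rep(1 / 22, 22), tolerance = 1e-9)
  expect_error(makeTaperedWindow(4, 2), ">= 3")
})

test_that("graphical LASSO agrees with an independent coordinate-descent oracle", {
  set.seed(17)
  for (rep in 1:6) {
    S <- cov2cor(crossprod(matrix(rnorm(60), 12, 5)) / 12)
    for (rho in c(0.05, 0.1)) {
      fit <- graphicalLasso(S, rho)
      ref <- glassoOracle(S, rho)
      expect_lt(max(abs(fit$wi - ref)), 1e-4)
      # KKT stationarity certificate, independent of any solver
      expect_lt(glassoKKT(S, rho, fit$wi), 1e-4)
    }
    # unpenalised limit is the plain inverse
    expect_lt(max(abs(graphicalLasso(S, 0)$wi - solve(S))), 1e-10)
  }
})

test_that("penalty increases never destroy precision sparsity", {
  set.seed(23)
  S <- cov2cor(crossprod(matrix(rnorm(100), 20, 5)) / 20)
  nz <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(rho)
    sum(abs(graphicalLasso(S, rho)$wi[upper.tri(S)]) < 1e-8), numeric(1))
  expect_true(all(diff(nz) >= 0))
})

test_that("windowed trajectories honour the one-TR step contract", {
  set.seed(6)
  for (width in c(30, 44, 60)) {
    X <- matrix(rnorm(150 * 5), 150, 5)
    wf <- windowedFNC(filteredSubject(X), makeTaperedWindow(width, 2),
                      lambda = 0.1)
    expect_identical(nrow(trajectory(wf)), 150L - as.integer(width / 2) + 1L)
    expect_identical(windowStarts(wf), seq_len(nrow(trajectory(wf))))
    expect_true(all(is.finite(trajectory(wf))))
  }
})

test_that("proportional components stay perfectly correlated in every window", {
  set.seed(9)
  base <- rnorm(100)
  X <- cbind(base, 3 * base, rnorm(100), rnorm(100))
  wf <- windowedFNC(filteredSubject(X), makeTaperedWindow(44, 2), lambda = 0)
  # pair (1,2) is the first upper-triangle entry
  expect_true(all(trajectory(wf)[, 1] > 13))
})

test_that("the unpenalised estimator equals the weighted sample correlation", {
  set.seed(10)
  X <- matrix(rnorm(40 * 4), 40, 4)
  win <- makeTaperedWindow(44, 2)
  wf <- windowedFNC(filteredSubject(X), win, lambda = 0)
  s <- 5
  seg <- X[s:(s + 21), ]
  mu <- colSums(seg * win@weights)
  Sc <- crossprod(sweep(seg, 2, mu) * sqrt(win@weights))
  expect_equal(trajectory(wf)[s, ],
               atanh(pmin(pmax(cov2cor(Sc)[upper.tri(Sc)], -(1 - 1e-12)),
                          1 - 1e-12)),
               tolerance = 1e-6)
})

test_that("wider windows smooth single-state connectivity fluctuations", {
  spec <- CohortSpec(list(GroupSpec("A", 3, diag(3))),
                     connectivityStateTemplates(6), C = 6, T = 150,
                     observationNoiseSd = 0, spikeRate = 0, seed = 14)
  co <- simulateCohort(spec)
  for (s in co) {
    f <- postprocessSubject(s)
    v30 <- mean(apply(trajectory(windowedFNC(f, makeTaperedWindow(30, 2))), 2, var))
    v60 <- mean(apply(trajectory(windowedFNC(f, makeTaperedWindow(60, 2))), 2, var))
    expect_lt(v60, v30)
  }
})

test_that("low-frequency fluctuation amplitude concentrates where the tone is", {
  nW <- 125 # 250 s of windowed series: 0.04 Hz and 0.2 Hz land on exact bins
  tt <- seq_len(nW) * 2
  traj <- cbind(rep(0.3, nW),
                sin(2 * pi * 0.04 * tt),
                sin(2 * pi * 0.2 * tt))
  w <- syntheticWFNC(traj)
  v <- alffFC(w)
  expect_equal(unname(v[1]), 0)                 # constant series: no fluctuation

  amp <- abs(stats::mvfft(sweep(traj, 2, colMeans(traj))))[2:(floor(nW / 2) + 1), ] / nW
  tot <- colSums(amp)
  expect_gt(v[2] * 0.5 / tot[2], 0.95)          # in-band tone captured
  expect_lt(v[3] * 0.5 / tot[3], 0.05)          # out-of-band tone excluded
  expect_true(all(v >= 0))

  expect_error(alffFC(w, band = c(0.01, 0.3)), "0.25")
  # Nyquist normalisation option rescales by band-independent constant
  expect_equal(unname(alffFC(w, normConst = "nyquist")[2]),
               unname(v[2] * 0.5 / 0.25), tolerance = 1e-12)
})
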