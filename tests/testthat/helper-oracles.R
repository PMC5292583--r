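# Independent oracles used to cross-check the package's estimators.

# Textbook blockwise coordinate-descent graphical LASSO, written in plain
# R independently of the package's compiled implementation. Penalises
# off-diagonal precision entries; returns the precision matrix.
glassoOracle <- function(S, rho, maxit = 400, tol = 1e-11) {
  p <- nrow(S)
  W <- S
  Beta <- matrix(0, p, p)
  for (iter in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      mj <- setdiff(seq_len(p), j)
      V <- W[mj, mj, drop = FALSE]
      s <- S[mj, j]
      b <- Beta[mj, j]
      for (sw in seq_len(1000)) {
        bold <- b
        for (l in seq_along(mj)) {
          r <- s[l] - sum(V[l, -l] * b[-l])
          b[l] <- sign(r) * max(abs(r) - rho, 0) / V[l, l]
        }
        if (max(abs(b - bold)) < 1e-13) break
      }
      Beta[mj, j] <- b
      W[mj, j] <- W[j, mj] <- as.numeric(V %*% b)
    }
    if (max(abs(W - Wold)) < tol * max(abs(S))) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    mj <- setdiff(seq_len(p), j)
    tjj <- 1 / (W[j, j] - sum(W[mj, j] * Beta[mj, j]))
    Theta[j, j] <- tjj
    Theta[mj, j] <- -Beta[mj, j] * tjj
  }
  (Theta + t(Theta)) / 2
}

# KKT optimality certificate for the graphical-LASSO solution: returns the
# largest violation of the stationarity conditions.
glassoKKT <- function(S, rho, Theta, zeroTol = 1e-8) {
  W <- solve(Theta)
  G <- W - S
  viol <- max(abs(diag(G)))
  off <- upper.tri(S)
  viol <- max(viol, max(pmax(abs(G[off]) - rho, 0)))
  act <- off & abs(Theta) > zeroTol
  if (any(act))
    viol <- max(viol, max(abs(G[act] - rho * sign(Theta[act]))))
  viol
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# Stationary distribution by power iteration on t(P).
stationaryOracle <- function(P, iters = 10000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(v %*% P)
    if (max(abs(v2 - v)) < 1e-14) return(v2)
    v <- v2
  }
  v
}

# Chi-square homogeneity of two transition-count tables, row by row,
# via stats::chisq.test on each origin row.
transitionChisqOracle <- function(A, B) {
  stat <- 0; df <- 0
  for (i in seq_len(nrow(A))) {
    O <- rbind(A[i, ], B[i, ])
    O <- O[, colSums(O) > 0, drop = FALSE]
    if (ncol(O) < 2) next
    ct <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
    stat <- stat + unname(ct$statistic)
    df <- df + unname(ct$parameter)
  }
  list(statistic = stat, df = df)
}
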