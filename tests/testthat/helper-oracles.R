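# Brute-force oracles shared across tests.

# all permutations of a vector (n <= 6)
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# minimum-cost one-to-one assignment by exhaustive search; returns the cost
bruteAssignmentCost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  if (n <= m) {
    for (cols in utils::combn(m, n, simplify = FALSE)) {
      for (p in allPerms(cols)) {
        best <- min(best, sum(cost[cbind(seq_len(n), p)]))
      }
    }
  } else {
    for (rows in utils::combn(n, m, simplify = FALSE)) {
      for (p in allPerms(rows)) {
        best <- min(best, sum(cost[cbind(p, seq_len(m))]))
      }
    }
  }
  best
}

# one textbook Kalman predict/update in plain matrix arithmetic
kalmanOracle <- function(m, P, dt, q, r, obs = NULL) {
  F <- diag(4); F[1, 3] <- dt; F[2, 4] <- dt
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- Q[2, 2] <- q * dt^3 / 3
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- q * dt^2 / 2
  Q[3, 3] <- Q[4, 4] <- q * dt
  m <- F %*% m
  P <- F %*% P %*% t(F) + Q
  if (!is.null(obs)) {
    H <- cbind(diag(2), matrix(0, 2, 2))
    S <- H %*% P %*% t(H) + diag(2) * r^2
    K <- P %*% t(H) %*% solve(S)
    m <- m + K %*% (obs - H %*% m)
    P <- (diag(4) - K %*% H) %*% P
  }
  list(m = as.numeric(m), P = (P + t(P)) / 2)
}

# small scene used by several detection/tracking tests
quietScene <- function(frameSize = c(100L, 140L), duration = 6,
                       nBirds = 2L, nFoamPatches = 0L, glintRate = 0,
                       sheddingFrequency = 0, ...) {
  sceneConfig(frameSize = frameSize, duration = duration, nBirds = nBirds,
              nFoamPatches = nFoamPatches, glintRate = glintRate,
              sheddingFrequency = sheddingFrequency, ...)
}
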