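# Independent oracles used across the test files. These deliberately share
# no code with the package: exhaustive loops and textbook formulas only.

# O(n^2) pair enumeration in plain R
oracle_pair_counts <- function(x, y) {
  n <- length(x)
  nc <- nd <- n1 <- n2 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0) n1 <- n1 + 1
    if (dy == 0) n2 <- n2 + 1
    if (dx != 0 && dy != 0) {
      if (dx * dy > 0) nc <- nc + 1 else nd <- nd + 1
    }
  }
  list(n_c = nc, n_d = nd, n_0 = n * (n - 1) / 2, n_1 = n1, n_2 = n2, n = n)
}

oracle_entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

# coefficient formulas written directly from their definitions
oracle_measure <- function(x, y, measure) {
  pc <- oracle_pair_counts(x, y)
  switch(measure,
    rho_s = suppressWarnings(stats::cor(rank(x), rank(y))),
    tau_a = (pc$n_c - pc$n_d) / pc$n_0,
    tau_b = {
      den <- sqrt((pc$n_0 - pc$n_1) * (pc$n_0 - pc$n_2))
      if (den == 0) NA_real_ else (pc$n_c - pc$n_d) / den
    },
    tau_c = {
      m <- min(length(unique(x)), length(unique(y)))
      if (m < 2) NA_real_
      else 2 * m * (pc$n_c - pc$n_d) / (pc$n^2 * (m - 1))
    },
    somers_d = if (pc$n_0 == pc$n_1) NA_real_
               else (pc$n_c - pc$n_d) / (pc$n_0 - pc$n_1),
    gk_tau = 2 * (pc$n_c - pc$n_d) / pc$n_0,
    gk_gamma = if (pc$n_c + pc$n_d == 0) NA_real_
               else (pc$n_c - pc$n_d) / (pc$n_c + pc$n_d),
    theil_u = {
      tab <- table(x, y); n <- sum(tab)
      hx <- oracle_entropy(rowSums(tab) / n)
      if (hx == 0) return(NA_real_)
      hxy <- 0
      for (j in seq_len(ncol(tab)))
        if (sum(tab[, j]) > 0)
          hxy <- hxy + sum(tab[, j]) / n *
            oracle_entropy(tab[, j] / sum(tab[, j]))
      (hx - hxy) / hx
    })
}

# random ordinal vector with ties
random_ordinal <- function(n, levels = sample(2:6, 1)) {
  sample.int(levels, n, replace = TRUE)
}

# textbook NIPALS PLS1 with covariance weights, centered + scaled data;
# written from the algorithm statement, independent of the package path
oracle_nipals <- function(Z, y, C) {
  Z <- scale(Z); y0 <- y - mean(y)
  n <- nrow(Z); p <- ncol(Z)
  W <- P <- matrix(0, p, C); Tm <- matrix(0, n, C); q <- numeric(C)
  for (c in seq_len(C)) {
    w <- drop(crossprod(Z, y0)); w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    t <- drop(Z %*% w); tt <- sum(t * t)
    pl <- drop(crossprod(Z, t)) / tt
    qc <- sum(y0 * t) / tt
    Z <- Z - tcrossprod(t, pl); y0 <- y0 - t * qc
    W[, c] <- w; P[, c] <- pl; Tm[, c] <- t; q[c] <- qc
  }
  beta <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, P = P, T = Tm, q = q, beta_std = beta)
}

# OLS by the normal equations
oracle_ols <- function(Z, y) {
  X <- cbind(1, Z)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# brute-force leave-one-out LDA (pooled covariance, proportional priors)
oracle_loocv_lda <- function(X, g) {
  X <- as.matrix(X); n <- nrow(X); correct <- 0
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; gi <- g[-i]
    cl <- sort(unique(gi)); C <- ncol(Xi)
    Sw <- matrix(0, C, C); mu <- list(); pri <- numeric(length(cl))
    for (k in seq_along(cl)) {
      Xk <- Xi[gi == cl[k], , drop = FALSE]
      mu[[k]] <- colMeans(Xk); pri[k] <- nrow(Xk) / nrow(Xi)
      Sw <- Sw + crossprod(sweep(Xk, 2, mu[[k]], "-"))
    }
    Sw <- Sw / (nrow(Xi) - length(cl))
    if (rcond(Sw) < 1e-12)
      Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / C + 1e-12, C)
    d <- vapply(seq_along(cl), function(k)
      drop(X[i, ] %*% solve(Sw, mu[[k]])) -
        0.5 * drop(t(mu[[k]]) %*% solve(Sw, mu[[k]])) + log(pri[k]),
      numeric(1))
    if (cl[which.max(d)] == g[i]) correct <- correct + 1
  }
  correct / n
}

# small dataset builder for fit tests
tiny_dataset <- function(n = 40, p = 5, seed = 1) {
  set.seed(seed)
  Z <- matrix(sample.int(4, n * p, replace = TRUE), n, p)
  y <- pmin(3, pmax(1, round(1 + Z[, 1] * 0.4 + rnorm(n, 0, 0.8))))
  if (length(unique(y)) < 2) y[1:2] <- c(1, 3)
  ranked_dataset(Z, y, quiet = TRUE)
}
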