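# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force Euclidean distance transform: per-pixel minimum over all
# source pixels (centre-to-centre), O(n^2) -- only for small grids.
brute_force_edt <- function(source, px = 1) {
  src <- which(source != 0, arr.ind = TRUE)
  nr <- nrow(source); nc <- ncol(source)
  out <- matrix(Inf, nr, nc)
  if (nrow(src) == 0) return(out)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2)) * px
    }
  }
  out
}

# All-pairs AUC with half credit for ties.
all_pairs_auc <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# Kuiper one-sample test against a CDF; asymptotic p-value.
kuiper_test <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(x))
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  V <- dplus + dminus
  lam <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = V, p.value = max(0, min(1, p)))
}

# Dense joint-Gaussian smoother oracle for the integrated-OU movement model
# on one axis: builds the full prior covariance of the stacked states by
# composing the transition/process matrices, conditions on the observations,
# and returns the conditional mean/sd of the positions. Matrix formulas
# written independently of the package's sequential filter.
dense_gaussian_smoother <- function(beta, sigma, times, y_obs, tau2,
                                    prior_var = 1e10) {
  m <- length(times)
  d <- 2 * m
  pos <- function(k) 2 * k - 1
  first_obs <- which(!is.na(y_obs))[1]
  mu <- numeric(d)
  mu[pos(1)] <- y_obs[first_obs]
  C <- matrix(0, d, d)
  C[1:2, 1:2] <- diag(c(prior_var, sigma^2 / (2 * beta)))
  for (k in 2:m) {
    dt <- times[k] - times[k - 1]
    phi <- exp(-beta * dt)
    Tm <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
    q_vv <- sigma^2 * (1 - phi^2) / (2 * beta)
    q_pp <- sigma^2 / beta^2 *
      (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
    q_pv <- sigma^2 / (2 * beta^2) * (1 - phi)^2
    Q <- matrix(c(q_pp, q_pv, q_pv, q_vv), 2, 2)
    ia <- (2 * k - 3):(2 * k - 2)  # previous state block
    ib <- (2 * k - 1):(2 * k)      # current state block
    mu[ib] <- Tm %*% mu[ia]
    # cross-covariances with all earlier states
    for (j in 1:(k - 1)) {
      jj <- (2 * j - 1):(2 * j)
      C[ib, jj] <- Tm %*% C[ia, jj]
      C[jj, ib] <- t(C[ib, jj])
    }
    C[ib, ib] <- Tm %*% C[ia, ia] %*% t(Tm) + Q
  }
  oi <- which(!is.na(y_obs))
  H <- matrix(0, length(oi), d)
  for (r in seq_along(oi)) H[r, pos(oi[r])] <- 1
  R <- diag(tau2[oi], length(oi))
  S <- H %*% C %*% t(H) + R
  K <- C %*% t(H) %*% solve(S)
  mu_post <- mu + K %*% (y_obs[oi] - H %*% mu)
  C_post <- C - K %*% H %*% C
  list(mean = mu_post[seq(1, d, 2)], sd = sqrt(pmax(diag(C_post)[seq(1, d, 2)], 0)))
}

# Exact simulation from the integrated-OU model on one axis (own arithmetic).
sim_iou_axis <- function(beta, sigma, times, x0 = 0, v0 = NULL) {
  m <- length(times)
  p <- numeric(m); v <- numeric(m)
  p[1] <- x0
  v[1] <- if (is.null(v0)) stats::rnorm(1, 0, sigma / sqrt(2 * beta)) else v0
  for (k in 2:m) {
    dt <- times[k] - times[k - 1]
    phi <- exp(-beta * dt)
    q_vv <- sigma^2 * (1 - phi^2) / (2 * beta)
    q_pp <- sigma^2 / beta^2 *
      (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
    q_pv <- sigma^2 / (2 * beta^2) * (1 - phi)^2
    Q <- matrix(c(q_pp, q_pv, q_pv, q_vv), 2, 2)
    L <- t(chol(Q + diag(1e-12, 2)))
    w <- L %*% stats::rnorm(2)
    p[k] <- p[k - 1] + v[k - 1] * (1 - phi) / beta + w[1]
    v[k] <- v[k - 1] * phi + w[2]
  }
  list(p = p, v = v)
}
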