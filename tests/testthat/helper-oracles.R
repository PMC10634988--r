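# Independent oracles used to verify the package's numerics. Each is a
# deliberately naive implementation sharing no code with the package paths
# it checks.

# Cox-de Boor recursion for a single B-spline basis function B_{k,ord}(t)
# on knot vector tau (1-based k). Right-continuous convention; valid at
# interior points.
cdb_basis <- function(t, tau, k, ord) {
  if (ord == 1L) {
    return(as.numeric(tau[k] <= t && t < tau[k + 1L]))
  }
  d1 <- tau[k + ord - 1L] - tau[k]
  d2 <- tau[k + ord] - tau[k + 1L]
  a <- if (d1 > 0) (t - tau[k]) / d1 * cdb_basis(t, tau, k, ord - 1L) else 0
  b <- if (d2 > 0) (tau[k + ord] - t) / d2 *
    cdb_basis(t, tau, k + 1L, ord - 1L) else 0
  a + b
}

# analytic first derivative of a cubic B-spline curve sum_k beta_k B_{k,4}
# via the degree-lowering formula
bspline_deriv_oracle <- function(t, tau, beta) {
  K <- length(beta)
  vapply(t, function(tt) {
    s <- 0
    for (k in seq_len(K)) {
      d1 <- tau[k + 3L] - tau[k]
      d2 <- tau[k + 4L] - tau[k + 1L]
      der <- 0
      if (d1 > 0) der <- der + 3 * cdb_basis(tt, tau, k, 3L) / d1
      if (d2 > 0) der <- der - 3 * cdb_basis(tt, tau, k + 1L, 3L) / d2
      s <- s + beta[k] * der
    }
    s
  }, numeric(1))
}

# negative-binomial log-likelihood as a plain function of stacked
# parameters (coefficients, log phi), for black-box optimization
nb_objective <- function(par, y, X, off) {
  coefs <- par[-length(par)]
  phi <- exp(par[length(par)])
  mu <- exp(drop(X %*% coefs) + off)
  -sum(dnbinom(y, size = phi, mu = mu, log = TRUE))
}

# dense-loop multiplicative KL-factorization with an edge-support mask:
# Y_gi ~ Poisson(N_i sum_t beta_tg a_ti), blockwise beta-then-a updates,
# same stopping rule as the package EM. Written with explicit loops.
kl_nmf_oracle <- function(Y, N, support, beta0, a0, tol = 1e-8,
                          max_iter = 500L) {
  beta <- beta0; A <- a0
  Tn <- nrow(beta); G <- ncol(beta); n <- ncol(A)
  loglik <- function(beta, A) {
    ll <- 0
    for (g in seq_len(G)) for (i in seq_len(n)) {
      lam <- N[i] * sum(beta[, g] * A[, i])
      ll <- ll + dpois(Y[g, i], max(lam, 1e-300), log = TRUE)
    }
    ll
  }
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    M <- matrix(0, G, n)
    for (g in seq_len(G)) for (i in seq_len(n)) {
      M[g, i] <- sum(beta[, g] * A[, i])
    }
    beta_new <- beta
    for (t_ in seq_len(Tn)) for (g in seq_len(G)) {
      if (!support[t_, g]) next
      num <- 0
      for (i in seq_len(n)) {
        if (Y[g, i] > 0) num <- num + Y[g, i] * A[t_, i] / max(M[g, i], 1e-12)
      }
      den <- max(sum(N * A[t_, ]), 1e-12)
      beta_new[t_, g] <- beta[t_, g] * num / den
    }
    beta <- beta_new
    for (g in seq_len(G)) for (i in seq_len(n)) {
      M[g, i] <- sum(beta[, g] * A[, i])
    }
    A_new <- A
    for (t_ in seq_len(Tn)) for (i in seq_len(n)) {
      num <- 0
      for (g in seq_len(G)) {
        if (Y[g, i] > 0) num <- num + Y[g, i] * beta[t_, g] /
            max(M[g, i], 1e-12)
      }
      A_new[t_, i] <- A[t_, i] * num / (N[i] * max(sum(beta[t_, ]), 1e-12))
    }
    A <- A_new
    ll <- loglik(beta, A)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(beta = beta, A = A, loglik = ll, trace = trace)
}

# exact hypergeometric upper tail P(X >= ov) by enumerating the pmf with
# binomial coefficients
hyper_tail_oracle <- function(ov, N, m, k) {
  xs <- ov:min(m, k)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# Benjamini-Hochberg step-up by the textbook formula
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# adjusted Rand index between two label vectors (contingency formula)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  sij <- s(tab); si <- s(rowSums(tab)); sj <- s(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
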