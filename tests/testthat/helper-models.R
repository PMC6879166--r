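# shared fixtures: tiny models and independent oracles

toy_disc <- function(t = 2) time_discretization(t)

toy_kernel <- function(t = 2, k = 2, rho0 = 0.01, alpha = 0.7, delta = 0.2) {
  build_kernel(time_discretization(t), rho_prior(rho0, alpha, delta, k))
}

# exhaustive path-sum likelihood and posteriors for small HMMs
brute_force_hmm <- function(obs, kernel, emissions) {
  n <- kernel$t * kernel$k
  em <- do.call(rbind, rep(list(emissions), kernel$k))
  L <- obs$L
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  lik <- 0
  post <- matrix(0, L, n)
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    p <- kernel$stationary[z[1]] * em[z[1], obs$codes[1] + 1]
    if (L > 1) for (i in 2:L)
      p <- p * kernel$q_mod[z[i - 1], z[i]] * em[z[i], obs$codes[i] + 1]
    lik <- lik + p
    for (i in seq_len(L)) post[i, z[i]] <- post[i, z[i]] + p
  }
  list(loglik = unname(log(lik)), posterior = post / lik)
}

# Monte-Carlo single-step SMC' transition oracle under constant lambda = 1:
# sample s from the prior restricted to interval i, Bernoulli recombination,
# uniform breakpoint, competing exponential re-coalescence with
# back-coalescence, then discretise the new TMRCA
mc_smc_row <- function(disc, i, rho, n_draws, seed) {
  set.seed(seed)
  a <- disc$boundaries[i]; b <- disc$boundaries[i + 1]
  u <- runif(n_draws)
  Fa <- 1 - exp(-a); Fb <- if (is.finite(b)) 1 - exp(-b) else 1
  s <- -log(1 - (Fa + u * (Fb - Fa)))
  rec <- runif(n_draws) < -expm1(-rho * s)
  bp <- runif(n_draws) * s
  e <- rexp(n_draws)
  new_t <- s
  inwin <- rec & (e < 2 * (s - bp))
  back <- runif(n_draws) < 0.5
  tc <- bp + e / 2
  sel <- inwin & !back
  new_t[sel] <- tc[sel]
  above <- rec & !inwin
  new_t[above] <- s[above] + (e[above] - 2 * (s[above] - bp[above]))
  emp <- tabulate(findInterval(new_t, disc$boundaries), disc$t) / n_draws
  se <- sqrt(emp * (1 - emp) / n_draws)
  list(p = emp, se = se)
}

# quadrature oracle for the mean of Gamma(alpha, alpha) inside quantile slices
quad_gamma_means <- function(alpha, k) {
  q <- c(0, stats::qgamma(seq_len(k - 1) / k, alpha, rate = alpha), Inf)
  vapply(seq_len(k), function(l) {
    k * stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                         q[l], q[l + 1], rel.tol = 1e-10)$value
  }, numeric(1))
}
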