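test_that("AIC bookkeeping and homogeneous-model invariances hold", {
  kern <- toy_kernel(t = 4, k = 1, rho0 = 0.003)
  em <- emission_matrix(0.002, kern$disc)
  sim <- sim_hmm_path(kern, em, 5e4, seed = 2)
  fit1 <- rhomap_fit(sim$obs, t = 4, k = 1)
  expect_equal(fit1$aic, 2 * fit1$n_params - 2 * fit1$loglik, tolerance = 1e-9)
  expect_identical(fit1$n_params, 1L)
  # alpha and delta do not enter the k = 1 likelihood
  d <- time_discretization(4)
  for (al in c(0.3, 2)) {
    kk <- build_kernel(d, rho_prior(fit1$prior$rho0, alpha = al,
                                    delta = 0.3, k = 1))
    expect_equal(forward_loglik(sim$obs, kk, fit1$emissions), fit1$loglik,
                 tolerance = 1e-9)
  }
  fit5 <- rhomap_fit(sim$obs, t = 4, k = 5, init = fit1,
                     control = list(max_eval = 60))
  expect_identical(fit5$n_params, fit1$n_params + 2L)
  sel <- select_model(fit1, fit5)
  expect_equal(sel$delta_aic, fit1$aic - fit5$aic)
  expect_equal(sel$delta_aic,
               2 * (fit5$loglik - fit1$loglik) - 2 * (fit5$n_params - fit1$n_params))
})

test_that("fitting is deterministic and refitting from the optimum is a near fixed point", {
  kern <- toy_kernel(t = 4, k = 2, rho0 = 0.002, alpha = 0.8, delta = 1e-3)
  em <- emission_matrix(0.002, kern$disc)
  sim <- sim_hmm_path(kern, em, 1e5, seed = 9)
  f1 <- rhomap_fit(sim$obs, 4, 2, control = list(max_eval = 80))
  f2 <- rhomap_fit(sim$obs, 4, 2, control = list(max_eval = 80))
  expect_identical(f1$prior$rho0, f2$prior$rho0)
  expect_identical(f1$loglik, f2$loglik)
  # at full convergence settings the optimum is a fixed point of refitting
  ctl <- list(max_eval = 400, maxit = 12, rel_tol = 1e-8, line_tol = 0.01)
  f1t <- rhomap_fit(sim$obs, 4, 2, control = ctl)
  f3 <- rhomap_fit(sim$obs, 4, 2, init = f1t, control = ctl)
  expect_lt(abs(f3$loglik - f1t$loglik), 1e-3)
})

test_that("maximum-likelihood recovery on a generative-model simulation at 10 Mb", {
  # exact model twin at full-identifiability scale: the rate landscape holds
  # ~100 category dwells, enough to pin down the prior parameters
  disc <- time_discretization(10)
  prior <- rho_prior(0.0012, 0.5, 1e-5, 5)
  kern <- build_kernel(disc, prior)
  em <- emission_matrix(0.003, disc)
  sim <- sim_hmm_path(kern, em, 1e7, seed = 1)
  fit <- rhomap_fit(sim$obs, t = 10, k = 5, control = list(max_eval = 100))
  expect_lt(abs(fit$prior$rho0 / 0.0012 - 1), 0.2)
  expect_lt(abs(log2(fit$prior$alpha / 0.5)), 1)
  expect_lt(abs(log10(fit$prior$delta / 1e-5)), 1)
})

test_that("model selection prefers parsimony on ties and flags mismatched data", {
  kern <- toy_kernel(t = 3, k = 1)
  em <- emission_matrix(0.01, kern$disc)
  sim <- sim_hmm_path(kern, em, 2e4, seed = 4)
  f1 <- rhomap_fit(sim$obs, 3, 1)
  fake_het <- f1
  fake_het$k <- 5L
  fake_het$n_params <- 3L
  fake_het$aic <- 2 * 3 - 2 * f1$loglik    # equal logL, more parameters
  expect_identical(select_model(f1, fake_het)$choice, "homogeneous")
  sim2 <- sim_hmm_path(kern, em, 2e4, seed = 5)
  f2 <- rhomap_fit(sim2$obs, 3, 1)
  expect_error(select_model(f1, f2), "same data")
})

test_that("fixed-prior decoding stores external values verbatim and matches an equivalent fit", {
  kern <- toy_kernel(t = 5, k = 1, rho0 = 0.002)
  em <- emission_matrix(0.003, kern$disc)
  sim <- sim_hmm_path(kern, em, 1e5, seed = 6)
  f1 <- rhomap_fit(sim$obs, 5, 1)
  fx <- decode_with_fixed_prior(sim$obs, f1, rho0 = 0.00015, alpha = 0.5,
                                delta = 0.000025, k = 10)
  expect_equal(fx$prior$rho0, 0.00015)
  expect_equal(fx$prior$alpha, 0.5)
  expect_equal(fx$prior$delta, 0.000025)
  expect_identical(fx$k, 10L)
  # identical model parameters => identical posteriors
  mod <- rhomap:::assemble_model(5, 10, 0.00015, 0.5, 0.000025, fx$theta,
                                 f1$demography)
  pf1 <- posterior_decode(sim$obs, fx$kernel, fx$emissions)
  pf2 <- posterior_decode(sim$obs, mod$kernel, mod$emissions)
  expect_equal(pf1$loglik, pf2$loglik, tolerance = 1e-10)
  expect_equal(pf1$cat_marginal[1:100, ], pf2$cat_marginal[1:100, ],
               tolerance = 1e-12)
  expect_error(decode_with_fixed_prior(sim$obs, fx, 0.001, 0.5, 1e-5),
               "k = 1")
})

test_that("fixed-prior decoding beats a joint fit when missing data is heavy", {
  land <- sim_rho_landscape(0.5, 5e4, 1e6, 0.0012, seed = 31)
  sim <- sim_smc_sequence(landscape = land, theta = 0.003, seed = 32)
  codes <- sim$obs$codes
  set.seed(33)                      # ~40% missing in long blocks
  nblock <- 160
  starts <- sample.int(length(codes) - 5000, nblock)
  for (s in starts) codes[s:(s + 2500)] <- 2L
  obs_miss <- observed_sequence(codes)
  expect_gt(mean(obs_miss$codes == 2L), 0.3)
  f1 <- rhomap_fit(obs_miss, 8, 1)
  joint <- rhomap_fit(obs_miss, 8, 5, init = f1,
                      control = list(max_eval = 25))  # starved, unconverged fit
  fx <- decode_with_fixed_prior(obs_miss, f1, 0.0012, 0.5, 1e-5, k = 5)
  truth <- bin_map(sim$rho, 5e4)
  r2_of <- function(fit) {
    pf <- rhomap_decode(obs_miss, fit)
    m <- posterior_mean_rho(pf, fit$prior, missing = obs_miss$codes == 2L)
    compare_r2(bin_map(m, 5e4), truth, bootstrap = 0)$r2
  }
  expect_gt(r2_of(fx), 0)
  expect_gte(r2_of(fx), r2_of(joint) - 0.05)
})
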