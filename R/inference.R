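# Maximum-likelihood fitting of the modulated SMC' model.
#
# Free parameters (all optimised on transformed scales):
#   log(rho0)                  genome-wide recombination rate
#   log(delta / (1 - delta))   category switch probability   (k > 1 only)
#   log(alpha)                 Gamma shape of the rate prior (k > 1 only)
#   knot log-rates (5)         spline demography             (optional)
# theta is fixed beforehand from global heterozygosity.

rm_box <- list(rho0 = c(1e-6, 0.1), delta = c(1e-8, 0.5), alpha = c(0.05, 20),
               log_lambda = c(-8, 8))

# classical Powell direction-set minimiser; line searches by stats::optimize
powell_minimize <- function(fn, x0, step = rep(1, length(x0)), maxit = 8,
                            rel_tol = 1e-4, par_tol = 1e-3, line_tol = 0.05,
                            max_eval = 400) {
  np <- length(x0)
  evals <- 0L
  wrapped <- function(x) {
    evals <<- evals + 1L
    if (evals > max_eval) return(NA_real_)
    fn(x)
  }
  dirs <- diag(np) * step
  x <- x0
  fx <- wrapped(x)
  if (!is.finite(fx)) stop("non-finite objective at the initial point")
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    x_start <- x; f_start <- fx
    biggest_drop <- 0; biggest_dir <- 1L
    for (d in seq_len(np)) {
      dir <- dirs[, d]
      g <- function(a) {
        v <- wrapped(x + a * dir)
        if (is.na(v)) 1e12 else v
      }
      opt <- stats::optimize(g, interval = c(-2, 2), tol = line_tol)
      if (opt$objective < fx) {
        drop <- fx - opt$objective
        if (drop > biggest_drop) { biggest_drop <- drop; biggest_dir <- d }
        x <- x + opt$minimum * dir
        fx <- opt$objective
      }
      if (evals > max_eval) break
    }
    # extrapolated direction x - x_start replaces the most productive one
    newdir <- x - x_start
    if (evals <= max_eval && sqrt(sum(newdir^2)) > 1e-10) {
      g <- function(a) {
        v <- wrapped(x + a * newdir)
        if (is.na(v)) 1e12 else v
      }
      opt <- stats::optimize(g, interval = c(-1, 2), tol = line_tol)
      if (opt$objective < fx) {
        x <- x + opt$minimum * newdir
        fx <- opt$objective
        dirs[, biggest_dir] <- newdir
      }
    }
    # periodically reset the direction set to the scaled axes; replacing
    # directions can otherwise make the set near-degenerate and park the
    # search short of the optimum
    if (it %% np == 0) dirs <- diag(np) * step
    move <- max(abs(x - x_start))
    if (2 * abs(f_start - fx) <= rel_tol * (abs(f_start) + abs(fx) + 1e-10) ||
        move < par_tol) {
      converged <- TRUE
      break
    }
    if (evals > max_eval) break
  }
  list(par = x, value = fx, iterations = it, evaluations = evals,
       converged = converged)
}

# build all model pieces for one parameter set
assemble_model <- function(t, k, rho0, alpha, delta, theta, demography,
                           s_nodes = 5, u_nodes = 5, step_table = NULL,
                           rate_from = "source") {
  disc <- time_discretization(t, demography)
  prior <- rho_prior(rho0 = rho0, alpha = alpha, delta = delta, k = k)
  kern <- build_kernel(disc, prior, s_nodes = s_nodes, u_nodes = u_nodes,
                       rate_from = rate_from, step_table = step_table)
  list(disc = disc, prior = prior, kernel = kern,
       emissions = emission_matrix(theta, disc))
}

hash_obs <- function(obs) {
  idx <- as.double(seq_along(obs$codes))
  sprintf("%d-%d-%.0f", obs$L, sum(obs$codes),
          sum(as.double(obs$codes) * idx) %% 2147483647)
}

run_loglik <- function(runs, kernel, emissions) {
  em <- expand_emissions(emissions, kernel$k)
  rm_forward_runs_cpp(kernel$q_mod, em, kernel$stationary,
                      runs$symbol, runs$length, runs$contig_runs)
}

#' Fit the modulated SMC' model by maximum likelihood
#'
#' Two-step protocol: with `k = 1` the model is the homogeneous-rho null
#' (PSMC'-like) and only rho0 (plus, optionally, the spline demography) is
#' free; with `k > 1` a homogeneous fit is run first and used as a warm
#' start for the joint optimisation of rho0, delta and alpha.  The scaled
#' mutation rate theta is fixed beforehand from the global heterozygosity.
#' Optimisation uses Powell's direction-set method and is deterministic
#' given the data and initial values.
#'
#' @param obs an [rm_obs][observed_sequence].
#' @param t number of TMRCA intervals.
#' @param k number of recombination-rate categories.
#' @param fit_demography co-estimate a cubic-spline demography (5 knot
#'   log-rates); otherwise a constant population size is assumed.
#' @param init optional warm start: an `rm_fit` (typically the k = 1 fit on
#'   the same data) or a named list with any of `rho0`, `alpha`, `delta`,
#'   `knot_log_rates`.
#' @param control list of optimiser settings: `maxit` (Powell iterations,
#'   default 6), `max_eval` (default 250), `rel_tol` (1e-4), `par_tol`
#'   (1e-3), `line_tol` (0.05), `s_nodes`, `u_nodes` (quadrature, default 5).
#' @return an object of class `rm_fit`.
#' @export
rhomap_fit <- function(obs, t, k, fit_demography = FALSE, init = NULL,
                       control = list()) {
  stopifnot(inherits(obs, "rm_obs"))
  if (t * k > 400) stop("t * k exceeds the supported number of hidden states")
  ctl <- utils::modifyList(list(maxit = 6, max_eval = 250, rel_tol = 1e-4,
                                par_tol = 1e-3, line_tol = 0.05,
                                s_nodes = 5, u_nodes = 5), control)
  theta <- theta_from_heterozygosity(obs)
  runs <- compress_runs(obs)

  # warm start
  start <- list(rho0 = 1e-3, alpha = 1.0, delta = 1e-4,
                knot_log_rates = rep(0, 5))
  if (inherits(init, "rm_fit")) {
    start$rho0 <- init$prior$rho0
    if (init$k > 1) { start$alpha <- init$prior$alpha; start$delta <- init$prior$delta }
    if (!is.null(init$demography$spline))
      start$knot_log_rates <- init$demography$spline$knot_log_rates
  } else if (is.list(init)) {
    start <- utils::modifyList(start, init)
  } else if (k > 1 && is.null(init)) {
    pre <- rhomap_fit(obs, t, 1, fit_demography = fit_demography,
                      control = control)
    start$rho0 <- pre$prior$rho0
    if (!is.null(pre$demography$spline))
      start$knot_log_rates <- pre$demography$spline$knot_log_rates
  }

  par0 <- log(start$rho0)
  if (k > 1) par0 <- c(par0, log(start$delta / (1 - start$delta)), log(start$alpha))
  if (fit_demography) par0 <- c(par0, start$knot_log_rates)

  decode_par <- function(par) {
    rho0 <- exp(par[1])
    i <- 2L
    if (k > 1) {
      delta <- stats::plogis(par[2]); alpha <- exp(par[3]); i <- 4L
    } else { delta <- 0; alpha <- 1 }
    demog <- if (fit_demography) spline_demography(par[i:(i + 4)])
             else constant_demography()
    list(rho0 = rho0, delta = delta, alpha = alpha, demog = demog)
  }
  in_box <- function(p) {
    p$rho0 >= rm_box$rho0[1] && p$rho0 <= rm_box$rho0[2] &&
    p$delta >= 0 && p$delta <= rm_box$delta[2] &&
    p$alpha >= rm_box$alpha[1] && p$alpha <= rm_box$alpha[2]
  }

  fixed_table <- if (!fit_demography)
    smc_step_table(time_discretization(t, constant_demography()),
                   s_nodes = ctl$s_nodes, u_nodes = ctl$u_nodes) else NULL

  objective <- function(par) {
    p <- decode_par(par)
    if (!in_box(p) ||
        (fit_demography && any(abs(par[i_knots]) > rm_box$log_lambda[2])))
      return(1e10 + sum(par^2))
    mod <- tryCatch(
      assemble_model(t, k, p$rho0, p$alpha, p$delta, theta, p$demog,
                     s_nodes = ctl$s_nodes, u_nodes = ctl$u_nodes,
                     step_table = if (fit_demography) NULL else fixed_table),
      error = function(e) NULL)
    if (is.null(mod)) return(1e10)
    ll <- run_loglik(runs, mod$kernel, mod$emissions)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  i_knots <- if (fit_demography) (length(par0) - 4):length(par0) else integer(0)

  step <- rep(0.7, length(par0))
  if (k > 1) step[2] <- 1.5   # delta spans orders of magnitude
  opt <- powell_minimize(objective, par0, step = step, maxit = ctl$maxit,
                         rel_tol = ctl$rel_tol, par_tol = ctl$par_tol,
                         line_tol = ctl$line_tol, max_eval = ctl$max_eval)

  p <- decode_par(opt$par)
  mod <- assemble_model(t, k, p$rho0, p$alpha, p$delta, theta, p$demog,
                        s_nodes = ctl$s_nodes, u_nodes = ctl$u_nodes)
  n_params <- 1L + (k > 1) * 2L + fit_demography * 5L
  ll <- -opt$value
  structure(list(prior = mod$prior, demography = p$demog, theta = theta,
                 t = t, k = k, loglik = ll, n_params = n_params,
                 aic = 2 * n_params - 2 * ll,
                 convergence = list(iterations = opt$iterations,
                                    evaluations = opt$evaluations,
                                    converged = opt$converged),
                 disc = mod$disc, kernel = mod$kernel,
                 emissions = mod$emissions,
                 fit_demography = fit_demography,
                 data_hash = hash_obs(obs)),
            class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat("Modulated SMC' fit: t =", x$t, " k =", x$k,
      if (x$fit_demography) "(spline demography)" else "(constant demography)", "\n")
  cat("  rho0 =", signif(x$prior$rho0, 4), " alpha =", signif(x$prior$alpha, 4),
      " delta =", signif(x$prior$delta, 4), " theta =", signif(x$theta, 4), "\n")
  cat("  logL =", signif(x$loglik, 8), " params =", x$n_params,
      " AIC =", signif(x$aic, 8), "\n")
  cat("  converged:", x$convergence$converged,
      "(", x$convergence$evaluations, "evaluations )\n")
  invisible(x)
}

#' AIC model selection between homogeneous and heterogeneous fits
#'
#' @param fit_homogeneous the k = 1 fit.
#' @param fit_heterogeneous the k > 1 fit on the same data and t.
#' @return list with `choice` ("homogeneous"/"heterogeneous"), `best` (the
#'   winning `rm_fit`), and `delta_aic` = AIC(hom) - AIC(het), positive when
#'   the heterogeneous model is favoured.  Ties go to the homogeneous model.
#' @export
select_model <- function(fit_homogeneous, fit_heterogeneous) {
  stopifnot(inherits(fit_homogeneous, "rm_fit"), inherits(fit_heterogeneous, "rm_fit"))
  if (fit_homogeneous$data_hash != fit_heterogeneous$data_hash)
    stop("fits were not produced on the same data")
  if (fit_homogeneous$t != fit_heterogeneous$t)
    stop("fits use different time discretisations")
  d <- fit_homogeneous$aic - fit_heterogeneous$aic
  if (d > 0)
    list(choice = "heterogeneous", best = fit_heterogeneous, delta_aic = d)
  else
    list(choice = "homogeneous", best = fit_homogeneous, delta_aic = d)
}

#' Heterogeneous model from a homogeneous fit plus external prior values
#'
#' The decoding protocol for low-quality samples: demography (coalescence
#' rates) comes from a homogeneous (k = 1) fit to the sample itself, while
#' rho0, alpha and delta are supplied externally (e.g. estimates from
#' high-quality samples of the same species).  No optimisation is run; the
#' returned object is ready for posterior decoding.
#'
#' @param obs the observed sequence (used for theta and the final
#'   likelihood evaluation).
#' @param demography_fit an `rm_fit` with k = 1 produced on the same sample.
#' @param rho0,alpha,delta externally supplied prior parameters.
#' @param k number of rate categories of the assembled model.
#' @return an `rm_fit` (with `n_params = 0` and `fixed_prior = TRUE`).
#' @export
decode_with_fixed_prior <- function(obs, demography_fit, rho0, alpha, delta,
                                    k = 5) {
  stopifnot(inherits(obs, "rm_obs"), inherits(demography_fit, "rm_fit"))
  if (demography_fit$k != 1)
    stop("demography_fit must be a homogeneous (k = 1) fit")
  theta <- theta_from_heterozygosity(obs)
  k <- as.integer(k)
  mod <- assemble_model(demography_fit$t, k, rho0, alpha, delta, theta,
                        demography_fit$demography)
  runs <- compress_runs(obs)
  ll <- run_loglik(runs, mod$kernel, mod$emissions)
  structure(list(prior = mod$prior, demography = demography_fit$demography,
                 theta = theta, t = demography_fit$t, k = k, loglik = ll,
                 n_params = 0L, aic = -2 * ll,
                 convergence = list(iterations = 0L, evaluations = 1L,
                                    converged = TRUE),
                 disc = mod$disc, kernel = mod$kernel,
                 emissions = mod$emissions,
                 fit_demography = demography_fit$fit_demography,
                 fixed_prior = TRUE,
                 data_hash = hash_obs(obs)),
            class = "rm_fit")
}

#' Decode a fitted model into a posterior field
#'
#' Convenience wrapper running [posterior_decode()] with the kernel and
#' emissions stored in a fit.
#'
#' @param obs the observed sequence (same sample the fit was made on).
#' @param fit an `rm_fit`.
#' @param ... passed to [posterior_decode()].
#' @export
rhomap_decode <- function(obs, fit, ...) {
  stopifnot(inherits(fit, "rm_fit"))
  posterior_decode(obs, fit$kernel, fit$emissions, ...)
}
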