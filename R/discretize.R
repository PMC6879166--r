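#' Discretise the TMRCA distribution
#'
#' Splits scaled coalescence time into `t` intervals carrying equal prior
#' coalescent mass under the supplied demography, the standard device of
#' pairwise SMC implementations: each hidden genealogy state then has the
#' same prior weight, balancing the information carried per state.  The
#' representative time of an interval is the conditional prior mean TMRCA
#' within it; for the final (infinite) interval the mean is truncated at
#' five times the penultimate boundary so that emission probabilities stay
#' finite.
#'
#' @param t number of TMRCA intervals (>= 1).
#' @param demography an [rm_demography][constant_demography]; default is the
#'   constant rate-1 coalescent.
#' @return an object of class `rm_time_disc` with fields `t`, `boundaries`
#'   (length t+1, first 0, last Inf), `representative` (length t), `lambda`
#'   (hazard-preserving per-interval coalescence rates) and `mass` (prior
#'   mass per interval).
#' @examples
#' d <- time_discretization(2)
#' d$boundaries[2]      # log(2), the median of Exp(1)
#' d$representative     # c(1 - log(2), 1 + log(2))
#' @export
time_discretization <- function(t, demography = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != round(t))
    stop("t must be a single integer >= 1")
  t <- as.integer(t)
  if (is.null(demography)) demography <- constant_demography()
  stopifnot(inherits(demography, "rm_demography"))

  bounds <- c(0, prior_tmrca_quantile(demography, seq_len(t - 1L) / t), Inf)
  cap <- if (t >= 2) 5 * bounds[t] else 5
  rep_t <- vapply(seq_len(t), function(j) {
    a <- bounds[j]; b <- bounds[j + 1L]
    if (is.finite(b)) conditional_mean_tmrca(demography, a, b)
    else min(conditional_mean_tmrca(demography, a, Inf), cap)
  }, numeric(1))

  # hazard-preserving projection of the demography onto the intervals:
  # lambda_j reproduces the prior mass of every finite interval exactly
  H <- cum_hazard(demography, bounds[seq_len(t)])
  lam <- numeric(t)
  if (t >= 2) {
    lam[seq_len(t - 1L)] <- diff(H) / diff(bounds[seq_len(t)])
  }
  lam[t] <- demography$rates[findInterval(rep_t[t], demography$breaks)]

  mass <- rep(1 / t, t)
  structure(list(t = t, boundaries = bounds, representative = rep_t,
                 lambda = lam, mass = mass),
            class = "rm_time_disc")
}

#' @export
print.rm_time_disc <- function(x, ...) {
  cat("TMRCA discretisation:", x$t, "interval(s)\n")
  cat("  boundaries:", signif(utils::head(x$boundaries, 8), 3),
      if (x$t + 1 > 8) "..." else "", "\n")
  invisible(x)
}

# the interval-projected demography actually used by the transition kernel
disc_demography <- function(disc) {
  piecewise_demography(disc$boundaries[seq_len(disc$t)], disc$lambda)
}

#' Per-interval coalescence rates from a spline demography
#'
#' Evaluates the demography's rate function as piecewise-constant values on
#' the intervals of a TMRCA discretisation (hazard-preserving averages, so
#' the interval prior masses are those of the continuous demography).
#'
#' @param demography an `rm_demography`.
#' @param disc an `rm_time_disc` built under the same demography.
#' @return numeric vector of `disc$t` positive rates.
#' @export
spline_lambdas <- function(demography, disc) {
  stopifnot(inherits(demography, "rm_demography"), inherits(disc, "rm_time_disc"))
  d <- time_discretization(disc$t, demography)
  lam <- d$lambda
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("non-finite coalescence rates from spline demography")
  lam
}
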