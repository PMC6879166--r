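#' Demographic histories as piecewise-constant coalescence rates
#'
#' A demography is the scaled coalescence-rate function lambda(tau) of the
#' pairwise coalescent, with time tau measured in units of 2*Ne(0) generations
#' so that under a constant population size lambda = 1 and the prior TMRCA is
#' Exp(1).  A rate above 1 at some epoch means the population was smaller than
#' the reference size during that epoch (faster coalescence), and vice versa.
#'
#' Internally every demography is a step function: `breaks` are the epoch
#' start times (first is 0) and `rates` the coalescence rate within each
#' epoch, the last epoch extending to infinity.
#'
#' @param rate constant coalescence rate (default 1).
#' @return an object of class `rm_demography`.
#' @export
constant_demography <- function(rate = 1) {
  piecewise_demography(breaks = 0, rates = rate)
}

#' @rdname constant_demography
#' @param breaks increasing epoch start times, first must be 0.
#' @param rates positive coalescence rate per epoch (same length as `breaks`).
#' @export
piecewise_demography <- function(breaks, rates) {
  stopifnot(length(breaks) == length(rates), length(breaks) >= 1)
  if (breaks[1] != 0) stop("first epoch must start at time 0")
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
  if (any(!is.finite(rates)) || any(rates <= 0)) stop("rates must be positive and finite")
  structure(list(breaks = as.numeric(breaks), rates = as.numeric(rates)),
            class = "rm_demography")
}

#' Spline-parameterised demography
#'
#' Coalescence rates are controlled by a natural cubic spline through
#' (log time, log rate) knots: two endpoint knots plus three internal knots,
#' so the number of free parameters does not depend on the number of TMRCA
#' intervals used downstream.  The spline is evaluated on a fine log-spaced
#' time grid and frozen into a piecewise-constant rate function; outside the
#' knot span the rate is held at the endpoint values.
#'
#' @param knot_log_rates numeric vector of log coalescence rates at the knots
#'   (length `length(knot_times)`).
#' @param knot_times knot positions in scaled time (increasing, default spans
#'   the bulk of the coalescent prior with three internal knots).
#' @param grid_size number of grid epochs used to freeze the spline.
#' @return an `rm_demography` whose `spline` element records the knots.
#' @export
spline_demography <- function(knot_log_rates,
                              knot_times = c(0.02, 0.1, 0.5, 2.0, 8.0),
                              grid_size = 48) {
  stopifnot(length(knot_log_rates) == length(knot_times))
  if (any(!is.finite(knot_log_rates))) stop("non-finite spline parameters")
  lt <- log(knot_times)
  grid <- exp(seq(log(knot_times[1]), log(knot_times[length(knot_times)]),
                  length.out = grid_size))
  sp <- stats::spline(lt, knot_log_rates, xout = log(grid), method = "natural")
  lr <- sp$y
  if (any(!is.finite(lr))) stop("spline interpolation produced non-finite rates")
  # clamp to keep rates numerically sane over the full optimisation range
  lr <- pmin(pmax(lr, -12), 12)
  breaks <- c(0, grid)
  rates <- c(exp(lr[1]), exp(lr))
  d <- piecewise_demography(breaks, rates)
  d$spline <- list(knot_times = knot_times, knot_log_rates = knot_log_rates)
  d
}

#' @export
print.rm_demography <- function(x, ...) {
  cat("Demography:", length(x$rates), "epoch(s)\n")
  n <- min(length(x$rates), 6L)
  cat("  start times:", signif(x$breaks[seq_len(n)], 3),
      if (length(x$rates) > n) "..." else "", "\n")
  cat("  coal. rates:", signif(x$rates[seq_len(n)], 3),
      if (length(x$rates) > n) "..." else "", "\n")
  invisible(x)
}

# cumulative coalescent hazard H(t) = int_0^t lambda, vectorised over t
cum_hazard <- function(demog, t) {
  b <- demog$breaks; r <- demog$rates
  cumH <- c(0, cumsum(r[-length(r)] * diff(b)))
  i <- findInterval(t, b)
  cumH[i] + r[i] * (t - b[i])
}

# inverse of the cumulative hazard (quantile machinery), vectorised over h
inv_hazard <- function(demog, h) {
  b <- demog$breaks; r <- demog$rates
  cumH <- c(0, cumsum(r[-length(r)] * diff(b)))
  i <- findInterval(h, cumH)
  b[i] + (h - cumH[i]) / r[i]
}

# quantile of the prior TMRCA distribution: P(T <= q(p)) = p
prior_tmrca_quantile <- function(demog, p) {
  inv_hazard(demog, -log1p(-p))
}

# E[T | a <= T < b] under the demography's coalescent prior (b may be Inf,
# in which case the last epoch rate carries the tail).
conditional_mean_tmrca <- function(demog, a, b) {
  br <- demog$breaks; r <- demog$rates
  pts <- sort(unique(c(a, br[br > a & br < b], b)))
  num <- 0
  Ha <- cum_hazard(demog, a)
  for (i in seq_len(length(pts) - 1L)) {
    p <- pts[i]; q <- pts[i + 1L]
    lam <- r[findInterval(p, br)]
    Sp <- exp(-(cum_hazard(demog, p)))
    if (is.finite(q)) {
      num <- num + Sp * ((p + 1 / lam) - exp(-lam * (q - p)) * (q + 1 / lam))
    } else {
      num <- num + Sp * (p + 1 / lam)
    }
  }
  Sa <- exp(-cum_hazard(demog, a))
  Sb <- if (is.finite(b)) exp(-cum_hazard(demog, b)) else 0
  num / (Sa - Sb)
}
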