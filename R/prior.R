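#' Discretised Gamma prior on the local recombination rate
#'
#' Spatial variation in rho is modelled as a multiplicative landscape drawn
#' from a Gamma distribution with shape = rate = alpha (mean 1), discretised
#' into `k` categories of equal prior probability.  The local rate in
#' category l is `rho0 * r_l`, with `r_l` the conditional mean of the Gamma
#' distribution within its l-th equal-probability slice.  A per-site switch
#' probability `delta` drives a Markov chain over categories with uniform
#' off-diagonal transitions.
#'
#' @param alpha Gamma shape (= rate), > 0.
#' @param k number of categories (>= 1).
#' @return `rho_categories`: numeric vector of k increasing category means
#'   with equal-weight mean 1.
#' @examples
#' rho_categories(1, 2)   # c(1 - log(2), 1 + log(2)) for the exponential
#' @export
rho_categories <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive number")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  if (k == 1L) return(1.0)
  # mean of Gamma(alpha, alpha) between consecutive quantiles q_{l-1}, q_l:
  #   k * [ P(alpha+1, alpha*q_l) - P(alpha+1, alpha*q_{l-1}) ]
  # with P the regularised lower incomplete gamma (mean-preserving identity).
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  pg <- stats::pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  means <- k * diff(pg)
  means / mean(means)  # guard against last-digit drift; exact mean 1
}

#' @rdname rho_categories
#' @param delta per-site category switch probability in [0, 1).
#' @return `rho_transition`: the k x k category transition matrix with
#'   diagonal 1 - delta and off-diagonals delta / (k - 1).
#' @export
rho_transition <- function(delta, k) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta >= 1)
    stop("delta must lie in [0, 1)")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  if (k == 1L) return(matrix(1, 1, 1))
  m <- matrix(delta / (k - 1), k, k)
  diag(m) <- 1 - delta
  m
}

#' @rdname rho_categories
#' @param rho0 genome-wide average population recombination rate per site.
#' @return `rho_prior`: an object of class `rm_rho_prior` bundling alpha, k,
#'   the category means, delta and rho0.
#' @export
rho_prior <- function(rho0, alpha = 1, delta = 0, k = 1) {
  if (!is.numeric(rho0) || length(rho0) != 1L || !is.finite(rho0) || rho0 < 0)
    stop("rho0 must be a non-negative number")
  means <- rho_categories(alpha, k)
  structure(list(alpha = alpha, k = as.integer(k), category_means = means,
                 delta = delta, rho0 = rho0),
            class = "rm_rho_prior")
}

#' @export
print.rm_rho_prior <- function(x, ...) {
  cat("Recombination-rate prior: rho0 =", signif(x$rho0, 4),
      " alpha =", signif(x$alpha, 4), " delta =", signif(x$delta, 4),
      " k =", x$k, "\n")
  cat("  category means:", signif(x$category_means, 4), "\n")
  invisible(x)
}
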