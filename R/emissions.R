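#' Emission probabilities for a pair of genomes
#'
#' Under the infinite-sites model, a site whose genealogy has TMRCA tau
#' (scaled time, total branch length 2*tau) is heterozygous with probability
#' 1 - exp(-theta * tau), where theta = 4*Ne*mu is the scaled mutation rate.
#' Missing sites are uninformative: every hidden state emits them with
#' probability 1, so they contribute no likelihood signal but keep the chain
#' ticking over.
#'
#' @param theta scaled mutation rate per site (> 0).
#' @param disc an `rm_time_disc`; emissions are evaluated at the
#'   representative (conditional mean) time of each interval.
#' @return a t x 3 matrix with columns `hom`, `het`, `missing`.
#' @export
emission_matrix <- function(theta, disc) {
  stopifnot(inherits(disc, "rm_time_disc"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("theta must be a positive number")
  tau <- disc$representative
  het <- -expm1(-theta * tau)
  cbind(hom = 1 - het, het = het, missing = rep(1, disc$t))
}

#' Estimate theta from global heterozygosity
#'
#' theta is fixed ahead of model optimisation from the fraction h of
#' heterozygous calls among non-missing sites, via theta = -log(1 - h)
#' (inverting the emission probability at the mean scaled TMRCA of 1).
#'
#' @param obs an [rm_obs][observed_sequence].
#' @return a positive scalar.
#' @export
theta_from_heterozygosity <- function(obs) {
  stopifnot(inherits(obs, "rm_obs"))
  nonmiss <- sum(obs$codes != 2L)
  if (nonmiss == 0) stop("no informative sites: all data missing")
  h <- sum(obs$codes == 1L) / nonmiss
  if (h <= 0) stop("no heterozygous sites: theta cannot be estimated")
  -log1p(-h)
}
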