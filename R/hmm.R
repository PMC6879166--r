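#' Observed pairwise-difference sequence
#'
#' Per-site observation codes for a pair of aligned sequences: 0 =
#' homozygous (identical nucleotides), 1 = heterozygous (different), 2 =
#' missing.  Contigs (chromosomes) are half-open 0-based intervals covering
#' the sequence; the HMM is re-initialised at the stationary distribution at
#' every contig start, since genealogies are not continuous across contigs.
#'
#' @param codes integer vector with values in {0, 1, 2}.
#' @param contigs optional two-column matrix (start, end) of half-open
#'   0-based contig intervals; default one contig covering everything.
#' @param contig_names optional character vector of contig names.
#' @return an object of class `rm_obs`.
#' @export
observed_sequence <- function(codes, contigs = NULL, contig_names = NULL) {
  codes <- as.integer(codes)
  if (length(codes) == 0) stop("empty sequence")
  if (any(is.na(codes)) || any(codes < 0L | codes > 2L))
    stop("codes must be 0 (hom), 1 (het) or 2 (missing)")
  L <- length(codes)
  if (is.null(contigs)) contigs <- matrix(c(0, L), 1, 2)
  contigs <- matrix(as.integer(contigs), ncol = 2)
  o <- order(contigs[, 1])
  contigs <- contigs[o, , drop = FALSE]
  if (contigs[1, 1] != 0L || contigs[nrow(contigs), 2] != L ||
      any(contigs[, 2] <= contigs[, 1]) ||
      (nrow(contigs) > 1 && any(contigs[-1, 1] != contigs[-nrow(contigs), 2])))
    stop("contigs must be disjoint, sorted and cover [0, L)")
  if (is.null(contig_names)) contig_names <- paste0("contig", seq_len(nrow(contigs)))
  structure(list(codes = codes, L = L, contigs = contigs,
                 contig_names = contig_names[o]),
            class = "rm_obs")
}

#' @export
print.rm_obs <- function(x, ...) {
  nm <- sum(x$codes == 2L)
  cat("Observed sequence:", x$L, "sites,", nrow(x$contigs), "contig(s),",
      sum(x$codes == 1L), "het,", sprintf("%.1f%%", 100 * nm / x$L), "missing\n")
  invisible(x)
}

#' Run-length compression of an observed sequence
#'
#' Maximal runs of identical observation symbols, the unit over which the
#' likelihood recursions advance using cached matrix powers (the role played
#' by block compression in zipHMM-style implementations).  Runs never span
#' contig boundaries.
#'
#' @param obs an `rm_obs`.
#' @return a list with `symbol`, `length` (per run) and `contig_runs`
#'   (number of runs per contig).
#' @export
compress_runs <- function(obs) {
  stopifnot(inherits(obs, "rm_obs"))
  sym <- integer(0); len <- integer(0); nrun <- integer(nrow(obs$contigs))
  for (ci in seq_len(nrow(obs$contigs))) {
    r <- rle(obs$codes[(obs$contigs[ci, 1] + 1L):obs$contigs[ci, 2]])
    sym <- c(sym, r$values); len <- c(len, r$lengths)
    nrun[ci] <- length(r$values)
  }
  list(symbol = sym, length = len, contig_runs = nrun)
}

# expand a t x 3 emission matrix to the n = t*k hidden states (category-major)
expand_emissions <- function(emissions, k) {
  do.call(rbind, rep(list(emissions), k))
}

#' Forward log-likelihood of the modulated HMM
#'
#' Scaled forward recursion over the n = t*k hidden states, starting from
#' the kernel's stationary distribution and re-initialised at each contig.
#' By default the recursion runs over run-length compressed input using
#' cached binary powers of the per-symbol update matrices, which is exact
#' up to floating point and orders of magnitude faster on realistic
#' (mutation-sparse) data.
#'
#' @param obs an `rm_obs`.
#' @param kernel an [rm_kernel][build_kernel].
#' @param emissions a t x 3 emission matrix from [emission_matrix()].
#' @param compressed use the run-length path (default TRUE).
#' @return the log-likelihood (scalar).
#' @export
forward_loglik <- function(obs, kernel, emissions, compressed = TRUE) {
  stopifnot(inherits(obs, "rm_obs"), inherits(kernel, "rm_kernel"))
  if (nrow(emissions) != kernel$t) stop("emissions do not match the discretisation")
  em <- expand_emissions(emissions, kernel$k)
  if (compressed) {
    runs <- compress_runs(obs)
    ll <- rm_forward_runs_cpp(kernel$q_mod, em, kernel$stationary,
                              runs$symbol, runs$length, runs$contig_runs)
  } else {
    ll <- 0
    for (ci in seq_len(nrow(obs$contigs))) {
      codes <- obs$codes[(obs$contigs[ci, 1] + 1L):obs$contigs[ci, 2]]
      ll <- ll + rm_forward_cpp(kernel$q_mod, em, kernel$stationary, codes)
    }
  }
  if (!is.finite(ll)) stop("zero total probability in forward recursion")
  ll
}

#' Posterior decoding of the modulated HMM
#'
#' Forward-backward smoothing of the per-site joint posterior over
#' {category, TMRCA interval} pairs.  To bound memory the full joint is only
#' materialised for small problems; what is always returned are the per-site
#' category marginals (enough for posterior-mean rho), the per-site MAP
#' TMRCA interval (marginalised over categories) and the category posterior
#' conditional on that interval (enough for time-restricted decoding).
#'
#' @inheritParams forward_loglik
#' @param keep_joint materialise the full L x n joint posterior (forced off
#'   when L * n exceeds `joint_limit`).
#' @param joint_limit size guard for the joint posterior.
#' @return an object of class `rm_field` with elements `cat_marginal`
#'   (L x k), `map_interval` (length L, 1-based), `cat_at_map` (L x k),
#'   `map_mass` (posterior mass of the MAP interval), `loglik`, and
#'   optionally `joint` (L x n, category-major columns).
#' @export
posterior_decode <- function(obs, kernel, emissions, keep_joint = FALSE,
                             joint_limit = 2e6) {
  stopifnot(inherits(obs, "rm_obs"), inherits(kernel, "rm_kernel"))
  if (nrow(emissions) != kernel$t) stop("emissions do not match the discretisation")
  n <- kernel$t * kernel$k
  keep_joint <- keep_joint && (as.double(obs$L) * n <= joint_limit)
  L <- obs$L
  cat_marg <- matrix(0, L, kernel$k)
  map_int <- integer(L)
  cat_at_map <- matrix(0, L, kernel$k)
  map_mass <- numeric(L)
  joint <- if (keep_joint) matrix(0, L, n) else NULL
  ll <- 0
  for (ci in seq_len(nrow(obs$contigs))) {
    idx <- (obs$contigs[ci, 1] + 1L):obs$contigs[ci, 2]
    res <- rm_posterior_cpp(kernel$q_smc_by_category, kernel$prior$delta,
                            emissions, kernel$stationary,
                            obs$codes[idx], kernel$t, kernel$k, keep_joint)
    ll <- ll + res$loglik
    cat_marg[idx, ] <- res$cat_marginal
    map_int[idx] <- res$map_interval
    cat_at_map[idx, ] <- res$cat_at_map
    map_mass[idx] <- res$map_mass
    if (keep_joint) joint[idx, ] <- res$joint
  }
  if (!is.finite(ll)) stop("zero total probability in forward recursion")
  structure(list(cat_marginal = cat_marg, map_interval = map_int,
                 cat_at_map = cat_at_map, map_mass = map_mass,
                 loglik = ll, joint = joint, t = kernel$t, k = kernel$k,
                 contigs = obs$contigs),
            class = "rm_field")
}

#' @export
print.rm_field <- function(x, ...) {
  cat("Posterior field:", nrow(x$cat_marginal), "sites,", x$k,
      "categories x", x$t, "intervals; logL =", signif(x$loglik, 8), "\n")
  invisible(x)
}
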