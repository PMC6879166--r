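#' Piecewise-constant rate landscapes
#'
#' Generates the multiplicative landscapes of the simulation designs:
#' segment scale factors drawn i.i.d. from a Gamma(alpha, rate = alpha)
#' distribution (mean 1) for recombination, or from a bounded uniform for
#' mutation, with segment lengths geometric with mean `g` (minimum 1 bp,
#' truncated at the sequence end).
#'
#' @param alpha Gamma shape (= rate) of the scale distribution.
#' @param g mean segment length in bases.
#' @param L sequence length.
#' @param rho0 base (genome-wide average) rate the scales multiply.
#' @param seed RNG seed; landscapes regenerate bit-exactly from it.
#' @return an object of class `rm_landscape`: data.frame `segments`
#'   (start, end, scale) tiling [0, L), plus the base rate and generator
#'   spec.
#' @export
sim_rho_landscape <- function(alpha, g, L, rho0, seed = 1L) {
  stopifnot(alpha > 0, g >= 1, L >= 1)
  segs <- local({
    set.seed(seed)
    n_guess <- max(16L, ceiling(2.5 * L / g))
    len <- stats::rgeom(n_guess, prob = 1 / g) + 1
    while (sum(len) < L)
      len <- c(len, stats::rgeom(n_guess, prob = 1 / g) + 1)
    len <- len[seq_len(which(cumsum(len) >= L)[1])]
    scale <- stats::rgamma(length(len), shape = alpha, rate = alpha)
    ends <- pmin(cumsum(len), L)
    data.frame(start = c(0, ends[-length(ends)]), end = ends, scale = scale)
  })
  structure(list(segments = segs, base = rho0, L = as.integer(L), seed = seed,
                 spec = list(kind = "gamma", alpha = alpha, g = g)),
            class = "rm_landscape")
}

#' @rdname sim_rho_landscape
#' @param lo,hi bounds of the uniform scale distribution (default 0.1 and
#'   10; note the mean is then 5.05, not 1, so the realised genome-wide
#'   average rate is 5.05 * theta0).
#' @param f mean segment length of the mutation landscape.
#' @param theta0 base scaled mutation rate.
#' @export
sim_theta_landscape <- function(f, L, theta0, lo = 0.1, hi = 10.0, seed = 1L) {
  stopifnot(lo < hi, f >= 1, L >= 1)
  segs <- local({
    set.seed(seed + 1000003L)
    n_guess <- max(16L, ceiling(2.5 * L / f))
    len <- stats::rgeom(n_guess, prob = 1 / f) + 1
    while (sum(len) < L)
      len <- c(len, stats::rgeom(n_guess, prob = 1 / f) + 1)
    len <- len[seq_len(which(cumsum(len) >= L)[1])]
    scale <- stats::runif(length(len), lo, hi)
    ends <- pmin(cumsum(len), L)
    data.frame(start = c(0, ends[-length(ends)]), end = ends, scale = scale)
  })
  structure(list(segments = segs, base = theta0, L = as.integer(L), seed = seed,
                 spec = list(kind = "uniform", lo = lo, hi = hi, f = f)),
            class = "rm_landscape")
}

#' Per-site rates of a landscape
#' @param landscape an `rm_landscape`.
#' @return numeric vector of length L with base * scale at every site.
#' @export
landscape_rates <- function(landscape) {
  stopifnot(inherits(landscape, "rm_landscape"))
  s <- landscape$segments
  rep(landscape$base * s$scale, times = s$end - s$start)
}

#' @export
print.rm_landscape <- function(x, ...) {
  cat("Landscape:", nrow(x$segments), "segments over", x$L, "bp; base rate",
      signif(x$base, 4), "\n")
  invisible(x)
}

#' Simulate from the fitted model itself (generative twin)
#'
#' Samples the hidden {category, TMRCA interval} chain of a kernel from its
#' stationary distribution and emits hom/het symbols, for parameter-recovery
#' tests under an exact model match.
#'
#' @param kernel an `rm_kernel`.
#' @param emissions t x 3 emission matrix.
#' @param L number of sites.
#' @param seed RNG seed.
#' @return an object of class `rm_sim`: `obs` (an `rm_obs`), `rho` (per-site
#'   true category rate rho0 * r_l), `state`, `seed`.
#' @export
sim_hmm_path <- function(kernel, emissions, L, seed = 1L) {
  stopifnot(inherits(kernel, "rm_kernel"), L >= 1)
  n <- kernel$t * kernel$k
  Q <- kernel$q_mod
  local({
    set.seed(seed)
    diagq <- diag(Q)
    state <- integer(0); runlen <- integer(0)
    z <- sample.int(n, 1, prob = kernel$stationary)
    pos <- 0L
    while (pos < L) {
      stay <- diagq[z]
      m <- if (stay >= 1) L - pos else min(stats::rgeom(1, 1 - stay) + 1, L - pos)
      state <- c(state, z); runlen <- c(runlen, m)
      pos <- pos + m
      if (pos < L) {
        p <- Q[z, ]; p[z] <- 0
        z <- sample.int(n, 1, prob = p)
      }
    }
    zs <- rep.int(state, runlen)
    cat_of <- (zs - 1L) %/% kernel$t + 1L
    int_of <- (zs - 1L) %% kernel$t + 1L
    p_het <- emissions[int_of, 2]
    codes <- ifelse(stats::runif(L) < p_het, 1L, 0L)
    rho <- kernel$prior$rho0 * kernel$prior$category_means[cat_of]
    structure(list(obs = observed_sequence(codes), rho = rho, tmrca = NULL,
                   state = zs, seed = seed),
              class = "rm_sim")
  })
}

# sample a re-coalescence time for a lineage detached at u on a tree of
# height s, under piecewise demography: hazard 2*lambda on (u, s) (either
# remaining branch), lambda above s; returns list(time, back)
sample_recoalescence <- function(u, s, demog) {
  br <- demog$breaks; r <- demog$rates
  e <- stats::rexp(1)
  # walk pieces of (u, s) with hazard 2*lambda
  pts <- sort(unique(c(u, br[br > u & br < s], s)))
  for (i in seq_len(length(pts) - 1L)) {
    lam <- 2 * r[findInterval(pts[i], br)]
    h <- lam * (pts[i + 1L] - pts[i])
    if (e < h) {
      tc <- pts[i] + e / lam
      if (stats::runif(1) < 0.5) return(list(time = s, back = TRUE))
      return(list(time = tc, back = FALSE))
    }
    e <- e - h
  }
  # above s: hazard lambda
  pts <- c(s, br[br > s], Inf)
  for (i in seq_len(length(pts) - 1L)) {
    lam <- r[findInterval(pts[i], br)]
    h <- lam * (pts[i + 1L] - pts[i])
    if (e < h || i == length(pts) - 1L)
      return(list(time = pts[i] + e / lam, back = FALSE))
    e <- e - h
  }
}

#' Sequential SMC' simulation of a genome pair
#'
#' Simulates the continuous-TMRCA genealogy process spatially along the
#' chromosome for one pair of lineages: the first TMRCA is drawn from the
#' demography's coalescent prior; moving along the sequence, each site
#' recombines with probability 1 - exp(-rho_i * s), the breakpoint falls
#' uniformly on the two branches, and the detached lineage re-coalesces
#' under the demography (possibly back onto its own branch, restoring the
#' previous TMRCA).  Heterozygous sites are emitted with probability
#' 1 - exp(-theta_i * s).  The TMRCA is never discretised here, so the
#' simulator is not the inference model's generative twin.
#'
#' @param landscape an `rm_landscape` of per-site rho (or NULL for a
#'   homogeneous rate `rho0`).
#' @param theta either a constant scaled mutation rate or an
#'   `rm_landscape` of per-site theta.
#' @param demography an `rm_demography` (default constant).
#' @param L sequence length (defaults to the landscape's).
#' @param rho0 homogeneous rate used when `landscape` is NULL.
#' @param seed RNG seed.
#' @return an `rm_sim` with `obs`, per-site `rho`, per-site `tmrca`, `seed`.
#' @export
sim_smc_sequence <- function(landscape = NULL, theta = 0.003,
                             demography = NULL, L = NULL, rho0 = NULL,
                             seed = 1L) {
  if (is.null(demography)) demography <- constant_demography()
  stopifnot(inherits(demography, "rm_demography"))
  if (is.null(landscape)) {
    stopifnot(!is.null(L), !is.null(rho0))
    segs <- data.frame(start = 0, end = L, scale = 1)
    landscape <- structure(list(segments = segs, base = rho0,
                                L = as.integer(L), seed = seed,
                                spec = list(kind = "constant")),
                           class = "rm_landscape")
  }
  L <- landscape$L
  rho_site <- landscape_rates(landscape)
  theta_site <- if (inherits(theta, "rm_landscape")) landscape_rates(theta)
                else rep(theta, L)
  stopifnot(length(theta_site) == L)

  local({
    set.seed(seed + 7L)
    s <- prior_tmrca_quantile(demography, stats::runif(1))
    seg <- landscape$segments
    tm_start <- integer(0); tm_val <- numeric(0)
    pos <- 1L
    tm_start <- c(tm_start, pos); tm_val <- c(tm_val, s)
    si <- 1L
    while (pos < L) {
      # within the current landscape segment rho is constant: jump to the
      # next recombination event with a geometric gap
      while (si < nrow(seg) && pos > seg$end[si]) si <- si + 1L
      rho <- landscape$base * seg$scale[si]
      p_rec <- -expm1(-rho * s)
      gap <- if (p_rec <= 0) Inf else stats::rgeom(1, p_rec) + 1
      seg_end <- seg$end[si]          # last site of this segment (1-based)
      if (pos + gap > seg_end || pos + gap > L) {
        pos <- min(seg_end, L)
        if (pos >= L) break
        pos <- pos + 1L               # first site of the next segment
        si <- si + 1L
        next
      }
      pos <- pos + gap
      u <- stats::runif(1, 0, s)
      rc <- sample_recoalescence(u, s, demography)
      if (!rc$back && rc$time != s) {
        s <- rc$time
        tm_start <- c(tm_start, pos); tm_val <- c(tm_val, s)
      }
    }
    tm_end <- c(tm_start[-1] - 1L, L)
    tmrca <- rep.int(tm_val, tm_end - tm_start + 1L)
    p_het <- -expm1(-theta_site * tmrca)
    codes <- ifelse(stats::runif(L) < p_het, 1L, 0L)
    structure(list(obs = observed_sequence(codes), rho = rho_site,
                   tmrca = tmrca, seed = seed),
              class = "rm_sim")
  })
}

#' @export
print.rm_sim <- function(x, ...) {
  cat("Simulated pair:", x$obs$L, "sites,", sum(x$obs$codes == 1L),
      "heterozygous\n")
  invisible(x)
}
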