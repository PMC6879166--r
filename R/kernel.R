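#' SMC' genealogy transition matrix
#'
#' Probability that the genealogy at the next site has its TMRCA in interval
#' j given it currently lies in interval i, under the SMC' process: on a tree
#' of scaled height s the site recombines with probability 1 - exp(-rho * s)
#' (rho is the per-site population recombination rate, time in units of 2*Ne
#' generations so the total branch length is 2s); the breakpoint falls
#' uniformly on the two branches; the floating lineage then re-coalesces at
#' the demography's rate, onto either remaining branch below s (coalescing
#' back onto its own branch restores the old TMRCA) or onto the single
#' ancestral lineage above s.
#'
#' The integrals over TMRCA intervals are evaluated by quadrature: s at
#' `s_nodes` conditional prior quantiles within each interval and the
#' breakpoint u by Gauss-Legendre nodes within each hazard piece, with the
#' re-coalescence integrals in closed form (the coalescence rate is constant
#' within intervals).  Because s is averaged against the prior, the
#' discretised prior is (numerically exactly) the stationary distribution of
#' the returned matrix.
#'
#' @param disc an [rm_time_disc][time_discretization].
#' @param rho per-site population recombination rate (>= 0).
#' @param s_nodes,u_nodes quadrature resolution.
#' @return a `disc$t` x `disc$t` row-stochastic matrix.
#' @export
smc_transition <- function(disc, rho, s_nodes = 5, u_nodes = 5) {
  stopifnot(inherits(disc, "rm_time_disc"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0)
    stop("rho must be a non-negative number")
  tab <- smc_step_table(disc, s_nodes = s_nodes, u_nodes = u_nodes)
  smc_transition_from_table(tab, rho)
}

# Precompute, per source interval i and s-quadrature node m, the sampled
# tree height s[i, m] and the conditional landing distribution
# mass[i, m, j] = P(next TMRCA in j | recombination on a tree of height s).
# These are rho-independent, so one table serves all rate categories.
smc_step_table <- function(disc, s_nodes = 5, u_nodes = 5) {
  t <- disc$t
  b <- disc$boundaries          # length t+1, last Inf
  lam <- disc$lambda
  # cumulative hazard at boundaries under the interval-projected rates
  cl <- c(0, cumsum(lam[-t] * diff(b[seq_len(t)])))
  cumhaz <- function(x) {       # vectorised, x >= 0 finite
    i <- findInterval(x, b[seq_len(t)])
    cl[i] + lam[i] * (x - b[i])
  }
  invhaz <- function(h) {
    i <- findInterval(h, cl)
    b[i] + (h - cl[i]) / lam[i]
  }
  # Gauss-Legendre nodes/weights on [0,1]
  gl <- gauss_legendre_01(u_nodes)

  s_arr <- matrix(0, t, s_nodes)
  w_arr <- matrix(1 / s_nodes, t, s_nodes)
  mass <- array(0, dim = c(t, s_nodes, t))
  probs <- (seq_len(s_nodes) - 0.5) / s_nodes
  glag <- gauss_laguerre(s_nodes)
  for (i in seq_len(t)) {
    if (i < t) {
      # conditional prior quantiles of s within interval i (equal mass:
      # global quantile levels are ((i-1) + p) / t)
      s_i <- invhaz(-log1p(-((i - 1 + probs) / t)))
    } else {
      # unbounded final interval: conditional prior is a shifted
      # exponential (constant hazard), integrate by Gauss-Laguerre so the
      # deep tail is represented
      s_i <- b[t] + glag$x / lam[t]
      w_arr[i, ] <- glag$w
    }
    s_arr[i, ] <- s_i
    for (m in seq_len(s_nodes)) {
      s <- s_i[m]
      Hs <- cumhaz(s)
      edges <- c(b[seq_len(i)], s)            # u-pieces: i pieces below s
      acc <- numeric(t)
      for (p in seq_len(i)) {
        lo <- edges[p]; hi <- edges[p + 1L]
        w <- hi - lo
        if (w <= 0) next
        u <- lo + gl$x * w                     # u_nodes points in piece p
        wu <- gl$w * w / s                     # uniform-u weights
        Hu <- cl[p] + lam[p] * (u - lo)
        E2 <- exp(-2 * (Hs - Hu))              # survive to s (no re-coal below)
        # landing below s: cuts at u, boundaries in (u, s), s
        cutj <- seq.int(p, i)                  # intervals intersected
        # exp(-2(H(c)-H(u))) at upper cut of each interval segment
        upper <- pmin(b[cutj + 1L], s)
        Hup <- cumhaz(upper)
        Eup <- exp(-2 * outer(Hup, Hu, `-`))   # (#cuts) x u_nodes
        Elo <- rbind(rep(1, length(u)), Eup[-length(cutj), , drop = FALSE])
        below <- 0.5 * (Elo - Eup)             # per interval segment x u
        acc[cutj] <- acc[cutj] + as.vector(below %*% wu)
        # back-coalescence onto own branch: TMRCA unchanged
        acc[i] <- acc[i] + sum(0.5 * (1 - E2) * wu)
        # escape above s: single lineage, rate lambda
        if (TRUE) {
          aj <- pmax(b[i:t], s)                # lower ends of intervals >= i
          Haj <- cumhaz(aj)
          up <- b[(i:t) + 1L]
          Hbj <- ifelse(is.finite(up), cumhaz(pmin(up, .Machine$double.xmax)), Inf)
          seg <- exp(-(Haj - Hs)) - ifelse(is.finite(Hbj), exp(-(Hbj - Hs)), 0)
          acc[i:t] <- acc[i:t] + seg * sum(E2 * wu)
        }
      }
      mass[i, m, ] <- acc
    }
  }
  list(t = t, s = s_arr, w = w_arr, mass = mass, s_nodes = s_nodes)
}

smc_transition_from_table <- function(tab, rho) {
  t <- tab$t
  Q <- matrix(0, t, t)
  for (i in seq_len(t)) {
    p_rec <- -expm1(-rho * tab$s[i, ])         # 1 - exp(-rho s), per s node
    w <- tab$w[i, ]
    row <- colSums(w * p_rec * matrix(tab$mass[i, , ], tab$s_nodes, t))
    row[i] <- row[i] + sum(w * (1 - p_rec))
    Q[i, ] <- row
  }
  Q
}

gauss_laguerre <- function(n) {
  # Golub-Welsch for the Laguerre weight e^{-x} on (0, Inf)
  if (n == 1) return(list(x = 1, w = 1))
  i <- seq_len(n)
  J <- diag(2 * i - 1)
  off <- seq_len(n - 1)
  J[cbind(off, off + 1)] <- off
  J[cbind(off + 1, off)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2)[ord])
}

gauss_legendre_01 <- function(n) {
  # Golub-Welsch on the Jacobi matrix for Legendre polynomials
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  list(x = (x + 1) / 2, w = w / 2)
}

#' Markov-modulated composite transition matrix
#'
#' Combines the k per-category SMC' genealogy matrices with the category
#' switching matrix into the n x n (n = t*k) transition matrix of the
#' modulated chain: block (l, m) equals `q_rho[l, m] * Q_SMC(rho0 * r_l)`,
#' the genealogy step being taken under the source (row) category's rate.
#'
#' @param q_smc_by_category list of k t x t stochastic matrices.
#' @param q_rho k x k category transition matrix.
#' @param rate_from `"source"` (default) or `"destination"`: which category's
#'   rate drives the genealogy step inside off-diagonal blocks.
#' @return an n x n row-stochastic matrix; states are ordered category-major,
#'   state index = (l - 1) * t + j.
#' @export
modulate_kernel <- function(q_smc_by_category, q_rho, rate_from = c("source", "destination")) {
  rate_from <- match.arg(rate_from)
  k <- length(q_smc_by_category)
  if (nrow(q_rho) != k || ncol(q_rho) != k)
    stop("q_rho dimension does not match the number of category matrices")
  t <- nrow(q_smc_by_category[[1]])
  if (any(vapply(q_smc_by_category, function(m) nrow(m) != t || ncol(m) != t, logical(1))))
    stop("all category matrices must be t x t")
  n <- t * k
  Q <- matrix(0, n, n)
  for (l in seq_len(k)) for (m in seq_len(k)) {
    blk <- if (rate_from == "source") q_smc_by_category[[l]] else q_smc_by_category[[m]]
    Q[(l - 1) * t + seq_len(t), (m - 1) * t + seq_len(t)] <- q_rho[l, m] * blk
  }
  Q
}

#' Assemble the full transition kernel of the modulated HMM
#'
#' @param disc an `rm_time_disc`.
#' @param prior an [rm_rho_prior][rho_prior].
#' @param s_nodes,u_nodes quadrature resolution for [smc_transition()].
#' @param step_table optional precomputed result of the internal step table
#'   (reused across likelihood evaluations when the demography is fixed).
#' @inheritParams modulate_kernel
#' @return an object of class `rm_kernel`: `q_smc_by_category`, `q_rho`,
#'   `q_mod`, `stationary`, plus `t`, `k` and the inputs.
#' @export
build_kernel <- function(disc, prior, s_nodes = 5, u_nodes = 5,
                         rate_from = "source", step_table = NULL) {
  stopifnot(inherits(disc, "rm_time_disc"), inherits(prior, "rm_rho_prior"))
  if (disc$t * prior$k > 400)
    stop("t * k exceeds the supported number of hidden states")
  if (is.null(step_table))
    step_table <- smc_step_table(disc, s_nodes = s_nodes, u_nodes = u_nodes)
  qs <- lapply(prior$category_means, function(r)
    smc_transition_from_table(step_table, prior$rho0 * r))
  qr <- rho_transition(prior$delta, prior$k)
  qi <- modulate_kernel(qs, qr, rate_from = rate_from)
  stat <- rep(disc$mass / prior$k, times = prior$k)
  structure(list(q_smc_by_category = qs, q_rho = qr, q_mod = qi,
                 stationary = stat, t = disc$t, k = prior$k,
                 disc = disc, prior = prior),
            class = "rm_kernel")
}

#' @export
print.rm_kernel <- function(x, ...) {
  cat("Modulated SMC' kernel:", x$t, "TMRCA intervals x", x$k,
      "rate categories =", x$t * x$k, "hidden states\n")
  invisible(x)
}
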