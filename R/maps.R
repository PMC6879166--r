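#' Posterior-mean recombination map
#'
#' The single-nucleotide landscape: at each site the posterior average
#' rho_i = rho0 * sum_l r_l * sum_j P_i(x_l, y_j), i.e. the category means
#' weighted by their marginal posterior probabilities.  Every value is a
#' convex combination of rho0 * r_l and therefore bounded by the smallest
#' and largest category rates.
#'
#' @param field an [rm_field][posterior_decode].
#' @param prior the [rm_rho_prior][rho_prior] of the decoded model.
#' @param missing optional logical vector marking missing sites (carried
#'   into binning as per-window missing fractions).
#' @return an object of class `rm_map` with per-site `rho`, inclusion flags
#'   and provenance.
#' @export
posterior_mean_rho <- function(field, prior, missing = NULL) {
  stopifnot(inherits(field, "rm_field"), inherits(prior, "rm_rho_prior"))
  if (field$k != prior$k) stop("field and prior disagree on k")
  rho <- as.numeric(prior$rho0 * (field$cat_marginal %*% prior$category_means))
  L <- length(rho)
  if (is.null(missing)) missing <- rep(FALSE, L)
  structure(list(rho = rho, include = rep(TRUE, L), missing = missing,
                 map_interval = field$map_interval, contigs = field$contigs,
                 prior = prior, restricted = FALSE),
            class = "rm_map")
}

#' Time-restricted recombination map
#'
#' Focuses the landscape on recent history in three steps: (1) the per-site
#' MAP TMRCA interval is taken marginalising over rate categories; (2) the
#' per-site posterior-average rho is computed from the category posterior
#' conditional on that interval, rho_i = rho0 * sum_l r_l * P_i(r_l | tau =
#' MAP); (3) downstream binning only averages sites whose MAP interval is at
#' most `max_interval`, discarding recombination signal carried by older
#' coalescences.  Sites whose MAP interval has essentially zero posterior
#' mass fall back to the unrestricted category marginal and are flagged.
#'
#' @inheritParams posterior_mean_rho
#' @param max_interval most recent TMRCA interval retained (1-based,
#'   inclusive; `max_interval = t` keeps every site).
#' @return an `rm_map` with `include` marking retained sites and `fallback`
#'   marking degenerate ones.
#' @export
time_restricted_rho <- function(field, prior, max_interval, missing = NULL) {
  stopifnot(inherits(field, "rm_field"), inherits(prior, "rm_rho_prior"))
  if (field$k != prior$k) stop("field and prior disagree on k")
  if (!is.numeric(max_interval) || length(max_interval) != 1L ||
      max_interval < 1 || max_interval > field$t)
    stop("max_interval must lie in 1..t")
  rho <- as.numeric(prior$rho0 * (field$cat_at_map %*% prior$category_means))
  L <- length(rho)
  if (is.null(missing)) missing <- rep(FALSE, L)
  structure(list(rho = rho, include = field$map_interval <= max_interval,
                 missing = missing, map_interval = field$map_interval,
                 fallback = field$map_mass < 1e-12, contigs = field$contigs,
                 prior = prior, restricted = TRUE,
                 max_interval = as.integer(max_interval)),
            class = "rm_map")
}

#' @export
print.rm_map <- function(x, ...) {
  cat("Recombination map:", length(x$rho), "sites",
      if (x$restricted) sprintf("(time-restricted to intervals <= %d)", x$max_interval)
      else "", "\n")
  cat("  mean rho =", signif(mean(x$rho[x$include]), 4), "\n")
  invisible(x)
}

#' Bin a single-nucleotide map into fixed-width windows
#'
#' Non-overlapping windows are laid out from the start of each contig
#' (0-based half-open coordinates); a trailing partial window is kept only
#' if at least half the width remains.  The window value is the mean rho
#' over included sites; windows whose missing-data fraction exceeds the
#' threshold are masked (value kept, `masked` flag set), following the
#' more-than-50%-missing exclusion rule.  Binning is agnostic to the true
#' breakpoints of any underlying landscape.
#'
#' @param map an `rm_map`, or a bare numeric vector of per-site values.
#' @param width window width in bases (common choices: 50 kb, 200 kb,
#'   500 kb, 1 Mb).
#' @param missing_threshold mask windows with more missing data than this
#'   (default 0.5).
#' @return an object of class `rm_binned`: a data.frame with columns
#'   `contig`, `start`, `end`, `rho`, `missing_frac`, `n_sites`, `masked`.
#' @export
bin_map <- function(map, width, missing_threshold = 0.5) {
  if (is.numeric(map) && is.null(attr(map, "class")))
    map <- structure(list(rho = map, include = rep(TRUE, length(map)),
                          missing = rep(FALSE, length(map)),
                          contigs = matrix(c(0L, length(map)), 1, 2)),
                     class = "rm_map")
  stopifnot(inherits(map, "rm_map"))
  if (!is.numeric(width) || width < 1) stop("width must be >= 1")
  width <- as.integer(width)
  rows <- list()
  for (ci in seq_len(nrow(map$contigs))) {
    cs <- map$contigs[ci, 1]; ce <- map$contigs[ci, 2]
    starts <- seq.int(cs, ce - 1L, by = width)
    ends <- pmin(starts + width, ce)
    keep <- (ends - starts) >= width / 2
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    nwin <- length(starts)
    pos <- seq.int(cs, ce - 1L)
    win <- findInterval(pos, starts)
    ok <- pos < ends[win]              # drops positions of a removed tail
    idx <- (cs + 1L):ce
    inc <- map$include[idx] & ok
    n_tot <- tabulate(win[ok], nbins = nwin)
    n_inc <- tabulate(win[inc], nbins = nwin)
    miss <- tabulate(win[ok & map$missing[idx]], nbins = nwin)
    rho_sum <- numeric(nwin)
    if (any(inc)) {
      rs <- rowsum(map$rho[idx][inc], win[inc])
      rho_sum[as.integer(rownames(rs))] <- rs[, 1]
    }
    rows[[ci]] <- data.frame(contig = ci, start = starts, end = ends,
                             rho = ifelse(n_inc > 0, rho_sum / n_inc, NA_real_),
                             missing_frac = miss / pmax(n_tot, 1),
                             n_sites = n_inc)
  }
  out <- do.call(rbind, rows)
  out$masked <- out$missing_frac > missing_threshold | is.na(out$rho)
  attr(out, "width") <- width
  class(out) <- c("rm_binned", "data.frame")
  out
}

binned_compatible <- function(a, b) {
  nrow(a) == nrow(b) && all(a$contig == b$contig) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' Squared Pearson correlation between two binned maps
#'
#' R^2 between inferred and reference landscapes over shared unmasked
#' windows, with a percentile confidence interval from bootstrap resampling
#' of windows.
#'
#' @param inferred,truth `rm_binned` maps on identical window grids.
#' @param bootstrap number of window-resampling replicates (default 100).
#' @param conf confidence level of the percentile interval.
#' @param seed RNG seed for the bootstrap (recorded in the output).
#' @return list with `r2`, `ci` (length 2), `n_windows`, `seed`.
#' @export
compare_r2 <- function(inferred, truth, bootstrap = 100, conf = 0.95,
                       seed = 1L) {
  stopifnot(inherits(inferred, "rm_binned"), inherits(truth, "rm_binned"))
  if (!binned_compatible(inferred, truth))
    stop("maps are not on identical window grids")
  keep <- !inferred$masked & !truth$masked
  x <- inferred$rho[keep]; y <- truth$rho[keep]
  if (length(x) < 3) stop("fewer than 3 shared unmasked windows")
  r2 <- stats::cor(x, y)^2
  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0) {
    rng <- local({ set.seed(seed); replicate(bootstrap, {
      i <- sample.int(length(x), replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])^2
    }) })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(rng, c(a, 1 - a), na.rm = TRUE))
  }
  list(r2 = r2, ci = ci, n_windows = length(x), seed = seed)
}

#' Distance-based clustering of recombination maps
#'
#' Pairwise distances 1 - r_s (Spearman rank correlation, average ranks for
#' ties) over windows unmasked in every map, UPGMA (average-linkage)
#' clustering, and clade bootstrap support by resampling windows with
#' replacement.  Clades below the support threshold are collapsed into
#' polytomies in the `collapsed` tree (topology only).
#'
#' @param maps named list of >= 3 `rm_binned` maps on a common grid.
#' @param bootstrap number of bootstrap replicates (default 1000).
#' @param support_threshold collapse clades below this support (default 0.6).
#' @param seed RNG seed for the bootstrap.
#' @return list with `distance` (matrix), `tree` (ape phylo, node labels =
#'   % support), `collapsed`, `support` (per internal node, proportion),
#'   `n_windows`, `seed`.
#' @export
map_distance_cluster <- function(maps, bootstrap = 1000,
                                 support_threshold = 0.6, seed = 1L) {
  if (length(maps) < 3) stop("at least 3 maps are required")
  if (is.null(names(maps))) names(maps) <- paste0("map", seq_along(maps))
  for (m in maps) stopifnot(inherits(m, "rm_binned"))
  for (m in maps[-1]) if (!binned_compatible(maps[[1]], m))
    stop("maps are not on identical window grids")
  keep <- Reduce(`&`, lapply(maps, function(m) !m$masked))
  if (sum(keep) < 10) stop("fewer than 10 windows unmasked in all maps")
  vals <- sapply(maps, function(m) m$rho[keep])

  upgma_tree <- function(v) {
    d <- 1 - stats::cor(v, method = "spearman")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    list(dist = d, tree = ape::as.phylo(hc))
  }
  main <- upgma_tree(vals)
  boots <- local({
    set.seed(seed)
    lapply(seq_len(bootstrap), function(b) {
      i <- sample.int(nrow(vals), replace = TRUE)
      upgma_tree(vals[i, , drop = FALSE])$tree
    })
  })
  counts <- ape::prop.clades(main$tree, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- counts / bootstrap
  tree <- main$tree
  tree$node.label <- round(100 * support)
  # collapse unsupported clades (root kept): zero out their subtending edge
  # on a unit-length copy and let di2multi merge them into polytomies
  unit <- tree
  unit$edge.length <- rep(1, nrow(unit$edge))
  ntip <- length(tree$tip.label)
  bad <- which(support < support_threshold) + ntip
  bad <- setdiff(bad, ntip + 1L)  # never collapse the root
  unit$edge.length[unit$edge[, 2] %in% bad] <- 0
  collapsed <- ape::di2multi(unit, tol = 0.5)
  collapsed$edge.length <- NULL
  list(distance = main$dist, tree = tree, collapsed = collapsed,
       support = support, n_windows = sum(keep), seed = seed)
}
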