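make_field <- function(cat_marginal, map_interval = NULL, cat_at_map = NULL,
                       t = 3) {
  L <- nrow(cat_marginal)
  structure(list(cat_marginal = cat_marginal,
                 map_interval = map_interval %||% rep(1L, L),
                 cat_at_map = cat_at_map %||% cat_marginal,
                 map_mass = rep(0.5, L), loglik = 0,
                 t = t, k = ncol(cat_marginal),
                 contigs = matrix(c(0L, L), 1, 2)),
            class = "rm_field")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("posterior-mean rho is the category-weighted convex combination", {
  pr1 <- rho_prior(0.004, k = 1)
  f1 <- make_field(matrix(1, 10, 1))
  expect_equal(posterior_mean_rho(f1, pr1)$rho, rep(0.004, 10))

  pr2 <- rho_prior(0.002, alpha = 1, k = 2)   # means 1 -/+ log 2
  funif <- make_field(matrix(0.5, 10, 2))
  expect_equal(posterior_mean_rho(funif, pr2)$rho, rep(0.002, 10))

  ftoy <- make_field(matrix(c(0.25, 0.75), 1, 2, byrow = TRUE))
  expect_equal(posterior_mean_rho(ftoy, pr2)$rho,
               0.002 * (0.25 * (1 - log(2)) + 0.75 * (1 + log(2))),
               tolerance = 1e-12)
  expect_equal(posterior_mean_rho(ftoy, pr2)$rho, 0.002 * 1.3466,
               tolerance = 1e-4)
  # convexity: always inside [rho0 r_1, rho0 r_k]
  set.seed(1)
  w <- matrix(rgamma(300, 1), 100, 3); w <- w / rowSums(w)
  pr3 <- rho_prior(0.001, alpha = 0.5, k = 3)
  rho <- posterior_mean_rho(make_field(w), pr3)$rho
  expect_true(all(rho >= 0.001 * pr3$category_means[1] - 1e-15))
  expect_true(all(rho <= 0.001 * pr3$category_means[3] + 1e-15))
})

test_that("time-restricted maps condition on the MAP interval and filter old sites", {
  pr <- rho_prior(0.002, alpha = 1, k = 2)
  cm <- matrix(0.5, 6, 2)
  at_map <- matrix(c(0.9, 0.1), 6, 2, byrow = TRUE)
  fld <- make_field(cm, map_interval = c(1L, 1L, 2L, 3L, 3L, 2L),
                    cat_at_map = at_map, t = 3)
  m_all <- time_restricted_rho(fld, pr, max_interval = 3)
  expect_true(all(m_all$include))                      # max_interval = t
  expect_equal(m_all$rho,
               rep(0.002 * (0.9 * (1 - log(2)) + 0.1 * (1 + log(2))), 6))
  # conditional values differ from the unrestricted marginal ones in general
  expect_false(isTRUE(all.equal(m_all$rho, posterior_mean_rho(fld, pr)$rho)))
  m2 <- time_restricted_rho(fld, pr, max_interval = 2)
  expect_identical(m2$include, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  b <- bin_map(m2, 3)
  expect_equal(b$n_sites, c(3, 1))                     # old sites dropped
  expect_error(time_restricted_rho(fld, pr, 4), "max_interval")
})

test_that("binning averages fixed-width windows and applies the missing-data mask", {
  const <- bin_map(rep(0.01, 200), width = 50)
  expect_equal(const$rho, rep(0.01, 4))
  expect_equal(nrow(bin_map(rep(1, 3e6), width = 5e4)), 60)  # integer division
  # trailing partial window kept only if >= half width
  expect_equal(nrow(bin_map(rep(1, 130), width = 50)), 3)
  expect_equal(nrow(bin_map(rep(1, 120), width = 50)), 2)
  # 60% missing at threshold 0.5 => masked
  m <- structure(list(rho = rep(0.01, 100), include = rep(TRUE, 100),
                      missing = c(rep(TRUE, 30), rep(FALSE, 70)),
                      contigs = matrix(c(0L, 100L), 1, 2)),
                 class = "rm_map")
  b <- bin_map(m, width = 50, missing_threshold = 0.5)
  expect_identical(b$masked, c(TRUE, FALSE))
  expect_equal(b$missing_frac, c(0.6, 0))
  # binning then averaging equals direct coarser binning on complete data
  set.seed(2)
  v <- runif(4e3)
  fine <- bin_map(v, 100)
  coarse <- bin_map(v, 200)
  expect_equal(colMeans(matrix(fine$rho, 2)), coarse$rho)
})

test_that("R-squared comparison is symmetric, affine-invariant and noise-calibrated", {
  set.seed(7)
  truth <- bin_map(rep(rgamma(100, 0.5, 0.5) * 0.001, each = 50), 50)
  expect_equal(compare_r2(truth, truth, bootstrap = 0)$r2, 1)
  aff <- truth; aff$rho <- 3 * truth$rho + 0.01
  expect_equal(compare_r2(aff, truth, bootstrap = 0)$r2, 1, tolerance = 1e-12)
  a <- compare_r2(truth, aff, bootstrap = 20, seed = 3)
  b <- compare_r2(aff, truth, bootstrap = 20, seed = 3)
  expect_equal(a$r2, b$r2)
  # equal-variance independent noise halves the explained variance
  set.seed(8)
  x <- rnorm(500)
  tb <- bin_map(rep(x, each = 10), 10)
  nb <- tb; nb$rho <- x + rnorm(500)
  r2 <- compare_r2(nb, tb, bootstrap = 50, seed = 1)
  expect_lt(abs(r2$r2 - 0.5), 0.1)
  expect_true(r2$ci[1] <= r2$r2 && r2$r2 <= r2$ci[2])
  # masked windows excluded pairwise; too few windows rejected
  short <- bin_map(rep(1, 100), 50)
  expect_error(compare_r2(short, short), "fewer than 3")
})

test_that("UPGMA map clustering recovers structure and is metric", {
  set.seed(21)
  base <- rgamma(200, 0.5, 0.5)
  mk <- function(v) bin_map(rep(v * 0.001, each = 20), 20)
  # two identical maps plus one unrelated
  maps <- list(a = mk(base), b = mk(base), c = mk(rgamma(200, 0.5, 0.5)))
  cl <- map_distance_cluster(maps, bootstrap = 50, seed = 2)
  expect_true(isSymmetric(cl$distance))
  expect_equal(diag(cl$distance), rep(0, 3), ignore_attr = TRUE)
  expect_equal(cl$distance["a", "b"], 0, tolerance = 1e-12)
  h <- stats::hclust(stats::as.dist(cl$distance), "average")
  expect_identical(sort(h$merge[1, ]), c(-2L, -1L))   # identical pair first
  # three-taxon landscape phylogeny: (A,B) share a component C lacks
  shared_ab <- rgamma(200, 0.5, 0.5)
  noise <- function() rnorm(200, 0, 0.2)
  maps2 <- list(A = mk(base + shared_ab + noise()),
                B = mk(base + shared_ab + noise()),
                C = mk(base + noise()))
  cl2 <- map_distance_cluster(maps2, bootstrap = 100, seed = 4)
  expect_lt(cl2$distance["A", "B"],
            min(cl2$distance["A", "C"], cl2$distance["B", "C"]))
  expect_s3_class(cl2$tree, "phylo")
  expect_s3_class(cl2$collapsed, "phylo")
  expect_error(map_distance_cluster(maps2[1:2]), "at least 3")
})
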