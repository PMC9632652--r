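test_that("gaussian kernel matches its closed form and validates input", {
  expect_equal(gaussian_kernel(c(1, 2, 3), c(1, 2, 3), kernel_spec(2)), 1.0)
  # ||x - y||^2 = 2 sigma^2 => exp(-1)
  expect_equal(gaussian_kernel(c(0, 0), c(2, 0), kernel_spec(sqrt(2))),
               exp(-1), tolerance = 1e-12)
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), kernel_spec(5)),
               exp(-25 / 50), tolerance = 1e-12)
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3), kernel_spec(1)),
               "dimension")
  expect_error(kernel_spec(-1), "positive")
  expect_error(kernel_spec(0), "positive")

  # the multi-kernel average lies between the extreme single-kernel values
  x <- c(0, 0); y <- c(1.5, 0.5)
  k_multi <- gaussian_kernel(x, y, kernel_spec(1, n_kernels = 5L))
  k_lo <- gaussian_kernel(x, y, kernel_spec(0.25))
  k_hi <- gaussian_kernel(x, y, kernel_spec(4))
  expect_gt(k_multi, k_lo)
  expect_lt(k_multi, k_hi)
})

test_that("squared MMD: identical sets, singletons, and the V-statistic oracle", {
  set.seed(11)
  A <- matrix(rnorm(24), 12, 2)
  expect_lt(mmd_squared(A, A, kernel_spec(1)), 1e-10)
  expect_lt(mmd_squared(A, A), 1e-10) # median bandwidth

  x <- matrix(c(1, -1), 1); y <- matrix(c(0.5, 2), 1)
  ks <- kernel_spec(1.7)
  expect_equal(mmd_squared(x, y, ks),
               2 - 2 * gaussian_kernel(drop(x), drop(y), ks),
               tolerance = 1e-12)

  # brute-force oracle over a seeded grid of sizes, plus symmetry
  for (s in 1:12) {
    set.seed(s)
    n <- sample(2:20, 1); m <- sample(2:20, 1); d <- sample(1:4, 1)
    Xs <- matrix(rnorm(n * d), n, d)
    Xt <- matrix(rnorm(m * d, 0.5), m, d)
    sig <- runif(1, 0.5, 3)
    v <- mmd_squared(Xs, Xt, kernel_spec(sig))
    expect_equal(v, oracle_mmd(Xs, Xt, sig), tolerance = 1e-12)
    expect_equal(v, mmd_squared(Xt, Xs, kernel_spec(sig)), tolerance = 1e-12)
  }
  expect_error(mmd_squared(matrix(1, 2, 2), matrix(1, 2, 3)), "dimension")
})

test_that("conditional MMD restricts to shared classes", {
  set.seed(3)
  xa <- matrix(rnorm(40), 20, 2); xb <- matrix(rnorm(40, 0.3), 20, 2)
  a <- feature_set(xa, labels = rep(0:1, each = 10))
  b <- feature_set(xb, labels = rep(0:1, each = 10))
  ks <- kernel_spec(1.5)
  cm <- conditional_mmd(a, b, ks)
  expect_named(cm, c("0", "1"))
  # slicing oracle
  expect_equal(cm[["0"]], mmd_squared(xa[1:10, ], xb[1:10, ], ks),
               tolerance = 1e-12)
  expect_equal(cm[["1"]], mmd_squared(xa[11:20, ], xb[11:20, ], ks),
               tolerance = 1e-12)

  # identical single-class sets -> zero for that class
  c1 <- feature_set(xa, labels = rep(0L, 20))
  expect_lt(conditional_mmd(c1, c1, ks)[["0"]], 1e-10)

  # class-0 identical, class-1 shifted
  xb2 <- xa; xb2[11:20, ] <- xb2[11:20, ] + 3
  b2 <- feature_set(xb2, labels = rep(0:1, each = 10))
  a2 <- feature_set(xa, labels = rep(0:1, each = 10))
  cm2 <- conditional_mmd(a2, b2, ks)
  expect_lt(cm2[["0"]], 1e-10)
  expect_gt(cm2[["1"]], 0.01)

  # disjoint class support -> degenerate-input error
  d0 <- feature_set(xa, labels = rep(0L, 20))
  d1 <- feature_set(xb, labels = rep(1L, 20))
  expect_error(suppressWarnings(conditional_mmd(d0, d1, ks)), "shared")
})

test_that("Wasserstein distance: closed forms, oracles, and the size guard", {
  # identical sets and singleton coupling
  set.seed(5)
  A <- matrix(rnorm(20), 10, 2)
  expect_equal(wasserstein_distance(A, A), 0, tolerance = 1e-12)
  expect_equal(wasserstein_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)),
               5, tolerance = 1e-12)

  # 1-D sorting oracle, equal and unequal sizes
  for (s in 1:10) {
    set.seed(s)
    n <- sample(2:30, 1); m <- sample(2:30, 1)
    a <- rnorm(n); b <- rnorm(m, 0.8)
    expect_equal(wasserstein_distance(matrix(a), matrix(b)),
                 oracle_w1_1d(a, b), tolerance = 1e-9)
  }

  # equal-size multivariate assignment oracle
  for (s in 1:6) {
    set.seed(100 + s)
    n <- sample(2:5, 1)
    A <- matrix(rnorm(2 * n), n, 2); B <- matrix(rnorm(2 * n, 1), n, 2)
    expect_equal(wasserstein_distance(A, B), oracle_w1_assignment(A, B),
                 tolerance = 1e-9)
  }

  # triangle inequality on random triples
  for (s in 1:8) {
    set.seed(200 + s)
    A <- matrix(rnorm(12), 6, 2)
    B <- matrix(rnorm(16, 1), 8, 2)
    C <- matrix(rnorm(10, -1), 5, 2)
    expect_lte(wasserstein_distance(A, C),
               wasserstein_distance(A, B) + wasserstein_distance(B, C) + 1e-8)
  }

  expect_error(wasserstein_distance(matrix(0, 513, 1), matrix(0, 10, 1)),
               "512")
})

test_that("adaptation factor covers its closed-form corners and is monotone", {
  expect_identical(adaptation_factor(1, c(`0` = 0.5, `1` = 0.5)), 0.5)
  expect_identical(adaptation_factor(2, c(0, 0)), 0)
  expect_identical(adaptation_factor(0, c(1, 2)), 1)
  expect_warning(mu0 <- adaptation_factor(0, c(0, 0)), "mu = 0.5")
  expect_identical(mu0, 0.5)

  # monotone: increasing in each class weight, decreasing in the global one
  base <- adaptation_factor(1, c(0.3, 0.4))
  expect_gt(adaptation_factor(1, c(0.5, 0.4)), base)
  expect_gt(adaptation_factor(1, c(0.3, 0.6)), base)
  expect_lt(adaptation_factor(2, c(0.3, 0.4)), base)
  grid <- seq(0.1, 3, length.out = 10)
  mus <- vapply(grid, function(w) adaptation_factor(w, c(0.5, 0.5)), numeric(1))
  expect_true(all(diff(mus) < 0))
  expect_true(all(mus >= 0 & mus <= 1))
})

test_that("pair divergence recombines its own components exactly", {
  doms <- gen_preset_domains("mixed", n_per_class = 25, dim = 6,
                             n_sources = 1, seed = 42)
  rep <- pair_divergence(doms[[2]], doms[[1]])
  manual_mu <- sum(rep$w_by_class) / (rep$w_global + sum(rep$w_by_class))
  expect_equal(rep$mu, manual_mu, tolerance = 1e-12)
  expect_equal(rep$combined,
               (1 - rep$mu) * rep$mmd_marginal +
                 rep$mu * sum(rep$mmd_conditional_by_class),
               tolerance = 1e-12)
  # and against independently computed component values at the same sigma
  ks <- kernel_spec(rep$sigma)
  expect_equal(rep$mmd_marginal,
               mmd_squared(doms[[2]]$x, doms[[1]]$x, ks), tolerance = 1e-12)
  expect_equal(unname(rep$mmd_conditional_by_class),
               unname(conditional_mmd(doms[[2]], doms[[1]], ks)),
               tolerance = 1e-12)
})

test_that("identical domains yield zero combined divergence with mu fallback", {
  set.seed(9)
  a <- feature_set(matrix(rnorm(30), 15, 2), labels = rep(0:1, c(7, 8)))
  expect_warning(rep <- pair_divergence(a, a), "mu = 0.5")
  expect_identical(rep$mu, 0.5)
  expect_lt(rep$combined, 1e-10)
  expect_lt(rep$mmd_marginal, 1e-10)
  expect_equal(rep$w_global, 0, tolerance = 1e-12)
})

test_that("pure global shift gives mu strictly inside (0,1) and positive divergence", {
  doms <- gen_preset_domains("marginal_shift", n_per_class = 30, dim = 8,
                             n_sources = 1, seed = 7)
  rep <- pair_divergence(doms[[2]], doms[[1]])
  expect_gt(rep$mu, 0)
  expect_lt(rep$mu, 1)
  expect_gt(rep$combined, 0)
})

test_that("multisource loss averages combined divergences", {
  expect_equal(multisource_mmd_loss(list(0.1, 0.2, 0.6)), 0.3)
  fake <- structure(list(combined = 0.4), class = "divergence_report")
  expect_equal(multisource_mmd_loss(list(fake, fake, fake)), 0.4)
  expect_error(multisource_mmd_loss(list()), "nonempty")
})
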