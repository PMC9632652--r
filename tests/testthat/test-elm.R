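test_that("hidden-layer initialization is seeded and correctly shaped", {
  m1 <- elm_init(5, L = 20, seed = 3)
  m2 <- elm_init(5, L = 20, seed = 3)
  m3 <- elm_init(5, L = 20, seed = 4)
  expect_identical(m1$omega, m2$omega)
  expect_identical(m1$b, m2$b)
  expect_false(identical(m1$omega, m3$omega))
  expect_equal(dim(m1$omega), c(5L, 20L))
  expect_length(m1$b, 20L)
  expect_true(all(abs(m1$omega) <= 1))
})

test_that("hidden output matches an elementwise loop oracle", {
  m <- elm_init(3, L = 7, activation = "sigmoid", seed = 5)
  m0 <- m; m0$omega[] <- 0; m0$b[] <- 0
  expect_true(all(hidden_output(matrix(rnorm(12), 4, 3), m0) == 0.5))

  set.seed(6)
  X <- matrix(rnorm(15), 5, 3)
  G <- hidden_output(X, m)
  for (i in 1:5) for (j in 1:7) {
    z <- sum(m$omega[, j] * X[i, ]) + m$b[j]
    expect_equal(G[i, j], 1 / (1 + exp(-z)), tolerance = 1e-12)
  }
  expect_error(hidden_output(matrix(0, 2, 4), m), "dimension")
})

test_that("pseudoinverse solver: exact inversion, zero target, normal-equation oracle", {
  set.seed(7)
  G <- matrix(rnorm(16), 4, 4)
  Y <- matrix(rnorm(8), 4, 2)
  phi <- solve_pinv(G, Y)
  expect_equal(G %*% phi, Y, tolerance = 1e-8)
  expect_equal(solve_pinv(G, matrix(0, 4, 2)), matrix(0, 4, 2))

  Gt <- matrix(rnorm(60), 20, 3) # overdetermined, full rank
  Yt <- matrix(rnorm(40), 20, 2)
  expect_equal(solve_pinv(Gt, Yt),
               solve(crossprod(Gt), crossprod(Gt, Yt)), tolerance = 1e-8)
})

test_that("ridge closed form matches the literal formula and its limits", {
  set.seed(8)
  G <- matrix(rnorm(80), 20, 4)
  Y <- matrix(rnorm(40), 20, 2)
  beta <- 0.05
  phi <- solve_ridge_closed_form(G, Y, beta)
  oracle <- solve(t(G) %*% G + diag(1 / beta, 4)) %*% t(G) %*% Y
  expect_equal(phi, oracle, tolerance = 1e-10)
  expect_equal(solve_ridge_closed_form(G, matrix(0, 20, 2), beta),
               matrix(0, 4, 2), tolerance = 1e-12)
  # very large beta (vanishing penalty 1/beta) approaches least squares
  expect_lt(norm(solve_ridge_closed_form(G, Y, 1e12) - solve_pinv(G, Y), "F"),
            1e-4)
  expect_error(solve_ridge_closed_form(G, Y, -1), "positive")

  # ||phi|| is non-decreasing in beta (penalty weakens as beta grows)
  norms <- vapply(c(1e-3, 0.05, 1, 1e3),
                  function(b) norm(solve_ridge_closed_form(G, Y, b), "F"),
                  numeric(1))
  expect_true(all(diff(norms) >= -1e-12))
})

test_that("L1 solver: null threshold, least-squares limit, proximal oracle, sparsity", {
  set.seed(9)
  G <- matrix(rnorm(15), 5, 3)
  y <- matrix(rnorm(5), 5, 1)
  thr <- max(abs(crossprod(G, y)))
  expect_true(all(solve_l1(G, y, beta = thr * 1.01) == 0))

  Gw <- matrix(rnorm(120), 40, 3)
  yw <- matrix(rnorm(40), 40, 1)
  expect_lt(norm(solve_l1(Gw, yw, beta = 1e-8) - solve_pinv(Gw, yw), "F"),
            1e-4)

  for (s in 1:4) {
    set.seed(30 + s)
    Gs <- matrix(rnorm(15), 5, 3)
    ys <- matrix(rnorm(5), 5, 1)
    b <- runif(1, 0.05, 0.5)
    expect_equal(as.numeric(solve_l1(Gs, ys, beta = b)),
                 oracle_lasso_pg(Gs, drop(ys), b), tolerance = 1e-5)
  }

  # sparsity is monotone non-decreasing in beta
  set.seed(10)
  Gb <- matrix(rnorm(200), 20, 10)
  yb <- matrix(rnorm(20), 20, 1)
  nz <- vapply(c(0.01, 0.1, 1, 5),
               function(b) sum(solve_l1(Gb, yb, beta = b) == 0), numeric(1))
  expect_true(all(diff(nz) >= 0))
})

test_that("all three solvers coincide without effective regularization", {
  set.seed(12)
  G <- matrix(rnorm(90), 30, 3)
  Y <- matrix(rnorm(60), 30, 2)
  p1 <- solve_pinv(G, Y)
  p2 <- solve_ridge_closed_form(G, Y, 1e10)
  p3 <- solve_l1(G, Y, 1e-8)
  expect_lt(norm(p1 - p2, "F"), 1e-5)
  expect_lt(norm(p1 - p3, "F"), 1e-4)
})

test_that("ELM interpolates training data when the system is square", {
  set.seed(14)
  fs <- make_blobs(5, seed = 14)
  fit <- elm(fs, L = 10, solver = "pinv", seed = 2)
  expect_identical(predict(fit, fs$x), fs$labels)
})

test_that("ELM classifies separable blobs and is deterministic", {
  accs <- vapply(1:10, function(s) {
    tr <- make_blobs(30, seed = s)
    te <- make_blobs(50, seed = 500 + s)
    fit <- elm_fit_predict(tr, te, L = 200, beta = 0.05, solver = "ridge",
                           seed = s)
    mean(fit$labels == te$labels)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)

  tr <- make_blobs(20, seed = 3)
  te <- make_blobs(20, seed = 4)
  a <- elm_fit_predict(tr, te, L = 100, seed = 9)
  b <- elm_fit_predict(tr, te, L = 100, seed = 9)
  expect_identical(a$scores, b$scores)
})

test_that("ridge regularization reduces accuracy variance vs pseudoinverse", {
  # the instability under test is the ELM's own: the random hidden layer.
  # Fix one noisy dataset (hidden layer wider than the sample count, so the
  # pseudoinverse interpolates noise) and vary only the hidden-layer seed.
  set.seed(1)
  n <- 30
  y <- rep(0:1, each = n / 2)
  x <- cbind(y + rnorm(n, sd = 0.8), matrix(rnorm(n * 9), n, 9))
  yt <- rep(0:1, each = 50)
  xt <- cbind(yt + rnorm(100, sd = 0.8), matrix(rnorm(100 * 9), 100, 9))
  acc <- function(solver) {
    vapply(1:20, function(s) {
      fit <- elm_fit_predict(feature_set(x, labels = y), xt, L = 120,
                             beta = 0.05, solver = solver, seed = s)
      mean(fit$labels == yt)
    }, numeric(1))
  }
  expect_lte(sd(acc("ridge")), sd(acc("pinv")))
})
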