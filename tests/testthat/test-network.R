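test_that("model construction exposes the declared structure", {
  m <- build_model(n_sources = 3, seed = 1)
  expect_length(m$params$specific, 3L)
  expect_length(m$params$pred, 3L)
  expect_equal(dim(m$params$common$c1$W), c(3, 3, 1, 16))
  expect_equal(dim(m$params$common$c2$W), c(3, 3, 16, 32))
  # specific stack: 1x1 -> 3x3 -> 1x1 with the configured widths
  expect_equal(dim(m$params$specific[[1]]$p1$W), c(32, 16))
  expect_equal(dim(m$params$specific[[1]]$c2$W), c(3, 3, 16, 16))
  expect_equal(dim(m$params$specific[[1]]$p3$W), c(16, 8))
  expect_gt(m$n_parameters, 0)

  m1 <- build_model(n_sources = 1, seed = 1)
  expect_length(m1$params$specific, 1L)

  expect_error(backbone_spec("resnet50"), "pretrained")
})

test_that("forward pass is bit-identical across same-seed constructions", {
  d <- tiny_domains(5, n_sources = 1)
  ma <- tiny_model(n_sources = 1, seed = 42)
  mb <- tiny_model(n_sources = 1, seed = 42)
  fa <- extract_deep_features(ma, d[[1]])
  fb <- extract_deep_features(mb, d[[1]])
  expect_identical(fa$x, fb$x)
})

test_that("alpha schedule matches its closed forms", {
  expect_equal(alpha_schedule(0, 10, "exp_clamped"), 1.0)
  expect_equal(alpha_schedule(1, 10, "exp_clamped"), 0.0) # clamped
  expect_equal(alpha_schedule(0.02, 10, "exp_clamped"),
               2 * exp(-0.2) - 1, tolerance = 1e-12)
  expect_equal(alpha_schedule(0, 10, "progressive"), 0.0)
  expect_equal(alpha_schedule(0.5, 10, "progressive"),
               2 / (1 + exp(-5)) - 1, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(alpha_schedule(p, 10) >= 0 & alpha_schedule(p, 10) <= 1))
})

test_that("ensemble prediction averages softmax outputs and is order-invariant", {
  ep <- ensemble_predict(list(c(1, 0), c(0, 1), c(0.5, 0.5)))
  expect_equal(drop(ep$averaged), c(0.5, 0.5))

  set.seed(3)
  probs <- lapply(1:3, function(i) {
    z <- matrix(runif(10), 5, 2); z / rowSums(z)
  })
  ep2 <- ensemble_predict(probs)
  expect_equal(ep2$averaged, (probs[[1]] + probs[[2]] + probs[[3]]) / 3,
               tolerance = 1e-12)
  ep3 <- ensemble_predict(probs[c(3, 1, 2)])
  expect_equal(ep2$averaged, ep3$averaged, tolerance = 1e-12)

  # linear predictors on feature streams
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  ep4 <- ensemble_predict(list(matrix(c(5, 0), 1), matrix(c(0, 5), 1)),
                          predictors = list(list(W = W, b = c(0, 0)),
                                            list(W = W, b = c(0, 0))))
  expect_equal(drop(ep4$averaged), c(0.5, 0.5), tolerance = 1e-6)

  expect_error(ensemble_predict(list(c(1, 0)), predictors = list()), "length")
  expect_error(ensemble_predict(list(c(2, 0))), "probability")
})

test_that("task loss is the mean negative log-likelihood of the ensemble", {
  expect_equal(task_loss(matrix(c(1, 0), 1), 0L), 0, tolerance = 1e-9)
  expect_equal(task_loss(matrix(c(0.5, 0.5), 1), 1L), log(2),
               tolerance = 1e-12)
  set.seed(4)
  p <- matrix(runif(20), 10, 2); p <- p / rowSums(p)
  y <- rbinom(10, 1, 0.5)
  expect_equal(task_loss(p, y),
               -mean(log(p[cbind(1:10, y + 1)])), tolerance = 1e-12)
  # floored at 1e-12 rather than -log(0)
  expect_lt(task_loss(matrix(c(1, 0), 1), 1L), 28)
})

test_that("training is reproducible and the alpha=0 ablation reduces to task loss", {
  doms <- tiny_domains(7)
  m <- tiny_model(seed = 7)
  cfg <- training_config(batch_size = 6, iterations = 30, seed = 9)
  tr1 <- train_msnet(m, doms[-1], doms[[1]], cfg)
  tr2 <- train_msnet(m, doms[-1], doms[[1]], cfg)
  expect_identical(tr1$history, tr2$history)
  expect_equal(tr1$history$l_total,
               tr1$history$alpha * tr1$history$l_mmd + tr1$history$l_task,
               tolerance = 1e-12)

  cfg0 <- training_config(batch_size = 6, iterations = 10, seed = 9,
                          alpha_override = 0)
  tr0 <- train_msnet(m, doms[-1], doms[[1]], cfg0)
  expect_true(all(tr0$history$alpha == 0))
  expect_equal(tr0$history$l_total, tr0$history$l_task, tolerance = 1e-12)
  expect_true(all(is.finite(tr0$history$l_mmd)))
})

test_that("an unlabeled target trains on pseudo-labels with no task loss", {
  doms <- tiny_domains(25)
  tgt <- doms[[1]]
  tgt$labels <- NULL
  m <- tiny_model(seed = 6)
  cfg <- training_config(batch_size = 6, iterations = 8, seed = 4,
                         alpha_mode = "progressive")
  tr <- train_msnet(m, doms[-1], tgt, cfg)
  expect_true(all(tr$history$l_task == 0))
  expect_equal(tr$history$l_total, tr$history$alpha * tr$history$l_mmd,
               tolerance = 1e-12)
  expect_true(all(is.finite(tr$history$l_mmd)))
})

test_that("a class missing from a domain is reported by name", {
  doms <- tiny_domains(8)
  bad <- doms[[2]]
  bad$labels <- rep(0L, length(bad$labels))
  bad$domain_id <- "S_bad"
  m <- tiny_model(seed = 2)
  expect_error(
    train_msnet(m, list(bad, doms[[3]], doms[[4]]), doms[[1]],
                training_config(batch_size = 6, iterations = 5)),
    "S_bad")
})

test_that("the divergence loss falls on no-shift domains when weighted", {
  doms <- tiny_domains(10, preset = "null", n_per_class = 12,
                       n_target_per_class = 12)
  m <- tiny_model(seed = 11)
  cfg <- training_config(batch_size = 8, iterations = 60, seed = 13,
                         alpha_mode = "progressive")
  tr <- train_msnet(m, doms[-1], doms[[1]], cfg)
  h <- tr$history
  early <- mean(h$l_mmd[1:10])
  late <- mean(h$l_mmd[51:60])
  expect_lt(late, early)
  expect_lt(late, 1.0)
})

test_that("total loss trends downward on separable data", {
  doms <- tiny_domains(15, noise_sd = 0.1, n_target_per_class = 12)
  m <- tiny_model(seed = 3)
  cfg <- training_config(batch_size = 8, iterations = 120, seed = 5)
  tr <- train_msnet(m, doms[-1], doms[[1]], cfg)
  h <- tr$history$l_total
  expect_lt(mean(tail(h, 30)), mean(head(h, 30)))
})

test_that("deep-feature export follows the channel-count formula", {
  # reference widths: 16 + 32 common, 8 per specific stream, 3 streams -> 72
  d <- gen_preset_image_domains("null", n_per_class = 3, image_size = 32,
                                n_sources = 3, seed = 2)
  m <- build_model(n_sources = 3, seed = 2)
  f <- extract_deep_features(m, d[[1]])
  expect_equal(ncol(f$x), 48 + 24)
  expect_true(all(grepl("^(common[12]|specific[123])_", colnames(f$x))))

  # n_total = c1 + c2 + n_sources * s3 for arbitrary widths
  m2 <- tiny_model(n_sources = 2)
  d2 <- tiny_domains(3, n_sources = 2, n_per_class = 3, n_target_per_class = 3)
  f2 <- extract_deep_features(m2, d2[[1]])
  expect_equal(ncol(f2$x), 4 + 8 + 2 * 4)

  # determinism: the same image yields identical rows
  dup <- d2[[1]]
  dup$images <- dup$images[, , c(1, 1, 2), drop = FALSE]
  dup$labels <- dup$labels[c(1, 1, 2)]
  fd <- extract_deep_features(m2, dup)
  expect_identical(fd$x[1, ], fd$x[2, ])
  expect_equal(nrow(f2$x), dim(d2[[1]]$images)[3])
})

test_that("batch divergence gradients agree with finite differences", {
  set.seed(41)
  Gs <- matrix(rnorm(24), 6, 4)
  Gt <- matrix(rnorm(24, 0.4), 6, 4)
  ys <- rep(0:1, 3); yt <- rep(0:1, 3)
  ks <- kernel_spec(1.2)
  pd <- mselm:::pair_divergence_batch(Gs, ys, Gt, yt, ks)
  eps <- 1e-6
  # gradient treats mu, sigma and the Wasserstein weights as per-batch
  # constants, so compare against the frozen-weight recombination
  frozen <- function(S, T_) {
    mh <- mmd_squared(S, T_, ks)
    mc <- sum(vapply(0:1, function(l)
      mmd_squared(S[ys == l, , drop = FALSE], T_[yt == l, , drop = FALSE], ks),
      numeric(1)))
    (1 - pd$report$mu) * mh + pd$report$mu * mc
  }
  for (k in 1:6) {
    i <- sample(6, 1); j <- sample(4, 1)
    Sp <- Gs; Sp[i, j] <- Sp[i, j] + eps
    expect_equal((frozen(Sp, Gt) - frozen(Gs, Gt)) / eps, pd$dS[i, j],
                 tolerance = 1e-4)
    Tp <- Gt; Tp[i, j] <- Tp[i, j] + eps
    expect_equal((frozen(Gs, Tp) - frozen(Gs, Gt)) / eps, pd$dT[i, j],
                 tolerance = 1e-4)
  }
})

test_that("single-head (no-ensemble) training only trains the first predictor", {
  doms <- tiny_domains(19)
  m <- tiny_model(seed = 23)
  cfg <- training_config(batch_size = 6, iterations = 15, seed = 2,
                         ensemble = FALSE, alpha_override = 0,
                         weight_decay = 0)
  tr <- train_msnet(m, doms[-1], doms[[1]], cfg)
  expect_false(identical(tr$params$pred[[1]]$W, m$params$pred[[1]]$W))
  expect_identical(tr$params$pred[[2]]$W, m$params$pred[[2]]$W)
  expect_identical(tr$params$pred[[3]]$W, m$params$pred[[3]]$W)
})
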