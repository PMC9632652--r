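# Independent oracles used across the suite. These are written as literal,
# loop-level evaluations of the defining formulas, deliberately sharing no
# code with the package internals they check.

# squared MMD by literal triple summation of the expanded kernel form
oracle_mmd <- function(Xs, Xt, sigma) {
  k <- function(x, y) exp(-sum((x - y)^2) / (2 * sigma^2))
  n <- nrow(Xs); m <- nrow(Xt)
  s1 <- 0; for (i in 1:n) for (j in 1:n) s1 <- s1 + k(Xs[i, ], Xs[j, ])
  s2 <- 0; for (i in 1:n) for (j in 1:m) s2 <- s2 + k(Xs[i, ], Xt[j, ])
  s3 <- 0; for (i in 1:m) for (j in 1:m) s3 <- s3 + k(Xt[i, ], Xt[j, ])
  s1 / n^2 - 2 * s2 / (n * m) + s3 / m^2
}

# exact 1-D Wasserstein-1 between uniform empirical measures (mass merge)
oracle_w1_1d <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- length(a); m <- length(b)
  wa <- rep(1 / n, n); wb <- rep(1 / m, m)
  i <- 1; j <- 1; cost <- 0
  while (i <= n && j <= m) {
    f <- min(wa[i], wb[j])
    cost <- cost + f * abs(a[i] - b[j])
    wa[i] <- wa[i] - f; wb[j] <- wb[j] - f
    if (wa[i] <= 1e-15) i <- i + 1
    if (j <= m && wb[j] <= 1e-15) j <- j + 1
  }
  cost
}

# exact equal-size Wasserstein by brute-force assignment over permutations
oracle_w1_assignment <- function(A, B) {
  n <- nrow(A)
  D <- as.matrix(stats::dist(rbind(A, B)))[1:n, (n + 1):(2 * n), drop = FALSE]
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) mean(D[cbind(seq_len(n), p)]), numeric(1)))
}

# AUC as the normalized pairwise Mann-Whitney U statistic (ties = 1/2)
oracle_auc <- function(truth, scores, positive = 1L) {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# lasso by plain proximal gradient (ISTA), run to tight tolerance
oracle_lasso_pg <- function(G, y, beta, tol = 1e-10, max_iter = 2e5) {
  L <- max(eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values)
  w <- numeric(ncol(G))
  st <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(max_iter)) {
    g <- drop(crossprod(G, G %*% w - y))
    w_new <- st(w - g / L, beta / L)
    if (max(abs(w_new - w)) < tol) return(w_new)
    w <- w_new
  }
  w
}

# greedy mRMR oracle using entropy identities, recomputing everything per step
oracle_mrmr <- function(X, y, k, bins = 10L) {
  disc <- function(v) {
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE, type = 7))
    if (length(qs) < 2L) return(rep(1L, length(v)))
    as.integer(cut(v, qs, include.lowest = TRUE))
  }
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  mi <- function(a, b) H(a) + H(b) - H(paste(a, b))
  D <- apply(X, 2, disc)
  rel <- apply(D, 2, function(f) mi(f, y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    best <- -Inf; pick <- NA_integer_
    for (f in seq_len(ncol(X))) {
      if (f %in% sel) next
      crit <- if (length(sel) == 0L) rel[f]
              else rel[f] - mean(vapply(sel, function(s) mi(D[, f], D[, s]),
                                        numeric(1)))
      if (crit > best + 1e-12) { best <- crit; pick <- f }
    }
    sel <- c(sel, pick)
  }
  sel
}

# small linearly separable 2-class blobs in 2-D
make_blobs <- function(n_per_class, seed, sep = 3, noise = 0.6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class, 0, noise), ncol = 2),
             matrix(rnorm(2 * n_per_class, sep, noise), ncol = 2))
  feature_set(x, labels = rep(0:1, each = n_per_class), domain_id = "blobs")
}

# small fast image domains for network tests (16x16 keeps training cheap)
tiny_domains <- function(seed, n_sources = 3L, preset = "mixed",
                         n_per_class = 16L, n_target_per_class = 8L,
                         image_size = 16L, noise_sd = 0.2) {
  gen_preset_image_domains(preset, n_per_class = n_per_class,
                           image_size = image_size, n_sources = n_sources,
                           n_target_per_class = n_target_per_class,
                           noise_sd = noise_sd, seed = seed)
}

tiny_model <- function(n_sources = 3L, seed = 1L, image_size = 16L) {
  build_model(backbone_spec(input_shape = c(1L, image_size, image_size),
                            channels = c(4L, 8L)),
              specific_spec(c(4L, 4L, 4L)),
              n_sources = n_sources, seed = seed)
}
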