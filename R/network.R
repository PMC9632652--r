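#' Backbone and specific-extractor specifications
#'
#' `backbone_spec()` describes the common feature extractor shared by all
#' domains. The tested backbone is `"tiny_cnn"`: two 3x3 convolution stages
#' (leaky-ReLU + 2x2 average pooling each) whose channel widths are configurable
#' and which is always constructible offline. `"resnet50"` is accepted as a
#' declared layout but requires externally supplied pretrained weights and
#' raises a configuration error when requested with `pretrained = TRUE` and
#' no weights are available (always, in this package).
#'
#' `specific_spec()` describes the per-pair domain-specific extractor: a
#' fixed three-stage 1x1 -> 3x3 -> 1x1 convolution stack with configurable
#' channel widths.
#'
#' @param kind `"tiny_cnn"` or `"resnet50"`.
#' @param input_shape integer vector (channels, height, width).
#' @param pretrained logical; pretrained weights are not bundled.
#' @param channels two channel widths for the tiny CNN stages.
#' @return a `backbone_spec` / `specific_spec` object.
#' @export
backbone_spec <- function(kind = c("tiny_cnn", "resnet50"),
                          input_shape = c(1L, 32L, 32L),
                          pretrained = FALSE,
                          channels = c(16L, 32L)) {
  kind <- match.arg(kind)
  if (kind == "resnet50")
    stop(paste("the resnet50 backbone requires externally supplied",
               "pretrained weights, which are not bundled; use kind =",
               "\"tiny_cnn\""), call. = FALSE)
  stopifnot(length(input_shape) == 3L, input_shape[1] == 1L,
            input_shape[2] >= 16L, input_shape[2] %% 4L == 0L,
            input_shape[2] == input_shape[3], length(channels) == 2L)
  structure(list(kind = kind, input_shape = as.integer(input_shape),
                 pretrained = isTRUE(pretrained),
                 channels = as.integer(channels)),
            class = "backbone_spec")
}

#' @rdname backbone_spec
#' @param out_channels three channel widths for the 1x1, 3x3, 1x1 stages.
#' @export
specific_spec <- function(out_channels = c(16L, 16L, 8L)) {
  stopifnot(length(out_channels) == 3L, all(out_channels >= 1L))
  structure(list(out_channels = as.integer(out_channels)),
            class = "specific_spec")
}

#' Build the multisource transfer feature-extraction network
#'
#' Assembles one shared common extractor, `n_sources` domain-specific
#' extractors (one per source-target pair) and `n_sources` softmax
#' sub-predictors, with seeded He-scaled random initialization. With
#' `n_sources = 1` the model degenerates to single-source adaptation.
#'
#' @param backbone a [backbone_spec()].
#' @param specific a [specific_spec()].
#' @param n_sources number of source domains.
#' @param n_classes number of target classes.
#' @param seed integer seed for the initialization.
#' @return object of class `msnet` (untrained).
#' @export
build_model <- function(backbone = backbone_spec(),
                        specific = specific_spec(),
                        n_sources = 3L, n_classes = 2L, seed = 1L) {
  stopifnot(inherits(backbone, "backbone_spec"),
            inherits(specific, "specific_spec"), n_sources >= 1L)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  c1 <- backbone$channels[1]; c2 <- backbone$channels[2]
  s <- specific$out_channels
  he_conv <- function(k, cin, cout)
    array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  he_mat <- function(cin, cout)
    matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  params <- list(
    common = list(
      c1 = list(W = he_conv(3, backbone$input_shape[1], c1), b = numeric(c1)),
      c2 = list(W = he_conv(3, c1, c2), b = numeric(c2))),
    specific = lapply(seq_len(n_sources), function(j) list(
      p1 = list(W = he_mat(c2, s[1]), b = numeric(s[1])),
      c2 = list(W = he_conv(3, s[1], s[2]), b = numeric(s[2])),
      p3 = list(W = he_mat(s[2], s[3]), b = numeric(s[3])))),
    pred = lapply(seq_len(n_sources), function(j) list(
      W = matrix(stats::rnorm(s[3] * n_classes, sd = sqrt(1 / s[3])),
                 s[3], n_classes),
      b = numeric(n_classes))))
  n_par <- sum(vapply(rapply(params, length, how = "unlist"), sum, numeric(1)))
  structure(list(backbone = backbone, specific_spec = specific,
                 n_sources = as.integer(n_sources),
                 n_classes = as.integer(n_classes),
                 params = params, n_parameters = n_par,
                 seed = as.integer(seed), trained = FALSE),
            class = "msnet")
}

#' @export
print.msnet <- function(x, ...) {
  cat(sprintf(paste0("Multisource transfer network (%s, %dx%d input): ",
                     "%d source streams, %d parameters%s\n"),
              x$backbone$kind, x$backbone$input_shape[2],
              x$backbone$input_shape[3], x$n_sources, x$n_parameters,
              if (x$trained) " [trained]" else ""))
  cat(sprintf("  common channels %s | specific stages %s | %d-class softmax x %d\n",
              paste(x$backbone$channels, collapse = "/"),
              paste(x$specific_spec$out_channels, collapse = "/"),
              x$n_classes, x$n_sources))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

common_forward <- function(pc, X0, H, W, N) {
  a1 <- conv3x3_fwd(X0, H, W, N, pc$c1$W, pc$c1$b, relu = TRUE)
  H1 <- H %/% 2L; W1 <- W %/% 2L
  p1 <- avgpool2_fwd(a1, H, W, N)
  a2 <- conv3x3_fwd(p1, H1, W1, N, pc$c2$W, pc$c2$b, relu = TRUE)
  H2 <- H1 %/% 2L; W2 <- W1 %/% 2L
  p2 <- avgpool2_fwd(a2, H1, W1, N)
  list(out = p2, H2 = H2, W2 = W2,
       cache = list(X0 = X0, a1 = a1, p1 = p1, a2 = a2, H = H, W = W, N = N))
}

common_backward <- function(pc, fw, dOut) {
  cc <- fw$cache
  H <- cc$H; W <- cc$W; N <- cc$N
  H1 <- H %/% 2L; W1 <- W %/% 2L
  da2 <- .relu_bwd(avgpool2_bwd(dOut, H1, W1, N, ncol(dOut)), cc$a2, .leak)
  g2 <- conv3x3_bwd(da2, cc$p1, H1, W1, N, pc$c2$W)
  da1 <- .relu_bwd(avgpool2_bwd(g2$dX, H, W, N, ncol(g2$dX)), cc$a1, .leak)
  g1 <- conv3x3_bwd(da1, cc$X0, H, W, N, pc$c1$W)
  list(c1 = list(W = g1$dW, b = g1$db), c2 = list(W = g2$dW, b = g2$db))
}

specific_forward <- function(ps, F0, H, W, N) {
  s1 <- relu_fwd(conv1x1_fwd(F0, ps$p1$W, ps$p1$b))
  s2 <- conv3x3_fwd(s1, H, W, N, ps$c2$W, ps$c2$b, relu = TRUE)
  s3 <- relu_fwd(conv1x1_fwd(s2, ps$p3$W, ps$p3$b))
  g <- gap_fwd(s3, H, W, N)
  list(gap = g, s3 = s3,
       cache = list(F0 = F0, s1 = s1, s2 = s2, s3 = s3, H = H, W = W, N = N))
}

specific_backward <- function(ps, fw, dGap) {
  cc <- fw$cache
  H <- cc$H; W <- cc$W; N <- cc$N
  ds3 <- .relu_bwd(gap_bwd(dGap, H, W, N), cc$s3, .leak)
  g3 <- conv1x1_bwd(ds3, cc$s2, ps$p3$W)
  ds2 <- .relu_bwd(g3$dX, cc$s2, .leak)
  g2 <- conv3x3_bwd(ds2, cc$s1, H, W, N, ps$c2$W)
  ds1 <- .relu_bwd(g2$dX, cc$s1, .leak)
  g1 <- conv1x1_bwd(ds1, cc$F0, ps$p1$W)
  list(dF = g1$dX,
       grads = list(p1 = list(W = g1$dW, b = g1$db),
                    c2 = list(W = g2$dW, b = g2$db),
                    p3 = list(W = g3$dW, b = g3$db)))
}

images_to_mat <- function(images) {
  d <- dim(images)
  list(X = matrix(as.vector(images), d[1] * d[2] * d[3], 1),
       H = d[1], W = d[2], N = d[3])
}

# ---- schedule, ensemble, task loss ----------------------------------------

#' Weighting schedule for the divergence loss
#'
#' Returns the weight `alpha` applied to the MMD loss at a given point of
#' training, as a function of normalized progress `iter_progress` =
#' iteration / total iterations:
#' * `"exp_clamped"` (default): `max(0, 2 exp(-theta p) - 1)` — starts at 1
#'   and decays to 0 (reaching it at `p = log(2)/theta`, about 7% of
#'   training for `theta = 10`); the raw formula would go negative, which
#'   would reward divergence, so it is clamped at 0.
#' * `"progressive"`: the standard ramp `2 / (1 + exp(-theta p)) - 1`,
#'   increasing from 0 towards 1.
#'
#' @param iter_progress nonnegative progress, usually in \[0, 1\].
#' @param theta positive decay rate (reference value 10).
#' @param mode `"exp_clamped"` or `"progressive"`.
#' @return weight in \[0, 1\].
#' @export
alpha_schedule <- function(iter_progress, theta = 10,
                           mode = c("exp_clamped", "progressive")) {
  mode <- match.arg(mode)
  stopifnot(theta > 0, iter_progress >= 0)
  if (mode == "exp_clamped") pmax(0, 2 * exp(-theta * iter_progress) - 1)
  else 2 / (1 + exp(-theta * iter_progress)) - 1
}

#' Ensemble prediction by sub-predictor averaging
#'
#' The final prediction is the arithmetic mean of the per-predictor softmax
#' outputs. Either pass raw feature streams plus linear softmax predictors
#' (`list(W, b)` each), or pass already-computed probability matrices with
#' `predictors = NULL`.
#'
#' @param streams list (one per predictor) of feature matrices, probability
#'   matrices, or probability vectors.
#' @param predictors optional list of predictors, each `list(W, b)` or a
#'   function mapping a feature matrix to class probabilities.
#' @return object of class `ensemble_prediction` with `per_predictor` (list
#'   of probability matrices) and `averaged`.
#' @examples
#' ensemble_predict(list(c(1, 0), c(0, 1), c(0.5, 0.5)))$averaged
#' @export
ensemble_predict <- function(streams, predictors = NULL) {
  if (length(streams) < 1L) stop("`streams` must be nonempty", call. = FALSE)
  if (!is.null(predictors) && length(predictors) != length(streams))
    stop("`streams` and `predictors` must have equal length", call. = FALSE)
  per <- lapply(seq_along(streams), function(j) {
    x <- streams[[j]]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (is.null(predictors)) {
      if (any(x < 0) || any(abs(rowSums(x) - 1) > 1e-6))
        stop("without predictors, streams must be probability rows", call. = FALSE)
      x
    } else {
      p <- predictors[[j]]
      if (is.function(p)) p(x)
      else softmax_rows(sweep(x %*% p$W, 2, p$b, "+"))
    }
  })
  structure(list(per_predictor = per, averaged = Reduce(`+`, per) / length(per)),
            class = "ensemble_prediction")
}

#' Cross-entropy task loss
#'
#' Mean negative log-probability assigned to the true class by the averaged
#' ensemble prediction. Probabilities are floored at 1e-12 before the log.
#'
#' @param prediction an `ensemble_prediction`, or a probability matrix with
#'   one row per sample.
#' @param labels integer class indices in \{0, ..., n_classes - 1\}.
#' @return nonnegative scalar loss.
#' @export
task_loss <- function(prediction, labels) {
  p <- if (inherits(prediction, "ensemble_prediction")) prediction$averaged
       else prediction
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(p), all(labels >= 0), all(labels < ncol(p)))
  pt <- p[cbind(seq_len(nrow(p)), labels + 1L)]
  -mean(log(pmax(pt, 1e-12)))
}

# ---- divergence on batch features with gradient ----------------------------

# V-statistic MMD gradient wrt both sample matrices at fixed sigma grid
mmd_grad <- function(S, T_, sigma, n_kernels = 1L) {
  n <- nrow(S); m <- nrow(T_)
  sigs <- sigma_grid(sigma, n_kernels)
  dS <- matrix(0, n, ncol(S)); dT <- matrix(0, m, ncol(T_))
  for (sg in sigs) {
    Kss <- kernel_matrix(S, S, sg)
    Kst <- kernel_matrix(S, T_, sg)
    Ktt <- kernel_matrix(T_, T_, sg)
    f <- -2 / sg^2
    dS <- dS + f * ((rowSums(Kss) * S - Kss %*% S) / n^2 -
                    (rowSums(Kst) * S - Kst %*% T_) / (n * m))
    dT <- dT + f * ((rowSums(Ktt) * T_ - Ktt %*% T_) / m^2 -
                    (colSums(Kst) * T_ - crossprod(Kst, S)) / (n * m))
  }
  list(dS = dS / length(sigs), dT = dT / length(sigs))
}

# pooled per-batch standardization of the pair's features (a parameter-free
# normalization layer). The divergence is computed on standardized features:
# without this, the scale-free MMD (median bandwidth shrinks with the
# features) admits a degenerate minimizer where the extractor collapses all
# outputs to a constant. Returns the standardized stack and a pullback for
# the gradient (full batch-norm backward, no learnable affine).
standardize_pair <- function(Gs, Gt, eps = 1e-8) {
  X <- rbind(Gs, Gt)
  R <- nrow(X)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  sd_ <- sqrt(colSums(xc^2) / R + eps)
  Z <- sweep(xc, 2, sd_, "/")
  pullback <- function(dZ) {
    t1 <- sweep(dZ, 2, colMeans(dZ))
    t2 <- sweep(Z, 2, colMeans(dZ * Z), "*")
    sweep(t1 - t2, 2, sd_, "/")
  }
  list(Zs = Z[seq_len(nrow(Gs)), , drop = FALSE],
       Zt = Z[nrow(Gs) + seq_len(nrow(Gt)), , drop = FALSE],
       pullback = pullback)
}

# full per-pair divergence + gradient of the combined value wrt the batch
# feature matrices; mu, sigma and the Wasserstein weights are treated as
# constants of the current batch (no gradient flows through them)
pair_divergence_batch <- function(Gs, ys, Gt, yt, spec) {
  src <- feature_set(Gs, labels = ys)
  tgt <- feature_set(Gt, labels = yt)
  rep <- pair_divergence(src, tgt, spec)
  shared <- as.integer(names(rep$mmd_conditional_by_class))
  gm <- mmd_grad(Gs, Gt, rep$sigma, spec$n_kernels)
  dS <- (1 - rep$mu) * gm$dS
  dT <- (1 - rep$mu) * gm$dT
  for (l in shared) {
    si <- which(ys == l); ti <- which(yt == l)
    gc <- mmd_grad(Gs[si, , drop = FALSE], Gt[ti, , drop = FALSE],
                   rep$sigma, spec$n_kernels)
    dS[si, ] <- dS[si, ] + rep$mu * gc$dS
    dT[ti, ] <- dT[ti, ] + rep$mu * gc$dT
  }
  list(report = rep, dS = dS, dT = dT)
}

# ---- training configuration and loop ---------------------------------------

#' Training configuration for the multisource network
#'
#' Defaults follow the reference training recipe: SGD with momentum 0.9 and
#' weight decay 1e-4, learning rate 0.001 for the common extractor and 0.01
#' for the domain-specific extractors and sub-predictors, batch size 32 per
#' domain, up to 2000 iterations, divergence-weight decay rate `theta = 10`.
#' Tests and examples scale `iterations` and `batch_size` down.
#'
#' @param lr_common,lr_specific learning rates of the two parameter groups.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size per-domain mini-batch size (class-balanced halves).
#' @param iterations number of SGD steps.
#' @param theta decay rate of the [alpha_schedule()].
#' @param alpha_mode schedule mode.
#' @param alpha_override optional fixed alpha (e.g. 0 to ablate the
#'   divergence loss); `NULL` uses the schedule.
#' @param ensemble if `FALSE`, only the first sub-predictor carries the task
#'   loss and the ensemble average is not used (the "no ensemble classifier"
#'   ablation); the other streams still train through the divergence loss.
#' @param lr_decay learning-rate decay applied to both groups as a function
#'   of progress p: `"inv"` (default) is the inverse-power annealing
#'   `lr0 / (1 + 10 p)^0.75` customary for ramped domain-adaptation
#'   training; `"cosine"` is half-cosine annealing to 0; `"none"` keeps the
#'   rates constant. The configured rates are initial rates.
#' @param seed integer seed controlling all training randomness.
#' @return object of class `training_config`.
#' @export
training_config <- function(lr_common = 0.001, lr_specific = 0.01,
                            momentum = 0.9, weight_decay = 1e-4,
                            batch_size = 32L, iterations = 2000L,
                            theta = 10,
                            alpha_mode = c("exp_clamped", "progressive"),
                            alpha_override = NULL, ensemble = TRUE,
                            lr_decay = c("inv", "cosine", "none"),
                            seed = 1L) {
  alpha_mode <- match.arg(alpha_mode)
  lr_decay <- match.arg(lr_decay)
  stopifnot(lr_common > 0, lr_specific > 0, momentum >= 0, weight_decay >= 0,
            batch_size >= 2L, iterations >= 1L, theta > 0)
  structure(list(lr_common = lr_common, lr_specific = lr_specific,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), theta = theta,
                 alpha_mode = alpha_mode, alpha_override = alpha_override,
                 ensemble = isTRUE(ensemble),
                 lr_decay = lr_decay, seed = as.integer(seed)),
            class = "training_config")
}

lr_factor <- function(progress, decay) {
  switch(decay,
         none = 1,
         inv = 1 / (1 + 10 * progress)^0.75,
         cosine = 0.5 * (1 + cos(pi * progress)))
}

#' Train the multisource transfer network
#'
#' Each iteration draws one class-balanced mini-batch per domain, passes all
#' domains through the common extractor, routes each source-target pair
#' through its own specific extractor, and minimizes
#' `l_total = alpha * l_MMD + l_task`, where `l_MMD` averages the
#' Wasserstein-weighted marginal/conditional MMD over the pairs and
#' `l_task` is the cross-entropy of the ensemble prediction on the target
#' batch. One SGD step per iteration with the two learning-rate groups.
#' Fully reproducible from `config$seed`.
#'
#' When the target set carries no labels, the conditional divergence uses
#' pseudo-labels (arg-max of the current ensemble prediction) and the task
#' loss is dropped from the objective.
#'
#' @param model an untrained [build_model()] network.
#' @param sources list of `image_set`s, one per source stream.
#' @param target labeled `image_set`.
#' @param config a [training_config()].
#' @param spec a [kernel_spec()] for the MMD terms.
#' @return the trained `msnet`, with a `history` data frame (per-iteration
#'   alpha, l_mmd, l_task, l_total and per-pair mu) and `final_divergence`
#'   (last per-pair `divergence_report`s) attached.
#' @export
train_msnet <- function(model, sources, target, config = training_config(),
                        spec = kernel_spec()) {
  stopifnot(inherits(model, "msnet"), inherits(config, "training_config"))
  if (!is.list(sources) || length(sources) != model$n_sources)
    stop(sprintf("expected %d source image sets", model$n_sources), call. = FALSE)
  has_target_labels <- !is.null(target$labels)
  B <- config$batch_size
  half <- B %/% 2L
  domains <- c(sources, list(target))
  dn <- length(domains)
  for (d in seq_len(dn)) {
    if (d < dn || has_target_labels) {
      tab <- table(factor(domains[[d]]$labels, levels = 0:1))
      if (any(tab == 0))
        stop(sprintf("domain '%s' is missing class %s; a class-balanced batch cannot be drawn",
                     domains[[d]]$domain_id,
                     paste(names(tab)[tab == 0], collapse = ",")), call. = FALSE)
    }
  }
  H <- dim(target$images)[1]; W <- dim(target$images)[2]
  old <- set_local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  params <- model$params
  vel <- rapply(params, function(x) x * 0, how = "replace")
  iters <- config$iterations
  ns <- model$n_sources
  hist_cols <- c("iter", "alpha", "l_mmd", "l_task", "l_total",
                 paste0("mu_", seq_len(ns)))
  history <- matrix(NA_real_, iters, length(hist_cols),
                    dimnames = list(NULL, hist_cols))
  final_reports <- vector("list", ns)

  draw_batch <- function(dom, labeled = TRUE) {
    if (labeled) {
      unlist(lapply(0:1, function(l) {
        pool <- which(dom$labels == l)
        sample(pool, half, replace = length(pool) < half)
      }))
    } else {
      pool <- seq_along(dom$labels %||% seq_len(dim(dom$images)[3]))
      sample(pool, B, replace = length(pool) < B)
    }
  }

  for (it in seq_len(iters)) {
    alpha <- if (!is.null(config$alpha_override)) config$alpha_override
             else alpha_schedule((it - 1) / iters, config$theta, config$alpha_mode)

    idx <- lapply(seq_len(dn), function(d)
      draw_batch(domains[[d]], labeled = d < dn || has_target_labels))
    yb <- lapply(seq_len(dn), function(d) domains[[d]]$labels[idx[[d]]])
    nb <- lengths(idx)
    stack <- array(unlist(lapply(seq_len(dn), function(d)
      domains[[d]]$images[, , idx[[d]], drop = FALSE])),
      dim = c(H, W, sum(nb)))
    xm <- images_to_mat(stack)
    cf <- common_forward(params$common, xm$X, H, W, xm$N)
    H2 <- cf$H2; W2 <- cf$W2
    sample_off <- cumsum(c(0L, nb))
    dom_rows <- lapply(seq_len(dn), function(d)
      rows_for_samples(H2, W2, sample_off[d] + seq_len(nb[d])))
    t_rows <- dom_rows[[dn]]

    sfw <- vector("list", ns)
    probs <- vector("list", ns)
    for (j in seq_len(ns)) {
      Fj <- rbind(cf$out[dom_rows[[j]], , drop = FALSE],
                  cf$out[t_rows, , drop = FALSE])
      sfw[[j]] <- specific_forward(params$specific[[j]], Fj, H2, W2,
                                   nb[j] + nb[dn])
      gt <- sfw[[j]]$gap[nb[j] + seq_len(nb[dn]), , drop = FALSE]
      probs[[j]] <- softmax_rows(sweep(gt %*% params$pred[[j]]$W, 2,
                                       params$pred[[j]]$b, "+"))
    }
    use_heads <- if (config$ensemble %||% TRUE) seq_len(ns) else 1L
    nheads <- length(use_heads)
    ybar <- Reduce(`+`, probs[use_heads]) / nheads

    y_t <- if (has_target_labels) yb[[dn]] else max.col(ybar) - 1L
    l_task <- if (has_target_labels) task_loss(ybar, y_t) else 0

    # divergence per pair on GAP features
    grads <- rapply(params, function(x) x * 0, how = "replace")
    l_mmd_terms <- numeric(ns)
    for (j in seq_len(ns)) {
      gs <- sfw[[j]]$gap[seq_len(nb[j]), , drop = FALSE]
      gt <- sfw[[j]]$gap[nb[j] + seq_len(nb[dn]), , drop = FALSE]
      std <- standardize_pair(gs, gt)
      pd <- suppressWarnings(
        pair_divergence_batch(std$Zs, yb[[j]], std$Zt, y_t, spec))
      l_mmd_terms[j] <- pd$report$combined
      history[it, paste0("mu_", j)] <- pd$report$mu
      if (it == iters) final_reports[[j]] <- pd$report
      dRaw <- std$pullback(rbind(pd$dS, pd$dT))

      # gradient of ensemble CE wrt predictor-j logits
      dGt <- alpha * dRaw[nb[j] + seq_len(nb[dn]), , drop = FALSE] / ns
      if (has_target_labels && j %in% use_heads) {
        # d l_task / d z_jm = -(1/(k * B * ybar_c)) * p_jc * (1[m=c] - p_jm)
        # over the k heads entering the ensemble average
        ptrue <- pmax(ybar[cbind(seq_len(nb[dn]), y_t + 1L)], 1e-12)
        pjc <- probs[[j]][cbind(seq_len(nb[dn]), y_t + 1L)]
        ind <- matrix(0, nb[dn], model$n_classes)
        ind[cbind(seq_len(nb[dn]), y_t + 1L)] <- 1
        dZ <- -(pjc / (nheads * nb[dn] * ptrue)) * (ind - probs[[j]])
        grads$pred[[j]]$W <- grads$pred[[j]]$W + crossprod(gt, dZ)
        grads$pred[[j]]$b <- grads$pred[[j]]$b + colSums(dZ)
        dGt <- dGt + dZ %*% t(params$pred[[j]]$W)
      }
      dGap <- rbind(alpha * dRaw[seq_len(nb[j]), , drop = FALSE] / ns, dGt)
      sb <- specific_backward(params$specific[[j]], sfw[[j]], dGap)
      grads$specific[[j]] <- add_grads(grads$specific[[j]], sb$grads)
      if (is.null(grads$.dcommon))
        grads$.dcommon <- matrix(0, nrow(cf$out), ncol(cf$out))
      nsrc_rows <- length(dom_rows[[j]])
      grads$.dcommon[dom_rows[[j]], ] <- grads$.dcommon[dom_rows[[j]], ] +
        sb$dF[seq_len(nsrc_rows), , drop = FALSE]
      grads$.dcommon[t_rows, ] <- grads$.dcommon[t_rows, ] +
        sb$dF[nsrc_rows + seq_len(length(t_rows)), , drop = FALSE]
    }
    cb <- common_backward(params$common, cf, grads$.dcommon)
    grads$common <- cb
    grads$.dcommon <- NULL

    l_mmd <- mean(l_mmd_terms)
    history[it, c("iter", "alpha", "l_mmd", "l_task", "l_total")] <-
      c(it, alpha, l_mmd, l_task, alpha * l_mmd + l_task)

    upd <- sgd_step(params, vel, grads, config,
                    lr_factor((it - 1) / iters, config$lr_decay))
    params <- upd$params
    vel <- upd$vel
  }

  model$params <- params
  model$trained <- TRUE
  model$history <- as.data.frame(history)
  model$final_divergence <- final_reports
  model$config <- config
  model
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

# SGD with momentum and decoupled-by-group learning rates (the common
# extractor trains at lr_common, specific extractors and predictors at
# lr_specific); velocity update v <- mom*v + (g + wd*w); w <- w - lr*v.
sgd_step <- function(params, vel, grads, cfg, lrf = 1) {
  upd1 <- function(w, v, g, lr) {
    v <- cfg$momentum * v + g + cfg$weight_decay * w
    list(w = w - lr * v, v = v)
  }
  walk <- function(p, v, g, lr) {
    for (k in seq_along(p)) {
      if (is.list(p[[k]])) {
        r <- walk(p[[k]], v[[k]], g[[k]], lr)
        p[[k]] <- r$p; v[[k]] <- r$v
      } else {
        r <- upd1(p[[k]], v[[k]], g[[k]], lr)
        p[[k]] <- r$w; v[[k]] <- r$v
      }
    }
    list(p = p, v = v)
  }
  rc <- walk(params$common, vel$common, grads$common, lrf * cfg$lr_common)
  rs <- walk(params$specific, vel$specific, grads$specific, lrf * cfg$lr_specific)
  rp <- walk(params$pred, vel$pred, grads$pred, lrf * cfg$lr_specific)
  list(params = list(common = rc$p, specific = rs$p, pred = rp$p),
       vel = list(common = rc$v, specific = rs$v, pred = rp$v))
}

# ---- feature export ---------------------------------------------------------

#' Export pooled deep features from a trained network
#'
#' Concatenates globally average-pooled channel activations from the two
#' common-extractor stages and from each specific extractor's final stage.
#' The feature count is `c1 + c2 + n_sources * s3` and feature names encode
#' the layer of origin (`common1_*`, `common2_*`, `specific<j>_*`).
#'
#' @param model a trained (or at least built) `msnet`.
#' @param images an `image_set`.
#' @return a `feature_set` carrying the image labels, if any.
#' @export
extract_deep_features <- function(model, images) {
  stopifnot(inherits(model, "msnet"), inherits(images, "image_set"))
  xm <- images_to_mat(images$images)
  H <- xm$H; W <- xm$W; N <- xm$N
  pc <- model$params$common
  z1 <- conv3x3_fwd(xm$X, H, W, N, pc$c1$W, pc$c1$b, relu = TRUE)
  g1 <- gap_fwd(z1, H, W, N)
  p1 <- avgpool2_fwd(z1, H, W, N)
  H1 <- H %/% 2L; W1 <- W %/% 2L
  z2 <- conv3x3_fwd(p1, H1, W1, N, pc$c2$W, pc$c2$b, relu = TRUE)
  g2 <- gap_fwd(z2, H1, W1, N)
  p2 <- avgpool2_fwd(z2, H1, W1, N)
  H2 <- H1 %/% 2L; W2 <- W1 %/% 2L
  gs <- lapply(seq_len(model$n_sources), function(j)
    specific_forward(model$params$specific[[j]], p2, H2, W2, N)$gap)
  feats <- do.call(cbind, c(list(g1, g2), gs))
  cn <- c(paste0("common1_c", seq_len(ncol(g1))),
          paste0("common2_c", seq_len(ncol(g2))),
          unlist(lapply(seq_len(model$n_sources), function(j)
            paste0("specific", j, "_c", seq_len(ncol(gs[[j]]))))))
  colnames(feats) <- cn
  feature_set(feats, labels = images$labels, domain_id = images$domain_id)
}

#' Network ensemble prediction for an image set
#'
#' Runs images through the trained network and returns the averaged softmax
#' ensemble prediction over the sub-predictors.
#'
#' @param model a trained `msnet`.
#' @param images an `image_set`.
#' @return an `ensemble_prediction`.
#' @export
msnet_predict <- function(model, images) {
  stopifnot(inherits(model, "msnet"))
  xm <- images_to_mat(images$images)
  cf <- common_forward(model$params$common, xm$X, xm$H, xm$W, xm$N)
  heads <- if (!is.null(model$config) && !isTRUE(model$config$ensemble)) 1L
           else seq_len(model$n_sources)
  streams <- lapply(heads, function(j)
    specific_forward(model$params$specific[[j]], cf$out, cf$H2, cf$W2, xm$N)$gap)
  ensemble_predict(streams, model$params$pred[heads])
}
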