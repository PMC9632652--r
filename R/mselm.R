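#' Fit the full multisource adaptive classification model
#'
#' End-to-end fit of the method on image domains: (1) train the multisource
#' transfer feature-extraction network on three (or `length(sources)`)
#' source domains and one labeled target domain, minimizing
#' `alpha * l_MMD + l_task`; (2) export pooled deep features for the target
#' training set; (3) keep the top `mrmr_fraction` of features by mRMR; (4)
#' fit an extreme learning machine on the selected target features. The
#' returned object predicts new image sets through the same feature path.
#'
#' All randomness fans out from `seed` by fixed offsets (network
#' initialization, training batches, ELM hidden layer), so a fit is fully
#' reproducible.
#'
#' @param sources list of labeled `image_set`s (the source domains).
#' @param target labeled `image_set` (the target training data).
#' @param backbone a [backbone_spec()].
#' @param specific a [specific_spec()].
#' @param config a [training_config()]; its `seed` is overridden by `seed`.
#' @param kernel a [kernel_spec()] for the divergence terms.
#' @param mrmr_fraction fraction of deep features kept by [mrmr_select()].
#' @param mrmr_bins discretization bins for the mutual information.
#' @param hidden ELM hidden-layer size.
#' @param activation ELM activation.
#' @param beta ELM regularization parameter.
#' @param solver ELM output-weight solver (`"ridge"`, `"pinv"`, `"l1"`).
#' @param use_elm if `FALSE`, skip feature export/selection/ELM and predict
#'   with the network's softmax ensemble directly (the end-to-end variant).
#' @param seed integer master seed.
#' @return object of class `mselm` with components `network` (trained
#'   `msnet` including `history`), `selection`, `elm`, `features_train`,
#'   and the configuration pieces.
#' @seealso [predict.mselm()], [run_pipeline()]
#' @export
mselm <- function(sources, target,
                  backbone = backbone_spec(), specific = specific_spec(),
                  config = training_config(), kernel = kernel_spec(),
                  mrmr_fraction = 0.10, mrmr_bins = 10L,
                  hidden = 1000L, activation = "sigmoid", beta = 0.05,
                  solver = c("ridge", "pinv", "l1"),
                  use_elm = TRUE, seed = 1L) {
  solver <- match.arg(solver)
  if (inherits(sources, "image_set")) sources <- list(sources)
  stopifnot(length(sources) >= 1L, inherits(target, "image_set"))
  seed <- as.integer(seed)

  model <- build_model(backbone, specific, n_sources = length(sources),
                       seed = seed + 11L)
  config$seed <- seed + 23L
  model <- train_msnet(model, sources, target, config, kernel)

  selection <- NULL; elm_fit <- NULL; f_train <- NULL
  if (use_elm) {
    f_train <- extract_deep_features(model, target)
    selection <- mrmr_select(f_train, fraction = mrmr_fraction,
                             bins = mrmr_bins)
    x_sel <- f_train$x[, selection$selected_indices, drop = FALSE]
    elm_fit <- elm(x_sel, f_train$labels, L = hidden,
                   activation = activation, beta = beta, solver = solver,
                   seed = seed + 37L)
  }
  structure(list(network = model, selection = selection, elm = elm_fit,
                 features_train = f_train, use_elm = use_elm,
                 mrmr_fraction = mrmr_fraction, seed = seed,
                 n_sources = length(sources),
                 source_ids = vapply(sources, `[[`, "", "domain_id"),
                 target_id = target$domain_id, call = match.call()),
            class = "mselm")
}

#' Predict from a fitted multisource model
#'
#' Runs an image set through the trained feature path. With the ELM head
#' (the default fit), deep features are extracted, reduced to the selected
#' mRMR columns and scored by the ELM; otherwise the network's softmax
#' ensemble is averaged.
#'
#' @param object a fitted `mselm`.
#' @param newdata an `image_set`.
#' @param type `"class"` for hard labels, `"score"` for the ROC score
#'   (class-1 column), `"prob"` for ensemble probabilities (network head
#'   only).
#' @param ... unused.
#' @export
predict.mselm <- function(object, newdata,
                          type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "image_set"))
  if (object$use_elm) {
    f <- extract_deep_features(object$network, newdata)
    x <- f$x[, object$selection$selected_indices, drop = FALSE]
    sc <- predict(object$elm, x, type = "score")
    switch(type,
           class = as.integer(sc[, 2] > sc[, 1]),
           score = sc[, 2],
           prob = stop("probabilities are only available without the ELM head",
                       call. = FALSE))
  } else {
    p <- msnet_predict(object$network, newdata)$averaged
    switch(type,
           class = max.col(p) - 1L,
           score = p[, 2],
           prob = p)
  }
}

#' @export
print.mselm <- function(x, ...) {
  cat(sprintf("Multisource adaptive classifier: %d sources (%s) -> '%s'\n",
              x$n_sources, paste(x$source_ids, collapse = ", "), x$target_id))
  print(x$network)
  if (x$use_elm) {
    cat(sprintf("  mRMR: %d of %d deep features kept (fraction %.3g)\n",
                length(x$selection$selected_indices),
                x$selection$n_features, x$mrmr_fraction))
    print(x$elm)
  } else cat("  end-to-end network ensemble head (no ELM)\n")
  invisible(x)
}

#' @export
summary.mselm <- function(object, ...) {
  h <- object$network$history
  mu_cols <- grep("^mu_", names(h), value = TRUE)
  out <- list(
    iterations = nrow(h),
    final_loss = h[nrow(h), c("l_mmd", "l_task", "l_total")],
    mean_mu = colMeans(h[mu_cols]),
    source_ids = object$source_ids,
    n_features = if (object$use_elm) object$selection$n_features else NA,
    n_selected = if (object$use_elm)
      length(object$selection$selected_indices) else NA,
    solver = if (object$use_elm) object$elm$solver else "ensemble")
  class(out) <- "summary.mselm"
  out
}

#' @export
print.summary.mselm <- function(x, ...) {
  cat(sprintf("Training: %d iterations; final l_mmd %.4f, l_task %.4f, l_total %.4f\n",
              x$iterations, x$final_loss$l_mmd, x$final_loss$l_task,
              x$final_loss$l_total))
  cat("Mean adaptation factor mu per source (training average):\n")
  for (i in seq_along(x$mean_mu))
    cat(sprintf("  %s: %.3f\n", x$source_ids[i], x$mean_mu[i]))
  if (!is.na(x$n_features))
    cat(sprintf("Features: %d selected of %d; ELM solver: %s\n",
                x$n_selected, x$n_features, x$solver))
  invisible(x)
}

#' Plot training history of a fitted multisource model
#'
#' Two panels: the loss components over iterations (task, weighted
#' divergence, total) and the per-source adaptation factor `mu`.
#'
#' @param x a fitted `mselm` (or a trained `msnet`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mselm <- function(x, ...) {
  h <- if (inherits(x, "mselm")) x$network$history else x$history
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::matplot(h$iter, cbind(h$l_task, h$alpha * h$l_mmd, h$l_total),
                    type = "l", lty = 1,
                    col = c("#1b6ca8", "#c1403d", "#444444"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c("task", "alpha x MMD", "total"),
                   lty = 1, col = c("#1b6ca8", "#c1403d", "#444444"),
                   bty = "n", cex = 0.8)
  mu_cols <- grep("^mu_", names(h), value = TRUE)
  graphics::matplot(h$iter, h[mu_cols], type = "l", lty = 1,
                    ylim = c(0, 1), xlab = "iteration", ylab = "mu")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' @export
coef.mselm <- function(object, ...) {
  if (!object$use_elm) stop("no ELM head; coefficients unavailable", call. = FALSE)
  coef(object$elm)
}

#' Evaluate a fitted model on a labeled image set
#'
#' Convenience wrapper combining [predict.mselm()] with
#' [evaluate_predictions()].
#'
#' @param object fitted `mselm`.
#' @param newdata labeled `image_set`.
#' @param positive positive class label.
#' @return an `evaluation_report` with AUC and ROC points.
#' @export
evaluate_mselm <- function(object, newdata, positive = 1L) {
  stopifnot(!is.null(newdata$labels))
  sc <- predict(object, newdata, type = "score")
  cl <- predict(object, newdata, type = "class")
  evaluate_predictions(newdata$labels, sc, predicted = cl,
                       positive = positive)
}
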