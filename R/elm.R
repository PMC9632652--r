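#' Initialize an extreme learning machine
#'
#' Draws the random input weights and biases of a single-hidden-layer
#' feedforward network. Input weights `omega` (n_features x L) and biases
#' `b` (length L) are i.i.d. uniform on \[-1, 1\] from the seeded generator
#' and are never trained; only the output weights `phi` are solved, by one of
#' the solvers below.
#'
#' @param n_features input dimension.
#' @param L hidden-layer size.
#' @param activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param seed integer seed.
#' @return object of class `elm` with unset output weights.
#' @export
elm_init <- function(n_features, L = 1000L,
                     activation = c("sigmoid", "tanh", "relu"), seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(n_features >= 1L, L >= 1L)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  structure(list(
    omega = matrix(stats::runif(n_features * L, -1, 1), n_features, L),
    b = stats::runif(L, -1, 1),
    L = as.integer(L), activation = activation,
    phi = NULL, beta = NULL, solver = NULL, seed = as.integer(seed),
    classes = NULL, feature_names = NULL
  ), class = "elm")
}

activate <- function(z, activation) {
  switch(activation,
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         relu = pmax(z, 0))
}

#' Hidden-layer output matrix
#'
#' `G[i, j] = g(omega_j . x_i + b_j)` for each sample `i` and hidden neuron
#' `j`.
#'
#' @param X feature matrix (n_samples x n_features).
#' @param model an `elm` from [elm_init()].
#' @return matrix G (n_samples x L).
#' @export
hidden_output <- function(X, model) {
  stopifnot(inherits(model, "elm"))
  X <- as_feature_matrix(X)
  if (ncol(X) != nrow(model$omega))
    stop(sprintf("feature dimension mismatch: got %d, model expects %d",
                 ncol(X), nrow(model$omega)), call. = FALSE)
  activate(sweep(X %*% model$omega, 2, model$b, "+"), model$activation)
}

#' Output-weight solvers
#'
#' Three ways to solve `G phi = Y` for the output weights:
#' * `solve_pinv()` — the minimum-norm least-squares (Moore-Penrose) solution.
#' * `solve_ridge_closed_form()` — the closed form
#'   `phi = (G'G + (1/beta) I)^{-1} G'Y`. Note the placement of `beta`:
#'   the penalty strength is `1/beta`, so a *larger* `beta` means *weaker*
#'   regularization (the reference configuration uses `beta = 0.05`, i.e.
#'   penalty 20).
#' * `solve_l1()` — coordinate-descent lasso on
#'   `(1/2)||G phi - y||^2 + beta ||phi||_1`, solved per output column; the
#'   sparse solution the L1 objective actually calls for.
#'
#' @param G hidden-layer output matrix (n x L).
#' @param Y target matrix (n x n_outputs), e.g. one-hot labels.
#' @param beta positive regularization parameter.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep.
#' @param max_sweeps maximum coordinate-descent sweeps.
#' @return matrix `phi` (L x n_outputs). `solve_l1` attaches the per-column
#'   zero counts as attribute `"sparsity"`.
#' @name elm_solvers
NULL

#' @rdname elm_solvers
#' @export
solve_pinv <- function(G, Y) {
  Y <- as.matrix(Y)
  if (nrow(G) != nrow(Y)) stop("G and Y must have equal row counts", call. = FALSE)
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(G), ncol(Y)))
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
}

#' @rdname elm_solvers
#' @export
solve_ridge_closed_form <- function(G, Y, beta = 0.05) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a positive number", call. = FALSE)
  Y <- as.matrix(Y)
  if (nrow(G) != nrow(Y)) stop("G and Y must have equal row counts", call. = FALSE)
  A <- crossprod(G) + diag(1 / beta, ncol(G))
  solve(A, crossprod(G, Y))
}

#' @rdname elm_solvers
#' @export
solve_l1 <- function(G, Y, beta = 0.05, tol = 1e-6, max_sweeps = 10000L) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a positive number", call. = FALSE)
  Y <- as.matrix(Y)
  if (nrow(G) != nrow(Y)) stop("G and Y must have equal row counts", call. = FALSE)
  L <- ncol(G)
  GtG <- crossprod(G)
  gtg_diag <- diag(GtG)
  phi <- matrix(0, L, ncol(Y))
  for (col in seq_len(ncol(Y))) {
    gty <- crossprod(G, Y[, col])
    w <- numeric(L)
    gradc <- gty            # gty - GtG %*% w, maintained incrementally
    converged <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      delta_max <- 0
      for (j in seq_len(L)) {
        if (gtg_diag[j] <= 0) next
        rho <- gradc[j] + gtg_diag[j] * w[j]
        wj_new <- soft_threshold(rho, beta) / gtg_diag[j]
        dj <- wj_new - w[j]
        if (dj != 0) {
          gradc <- gradc - GtG[, j] * dj
          w[j] <- wj_new
          delta_max <- max(delta_max, abs(dj))
        }
      }
      if (delta_max < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("L1 solver did not reach tolerance %g in %d sweeps", tol,
                   max_sweeps), call. = FALSE)
    phi[, col] <- w
  }
  attr(phi, "sparsity") <- colSums(phi == 0)
  phi
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit an extreme learning machine classifier
#'
#' Random-hidden-layer classifier for binary labels: the hidden layer is
#' drawn once from the seed, labels are one-hot encoded over \{0, 1\}, and
#' the output weights are solved by the chosen solver (the ridge closed form
#' with `beta = 0.05` by default).
#'
#' @param x feature matrix or labeled `feature_set`.
#' @param y class labels in \{0, 1\} (taken from `x` when it is a labeled
#'   feature set).
#' @param L hidden-layer size.
#' @param activation hidden activation function.
#' @param beta regularization parameter (see [elm_solvers]).
#' @param solver `"ridge"`, `"pinv"` or `"l1"`.
#' @param seed integer seed for the random hidden layer.
#' @return a fitted object of class `elm`.
#' @examples
#' doms <- gen_preset_domains("null", n_per_class = 40, dim = 6, n_sources = 1)
#' fit <- elm(doms[[1]], L = 50, seed = 2)
#' mean(predict(fit, doms[[2]]$x) == doms[[2]]$labels)
#' @export
elm <- function(x, y = NULL, L = 1000L,
                activation = c("sigmoid", "tanh", "relu"),
                beta = 0.05, solver = c("ridge", "pinv", "l1"), seed = 1L) {
  solver <- match.arg(solver)
  activation <- match.arg(activation)
  if (inherits(x, "feature_set")) {
    y <- x$labels
    x <- x$x
  }
  if (is.null(y)) stop("labels `y` are required to fit an ELM", call. = FALSE)
  y <- as.integer(y)
  model <- elm_init(ncol(x), L = L, activation = activation, seed = seed)
  model$feature_names <- colnames(x)
  model$classes <- 0:1
  G <- hidden_output(x, model)
  Y <- cbind(`0` = as.numeric(y == 0L), `1` = as.numeric(y == 1L))
  model$phi <- switch(solver,
                      ridge = solve_ridge_closed_form(G, Y, beta),
                      pinv = solve_pinv(G, Y),
                      l1 = solve_l1(G, Y, beta))
  model$beta <- beta
  model$solver <- solver
  model$n_train <- nrow(x)
  model
}

#' Predict from a fitted ELM
#'
#' Scores are `G_test phi`; the predicted label is the arg-max column and
#' the class-1 score column is the ROC score.
#'
#' @param object fitted `elm`.
#' @param newdata feature matrix or `feature_set`.
#' @param type `"class"` for hard labels, `"score"` for the score matrix.
#' @param ... unused.
#' @return integer labels or a score matrix with columns `"0"`, `"1"`.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$phi)) stop("the ELM output weights are not solved yet",
                                call. = FALSE)
  G <- hidden_output(as_feature_matrix(newdata), object)
  scores <- G %*% object$phi
  colnames(scores) <- c("0", "1")
  if (type == "score") return(scores)
  as.integer(scores[, 2] > scores[, 1])
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("Extreme learning machine: %d -> %d hidden (%s)",
              nrow(x$omega), x$L, x$activation))
  if (is.null(x$phi)) cat(" [output weights unsolved]\n")
  else cat(sprintf(", solver %s (beta = %g), fitted on %d samples\n",
                   x$solver, x$beta %||% NA, x$n_train %||% NA))
  invisible(x)
}

#' @export
coef.elm <- function(object, ...) object$phi

#' Fit on one set, predict on another
#'
#' Convenience wrapper: fits an ELM on a labeled training set and returns
#' scores and predicted labels for a test set.
#'
#' @param train labeled `feature_set`.
#' @param test `feature_set` or matrix with matching feature dimension.
#' @inheritParams elm
#' @return list with `model`, `scores` (test score matrix), `labels`
#'   (predicted), and `roc_score` (class-1 score column).
#' @export
elm_fit_predict <- function(train, test, L = 1000L,
                            activation = "sigmoid", beta = 0.05,
                            solver = "ridge", seed = 1L) {
  model <- elm(train, L = L, activation = activation, beta = beta,
               solver = solver, seed = seed)
  scores <- predict(model, test, type = "score")
  list(model = model, scores = scores,
       labels = as.integer(scores[, 2] > scores[, 1]),
       roc_score = scores[, 2])
}
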