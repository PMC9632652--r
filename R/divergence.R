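#' Squared maximum mean discrepancy between two sample sets
#'
#' Biased (V-statistic) estimator of the squared MMD between the empirical
#' distributions of a source and a target feature set under a Gaussian
#' kernel:
#' \deqn{\widehat{M}_H = \frac{1}{n^2}\sum_{i,j} k(x_i^s, x_j^s)
#'   - \frac{2}{nm}\sum_{i,j} k(x_i^s, x_j^t)
#'   + \frac{1}{m^2}\sum_{i,j} k(x_i^t, x_j^t).}
#' The cross-term carries the factor 2 that the squared-norm expansion of the
#' mean-embedding difference requires.
#'
#' @param source,target `feature_set` objects (or numeric matrices) with the
#'   same number of columns.
#' @param spec a [kernel_spec()]; `"median"` bandwidths are resolved once on
#'   the concatenated pair.
#' @return nonnegative scalar (clipped at 0 to absorb rounding).
#' @seealso [conditional_mmd()], [pair_divergence()]
#' @export
mmd_squared <- function(source, target, spec = kernel_spec()) {
  Xs <- as_feature_matrix(source)
  Xt <- as_feature_matrix(target)
  if (ncol(Xs) != ncol(Xt))
    stop("source and target must have the same feature dimension", call. = FALSE)
  if (nrow(Xs) < 1L || nrow(Xt) < 1L)
    stop("both sample sets must be nonempty", call. = FALSE)
  sig <- resolve_sigma(spec, Xs, Xt)
  mmd_squared_resolved(Xs, Xt, sig, spec$n_kernels)
}

mmd_squared_resolved <- function(Xs, Xt, sigma, n_kernels = 1L) {
  Kss <- kernel_matrix(Xs, Xs, sigma, n_kernels)
  Kst <- kernel_matrix(Xs, Xt, sigma, n_kernels)
  Ktt <- kernel_matrix(Xt, Xt, sigma, n_kernels)
  v <- mean(Kss) - 2 * mean(Kst) + mean(Ktt)
  max(v, 0)
}

#' Class-conditional MMD
#'
#' Restricts [mmd_squared()] to the samples of each class present in both
#' sets; classes missing from either set are dropped (with a warning), so the
#' per-class map and the Wasserstein class weights always range over the same
#' classes.
#'
#' @inheritParams mmd_squared
#' @return named numeric vector, one entry per shared class (names "0"/"1").
#' @export
conditional_mmd <- function(source, target, spec = kernel_spec()) {
  if (!inherits(source, "feature_set") || !inherits(target, "feature_set") ||
      is.null(source$labels) || is.null(target$labels))
    stop("conditional MMD needs labeled feature sets", call. = FALSE)
  shared <- shared_classes(source, target, warn = TRUE)
  if (length(shared) == 0L)
    stop("no class is shared by both sets; conditional MMD is undefined",
         call. = FALSE)
  out <- vapply(shared, function(l) {
    mmd_squared(source$x[source$labels == l, , drop = FALSE],
                target$x[target$labels == l, , drop = FALSE], spec)
  }, numeric(1))
  names(out) <- as.character(shared)
  out
}

shared_classes <- function(source, target, warn = FALSE) {
  cs <- sort(unique(source$labels))
  ct <- sort(unique(target$labels))
  shared <- intersect(cs, ct)
  if (warn && length(shared) < length(union(cs, ct)))
    warning(sprintf("classes {%s} are missing from one set and were dropped",
                    paste(setdiff(union(cs, ct), shared), collapse = ", ")),
            call. = FALSE)
  shared
}

#' Exact empirical Wasserstein-1 distance
#'
#' Wasserstein distance with Euclidean ground cost between the uniform
#' empirical measures of two sample sets, solved exactly as a linear
#' transportation problem (successive shortest augmenting paths). Intended
#' for the modest set sizes arising in mini-batch divergence estimation; sets
#' larger than 512 per side raise an error directing the caller to subsample.
#'
#' @param a,b `feature_set` objects or numeric matrices with equal column
#'   count.
#' @return nonnegative scalar distance.
#' @examples
#' wasserstein_distance(matrix(0, 1, 2), matrix(c(3, 4), 1, 2)) # 5
#' @export
wasserstein_distance <- function(a, b) {
  A <- as_feature_matrix(a)
  B <- as_feature_matrix(b)
  if (ncol(A) != ncol(B))
    stop("the two sets must have the same feature dimension", call. = FALSE)
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("both sample sets must be nonempty", call. = FALSE)
  if (nrow(A) > 512L || nrow(B) > 512L)
    stop("exact transport is limited to 512 samples per side; subsample first",
         call. = FALSE)
  .ot_wasserstein(A, B)
}

#' Probability-distribution adaptation factor
#'
#' Balances conditional against marginal divergence from Wasserstein
#' weights: \deqn{\mu = \frac{\sum_l W_l}{W_g + \sum_l W_l}.}
#' `mu` near 0 says the global (marginal) discrepancy dominates; near 1 the
#' class-conditional discrepancy dominates; 0.5 weighs them equally. When
#' every distance is zero (identical domains) the factor is undefined and a
#' neutral 0.5 is returned with a warning — the combined divergence is zero
#' regardless.
#'
#' @param w_global nonnegative global Wasserstein distance.
#' @param w_by_class named nonnegative vector of per-class Wasserstein
#'   distances.
#' @return scalar in \[0, 1\].
#' @export
adaptation_factor <- function(w_global, w_by_class) {
  stopifnot(is.numeric(w_global), length(w_global) == 1L, w_global >= 0,
            is.numeric(w_by_class), all(w_by_class >= 0))
  s <- sum(w_by_class)
  denom <- w_global + s
  if (denom == 0) {
    warning("all Wasserstein distances are zero (identical domains); using mu = 0.5",
            call. = FALSE)
    return(0.5)
  }
  s / denom
}

#' Full divergence report for one source-target pair
#'
#' Computes every quantity of the adaptive divergence between one source and
#' the target: marginal MMD, per-class conditional MMD, global and per-class
#' Wasserstein distances, the adaptation factor `mu`, and the combined
#' divergence
#' \deqn{M_{MMD} = (1 - \mu)\, M_H + \mu \sum_l M_H^{(l)}.}
#'
#' The per-class Wasserstein weights are computed after centering each
#' domain by its own global mean, so they measure differences in class
#' structure relative to the domain mean; a pure translation of a whole
#' domain therefore loads on the global weight, not the class weights.
#' Conditional MMD terms are computed on the raw features.
#'
#' @inheritParams conditional_mmd
#' @return object of class `divergence_report` with fields `mmd_marginal`,
#'   `mmd_conditional_by_class`, `w_global`, `w_by_class`, `mu`, `combined`.
#' @export
pair_divergence <- function(source, target, spec = kernel_spec()) {
  if (!inherits(source, "feature_set") || !inherits(target, "feature_set") ||
      is.null(source$labels) || is.null(target$labels))
    stop("pair_divergence needs labeled feature sets", call. = FALSE)
  sig <- resolve_sigma(spec, source$x, target$x)
  rspec <- kernel_spec(sigma = sig, n_kernels = spec$n_kernels)

  m_h <- mmd_squared(source$x, target$x, rspec)
  shared <- shared_classes(source, target, warn = TRUE)
  if (length(shared) == 0L)
    stop("no class is shared by both sets", call. = FALSE)

  m_cond <- vapply(shared, function(l) {
    mmd_squared(source$x[source$labels == l, , drop = FALSE],
                target$x[target$labels == l, , drop = FALSE], rspec)
  }, numeric(1))
  names(m_cond) <- as.character(shared)

  w_g <- wasserstein_distance(source$x, target$x)
  sc <- scale(source$x, center = TRUE, scale = FALSE)
  tc <- scale(target$x, center = TRUE, scale = FALSE)
  w_l <- vapply(shared, function(l) {
    wasserstein_distance(sc[source$labels == l, , drop = FALSE],
                         tc[target$labels == l, , drop = FALSE])
  }, numeric(1))
  names(w_l) <- as.character(shared)

  mu <- adaptation_factor(w_g, w_l)

  structure(list(
    mmd_marginal = m_h,
    mmd_conditional_by_class = m_cond,
    w_global = w_g,
    w_by_class = w_l,
    mu = mu,
    combined = (1 - mu) * m_h + mu * sum(m_cond),
    sigma = sig,
    source_id = source$domain_id,
    target_id = target$domain_id
  ), class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("Divergence %s -> %s\n", x$source_id, x$target_id))
  cat(sprintf("  marginal MMD^2   : %.6g\n", x$mmd_marginal))
  cat(sprintf("  conditional MMD^2: %s\n",
              paste(sprintf("[%s] %.6g", names(x$mmd_conditional_by_class),
                            x$mmd_conditional_by_class), collapse = "  ")))
  cat(sprintf("  Wasserstein      : global %.6g, by class %s\n", x$w_global,
              paste(sprintf("[%s] %.6g", names(x$w_by_class), x$w_by_class),
                    collapse = "  ")))
  cat(sprintf("  mu = %.4f, combined divergence = %.6g\n", x$mu, x$combined))
  invisible(x)
}

#' Multisource MMD loss
#'
#' Arithmetic mean of the combined divergences over all source-target pairs
#' (the training objective averages however many pairs are supplied; the
#' reference configuration uses three).
#'
#' @param pairs list of `divergence_report` objects (or bare numbers).
#' @return nonnegative scalar.
#' @export
multisource_mmd_loss <- function(pairs) {
  if (length(pairs) == 0L) stop("`pairs` must be nonempty", call. = FALSE)
  vals <- vapply(pairs, function(p) {
    if (inherits(p, "divergence_report")) p$combined else as.numeric(p)
  }, numeric(1))
  mean(vals)
}
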