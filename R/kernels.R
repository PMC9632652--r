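#' Gaussian kernel specification
#'
#' Describes the kernel used by the MMD estimators: a bandwidth `sigma`
#' (either a positive number or the string `"median"` for the standard
#' two-sample median heuristic, resolved on the concatenated pair) and an
#' optional multi-kernel count. With `n_kernels > 1` the kernel is the
#' average of Gaussians at bandwidths `sigma * 2^(-h..h)` centred on the
#' resolved `sigma` (h chosen so that `n_kernels` bandwidths are used);
#' the default is a single kernel.
#'
#' @param sigma positive bandwidth, or `"median"`.
#' @param n_kernels positive integer number of Gaussians to average.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma = "median", n_kernels = 1L) {
  if (is.character(sigma)) {
    if (!identical(sigma, "median"))
      stop("`sigma` must be a positive number or \"median\"", call. = FALSE)
  } else {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
      stop("`sigma` must be a positive number or \"median\"", call. = FALSE)
  }
  n_kernels <- as.integer(n_kernels)
  if (n_kernels < 1L) stop("`n_kernels` must be a positive integer", call. = FALSE)
  structure(list(sigma = sigma, n_kernels = n_kernels), class = "kernel_spec")
}

# Resolve "median" to a number on the concatenated pair: median of the
# pairwise Euclidean distances between all distinct rows of rbind(xs, xt).
# Degenerate all-identical input falls back to sigma = 1.
resolve_sigma <- function(spec, xs, xt = NULL) {
  if (!identical(spec$sigma, "median")) return(spec$sigma)
  z <- if (is.null(xt)) xs else rbind(xs, xt)
  d <- stats::dist(z)
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

sigma_grid <- function(sigma, n_kernels) {
  if (n_kernels == 1L) return(sigma)
  h <- (n_kernels - 1L) / 2
  sigma * 2^seq(-h, h, length.out = n_kernels)
}

#' Gaussian kernel between two vectors
#'
#' Evaluates `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))` (averaged over the
#' bandwidth grid when the spec requests multiple kernels). `sigma = "median"`
#' is resolved on the two points alone, which for distinct points gives
#' `sigma = ||x - y||`.
#'
#' @param x,y numeric vectors of equal length.
#' @param spec a [kernel_spec()].
#' @return kernel value in (0, 1].
#' @examples
#' gaussian_kernel(c(0, 0), c(3, 4), kernel_spec(sigma = 5)) # exp(-1/2)
#' @export
gaussian_kernel <- function(x, y, spec = kernel_spec()) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same dimension", call. = FALSE)
  sig <- resolve_sigma(spec, matrix(x, 1), matrix(y, 1))
  sigs <- sigma_grid(sig, spec$n_kernels)
  d2 <- sum((x - y)^2)
  mean(exp(-d2 / (2 * sigs^2)))
}

# Full Gram matrix between rows of A and rows of B at a resolved bandwidth
# (or averaged over the multi-kernel grid). Squared distances are clipped at
# zero to absorb rounding in the quadratic expansion.
kernel_matrix <- function(A, B, sigma, n_kernels = 1L) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sigs <- sigma_grid(sigma, n_kernels)
  K <- 0
  for (s in sigs) K <- K + exp(-d2 / (2 * s^2))
  K / length(sigs)
}
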