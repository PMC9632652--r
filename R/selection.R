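#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection of the fraction of features most relevant to the
#' class label and least redundant with one another. Mutual information is
#' estimated on equal-frequency discretized features (`bins` bins, natural
#' log). The first pick is the maximum-relevance feature; each later step
#' maximizes either the difference criterion (MID, default)
#' `MI(f; label) - mean_{s in S} MI(f; s)` or the quotient criterion (MIQ)
#' `MI(f; label) / mean_{s in S} MI(f; s)`. Ties are broken by lowest column
#' index, so the procedure is deterministic.
#'
#' @param features a labeled `feature_set` (or a matrix plus `labels`).
#' @param fraction fraction of features to keep, in (0, 1]; the number kept
#'   is `ceiling(fraction * n_features)`.
#' @param labels class labels when `features` is a bare matrix.
#' @param bins number of equal-frequency bins for discretization.
#' @param criterion `"mid"` (difference) or `"miq"` (quotient).
#' @return object of class `selection_result` with `selected_indices`
#'   (ordered as picked), `scores` (criterion value at each pick),
#'   `relevance` (MI with the label for all features), and `fraction`.
#' @examples
#' fs <- gen_preset_domains("null", n_per_class = 30, dim = 8, n_sources = 1)[[1]]
#' mrmr_select(fs, fraction = 0.5)
#' @export
mrmr_select <- function(features, fraction = 0.10, labels = NULL,
                        bins = 10L, criterion = c("mid", "miq")) {
  criterion <- match.arg(criterion)
  if (inherits(features, "feature_set")) {
    labels <- features$labels
    X <- features$x
  } else X <- features
  if (is.null(labels)) stop("labels are required for mRMR selection", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  p <- ncol(X)
  k <- selection_size(fraction, p)

  disc <- lapply(seq_len(p), function(j) discretize_ef(X[, j], bins))
  y <- factor(labels)
  relevance <- vapply(disc, function(f) mutual_information(f, y), numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  # redundancy matrix filled lazily: MI of every feature vs each selected one
  red <- matrix(NA_real_, nrow = p, ncol = k)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    if (step == 1L) {
      crit <- relevance
    } else {
      mean_red <- rowMeans(red[, seq_len(step - 1L), drop = FALSE])
      crit <- if (criterion == "mid") relevance - mean_red
              else relevance / pmax(mean_red, .Machine$double.eps)
    }
    crit[selected] <- -Inf
    pick <- which.max(crit)  # which.max takes the lowest index on ties
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step < k)
      red[, step] <- vapply(disc, function(f)
        mutual_information(f, disc[[pick]]), numeric(1))
  }
  structure(list(selected_indices = selected, scores = scores,
                 relevance = relevance, fraction = fraction,
                 n_features = p, criterion = criterion, bins = bins),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("mRMR selection (%s, %d bins): kept %d of %d features (fraction %.3g)\n",
              toupper(x$criterion), x$bins, length(x$selected_indices),
              x$n_features, x$fraction))
  show <- utils::head(x$selected_indices, 10L)
  cat("  first picks:", paste(show, collapse = ", "),
      if (length(x$selected_indices) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Number of features kept at a given fraction
#'
#' `ceiling(fraction * n_features)`, the size rule used by [mrmr_select()].
#'
#' @param fraction fraction in (0, 1].
#' @param n_features total feature count.
#' @return integer count.
#' @examples
#' selection_size(0.10, 21440) # 2144
#' @export
selection_size <- function(fraction, n_features) {
  as.integer(ceiling(fraction * n_features))
}

# Equal-frequency discretization into at most `bins` bins; constant columns
# collapse to a single bin (mutual information 0).
discretize_ef <- function(x, bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = qs, include.lowest = TRUE)
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}
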