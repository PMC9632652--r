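#' Construct a labeled feature set
#'
#' A feature set is one domain's worth of samples: a numeric feature matrix,
#' optional binary class labels, and a domain identifier. It is the common
#' currency of the divergence, selection and ELM layers.
#'
#' @param x numeric matrix (n_samples x n_features) or a data frame of
#'   numeric columns. All values must be finite.
#' @param labels optional vector of class indices in \{0, 1\}, one per row.
#' @param domain_id character tag naming the domain (e.g. "S1", "target").
#' @return an object of class `feature_set` with elements `x`, `labels`,
#'   `domain_id`.
#' @examples
#' fs <- feature_set(matrix(rnorm(20), 10, 2), labels = rep(0:1, 5), "demo")
#' fs
#' @export
feature_set <- function(x, labels = NULL, domain_id = "") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix or data frame", call. = FALSE)
  if (nrow(x) < 1L) stop("feature set must contain at least one sample", call. = FALSE)
  if (any(!is.finite(x))) stop("all feature values must be finite", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x))
      stop("`labels` length must equal the number of rows of `x`", call. = FALSE)
    if (any(!labels %in% c(0L, 1L)))
      stop("labels must be class indices in {0, 1}", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, labels = labels, domain_id = as.character(domain_id)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set '%s': %d samples x %d features",
              x$domain_id, nrow(x$x), ncol(x$x)))
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:1))
    cat(sprintf(" (labels: %d class-0, %d class-1)", tab[["0"]], tab[["1"]]))
  }
  cat("\n")
  invisible(x)
}

as_feature_matrix <- function(a) {
  if (inherits(a, "feature_set")) a$x
  else if (is.matrix(a)) a
  else stop("expected a feature_set or numeric matrix", call. = FALSE)
}

#' Read / write feature tables
#'
#' Feature sets are stored as tab-delimited tables with a header row of
#' feature names and, when labeled, a final `label` column. The domain tag is
#' taken from the filename stem unless given explicitly.
#'
#' @param path file path of a tab-delimited table.
#' @param domain_id domain tag; defaults to the filename stem.
#' @return `read_feature_set` returns a `feature_set`.
#' @export
read_feature_set <- function(path, domain_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df[["label"]]
    df[["label"]] <- NULL
  }
  if (is.null(domain_id))
    domain_id <- sub("\\.[^.]*$", "", basename(path))
  feature_set(as.matrix(df), labels = labels, domain_id = domain_id)
}

#' @rdname read_feature_set
#' @param fs a `feature_set`.
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- as.data.frame(fs$x, check.names = FALSE)
  if (!is.null(fs$labels)) df$label <- fs$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
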