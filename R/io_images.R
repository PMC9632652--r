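#' Write / read an image domain as PNG files with a manifest
#'
#' The interchange format for image domains: one grayscale PNG per image
#' plus a tab-delimited manifest with columns `path` (relative to the
#' manifest), `label`, `domain`, and the affine intensity mapping
#' (`offset`, `scale`) used to fit the unbounded image values into \[0, 1\]
#' for PNG storage (`stored = (value - offset) / scale`). Reading inverts
#' the mapping, so a round trip reproduces the images up to 8-bit
#' quantization.
#'
#' @param images an `image_set`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return `write_image_domain` returns the manifest path;
#'   `read_image_domain` returns an `image_set`.
#' @export
write_image_domain <- function(images, dir, prefix = images$domain_id) {
  stopifnot(inherits(images, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(images$images)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  n <- dim(images$images)[3]
  rel <- sprintf("%s_%04d.png", prefix, seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG((images$images[, , i] - offset) / scale,
                  file.path(dir, rel[i]))
  }
  manifest <- data.frame(path = rel,
                         label = if (is.null(images$labels)) NA_integer_
                                 else images$labels,
                         domain = images$domain_id,
                         offset = offset, scale = scale)
  mpath <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_image_domain
#' @param manifest path to a manifest written by `write_image_domain`.
#' @export
read_image_domain <- function(manifest) {
  man <- utils::read.delim(manifest)
  base <- dirname(manifest)
  imgs <- lapply(man$path, function(p) {
    m <- png::readPNG(file.path(base, p))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  arr <- array(unlist(imgs), dim = c(nrow(imgs[[1]]), ncol(imgs[[1]]),
                                     length(imgs)))
  arr <- arr * man$scale[1] + man$offset[1]
  labels <- if (all(is.na(man$label))) NULL else as.integer(man$label)
  structure(list(images = arr, labels = labels,
                 domain_id = as.character(man$domain[1])),
            class = "image_set")
}
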