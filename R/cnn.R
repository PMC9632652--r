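# Minimal CNN layer primitives operating on flattened spatial batches.
#
# An activation tensor of shape (H, W, C, N) is stored as a matrix with
# H*W*N rows (row index = i + (j-1)*H + (n-1)*H*W, i fastest) and C columns.
# Convolutions are evaluated as a sum over kernel offsets of shifted-slice
# matrix products, which keeps everything inside BLAS.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- make()
    .idx_cache[[key]] <- v
  }
  v
}

# leaky-ReLU slope used throughout the tiny CNN; keeps gradients alive when a
# strong early divergence weight would otherwise kill whole feature streams
.leak <- 0.1

conv3x3_fwd <- function(X, H, W, N, Wk, b, relu = FALSE) {
  .conv3x3_fwd(X, H, W, N, Wk, b, if (relu) .leak else -1)
}

conv3x3_bwd <- function(dY, X, H, W, N, Wk) {
  .conv3x3_bwd(dY, X, H, W, N, Wk)
}

conv1x1_fwd <- function(X, Wm, b) sweep(X %*% Wm, 2, b, "+")

conv1x1_bwd <- function(dY, X, Wm) {
  list(dX = dY %*% t(Wm), dW = crossprod(X, dY), db = colSums(dY))
}

pool2_idx <- function(H, W, N) {
  key <- paste("p", H, W, N, sep = "_")
  cache_get(key, function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    i2 <- seq_len(H2); j2 <- seq_len(W2)
    lapply(0:3, function(k) {
      a <- k %% 2L; b <- k %/% 2L
      cell <- as.vector(outer(2L * i2 - 1L + a, (2L * j2 - 2L + b) * H, "+"))
      rep(cell, N) + rep((seq_len(N) - 1L) * H * W, each = length(cell))
    })
  })
}

avgpool2_fwd <- function(X, H, W, N) {
  ix <- pool2_idx(H, W, N)
  (X[ix[[1]], , drop = FALSE] + X[ix[[2]], , drop = FALSE] +
     X[ix[[3]], , drop = FALSE] + X[ix[[4]], , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dY, H, W, N, C) {
  ix <- pool2_idx(H, W, N)
  dX <- matrix(0, H * W * N, C)
  for (k in 1:4) dX[ix[[k]], ] <- dY / 4
  dX
}

gap_fwd <- function(X, H, W, N) {
  grp <- rep(seq_len(N), each = H * W)
  rowsum(X, grp, reorder = FALSE) / (H * W)
}

gap_bwd <- function(dG, H, W, N) {
  dG[rep(seq_len(N), each = H * W), , drop = FALSE] / (H * W)
}

relu_fwd <- function(X) {
  neg <- X < 0
  X[neg] <- .leak * X[neg]
  X
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# row indices of a sample subset within a flattened (H, W, *, N) matrix
rows_for_samples <- function(H, W, idx) {
  as.vector(outer(seq_len(H * W), (idx - 1L) * H * W, "+"))
}
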