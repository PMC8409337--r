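# independent double-precision reference forward for the CNN-only variant
# (dropout 0): direct array convolution, batch norm from first principles.
# Used to pin down the single-precision core's loss and gradients.
reference_cnn_loss <- function(params, xidx, y, cfg) {
  n <- nrow(xidx)
  IH <- cfg$window_length; IW <- cfg$embedding_dim
  C <- cfg$cnn_channels; B <- cfg$cnn_blocks
  nval <- IH * IW
  A <- array(0, c(n, IH, IW, 1))
  for (s in 1:n) A[s, , , 1] <- params$embedding[xidx[s, ] + 1, ]
  for (k in 1:B) {
    cin <- dim(A)[4]
    Wk <- params[[paste0("conv", k, "_w")]]
    Apad <- array(0, c(n, IH + 2, IW + 2, cin))
    Apad[, 2:(IH + 1), 2:(IW + 1), ] <- A
    Z <- matrix(0, n * IH * IW, C)
    o <- 0
    for (ky in -1:1) for (kx in -1:1) {
      o <- o + 1
      sh <- Apad[, (2 + ky):(IH + 1 + ky), (2 + kx):(IW + 1 + kx), ,
                 drop = FALSE]
      Z <- Z + matrix(sh, n * IH * IW, cin) %*%
        Wk[((o - 1) * cin + 1):(o * cin), , drop = FALSE]
    }
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    xh <- sweep(sweep(Z, 2, mu), 2, sqrt(va + 1e-5), "/")
    a <- sweep(sweep(xh, 2, as.numeric(params[[paste0("bn", k, "_gamma")]]),
                     "*"),
               2, as.numeric(params[[paste0("bn", k, "_beta")]]), "+")
    out <- pmax(a, 0)
    if (k > 1) out <- out + matrix(A, n * IH * IW, C)
    A <- array(out, c(n, IH, IW, C))
  }
  flat <- matrix(0, n, nval * C)
  for (ch in 1:C) for (yy in 1:IH) for (xx in 1:IW)
    flat[, (ch - 1) * nval + (yy - 1) * IW + xx] <- A[, yy, xx, ch]
  lat <- flat %*% params$cnn_latent_w +
    matrix(params$cnn_latent_b, n, cfg$latent_dim, byrow = TRUE)
  sc <- lat %*% params$head_w + matrix(params$head_b, n, 2, byrow = TRUE)
  p <- exp(sc - apply(sc, 1, max))
  p <- p / rowSums(p)
  -mean(log(p[cbind(1:n, y + 1)]))
}
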