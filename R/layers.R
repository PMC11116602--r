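# ---------------------------------------------------------------------------
# Minimal convolutional layer machinery for the compact detector: seeded
# He-normal init, leaky-ReLU convolutions backed by the C++ im2col kernels,
# and an Adam optimizer with decoupled weight decay. The detector graph is
# hand-wired in network.R; layers cache their inputs during the forward
# pass so the backward pass can run in reverse order.
# ---------------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky <- function(x, slope = 0.1) ifelse(x > 0, x, slope * x)

# deterministic per-layer seed so shared layers initialize identically
# whether or not the micro-scale path is present
layer_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  (as.integer(master) + h) %% 2000000011L
}

new_conv <- function(name, cin, cout, k, stride, act, master_seed) {
  fan_in <- k * k * cin
  w <- with_seed(layer_seed(master_seed, name),
                 matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                        fan_in, cout))
  list(name = name, w = w, b = numeric(cout), k = k, stride = stride,
       pad = (k - 1L) %/% 2L, act = act, cin = cin, cout = cout,
       mw = w * 0, vw = w * 0, mb = numeric(cout), vb = numeric(cout))
}

conv_forward <- function(det, name, x, cache) {
  l <- det$layers[[name]]
  y <- conv2d_fwd(x, l$w, l$b, l$k, l$stride, l$pad)
  cache[[name]] <- list(x = x, y = y)
  if (l$act == "leaky") leaky(y) else y
}

conv_backward <- function(det, name, da, cache, grads) {
  l <- det$layers[[name]]
  cc <- cache[[name]]
  dy <- if (l$act == "leaky") da * ifelse(cc$y > 0, 1, 0.1) else da
  g <- conv2d_bwd(cc$x, l$w, dy, l$k, l$stride, l$pad)
  if (is.null(grads[[name]])) {
    grads[[name]] <- list(dw = g$dw, db = g$db)
  } else {
    grads[[name]]$dw <- grads[[name]]$dw + g$dw
    grads[[name]]$db <- grads[[name]]$db + g$db
  }
  g$dx
}

concat_c <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

split_c <- function(d, n1) {
  list(d[, , seq_len(n1), drop = FALSE],
       d[, , n1 + seq_len(dim(d)[3] - n1), drop = FALSE])
}

adam_step <- function(det, grads, lr, beta1, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  det$t <- det$t + 1L
  bc1 <- 1 - beta1^det$t
  bc2 <- 1 - beta2^det$t
  for (name in names(grads)) {
    l <- det$layers[[name]]
    g <- grads[[name]]
    l$mw <- beta1 * l$mw + (1 - beta1) * g$dw
    l$vw <- beta2 * l$vw + (1 - beta2) * g$dw^2
    l$mb <- beta1 * l$mb + (1 - beta1) * g$db
    l$vb <- beta2 * l$vb + (1 - beta2) * g$db^2
    l$w <- l$w - lr * (l$mw / bc1 / (sqrt(l$vw / bc2) + eps) + weight_decay * l$w)
    l$b <- l$b - lr * (l$mb / bc1 / (sqrt(l$vb / bc2) + eps))
    det$layers[[name]] <- l
  }
  invisible(det)
}
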