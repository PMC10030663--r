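## Minimal convolutional-network machinery: explicit forward/backward passes
## over im2col+GEMM convolution primitives, gated convolutions, nearest
## up/down-sampling and an Adam optimizer. Parameters live in flat named
## lists of arrays so the optimizer state can mirror them 1:1. All sizes are
## desk-scale by design (3 levels, 8 base channels).

nnInitConv2 <- function(k, cin, cout, scale = 1) {
  list(W = array(rnorm(k * k * cin * cout,
                       sd = scale * sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

nnInitConv3 <- function(k, cin, cout, scale = 1) {
  list(W = array(rnorm(k^3 * cin * cout,
                       sd = scale * sqrt(2 / (k^3 * cin))),
                 c(k, k, k, cin, cout)),
       b = numeric(cout))
}

## Forward passes cache only the layer input; the im2col buffer is
## rebuilt inside the fused C++ backward, keeping R-side memory flat.
nnConv2F <- function(x, p, stride = 1L) {
  list(y = .conv2Fwd(x, p$W, p$b, stride),
       cache = list(x = x, stride = stride))
}

nnConv2B <- function(p, cache, dy) {
  .conv2Bwd(cache$x, p$W, dy, cache$stride)
}

nnConv3F <- function(x, p, stride = 1L) {
  list(y = .conv3Fwd(x, as.integer(dim(x)), p$W, p$b, stride),
       cache = list(x = x, stride = stride))
}

nnConv3B <- function(p, cache, dy) {
  .conv3Bwd(cache$x, as.integer(dim(cache$x)), p$W, dy, cache$stride)
}

nnElu <- function(x) ifelse(x > 0, x, expm1(x))
nnEluGrad <- function(x, h) ifelse(x > 0, 1, h + 1)
nnSigmoid <- function(x) 1 / (1 + exp(-x))

## Gated convolution: h = elu(conv_f(x)) * sigmoid(conv_g(x)).
nnGated2F <- function(x, pf, pg, stride = 1L) {
  f <- nnConv2F(x, pf, stride)
  g <- nnConv2F(x, pg, stride)
  hf <- nnElu(f$y)
  hg <- nnSigmoid(g$y)
  list(h = hf * hg,
       cache = list(f = f, g = g, hf = hf, hg = hg))
}

nnGated2B <- function(pf, pg, cache, dh) {
  df <- dh * cache$hg * nnEluGrad(cache$f$y, cache$hf)
  dg <- dh * cache$hf * cache$hg * (1 - cache$hg)
  bf <- nnConv2B(pf, cache$f$cache, df)
  bg <- nnConv2B(pg, cache$g$cache, dg)
  list(dx = bf$dx + bg$dx, f = bf, g = bg)
}

nnUp2F <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

nnUp2B <- function(dy) {
  d <- dim(dy)
  a <- array(dy, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3]))
  array(a[1, , 1, , ] + a[2, , 1, , ] + a[1, , 2, , ] + a[2, , 2, , ],
        c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
}

nnUp3F <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
    rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

nnUp3B <- function(dy) {
  d <- dim(dy)
  a <- array(dy, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, 2L, d[3] %/% 2L, d[4]))
  out <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    out <- out + a[i, , j, , k, , ]
  array(out, c(d[1] %/% 2L, d[2] %/% 2L, d[3] %/% 2L, d[4]))
}

## Adam over flat named parameter lists; each parameter is list(W=, b=).
nnAdamInit <- function(params) {
  zero <- function(p) lapply(p, function(a) array(0, dim(a) %||% length(a)))
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nnAdamStep <- function(params, grads, state, lr = 2e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (part in names(params[[nm]])) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- beta1 * state$m[[nm]][[part]] + (1 - beta1) * g
      state$v[[nm]][[part]] <- beta2 * state$v[[nm]][[part]] +
        (1 - beta2) * g^2
      params[[nm]][[part]] <- params[[nm]][[part]] -
        lr * (state$m[[nm]][[part]] / bc1) /
          (sqrt(state$v[[nm]][[part]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

## Weighted binary cross-entropy on logits (numerically stable).
nnBceLoss <- function(z, target, w) {
  sw <- sum(w)
  l <- w * (pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  p <- nnSigmoid(z)
  list(loss = sum(l) / sw, dz = w * (p - target) / sw)
}

## Weighted L1.
nnL1Loss <- function(y, target, w) {
  sw <- sum(w)
  list(loss = sum(w * abs(y - target)) / sw,
       dy = w * sign(y - target) / sw)
}
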