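# Minimal neural-network primitives with explicit forward caches and
# hand-written backward passes, on base-R matrix ops (BLAS). All parameters
# live in flat named lists so the optimizer is a simple elementwise walk.

LN_EPS <- 1e-6

addbias <- function(x, b) x + rep(b, each = nrow(x))

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- addbias(xhat * rep(g, each = nrow(x)), b)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  n <- nrow(dy); D <- ncol(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(cache$g, each = n)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- (dxhat - s1 / D - xhat * (s2 / D)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# ReLU activation (the original transformer choice; cheap and exact)
act_fwd <- function(x) (x > 0) * x
act_grad <- function(x) (x > 0) * 1

drop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

drop_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

rmat <- function(n, m, sd = 0.02) matrix(rnorm(n * m, sd = sd), n, m)

# Adam over flat named parameter lists --------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)
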