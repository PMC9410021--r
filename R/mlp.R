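# Minimal per-pixel multilayer perceptron with hand-written backpropagation
# and an Adam optimizer. Both pipeline stages share this model family: each
# voxel/pixel is classified (detection) or regressed (identification) from a
# small vector of local image features. The model contract required by the
# training routines is: mlp_forward() mapping a feature matrix to one output
# per row, mlp_backward() mapping the output-preactivation gradient to
# parameter gradients, and a flat parameter list that adam_step() updates.
# Everything is deterministic given the seed.

pixel_mlp <- function(n_features, hidden = 16L, output = c("linear", "sigmoid"),
                      seed = 1L) {
  output <- match.arg(output)
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(hidden * n_features, 0, sqrt(2 / n_features)), hidden),
    b1 = rep(0, hidden),
    W2 = matrix(rnorm(hidden, 0, sqrt(1 / hidden)), 1),
    b2 = 0))
  structure(list(params = params, n_features = n_features,
                 hidden = as.integer(hidden), output = output),
            class = "pixel_mlp")
}

# X: n x p feature matrix. Returns list(y, cache) with y length n.
mlp_forward <- function(model, X) {
  p <- model$params
  Z <- tcrossprod(X, p$W1)
  Z <- sweep(Z, 2L, p$b1, `+`)
  A <- tanh(Z)
  pre <- drop(A %*% t(p$W2)) + p$b2
  y <- if (model$output == "sigmoid") plogis(pre) else pre
  list(y = y, cache = list(X = X, A = A))
}

# d_pre: gradient of the loss w.r.t. the output pre-activation (length n).
mlp_backward <- function(model, cache, d_pre) {
  p <- model$params
  dW2 <- matrix(crossprod(d_pre, cache$A), 1)
  db2 <- sum(d_pre)
  dA <- d_pre %*% p$W2            # n x hidden
  dZ <- dA * (1 - cache$A^2)
  list(W1 = crossprod(dZ, cache$X), b1 = colSums(dZ),
       W2 = dW2, b2 = db2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

scale_grads <- function(grads, f) lapply(grads, function(g) g * f)

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  Map(`+`, a, b)
}
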