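# Minimal multilayer-perceptron machinery: He-initialised affine layers,
# ReLU + inverted dropout between layers, optional sigmoid head, exact
# backpropagation (including gradients w.r.t. the input, needed for
# integrated gradients) and an Adam optimiser. Internal; the public surface
# is the adda() fit and its methods.

mlp_init <- function(sizes, head = c("identity", "sigmoid")) {
  head <- match.arg(head)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (i in seq_len(L)) {
    # He initialisation, suited to the ReLU nonlinearity
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], 0,
                                  sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- rep(0, sizes[i + 1L])
  }
  structure(list(W = W, b = b, sizes = sizes, head = head), class = "mlp")
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Forward pass. In training mode, dropout masks are drawn from the current
# RNG stream (inverted dropout: kept units scaled by 1/(1-p)).
mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  L <- length(net$W)
  caches <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    Z <- add_bias(A %*% net$W[[i]], net$b[[i]])
    if (i < L) {
      H <- pmax(Z, 0)
      mask <- NULL
      if (train && dropout > 0) {
        mask <- matrix((stats::runif(length(H)) >= dropout) / (1 - dropout),
                       nrow(H), ncol(H))
        H <- H * mask
      }
      caches[[i]] <- list(A_in = A, Z = Z, mask = mask)
      A <- H
    } else {
      caches[[i]] <- list(A_in = A, Z = Z)
      A <- if (net$head == "sigmoid") stats::plogis(Z) else Z
    }
  }
  list(out = A, caches = caches)
}

# Backward pass. `dZ_last` is the gradient w.r.t. the final pre-head affine
# output (for a sigmoid head trained with cross-entropy this is simply
# (p - y) / n, which is why the head is folded into the loss gradient).
mlp_backward <- function(net, caches, dZ_last) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dZ <- dZ_last
  dX <- NULL
  for (i in L:1) {
    ci <- caches[[i]]
    gW[[i]] <- crossprod(ci$A_in, dZ)
    gb[[i]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[i]])
    if (i > 1L) {
      cp <- caches[[i - 1L]]
      if (!is.null(cp$mask)) dA <- dA * cp$mask
      dZ <- dA * (cp$Z > 0)
    } else {
      dX <- dA
    }
  }
  list(gW = gW, gb = gb, dX = dX)
}

adam_init <- function(net) {
  zeros <- function(p) if (is.matrix(p)) p * 0 else rep(0, length(p))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  # bias-corrected step size folded into one scalar (standard Adam rewrite)
  alpha <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$gW[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$gW[[i]]^2
    net$W[[i]] <- net$W[[i]] - alpha * state$mW[[i]] / (sqrt(state$vW[[i]]) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$gb[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$gb[[i]]^2
    net$b[[i]] <- net$b[[i]] - alpha * state$mb[[i]] / (sqrt(state$vb[[i]]) + eps)
  }
  list(net = net, state = state)
}

n_params <- function(net) {
  sum(vapply(net$W, length, numeric(1))) +
    sum(vapply(net$b, length, numeric(1)))
}
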