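## Internal neural-network primitives.
##
## Convention: activations are matrices with features in rows and samples in
## columns (column-major recycling then matches per-feature vectors).
## Parameters live in a flat named list `par`; batch-norm running statistics
## in `state`; forward caches and gradients in parallel named lists.

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

dense_fwd <- function(W, b, X) W %*% X + b

dense_bwd <- function(W, X, dY) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd_train <- function(g, be, X) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (X - mu) * ivar
  list(Y = g * xhat + be, xhat = xhat, ivar = ivar, mu = mu, v = v)
}

bn_fwd_eval <- function(g, be, rm, rv, X) {
  g * ((X - rm) / sqrt(rv + BN_EPS)) + be
}

bn_bwd <- function(g, cache, dY) {
  m <- ncol(dY)
  dxhat <- dY * g
  xhat <- cache$xhat
  dX <- (cache$ivar / m) *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dX = dX, dg = rowSums(dY * xhat), dbe = rowSums(dY))
}

drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## ---- an MLP block: [input dropout] then depth x (dense -> BN -> ReLU ->
## hidden dropout); parameters named <prefix>.L<l>.{W,b,g,be}, running stats
## <prefix>.L<l>.{rm,rv} -----------------------------------------------------

mlp_init <- function(ctx, prefix, n_in, widths) {
  for (l in seq_along(widths)) {
    nm <- sprintf("%s.L%d", prefix, l)
    ctx$par[[paste0(nm, ".W")]] <- he_init(widths[l], n_in)
    ctx$par[[paste0(nm, ".b")]] <- numeric(widths[l])
    ctx$par[[paste0(nm, ".g")]] <- rep(1, widths[l])
    ctx$par[[paste0(nm, ".be")]] <- numeric(widths[l])
    ctx$state[[paste0(nm, ".rm")]] <- numeric(widths[l])
    ctx$state[[paste0(nm, ".rv")]] <- rep(1, widths[l])
    n_in <- widths[l]
  }
  invisible(NULL)
}

mlp_fwd <- function(ctx, prefix, depth, X, drop_in = 0, drop_hidden = 0) {
  tr <- ctx$training
  if (tr && drop_in > 0) {
    m <- drop_mask(nrow(X), ncol(X), drop_in)
    ctx$cache[[paste0(prefix, ".din")]] <- m
    X <- X * m
  }
  for (l in seq_len(depth)) {
    nm <- sprintf("%s.L%d", prefix, l)
    ctx$cache[[paste0(nm, ".X")]] <- X
    Z <- dense_fwd(ctx$par[[paste0(nm, ".W")]], ctx$par[[paste0(nm, ".b")]], X)
    if (tr) {
      bn <- bn_fwd_train(ctx$par[[paste0(nm, ".g")]],
                         ctx$par[[paste0(nm, ".be")]], Z)
      ctx$cache[[paste0(nm, ".bn")]] <- bn[c("xhat", "ivar")]
      ctx$state[[paste0(nm, ".rm")]] <-
        (1 - BN_MOMENTUM) * ctx$state[[paste0(nm, ".rm")]] + BN_MOMENTUM * bn$mu
      ctx$state[[paste0(nm, ".rv")]] <-
        (1 - BN_MOMENTUM) * ctx$state[[paste0(nm, ".rv")]] + BN_MOMENTUM * bn$v
      A <- bn$Y
    } else {
      A <- bn_fwd_eval(ctx$par[[paste0(nm, ".g")]], ctx$par[[paste0(nm, ".be")]],
                       ctx$state[[paste0(nm, ".rm")]],
                       ctx$state[[paste0(nm, ".rv")]], Z)
    }
    ctx$cache[[paste0(nm, ".pre")]] <- A
    X <- pmax(A, 0)
    if (tr && drop_hidden > 0) {
      m <- drop_mask(nrow(X), ncol(X), drop_hidden)
      ctx$cache[[paste0(nm, ".dh")]] <- m
      X <- X * m
    }
  }
  X
}

mlp_bwd <- function(ctx, prefix, depth, dY) {
  for (l in rev(seq_len(depth))) {
    nm <- sprintf("%s.L%d", prefix, l)
    m <- ctx$cache[[paste0(nm, ".dh")]]
    if (!is.null(m)) dY <- dY * m
    dY <- dY * (ctx$cache[[paste0(nm, ".pre")]] > 0)
    bn <- bn_bwd(ctx$par[[paste0(nm, ".g")]], ctx$cache[[paste0(nm, ".bn")]], dY)
    ctx$grad[[paste0(nm, ".g")]] <- bn$dg
    ctx$grad[[paste0(nm, ".be")]] <- bn$dbe
    dd <- dense_bwd(ctx$par[[paste0(nm, ".W")]], ctx$cache[[paste0(nm, ".X")]],
                    bn$dX)
    ctx$grad[[paste0(nm, ".W")]] <- dd$dW
    ctx$grad[[paste0(nm, ".b")]] <- dd$db
    dY <- dd$dX
  }
  m <- ctx$cache[[paste0(prefix, ".din")]]
  if (!is.null(m)) dY <- dY * m
  dY
}

## ---- temporal max/mean pooling over a (L, T, b) array ----------------------

pool_fwd <- function(Zarr, type) {
  L <- dim(Zarr)[1]; Tb <- dim(Zarr)[2]; b <- dim(Zarr)[3]
  if (type == "mean") {
    M <- Zarr[, 1, ]
    if (Tb > 1) for (t in 2:Tb) M <- M + Zarr[, t, ]
    list(Y = matrix(M / Tb, L, b), amax = NULL)
  } else {
    M <- matrix(Zarr[, 1, ], L, b)
    amax <- matrix(1L, L, b)
    if (Tb > 1) for (t in 2:Tb) {
      Zt <- matrix(Zarr[, t, ], L, b)
      upd <- Zt > M
      M[upd] <- Zt[upd]
      amax[upd] <- t
    }
    list(Y = M, amax = amax)
  }
}

pool_bwd <- function(dM, type, amax, L, Tb, b) {
  dZ <- array(0, dim = c(L, Tb, b))
  if (type == "mean") {
    for (t in seq_len(Tb)) dZ[, t, ] <- dM / Tb
  } else {
    i <- rep(seq_len(L), b)
    p <- rep(seq_len(b), each = L)
    flat <- i + L * (as.vector(amax) - 1L) + L * Tb * (p - 1L)
    dZ[flat] <- as.vector(dM)
  }
  dZ
}

## ---- valid temporal convolution via im2col ---------------------------------
## input (L, T, b); kernel size k, stride 1, no padding; column layout:
## position fastest within patient

conv_im2col <- function(Zarr, k) {
  L <- dim(Zarr)[1]; Tb <- dim(Zarr)[2]; b <- dim(Zarr)[3]
  P <- Tb - k + 1L
  do.call(rbind, lapply(seq_len(k), function(j)
    matrix(Zarr[, j:(j + P - 1L), , drop = FALSE], L, P * b)))
}

conv_col2im <- function(dXcol, k, L, Tb, b) {
  P <- Tb - k + 1L
  dZ <- array(0, dim = c(L, Tb, b))
  for (j in seq_len(k)) {
    blk <- array(dXcol[((j - 1L) * L + 1L):(j * L), , drop = FALSE],
                 dim = c(L, P, b))
    dZ[, j:(j + P - 1L), ] <- dZ[, j:(j + P - 1L), ] + blk
  }
  dZ
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(par = par, opt = opt)
}
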