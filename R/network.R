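#' Network hyperparameters
#'
#' Tunable settings of the multimodal risk network. Encoder, domain and
#' fusion stages are bottleneck feedforward blocks of 1-4 hidden layers
#' (deeper is rejected); temporal aggregation is max or mean pooling over the
#' whole history, optionally augmented with valid temporal convolutions at
#' several kernel sizes whose filter outputs are max-pooled over positions
#' and concatenated with the pooled latents.
#'
#' @param enc_depth,enc_units subdomain encoder depth (1-4) and units: a
#'   scalar (repeated) or a vector of length `enc_depth`.
#' @param dom_depth,dom_units per-domain bottleneck depth and units.
#' @param fin_depth,fin_units fusion bottleneck depth and units.
#' @param pooling `"max"` or `"mean"` temporal pooling.
#' @param conv_enabled apply temporal convolutions in addition to pooling.
#' @param conv_kernels integer kernel sizes (each must be <= the number of
#'   time bins); three sizes by default.
#' @param conv_filters filters per kernel size.
#' @param dropout_input,dropout_hidden dropout rates in `[0, 1)` for input
#'   and hidden layers.
#' @param lambda groupwise elastic-net weights: list with `l1`, `l2`
#'   (scalar, or named vector with one entry per time-dependent/static
#'   subdomain group) applied to each subdomain's first-layer weights, and
#'   `l1_out`, `l2_out` for the weights feeding the output unit.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size; the Cox partial likelihood is computed
#'   within each minibatch, so this is a modelling choice, not only a
#'   throughput knob.
#' @param activation hidden activation (rectified linear only).
#' @return Validated list of class `hyperparams`.
#' @export
hyperparams <- function(enc_depth = 1L, enc_units = 16L,
                        dom_depth = 1L, dom_units = 16L,
                        fin_depth = 1L, fin_units = 16L,
                        pooling = c("max", "mean"),
                        conv_enabled = FALSE,
                        conv_kernels = c(2L, 3L, 4L), conv_filters = 4L,
                        dropout_input = 0, dropout_hidden = 0,
                        lambda = list(l1 = 0, l2 = 0, l1_out = 0, l2_out = 0),
                        lr = 0.01, batch_size = 256L,
                        activation = "relu") {
  pooling <- match.arg(pooling)
  chk_depth <- function(d, what) {
    if (!is.numeric(d) || d < 1 || d > 4)
      stop(what, " must have 1-4 hidden layers (got ", d, ")")
    as.integer(d)
  }
  expand <- function(units, depth) {
    u <- as.integer(units)
    if (length(u) == 1L) u <- rep(u, depth)
    if (length(u) != depth) stop("units vector must match depth")
    stopifnot(all(u >= 1))
    u
  }
  enc_depth <- chk_depth(enc_depth, "subdomain encoder")
  dom_depth <- chk_depth(dom_depth, "domain bottleneck")
  fin_depth <- chk_depth(fin_depth, "fusion bottleneck")
  stopifnot(dropout_input >= 0, dropout_input < 1,
            dropout_hidden >= 0, dropout_hidden < 1,
            lr > 0, batch_size >= 2, conv_filters >= 1,
            all(conv_kernels >= 1))
  if (!identical(activation, "relu"))
    stop("only the rectified-linear activation is implemented")
  for (nm in c("l1", "l2", "l1_out", "l2_out")) {
    if (is.null(lambda[[nm]])) lambda[[nm]] <- 0
    if (any(unlist(lambda[[nm]]) < 0)) stop("penalty weights must be >= 0")
  }
  structure(list(enc_depth = enc_depth, enc_units = expand(enc_units, enc_depth),
                 dom_depth = dom_depth, dom_units = expand(dom_units, dom_depth),
                 fin_depth = fin_depth, fin_units = expand(fin_units, fin_depth),
                 pooling = pooling, conv_enabled = conv_enabled,
                 conv_kernels = as.integer(conv_kernels),
                 conv_filters = as.integer(conv_filters),
                 dropout_input = dropout_input, dropout_hidden = dropout_hidden,
                 lambda = lambda, lr = lr, batch_size = as.integer(batch_size),
                 activation = activation),
            class = "hyperparams")
}

#' Build the multimodal risk network
#'
#' Constructs the scorer \eqn{N_W}: one bottleneck encoder per subdomain
#' (shared across time bins, applied position-wise for time-dependent
#' subdomains), latents concatenated within each domain; per-domain temporal
#' aggregation (pooling over the full time axis per latent component, plus
#' optional temporal convolutions — general-domain features bypass this
#' stage); a per-domain bottleneck; concatenation across domains; a fusion
#' bottleneck; and a single linear output unit. Batch normalization precedes
#' every activation, and dropout acts on input and hidden layers during
#' training.
#'
#' Weight groups are identifiable by name: `W_s` (first-layer weights of
#' subdomain `s`) and `W_D` (weights feeding the output unit) carry the
#' groupwise elastic-net penalties.
#'
#' @param schema a `feature_schema`.
#' @param hp a [hyperparams] object.
#' @param T_bins number of 30-day time bins (15 for the 456-day window).
#' @param seed integer seed for weight initialization.
#' @return Object of class `risk_model`.
#' @export
build_network <- function(schema, hp, T_bins = 15L, seed = 1L) {
  stopifnot(inherits(schema, "feature_schema"), inherits(hp, "hyperparams"))
  if (length(schema$subdomains) == 0) stop("schema is empty")
  if (hp$conv_enabled && any(hp$conv_kernels > T_bins))
    stop("convolution kernel size exceeds the number of time bins (",
         T_bins, ")")
  set.seed(seed)
  ctx <- new.env(parent = emptyenv())
  ctx$par <- list(); ctx$state <- list()

  domains <- schema_domains(schema)
  arch <- list(domains = domains, sub = list(), dom = list())
  for (s in schema$subdomains) {
    mlp_init(ctx, paste0("enc.", s$name), length(s$features), hp$enc_units)
    arch$sub[[s$name]] <- list(d = length(s$features),
                               out = hp$enc_units[hp$enc_depth],
                               time_dependent = s$time_dependent)
  }
  for (D in names(domains)) {
    L <- sum(vapply(arch$sub[domains[[D]]], `[[`, 0, "out"))
    timedep <- arch$sub[[domains[[D]][1]]]$time_dependent
    width <- L
    if (timedep && hp$conv_enabled) {
      for (k in hp$conv_kernels) {
        nm <- sprintf("conv.%s.k%d", D, k)
        ctx$par[[paste0(nm, ".W")]] <- he_init(hp$conv_filters, L * k)
        ctx$par[[paste0(nm, ".b")]] <- numeric(hp$conv_filters)
        ctx$par[[paste0(nm, ".g")]] <- rep(1, hp$conv_filters)
        ctx$par[[paste0(nm, ".be")]] <- numeric(hp$conv_filters)
        ctx$state[[paste0(nm, ".rm")]] <- numeric(hp$conv_filters)
        ctx$state[[paste0(nm, ".rv")]] <- rep(1, hp$conv_filters)
      }
      width <- L + hp$conv_filters * length(hp$conv_kernels)
    }
    mlp_init(ctx, paste0("dom.", D), width, hp$dom_units)
    arch$dom[[D]] <- list(latent = L, width = width, timedep = timedep,
                          out = hp$dom_units[hp$dom_depth])
  }
  fusion_in <- sum(vapply(arch$dom, `[[`, 0, "out"))
  mlp_init(ctx, "fin", fusion_in, hp$fin_units)
  ctx$par[["out.W"]] <- he_init(1L, hp$fin_units[hp$fin_depth])
  ctx$par[["out.b"]] <- 0

  groups <- list(
    subdomain = stats::setNames(
      lapply(names(schema$subdomains), function(s) paste0("enc.", s, ".L1.W")),
      names(schema$subdomains)),
    output = "out.W")
  structure(list(par = ctx$par, state = ctx$state, hp = hp, schema = schema,
                 arch = arch, T_bins = as.integer(T_bins), groups = groups,
                 schema_hash = schema_hash(schema)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, 0))
  cat("risk_model:", length(x$arch$sub), "subdomain branches,",
      length(x$arch$dom), "domains,", np, "parameters, T =", x$T_bins, "\n")
  invisible(x)
}

## check that a cube_set structurally matches the model's schema
check_cubes <- function(model, cubes) {
  for (nm in names(model$arch$sub)) {
    a <- cubes$sub[[nm]]
    if (is.null(a)) stop("cube set lacks subdomain '", nm, "'")
    d <- if (length(dim(a)) == 3) dim(a)[1] else nrow(a)
    if (d != model$arch$sub[[nm]]$d)
      stop("subdomain '", nm, "' dimension mismatch: model ",
           model$arch$sub[[nm]]$d, ", cubes ", d)
    if (model$arch$sub[[nm]]$time_dependent && dim(a)[2] != model$T_bins)
      stop("subdomain '", nm, "' has ", dim(a)[2], " bins, model expects ",
           model$T_bins)
  }
  invisible(TRUE)
}

## full forward pass; returns scores and (when keep_cache) everything the
## backward pass needs. `idx` selects patients from the cube set.
nn_forward <- function(model, cubes, idx = NULL, training = FALSE,
                       keep_cache = FALSE) {
  check_cubes(model, cubes)
  if (is.null(idx)) idx <- seq_along(cubes$patient_ids)
  b <- length(idx)
  hp <- model$hp
  Tb <- model$T_bins
  ctx <- new.env(parent = emptyenv())
  ctx$par <- model$par; ctx$state <- model$state
  ctx$cache <- list(); ctx$grad <- list()
  ctx$training <- training

  dom_out <- list()
  meta <- list()
  for (D in names(model$arch$domains)) {
    subs <- model$arch$domains[[D]]
    timedep <- model$arch$dom[[D]]$timedep
    lat <- list()
    for (s in subs) {
      a <- cubes$sub[[s]]
      X <- if (timedep) {
        sl <- a[, , idx, drop = FALSE]
        matrix(sl, dim(a)[1], Tb * b)
      } else {
        a[, idx, drop = FALSE]
      }
      lat[[s]] <- mlp_fwd(ctx, paste0("enc.", s), hp$enc_depth, X,
                          hp$dropout_input, hp$dropout_hidden)
    }
    Z <- do.call(rbind, lat)
    if (timedep) {
      L <- nrow(Z)
      Zarr <- array(Z, dim = c(L, Tb, b))
      pl <- pool_fwd(Zarr, hp$pooling)
      parts <- list(pl$Y)
      convmeta <- list()
      if (hp$conv_enabled) {
        for (k in hp$conv_kernels) {
          nm <- sprintf("conv.%s.k%d", D, k)
          Xcol <- conv_im2col(Zarr, k)
          ctx$cache[[paste0(nm, ".X")]] <- Xcol
          Zc <- dense_fwd(ctx$par[[paste0(nm, ".W")]],
                          ctx$par[[paste0(nm, ".b")]], Xcol)
          if (training) {
            bn <- bn_fwd_train(ctx$par[[paste0(nm, ".g")]],
                               ctx$par[[paste0(nm, ".be")]], Zc)
            ctx$cache[[paste0(nm, ".bn")]] <- bn[c("xhat", "ivar")]
            ctx$state[[paste0(nm, ".rm")]] <-
              (1 - BN_MOMENTUM) * ctx$state[[paste0(nm, ".rm")]] +
              BN_MOMENTUM * bn$mu
            ctx$state[[paste0(nm, ".rv")]] <-
              (1 - BN_MOMENTUM) * ctx$state[[paste0(nm, ".rv")]] +
              BN_MOMENTUM * bn$v
            A <- bn$Y
          } else {
            A <- bn_fwd_eval(ctx$par[[paste0(nm, ".g")]],
                             ctx$par[[paste0(nm, ".be")]],
                             ctx$state[[paste0(nm, ".rm")]],
                             ctx$state[[paste0(nm, ".rv")]], Zc)
          }
          ctx$cache[[paste0(nm, ".pre")]] <- A
          H <- pmax(A, 0)
          P <- Tb - k + 1L
          Harr <- array(H, dim = c(hp$conv_filters, P, b))
          cp <- pool_fwd(Harr, "max")
          convmeta[[as.character(k)]] <- list(amax = cp$amax, P = P)
          parts[[length(parts) + 1L]] <- cp$Y
        }
      }
      U <- do.call(rbind, parts)
      meta[[D]] <- list(L = L, amax = pl$amax, convmeta = convmeta)
    } else {
      U <- Z
      meta[[D]] <- list(L = nrow(Z))
    }
    ctx$cache[[paste0("domin.", D)]] <- U
    dom_out[[D]] <- mlp_fwd(ctx, paste0("dom.", D), hp$dom_depth, U,
                            0, hp$dropout_hidden)
  }
  F_in <- do.call(rbind, dom_out)
  Fh <- mlp_fwd(ctx, "fin", hp$fin_depth, F_in, 0, hp$dropout_hidden)
  scores <- as.vector(dense_fwd(ctx$par[["out.W"]], ctx$par[["out.b"]], Fh))
  if (!keep_cache)
    return(list(scores = scores, state = ctx$state))
  ctx$cache[["fin.X"]] <- Fh
  list(scores = scores, state = ctx$state, ctx = ctx, meta = meta,
       idx = idx, b = b)
}

## backward pass: dscores (length b) -> flat gradient list over model$par
nn_backward <- function(model, fwd, dscores) {
  hp <- model$hp
  Tb <- model$T_bins
  ctx <- fwd$ctx
  b <- fwd$b
  dY <- matrix(dscores, nrow = 1)
  dd <- dense_bwd(ctx$par[["out.W"]], ctx$cache[["fin.X"]], dY)
  ctx$grad[["out.W"]] <- dd$dW
  ctx$grad[["out.b"]] <- dd$db
  dF <- mlp_bwd(ctx, "fin", hp$fin_depth, dd$dX)

  offs <- 0
  for (D in names(model$arch$domains)) {
    w <- model$arch$dom[[D]]$out
    dUout <- dF[(offs + 1):(offs + w), , drop = FALSE]
    offs <- offs + w
    dU <- mlp_bwd(ctx, paste0("dom.", D), hp$dom_depth, dUout)
    timedep <- model$arch$dom[[D]]$timedep
    m <- fwd$meta[[D]]
    if (timedep) {
      dP <- dU[1:m$L, , drop = FALSE]
      dZarr <- pool_bwd(dP, hp$pooling, m$amax, m$L, Tb, b)
      if (hp$conv_enabled) {
        row0 <- m$L
        for (k in hp$conv_kernels) {
          nm <- sprintf("conv.%s.k%d", D, k)
          cm <- m$convmeta[[as.character(k)]]
          dC <- dU[(row0 + 1):(row0 + hp$conv_filters), , drop = FALSE]
          row0 <- row0 + hp$conv_filters
          dH <- pool_bwd(dC, "max", cm$amax, hp$conv_filters, cm$P, b)
          dH <- matrix(dH, hp$conv_filters, cm$P * b)
          dH <- dH * (ctx$cache[[paste0(nm, ".pre")]] > 0)
          bn <- bn_bwd(ctx$par[[paste0(nm, ".g")]],
                       ctx$cache[[paste0(nm, ".bn")]], dH)
          ctx$grad[[paste0(nm, ".g")]] <- bn$dg
          ctx$grad[[paste0(nm, ".be")]] <- bn$dbe
          cd <- dense_bwd(ctx$par[[paste0(nm, ".W")]],
                          ctx$cache[[paste0(nm, ".X")]], bn$dX)
          ctx$grad[[paste0(nm, ".W")]] <- cd$dW
          ctx$grad[[paste0(nm, ".b")]] <- cd$db
          dZarr <- dZarr + conv_col2im(cd$dX, k, m$L, Tb, b)
        }
      }
      dZ <- matrix(dZarr, m$L, Tb * b)
    } else {
      dZ <- dU
    }
    roff <- 0
    for (s in model$arch$domains[[D]]) {
      ws <- model$arch$sub[[s]]$out
      dls <- dZ[(roff + 1):(roff + ws), , drop = FALSE]
      roff <- roff + ws
      mlp_bwd(ctx, paste0("enc.", s), hp$enc_depth, dls)
    }
  }
  ctx$grad
}

#' Patient risk scores
#'
#' Evaluates the network in inference mode (dropout off, batch
#' normalization using stored running statistics): deterministic, finite
#' scores, one per patient.
#'
#' @param model a `risk_model`.
#' @param cubes a `cube_set` matching the model's schema (mismatch is an
#'   error).
#' @param idx optional integer subset of patients.
#' @return Numeric vector of risk scores (higher = riskier).
#' @export
risk_score <- function(model, cubes, idx = NULL) {
  nn_forward(model, cubes, idx = idx, training = FALSE)$scores
}
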