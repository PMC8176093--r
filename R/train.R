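#' Train a risk network
#'
#' Minimizes the penalized negative Cox partial log-likelihood by Adam over
#' minibatches (risk sets are formed within each minibatch). After every
#' epoch, Harrell's C on a held-out validation split is computed; training
#' stops at `epochs` or once the validation metric has not improved for
#' `patience` consecutive epochs, and the best-epoch weights are returned.
#'
#' @param model a `risk_model` from [build_network].
#' @param cubes a `cube_set`.
#' @param labels [survival_labels] aligned with `cubes$patient_ids`.
#' @param epochs maximum epochs (>= 1).
#' @param patience epochs without validation improvement before stopping.
#' @param val_frac fraction of patients held out for validation when
#'   `val_idx` is not given.
#' @param val_idx optional explicit validation indices.
#' @param verbose print per-epoch progress.
#' @return The trained `risk_model` with elements `history` (data.frame
#'   `epoch`, `loss`, `val_c`) and `best_epoch` added.
#' @export
train <- function(model, cubes, labels, epochs = 100L, patience = 10L,
                  val_frac = 0.2, val_idx = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "risk_model"), inherits(labels, "survival_labels"))
  if (epochs < 1) stop("'epochs' must be >= 1")
  n <- n_patients(cubes)
  if (nrow(labels) != n) stop("labels and cubes are misaligned")
  if (is.null(val_idx)) {
    n_val <- max(2L, floor(val_frac * n))
    val_idx <- sample.int(n, n_val)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  hp <- model$hp
  opt <- adam_init(model$par)
  best <- list(val = -Inf, par = model$par, state = model$state, epoch = 0L)
  since_best <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), val_c = numeric(0))

  for (ep in seq_len(epochs)) {
    sh <- sample(tr_idx)
    nb <- max(1L, ceiling(length(sh) / hp$batch_size))
    ep_loss <- 0; ep_events <- 0
    for (bi in seq_len(nb)) {
      bidx <- sh[((bi - 1L) * hp$batch_size + 1L):min(bi * hp$batch_size,
                                                      length(sh))]
      lb <- labels[bidx, , drop = FALSE]
      nev <- sum(lb$status)
      if (nev == 0 || length(bidx) < 2) next
      fwd <- nn_forward(model, cubes, idx = bidx, training = TRUE,
                        keep_cache = TRUE)
      if (any(!is.finite(fwd$scores)))
        stop("non-finite risk scores at epoch ", ep,
             " (batch ", bi, "); lower the learning rate")
      ll <- cox_partial_loglik(fwd$scores, lb)
      if (!is.finite(ll))
        stop("non-finite partial likelihood at epoch ", ep, " (batch ", bi, ")")
      ep_loss <- ep_loss - ll; ep_events <- ep_events + nev
      gs <- -cox_loglik_grad(fwd$scores, lb$time, lb$status) / nev
      grads <- nn_backward(model, fwd, gs)
      grads <- add_penalty_grads(model, grads)
      model$state <- fwd$state
      st <- adam_step(model$par, grads, opt, hp$lr)
      model$par <- st$par; opt <- st$opt
    }
    val_scores <- nn_forward(model, cubes, idx = val_idx)$scores
    vc <- suppressWarnings(
      harrell_c(val_scores, labels[val_idx, , drop = FALSE]))
    vc <- as.numeric(vc)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   loss = ep_loss / max(1, ep_events),
                                   val_c = vc))
    if (verbose)
      message(sprintf("epoch %3d  loss/event %.4f  val C %.4f", ep,
                      ep_loss / max(1, ep_events), vc))
    if (is.finite(vc) && vc > best$val) {
      best <- list(val = vc, par = model$par, state = model$state, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  model$par <- best$par
  model$state <- best$state
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

## groupwise elastic-net gradient contributions (squared l2 convention)
add_penalty_grads <- function(model, grads) {
  hp <- model$hp
  for (s in names(model$groups$subdomain)) {
    nm <- model$groups$subdomain[[s]]
    W <- model$par[[nm]]
    l1 <- group_lambda(hp$lambda$l1, s)
    l2 <- group_lambda(hp$lambda$l2, s)
    if (l1 > 0 || l2 > 0)
      grads[[nm]] <- grads[[nm]] + l1 * sign(W) + 2 * l2 * W
  }
  nm <- model$groups$output
  W <- model$par[[nm]]
  if (hp$lambda$l1_out > 0 || hp$lambda$l2_out > 0)
    grads[[nm]] <- grads[[nm]] + hp$lambda$l1_out * sign(W) +
      2 * hp$lambda$l2_out * W
  grads
}

#' Save / load a model checkpoint
#'
#' Serializes parameter groups by name (the subdomain first-layer groups
#' `W_s` and output group `W_D` stay identifiable), hyperparameters, the
#' schema and its hash, and fitted scaling constants, as JSON text.
#'
#' @param model a `risk_model`.
#' @param path checkpoint file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `risk_model`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    par = lapply(model$par, function(p)
      list(dim = dim(p), data = as.vector(p))),
    state = model$state,
    hp = unclass(model$hp),
    schema = model$schema$subdomains,
    schema_hash = model$schema_hash,
    T_bins = model$T_bins,
    groups = model$groups,
    scaling = model$scaling,
    best_epoch = model$best_epoch)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(pl$par, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  hp <- pl$hp
  hp$lambda <- as.list(hp$lambda)
  hp <- do.call(hyperparams, hp[names(hp) %in% names(formals(hyperparams))])
  schema <- structure(list(subdomains = lapply(pl$schema, function(s) {
    s$features <- as.character(s$features); s
  })), class = "feature_schema")
  model <- build_network(schema, hp, T_bins = pl$T_bins, seed = 1L)
  model$par <- par[names(model$par)]
  model$state <- lapply(pl$state, as.numeric)[names(model$state)]
  model$scaling <- pl$scaling
  model$best_epoch <- pl$best_epoch
  model
}
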