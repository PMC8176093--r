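#' Hyperparameter search space
#'
#' Declares one searchable dimension per entry. Numeric dimensions:
#' `list(type = "num"|"int", lower, upper, log = FALSE)`; categorical:
#' `list(type = "cat", values = c(...))`. Entry names map onto
#' [hyperparams] arguments, with `lambda_l1`, `lambda_l2`, `lambda_l1_out`,
#' `lambda_l2_out` folded into the `lambda` list.
#'
#' @param ... named dimension specs.
#' @return Object of class `hp_space`.
#' @export
hp_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0) stop("empty hyperparameter space")
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!d$type %in% c("num", "int", "cat"))
      stop("dimension '", nm, "': unknown type '", d$type, "'")
    if (d$type == "cat") {
      if (length(d$values) < 1) stop("dimension '", nm, "' has no values")
    } else if (is.null(d$lower) || is.null(d$upper) || d$lower > d$upper) {
      stop("dimension '", nm, "' needs lower <= upper")
    }
  }
  structure(dims, class = "hp_space")
}

## a space is degenerate when every dimension admits a single value
space_degenerate <- function(space) {
  all(vapply(space, function(d) {
    if (d$type == "cat") length(d$values) == 1
    else if (d$type == "int") d$lower == d$upper
    else isTRUE(all.equal(d$lower, d$upper))
  }, logical(1)))
}

## draw one configuration uniformly (log scale where declared)
space_sample <- function(space) {
  draw <- list()
  for (nm in names(space)) {
    d <- space[[nm]]
    draw[[nm]] <- switch(d$type,
      cat = d$values[[sample.int(length(d$values), 1)]],
      int = {
        if (isTRUE(d$log)) {
          round(exp(stats::runif(1, log(d$lower), log(d$upper))))
        } else {
          vals <- seq.int(d$lower, d$upper)
          vals[sample.int(length(vals), 1)]
        }
      },
      num = {
        if (isTRUE(d$log)) exp(stats::runif(1, log(d$lower), log(d$upper)))
        else stats::runif(1, d$lower, d$upper)
      })
  }
  draw
}

## map a draw onto [0,1]^d for the surrogate model
space_encode <- function(space, draw) {
  unlist(lapply(names(space), function(nm) {
    d <- space[[nm]]
    v <- draw[[nm]]
    if (d$type == "cat") {
      k <- length(d$values)
      if (k == 1) 0 else (match(v, d$values) - 1) / (k - 1)
    } else if (isTRUE(d$log)) {
      if (d$upper == d$lower) 0
      else (log(v) - log(d$lower)) / (log(d$upper) - log(d$lower))
    } else {
      if (d$upper == d$lower) 0 else (v - d$lower) / (d$upper - d$lower)
    }
  }))
}

## turn a draw into a hyperparams object (folding lambda_* into the list)
hp_from_draw <- function(draw, fixed = list()) {
  args <- utils::modifyList(fixed, draw)
  lam <- list(l1 = 0, l2 = 0, l1_out = 0, l2_out = 0)
  if (!is.null(args[["lambda"]]))
    lam <- utils::modifyList(lam, args[["lambda"]])
  for (nm in c("l1", "l2", "l1_out", "l2_out")) {
    key <- paste0("lambda_", nm)
    if (!is.null(args[[key]])) {
      lam[[nm]] <- args[[key]]
      args[[key]] <- NULL
    }
  }
  args$lambda <- lam
  do.call(hyperparams, args[names(args) %in% names(formals(hyperparams))])
}

## Gaussian-process expected improvement over encoded configurations
gp_ei <- function(X, y, Xcand, noise = 0.01, xi = 0.01) {
  d <- ncol(X)
  ell <- 0.3 * sqrt(d)
  sqd <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    outer(an, bn, "+") - 2 * tcrossprod(A, B)
  }
  K <- exp(-0.5 * pmax(sqd(X, X), 0) / ell^2) + diag(noise^2 + 1e-8, nrow(X))
  mu0 <- mean(y)
  a <- solve(K, y - mu0)
  Ks <- exp(-0.5 * pmax(sqd(Xcand, X), 0) / ell^2)
  mu <- as.vector(Ks %*% a) + mu0
  v <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  s <- sqrt(v)
  best <- max(y)
  z <- (mu - best - xi) / s
  (mu - best - xi) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Bayesian hyperparameter optimization
#'
#' Sequential model-based search maximizing cross-validated Harrell's C: an
#' initial block of random configurations, then a Gaussian-process surrogate
#' with expected-improvement acquisition over encoded configurations. Each
#' candidate is evaluated by `inner_folds`-fold cross-validation (a single
#' 75/25 split when `inner_folds = 1`). Reproducible under `seed`; a
#' degenerate single-point space returns after one trial.
#'
#' @param space an [hp_space].
#' @param cubes,labels training data.
#' @param n_trials number of configurations to evaluate (default 100).
#' @param inner_folds folds of the inner evaluation (default 5).
#' @param seed RNG seed controlling draws, folds and training.
#' @param fixed named list of [hyperparams] arguments held fixed.
#' @param epochs,patience per-trial training budget.
#' @param n_candidates candidate pool size per acquisition step.
#' @return Object of class `hpo_result`: `best_hp` ([hyperparams]),
#'   `best_draw`, `best_score`, and `trials` (data.frame log with one row
#'   per trial: trial number, score, JSON-encoded draw).
#' @export
bayesian_hpo <- function(space, cubes, labels, n_trials = 100L,
                         inner_folds = 5L, seed = 1L, fixed = list(),
                         epochs = 30L, patience = 5L, n_candidates = 128L) {
  stopifnot(inherits(space, "hp_space"))
  if (space_degenerate(space)) n_trials <- 1L
  n <- n_patients(cubes)
  set.seed(seed)
  folds <- make_folds(n, if (inner_folds >= 2L) inner_folds else 4L)
  eval_draw <- function(draw, trial) {
    hp <- hp_from_draw(draw, fixed)
    cs <- numeric(0)
    for (f in seq_len(max(inner_folds, 1L))) {
      set.seed(seed + 7919L * trial + f)
      if (inner_folds >= 2) {
        te <- which(folds == f); tr <- which(folds != f)
      } else {
        te <- which(folds == 1); tr <- which(folds != 1)
      }
      if (sum(labels$status[tr]) == 0 || sum(labels$status[te]) == 0) next
      mdl <- build_network(cubes$schema, hp, T_bins = cubes$T_bins,
                           seed = seed + trial)
      mdl <- train(mdl, subset_cubes(cubes, tr),
                   labels[tr, , drop = FALSE],
                   epochs = epochs, patience = patience)
      sc <- risk_score(mdl, cubes, idx = te)
      cs <- c(cs, suppressWarnings(
        as.numeric(harrell_c(sc, labels[te, , drop = FALSE]))))
      if (inner_folds <= 1) break
    }
    if (length(cs) == 0 || all(is.na(cs))) return(NA_real_)
    mean(cs, na.rm = TRUE)
  }

  n_init <- min(n_trials, max(4L, ceiling(n_trials / 3)))
  draws <- list(); scores <- numeric(0)
  for (tr in seq_len(n_trials)) {
    set.seed(seed + 104729L * tr)
    if (tr <= n_init || length(stats::na.omit(scores)) < 3) {
      draw <- space_sample(space)
    } else {
      ok <- which(!is.na(scores))
      X <- do.call(rbind, lapply(draws[ok], function(d) space_encode(space, d)))
      cand <- replicate(n_candidates, space_sample(space), simplify = FALSE)
      Xc <- do.call(rbind, lapply(cand, function(d) space_encode(space, d)))
      ei <- gp_ei(X, scores[ok], Xc)
      draw <- cand[[which.max(ei)]]
    }
    draws[[tr]] <- draw
    scores[tr] <- eval_draw(draw, tr)
  }
  best <- which.max(scores)
  trials <- data.frame(
    trial = seq_len(n_trials), score = scores,
    params = vapply(draws, function(d)
      as.character(jsonlite::toJSON(d, auto_unbox = TRUE)), character(1)))
  structure(list(best_hp = hp_from_draw(draws[[best]], fixed),
                 best_draw = draws[[best]], best_score = scores[best],
                 trials = trials),
            class = "hpo_result")
}

#' @export
print.hpo_result <- function(x, ...) {
  cat(sprintf("hpo_result: %d trials, best inner-CV Harrell's C = %.4f\n",
              nrow(x$trials), x$best_score))
  cat("  best:", x$trials$params[which.max(x$trials$score)], "\n")
  invisible(x)
}

## deterministic fold assignment
make_folds <- function(n, k) sample(rep_len(seq_len(k), n))

#' Nested cross-validation
#'
#' Outer `outer_folds`-fold cross-validation where hyperparameters are tuned
#' (via [bayesian_hpo]) on each outer-training set only, a final model is
#' refit on the full outer-training set, and Uno's IPCW C-index is reported
#' on the untouched outer test fold. Folds are fixed by `seed`; the five
#' test sets are disjoint and cover all patients.
#'
#' @inheritParams bayesian_hpo
#' @param outer_folds number of outer folds.
#' @param hp optional fixed [hyperparams]; when supplied (and `space` is
#'   `NULL`) tuning is skipped.
#' @param space optional [hp_space] for tuning.
#' @param final_epochs,final_patience training budget of the per-fold final
#'   model.
#' @return Object of class `nested_cv_result`: `folds` (data.frame `fold`,
#'   `n_test`, `n_events`, `uno_c`, `tau`), `mean`, `sd`, `fold_assign`.
#' @export
nested_cv <- function(cubes, labels, outer_folds = 5L, space = NULL,
                      hp = NULL, n_trials = 10L, inner_folds = 2L,
                      seed = 1L, fixed = list(), epochs = 30L, patience = 5L,
                      final_epochs = 60L, final_patience = 10L) {
  n <- n_patients(cubes)
  set.seed(seed)
  fold_assign <- make_folds(n, outer_folds)
  rows <- list()
  for (f in seq_len(outer_folds)) {
    te <- which(fold_assign == f); tr <- which(fold_assign != f)
    if (sum(labels$status[tr]) == 0) {
      warning("outer fold ", f, " has no training events; skipped")
      next
    }
    tr_cubes <- subset_cubes(cubes, tr)
    tr_lab <- labels[tr, , drop = FALSE]
    if (!is.null(space)) {
      tuned <- bayesian_hpo(space, tr_cubes, tr_lab, n_trials = n_trials,
                            inner_folds = inner_folds, seed = seed + 13L * f,
                            fixed = fixed, epochs = epochs, patience = patience)
      hp_f <- tuned$best_hp
    } else if (!is.null(hp)) {
      hp_f <- hp
    } else stop("provide either 'space' or 'hp'")
    set.seed(seed + 977L * f)
    mdl <- build_network(cubes$schema, hp_f, T_bins = cubes$T_bins,
                         seed = seed + f)
    mdl <- train(mdl, tr_cubes, tr_lab, epochs = final_epochs,
                 patience = final_patience)
    sc <- risk_score(mdl, cubes, idx = te)
    te_lab <- labels[te, , drop = FALSE]
    uc <- suppressWarnings(uno_c(sc, te_lab))
    rows[[f]] <- data.frame(fold = f, n_test = length(te),
                            n_events = sum(te_lab$status),
                            uno_c = uc$estimate, tau = uc$tau)
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds, mean = mean(folds$uno_c, na.rm = TRUE),
                 sd = stats::sd(folds$uno_c), fold_assign = fold_assign),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  print(x$folds, row.names = FALSE)
  cat(sprintf("mean Uno's C = %.4f +/- %.4f over %d folds\n",
              x$mean, x$sd, nrow(x$folds)))
  invisible(x)
}
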