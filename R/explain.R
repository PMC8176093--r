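#' Exact Shapley values by subset enumeration
#'
#' Game-theoretic attribution of a black-box score to each input feature:
#' \deqn{\Phi_i(x) = \sum_{S \subseteq F \setminus \{i\}}
#'   \frac{|S|!\,(|F|-|S|-1)!}{|F|!}\,[f(x_{S \cup \{i\}}) - f(x_S)]}
#' where "absent" features are replaced by their reference value. Exact
#' enumeration needs `2^|F|` evaluations and is limited to small feature
#' sets; it serves as the oracle against which approximations are checked.
#'
#' @param f function taking a numeric vector (same length as `x`) and
#'   returning a scalar.
#' @param x numeric feature vector to explain.
#' @param reference numeric reference ("absent") vector.
#' @param max_features refuse larger problems (directing to [approx_shap]).
#' @return Numeric vector `phi` with `sum(phi) = f(x) - f(reference)` to
#'   machine precision, plus attribute `base` (`f(reference)`).
#' @export
exact_shapley <- function(f, x, reference, max_features = 15L) {
  M <- length(x)
  stopifnot(length(reference) == M)
  if (M > max_features)
    stop(M, " features exceed the exact enumeration limit (", max_features,
         "); use approx_shap()")
  n_masks <- bitwShiftL(1L, M)
  vals <- numeric(n_masks)
  for (m in 0:(n_masks - 1L)) {
    on <- bitwAnd(bitwShiftR(m, 0:(M - 1L)), 1L) == 1L
    z <- reference
    z[on] <- x[on]
    vals[m + 1L] <- f(z)
  }
  wt <- exp(lfactorial(0:(M - 1L)) + lfactorial(M - 1L - 0:(M - 1L)) -
              lfactorial(M))
  phi <- numeric(M)
  sizes <- vapply(0:(n_masks - 1L),
                  function(m) sum(bitwAnd(bitwShiftR(m, 0:(M - 1L)), 1L)),
                  numeric(1))
  for (i in seq_len(M)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L)
    s <- sizes[without]
    phi[i] <- sum(wt[s + 1L] * (vals[without + bit] - vals[without]))
  }
  structure(phi, base = vals[1L])
}

## ---- kernel-based Shapley approximation -----------------------------------
## Weighted-least-squares formulation; with full mask enumeration this is
## exact, with sampled masks it is the model-agnostic fallback. Masks with
## 0 < |z| < M carry kernel weight (M-1)/(choose(M,|z|) |z| (M-|z|)); the
## empty and full coalitions enter as hard constraints.
kernel_shap_solve <- function(y_masked, Z, f0, fx) {
  M <- ncol(Z)
  sz <- rowSums(Z)
  keep <- sz > 0 & sz < M
  Z <- Z[keep, , drop = FALSE]; y <- y_masked[keep]; sz <- sz[keep]
  if (M == 1) return(fx - f0)
  w <- (M - 1) / (choose(M, sz) * sz * (M - sz))
  ## eliminate phi_M through the efficiency constraint
  yt <- (y - f0) - Z[, M] * (fx - f0)
  A <- Z[, -M, drop = FALSE] - Z[, M]
  WA <- A * w
  G <- crossprod(WA, A)
  diag(G) <- diag(G) + 1e-10
  phi_head <- solve(G, crossprod(WA, yt))
  phi <- c(phi_head, (fx - f0) - sum(phi_head))
  as.numeric(phi)
}

## all 2^M masks as a logical matrix (rows = masks)
all_masks <- function(M) {
  n <- bitwShiftL(1L, M)
  outer(0:(n - 1L), 0:(M - 1L),
        function(m, i) bitwAnd(bitwShiftR(m, i), 1L) == 1L)
}

## sampled masks: sizes from the kernel distribution, antithetic complements
sample_masks <- function(M, nsamples) {
  s_grid <- 1:(M - 1)
  p <- (M - 1) / (s_grid * (M - s_grid))
  p <- p / sum(p)
  half <- ceiling(nsamples / 2)
  sizes <- sample(s_grid, half, replace = TRUE, prob = p)
  Z <- matrix(FALSE, 2L * half, M)
  for (r in seq_len(half)) {
    on <- sample.int(M, sizes[r])
    Z[2L * r - 1L, on] <- TRUE
    Z[2L * r, ] <- TRUE
    Z[2L * r, on] <- FALSE
  }
  Z
}

#' Reference ("average patient") cube
#'
#' The absent-feature baseline: zero for one-hot features (time-dependent
#' subdomains and binary static features), the background mean for
#' continuous static features.
#'
#' @param background a `cube_set` of background patients (training sample).
#' @return list: per subdomain, a `d x T` zero matrix or a static reference
#'   vector.
#' @export
reference_cube <- function(background) {
  out <- list()
  for (nm in names(background$sub)) {
    a <- background$sub[[nm]]
    if (length(dim(a)) == 3) {
      out[[nm]] <- matrix(0, dim(a)[1], dim(a)[2])
    } else {
      mu <- rowMeans(a)
      binary <- apply(a, 1, function(v) all(v %in% c(0, 1)))
      mu[binary] <- 0
      out[[nm]] <- mu
    }
  }
  out
}

## flat player directory for a cube set: one player per (subdomain, feature)
player_directory <- function(cubes) {
  do.call(rbind, lapply(names(cubes$sub), function(nm) {
    s <- cubes$schema$subdomains[[nm]]
    data.frame(subdomain = nm, feature = s$features,
               fidx = seq_along(s$features),
               name = paste0(nm, ":", s$features))
  }))
}

#' Approximate Shapley attributions for a risk model
#'
#' Kernel-based Shapley values over *features*: each feature (its full time
#' row for time-dependent subdomains) is one player; switching a player off
#' replaces its row/entry by the reference. With few active players all
#' coalitions are enumerated and the values are exact; otherwise coalitions
#' are sampled (model-agnostic fallback). Features already at their
#' reference value are exact dummies and receive zero. Additivity
#' \eqn{\sum_i \Phi_i = f(x) - f(\mathrm{ref})} holds by construction.
#'
#' @param model a `risk_model`.
#' @param cubes a `cube_set` of patients to explain.
#' @param background a `cube_set` of background (training) patients defining
#'   the reference; must be non-empty.
#' @param idx optional patient subset of `cubes`.
#' @param exact_limit enumerate all coalitions when the number of active
#'   players is at most this (default 12).
#' @param nsamples sampled coalitions otherwise (default `max(4M, 1024)`).
#' @return Matrix (patients x all features, named `subdomain:feature`) of
#'   signed attributions, with attributes `base` (reference score) and
#'   `fx` (per-patient scores).
#' @export
approx_shap <- function(model, cubes, background, idx = NULL,
                        exact_limit = 12L, nsamples = NULL) {
  if (is.null(background) || n_patients(background) == 0)
    stop("background sample is empty")
  if (is.null(idx)) idx <- seq_along(cubes$patient_ids)
  ref <- reference_cube(background)
  dir <- player_directory(cubes)
  ## reference score
  ref_cubes <- structure(list(
    sub = lapply(names(ref), function(nm) {
      r <- ref[[nm]]
      if (is.matrix(r)) array(r, dim = c(dim(r), 1L)) else matrix(r, ncol = 1)
    }) |> stats::setNames(names(ref)),
    patient_ids = "reference", T_bins = cubes$T_bins,
    schema = cubes$schema, scaling = cubes$scaling), class = "cube_set")
  f0 <- risk_score(model, ref_cubes)
  fx <- risk_score(model, cubes, idx = idx)

  phi <- matrix(0, length(idx), nrow(dir),
                dimnames = list(cubes$patient_ids[idx], dir$name))
  for (pi in seq_along(idx)) {
    p <- idx[pi]
    ## active players: entries differing from the reference
    active <- logical(nrow(dir))
    xvals <- numeric(nrow(dir))
    for (nm in names(cubes$sub)) {
      a <- cubes$sub[[nm]]
      rows <- which(dir$subdomain == nm)
      if (length(dim(a)) == 3) {
        xi <- a[, , p, drop = FALSE]
        active[rows] <- rowSums(abs(matrix(xi, dim(a)[1], dim(a)[2]) -
                                      ref[[nm]])) > 0
      } else {
        active[rows] <- abs(a[, p] - ref[[nm]]) > 0
      }
    }
    act <- which(active)
    M <- length(act)
    if (M == 0) next
    if (M <= exact_limit) {
      Z <- all_masks(M)
    } else {
      ns <- if (is.null(nsamples)) max(4L * M, 1024L) else nsamples
      Z <- rbind(rep(FALSE, M), rep(TRUE, M), sample_masks(M, ns))
    }
    ## evaluate all masked variants in one forward pass
    nm_list <- names(cubes$sub)
    masked <- list()
    for (nm in nm_list) {
      a <- cubes$sub[[nm]]
      rows_all <- which(dir$subdomain == nm)
      act_here <- intersect(act, rows_all)
      if (length(dim(a)) == 3) {
        d <- dim(a)[1]; Tb <- dim(a)[2]
        base <- array(ref[[nm]], dim = c(d, Tb, nrow(Z)))
        xi <- matrix(a[, , p], d, Tb)
        for (k in seq_along(act_here)) {
          fi <- dir$fidx[act_here[k]]
          on <- Z[, match(act_here[k], act)]
          if (any(on)) base[fi, , on] <- xi[fi, ]
        }
        masked[[nm]] <- base
      } else {
        base <- matrix(ref[[nm]], nrow(a), nrow(Z))
        for (k in seq_along(act_here)) {
          fi <- dir$fidx[act_here[k]]
          on <- Z[, match(act_here[k], act)]
          base[fi, on] <- a[fi, p]
        }
        masked[[nm]] <- base
      }
    }
    mc <- structure(list(sub = masked,
                         patient_ids = paste0("m", seq_len(nrow(Z))),
                         T_bins = cubes$T_bins, schema = cubes$schema,
                         scaling = cubes$scaling), class = "cube_set")
    yv <- risk_score(model, mc)
    if (M == 1) {
      phi[pi, act] <- fx[pi] - f0
    } else {
      phi[pi, act] <- kernel_shap_solve(yv, Z, f0, fx[pi])
    }
  }
  structure(phi, base = f0, fx = fx)
}

#' Subsampled Shapley analysis
#'
#' Repeatedly subsamples a fraction of the cohort with replacement,
#' recomputes Shapley attributions on each subsample, aggregates them per
#' feature / subdomain / domain, and reports across-repeat means and
#' variances as a robustness check.
#'
#' @inheritParams approx_shap
#' @param fraction subsample fraction (default 0.05).
#' @param repeats number of subsamples (default 30).
#' @param seed RNG seed.
#' @param background_size background patients drawn once from `cubes`.
#' @return Object of class `shap_report`: `feature`, `subdomain`, `domain`,
#'   `origin` data.frames (columns `mean`, `var` across repeats plus the
#'   grouping), `repeats`, `fraction`.
#' @export
subsampled_shap <- function(model, cubes, fraction = 0.05, repeats = 30L,
                            seed = 1L, background_size = 50L,
                            exact_limit = 12L, nsamples = NULL) {
  n <- n_patients(cubes)
  m <- ceiling(fraction * n)
  if (m < 2) stop("fraction * n = ", fraction * n,
                  " < 2: subsample too small")
  set.seed(seed)
  bg <- subset_cubes(cubes, sample.int(n, min(background_size, n)))
  agg_feat <- list(); agg_sub <- list(); agg_dom <- list(); agg_org <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + 31L * r)
    ids <- sample.int(n, m, replace = TRUE)
    phi <- approx_shap(model, cubes, bg, idx = ids,
                       exact_limit = exact_limit, nsamples = nsamples)
    ag <- aggregate_importance(phi, cubes$schema)
    agg_feat[[r]] <- ag$feature$mean_abs_phi
    agg_sub[[r]] <- ag$subdomain$mean_abs_phi
    agg_dom[[r]] <- ag$domain$mean_abs_phi
    agg_org[[r]] <- ag$origin$mean_abs_phi
    if (r == 1) template <- ag
  }
  pack <- function(lst, tmpl) {
    mat <- do.call(cbind, lst)
    tmpl$mean_abs_phi <- NULL
    tmpl$share <- NULL
    tmpl$mean <- rowMeans(mat)
    tmpl$var <- apply(mat, 1, stats::var)
    tmpl
  }
  structure(list(feature = pack(agg_feat, template$feature),
                 subdomain = pack(agg_sub, template$subdomain),
                 domain = pack(agg_dom, template$domain),
                 origin = pack(agg_org, template$origin),
                 repeats = repeats, fraction = fraction),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("shap_report:", x$repeats, "subsamples of fraction", x$fraction, "\n")
  cat("domain importance (mean |Phi| across repeats):\n")
  print(x$domain, row.names = FALSE)
  invisible(x)
}

#' Aggregate Shapley attributions over the feature hierarchy
#'
#' Per-feature importance is the mean absolute attribution. Group
#' (subdomain, domain, feature-origin) importance exploits additivity:
#' attributions are summed *within the group per patient first*, then the
#' absolute value is taken, then averaged over patients. Shares are
#' normalized within each partition (domains sum to 1; origins sum to 1).
#'
#' @param phi attribution matrix from [approx_shap] (columns named
#'   `subdomain:feature`).
#' @param schema the `feature_schema`; every column must map to a schema
#'   subdomain (unmapped features are an error).
#' @return list of data.frames: `feature` (`subdomain`, `feature`,
#'   `mean_abs_phi`, `share`), `subdomain`, `domain`, `origin` (each with
#'   `mean_abs_phi` and `share`).
#' @export
aggregate_importance <- function(phi, schema) {
  sub_of <- sub(":.*$", "", colnames(phi))
  unknown <- setdiff(unique(sub_of), names(schema$subdomains))
  if (length(unknown))
    stop("features map to no schema subdomain: ",
         paste(unknown, collapse = ", "))
  dom_of <- vapply(schema$subdomains, `[[`, "", "domain")[sub_of]
  org_of <- vapply(schema$subdomains, `[[`, "", "origin")[sub_of]

  feat <- data.frame(subdomain = sub_of,
                     feature = sub("^[^:]*:", "", colnames(phi)),
                     mean_abs_phi = colMeans(abs(phi)))
  feat$share <- if (sum(feat$mean_abs_phi) > 0)
    feat$mean_abs_phi / sum(feat$mean_abs_phi) else 0
  group_agg <- function(groups) {
    g <- unique(groups)
    v <- vapply(g, function(k) {
      mean(abs(rowSums(phi[, groups == k, drop = FALSE])))
    }, numeric(1))
    df <- data.frame(group = g, mean_abs_phi = v)
    df$share <- if (sum(v) > 0) v / sum(v) else 0
    df
  }
  sub_df <- group_agg(sub_of); names(sub_df)[1] <- "subdomain"
  dom_df <- group_agg(dom_of); names(dom_df)[1] <- "domain"
  org_df <- group_agg(org_of); names(org_df)[1] <- "origin"
  list(feature = feat, subdomain = sub_df, domain = dom_df, origin = org_df)
}

#' Marginal dependency of attribution on feature exposure
#'
#' For a time-dependent feature, a patient's exposure is the fraction of
#' history bins in which the feature is present (0% = never observed, 100% =
#' observed every month); for a static feature it is the raw value. Each
#' patient contributes one (exposure, attribution) pair.
#'
#' @param phi attribution matrix from [approx_shap].
#' @param cubes the `cube_set` the attributions were computed on (same
#'   patient order as `phi` rows).
#' @param subdomain,feature the feature to profile.
#' @return data.frame `patient_id`, `exposure` (fraction in `[0, 1]` for
#'   time-dependent features), `phi`.
#' @export
marginal_dependency <- function(phi, cubes, subdomain, feature) {
  col <- paste0(subdomain, ":", feature)
  if (!col %in% colnames(phi)) stop("no attribution column '", col, "'")
  a <- cubes$sub[[subdomain]]
  fi <- match(feature, cubes$schema$subdomains[[subdomain]]$features)
  if (is.na(fi)) stop("feature '", feature, "' not in subdomain '",
                      subdomain, "'")
  pidx <- match(rownames(phi), cubes$patient_ids)
  exposure <- if (length(dim(a)) == 3) {
    colMeans(matrix(a[fi, , ] > 0, dim(a)[2], dim(a)[3]))[pidx]
  } else {
    a[fi, pidx]
  }
  data.frame(patient_id = rownames(phi), exposure = exposure,
             phi = phi[, col])
}
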