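test_that("exact Shapley values satisfy additivity and dummy on closed-form models", {
  # additive model: Phi_i = x_i with zero reference
  f_add <- function(z) sum(z)
  x <- c(1.5, -2, 0.5)
  phi <- exact_shapley(f_add, x, rep(0, 3))
  expect_equal(as.numeric(phi), x)
  # a feature the model never reads gets zero
  f_part <- function(z) 3 * z[1] - z[2]
  phi2 <- exact_shapley(f_part, c(1, 1, 7), c(0, 0, 0))
  expect_equal(as.numeric(phi2[3]), 0)
  # 3-feature product model vs the independent permutation-average oracle
  f_prod <- function(z) z[1] * z[2] * z[3] + 2 * z[1]
  x3 <- c(2, 3, 0.5); r3 <- c(0.1, -1, 0.2)
  phi3 <- exact_shapley(f_prod, x3, r3)
  expect_equal(as.numeric(phi3), oracle_shapley_perm(f_prod, x3, r3),
               tolerance = 1e-12)
  # efficiency to machine precision
  expect_equal(sum(phi3), f_prod(x3) - f_prod(r3), tolerance = 1e-12)
  # enumeration limit
  expect_error(exact_shapley(f_add, rep(1, 20), rep(0, 20)), "limit")
})

test_that("exact Shapley passes efficiency, symmetry, dummy and linearity on random models", {
  set.seed(55)
  for (r in 1:12) {
    M <- sample(3:8, 1)
    W1 <- matrix(rnorm(4 * M), 4)
    w2 <- rnorm(4)
    f <- function(z) sum(w2 * tanh(W1 %*% z))
    g <- function(z) sum(z^2) / 2
    x <- rnorm(M); ref <- rnorm(M, sd = 0.3)
    pf <- exact_shapley(f, x, ref)
    pg <- exact_shapley(g, x, ref)
    # efficiency
    expect_equal(sum(pf), f(x) - f(ref), tolerance = 1e-10)
    # linearity: Phi[a f + b g] = a Phi[f] + b Phi[g]
    pl <- exact_shapley(function(z) 2 * f(z) - 3 * g(z), x, ref)
    expect_equal(as.numeric(pl), as.numeric(2 * pf - 3 * pg),
                 tolerance = 1e-10)
    # dummy: an ignored coordinate gets zero
    fd <- function(z) f(c(z[-M], ref[M]))
    pd <- exact_shapley(fd, x, ref)
    expect_equal(as.numeric(pd[M]), 0, tolerance = 1e-12)
    # symmetry: swap two interchangeable features
    fs <- function(z) z[1] + z[2] + sum(sin(z[-c(1, 2)]))
    xs <- x; xs[2] <- xs[1]
    rs <- ref; rs[2] <- rs[1]
    ps <- exact_shapley(fs, xs, rs)
    expect_equal(as.numeric(ps[1]), as.numeric(ps[2]), tolerance = 1e-10)
  }
})

## a tiny featurized model for the attribution tests: 6 binary features
shap_fixture <- function() {
  if (is.null(.fixture_env$shapfix)) {
    set.seed(91)
    n <- 160
    X <- matrix(rbinom(6 * n, 1, 0.45), 6)
    cubes <- toy_cubes(X, T_bins = 3)
    lp <- 3 * X[1, ] - 1.5 * X[2, ]
    tt <- rexp(n, exp(lp) / 8)
    cc <- rexp(n, 1 / 10)
    labels <- survival_labels(ceiling(pmin(tt, cc)), as.integer(tt <= cc))
    hp <- hyperparams(enc_units = 6, dom_units = 6, fin_units = 6,
                      pooling = "mean", batch_size = 64)
    m <- build_network(cubes$schema, hp, T_bins = 3, seed = 8)
    set.seed(12)
    m <- train(m, cubes, labels, epochs = 40, patience = 40)
    .fixture_env$shapfix <- list(model = m, cubes = cubes, labels = labels)
  }
  .fixture_env$shapfix
}

test_that("kernel approximation matches exact Shapley on a linear single-layer model", {
  set.seed(17)
  M <- 7
  w <- rnorm(M)
  sch <- build_schema(list(phewas = sprintf("f%02d", 1:M)))
  # linear scorer expressed through the package's kernel machinery
  f <- function(z) sum(w * z) + 1
  x <- rbinom(M, 1, 0.7); ref <- rep(0, M)
  exact <- exact_shapley(f, x, ref)
  Z <- claimrisk:::all_masks(sum(x != ref))
  act <- which(x != ref)
  yv <- apply(Z, 1, function(on) {
    z <- ref; z[act[on]] <- x[act[on]]; f(z)
  })
  phi_act <- claimrisk:::kernel_shap_solve(yv, Z, f(ref), f(x))
  phi <- numeric(M); phi[act] <- phi_act
  expect_equal(phi, as.numeric(exact), tolerance = 1e-6)
})

test_that("model attributions: linear-model agreement, reference zeroes, additivity", {
  fix <- shap_fixture()
  bg <- subset_cubes(fix$cubes, 1:40)
  # agreement with exact enumeration through the model itself
  phi <- approx_shap(fix$model, fix$cubes, bg, idx = 1:25)
  fx <- attr(phi, "fx"); f0 <- attr(phi, "base")
  # all-reference input yields ~zero attributions
  zc <- fix$cubes
  zc$sub$phewas[, , 1] <- 0
  phi0 <- approx_shap(fix$model, zc, bg, idx = 1)
  expect_equal(max(abs(phi0)), 0)
  # additivity residual below tolerance for every patient
  expect_equal(unname(rowSums(phi)), fx - f0, tolerance = 1e-8)
  # cross-check one patient against exact_shapley on the model black box
  p <- 3
  xvec <- fix$cubes$sub$phewas[, 1, p]  # identical across bins by fixture
  fmod <- function(z) {
    cc <- fix$cubes
    cc$sub$phewas[, , p] <- matrix(z, 6, 3)
    risk_score(fix$model, cc, idx = p)
  }
  ex <- exact_shapley(fmod, xvec, rep(0, 6))
  expect_equal(unname(phi[p, ]), as.numeric(ex), tolerance = 1e-8)
})

test_that("subsampled SHAP is reproducible, degenerates to a single pass, and ranks planted signal", {
  fix <- shap_fixture()
  r1 <- subsampled_shap(fix$model, fix$cubes, fraction = 0.05, repeats = 1,
                        seed = 5)
  expect_true(all(is.na(r1$feature$var)))
  # repeats = 1: report equals the single-pass aggregation, replayed by hand
  n <- n_patients(fix$cubes)
  set.seed(5)
  bg1 <- subset_cubes(fix$cubes, sample.int(n, min(50, n)))
  set.seed(5 + 31)
  ids1 <- sample.int(n, ceiling(0.05 * n), replace = TRUE)
  phi1 <- approx_shap(fix$model, fix$cubes, bg1, idx = ids1)
  ag1p <- aggregate_importance(phi1, fix$cubes$schema)
  expect_equal(r1$feature$mean, unname(ag1p$feature$mean_abs_phi))
  r2 <- subsampled_shap(fix$model, fix$cubes, fraction = 0.05, repeats = 3,
                        seed = 5)
  r3 <- subsampled_shap(fix$model, fix$cubes, fraction = 0.05, repeats = 3,
                        seed = 5)
  expect_equal(r2$feature$mean, r3$feature$mean)   # fixed seed reruns
  expect_error(subsampled_shap(fix$model, fix$cubes, fraction = 0.001,
                               repeats = 2, seed = 1),
               "too small")
  # planted signal: strongest feature beats every noise feature in >= 27/30
  rep30 <- 30
  wins <- 0
  set.seed(44)
  for (r in seq_len(rep30)) {
    ids <- sample.int(n_patients(fix$cubes), 14, replace = TRUE)
    phi <- approx_shap(fix$model, fix$cubes,
                       subset_cubes(fix$cubes, 1:40), idx = ids)
    imp <- colMeans(abs(phi))
    if (all(imp[1] > imp[3:6])) wins <- wins + 1
  }
  expect_gte(wins, 27)
})

test_that("importance aggregation respects hierarchy, shares, and the documented order", {
  sch <- build_schema(list(phewas = c("a", "b"), substance = "s"),
                      static = list(demographics = "age"))
  phi <- matrix(c(1, -2, 0.5, 3,
                  -1, 1, 0.5, -3), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("phewas:a", "phewas:b",
                                        "substance:s", "demographics:age")))
  ag <- aggregate_importance(phi, sch)
  # per-feature mean |Phi|
  expect_equal(ag$feature$mean_abs_phi, c(1, 1.5, 0.5, 3))
  # group order: sum within group per patient, then abs, then mean
  expect_equal(ag$subdomain$mean_abs_phi[ag$subdomain$subdomain == "phewas"],
               mean(c(abs(1 - 2), abs(-1 + 1))))
  # domain shares sum to 1; origin shares sum to 1
  expect_equal(sum(ag$domain$share), 1)
  expect_equal(sum(ag$origin$share), 1)
  # single feature: 100% share
  ag1 <- aggregate_importance(phi[, 1, drop = FALSE], sch)
  expect_equal(ag1$feature$share, 1)
  # unmapped feature errors
  colnames(phi)[1] <- "mystery:a"
  expect_error(aggregate_importance(phi, sch), "no schema subdomain")
})

test_that("marginal dependency pairs exposures with attributions", {
  fix <- shap_fixture()
  bg <- subset_cubes(fix$cubes, 1:40)
  phi <- approx_shap(fix$model, fix$cubes, bg, idx = 1:12)
  md <- marginal_dependency(phi, fix$cubes, "phewas", "f01")
  expect_equal(nrow(md), 12)
  # fixture repeats the same value in all 3 bins: exposure is 0 or 1
  expect_true(all(md$exposure %in% c(0, 1)))
  x <- fix$cubes$sub$phewas[1, 1, 1:12]
  expect_equal(md$exposure, as.numeric(x > 0))
  # a feature present in every bin has exposure 100%
  expect_error(marginal_dependency(phi, fix$cubes, "phewas", "nope"),
               "no attribution column")
})
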