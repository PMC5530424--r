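test_that("offset logistic model matches closed forms", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(unname(fit_offset_logistic(y)$beta), 0)
  y2 <- rep(c(0, 1), c(15, 5))
  expect_equal(unname(fit_offset_logistic(y2)$beta), log(1 / 3))

  # single binary covariate: coefficients are the table log-odds / log-OR
  y3 <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  x <- matrix(rep(c(0, 1), each = 40), dimnames = list(NULL, "exposure"))
  beta <- fit_offset_logistic(y3, x)$beta
  expect_equal(unname(beta[1]), log(10 / 30), tolerance = 1e-6)
  expect_equal(unname(beta[2]), log((30 / 10) / (10 / 30)), tolerance = 1e-6)

  expect_error(fit_offset_logistic(rep(1, 10)), "both cases and controls")
  # perfect separation must be refused, not silently penalized
  ys <- rep(c(0, 1), each = 20)
  xs <- matrix(ys + 0)
  expect_error(fit_offset_logistic(ys, xs), "separation")
})

test_that("negative gradient equals y - expit(eta) and differentiates the loss", {
  expect_equal(negative_gradient(1, 0), 0.5)
  expect_equal(negative_gradient(0, 0), -0.5)
  expect_equal(negative_gradient(1, 20), 0, tolerance = 1e-8)
  set.seed(2)
  loss <- function(y, eta) -y * eta + log(1 + exp(eta))
  for (i in 1:10) {
    y <- rbinom(1, 1, 0.5); eta <- rnorm(1, 0, 2); h <- 1e-5
    num <- -(loss(y, eta + h) - loss(y, eta - h)) / (2 * h)
    expect_equal(negative_gradient(y, eta), num, tolerance = 1e-6)
  }
})

test_that("penalty calibration hits the df target", {
  expect_equal(calibrate_lambda(c(4, 1), df_target = 1), 2, tolerance = 1e-6)
  set.seed(4)
  for (method in c("trace", "corrected")) {
    d <- sort(rexp(12, 1 / 5), decreasing = TRUE)
    for (df in c(1, 4, 8)) {
      lam <- calibrate_lambda(d, df, method = method)
      s <- d / (d + lam)
      got <- if (method == "trace") sum(s) else sum(2 * s - s^2)
      expect_equal(got, df, tolerance = 1e-6)
      expect_gt(lam, 0)
    }
  }
  expect_error(calibrate_lambda(c(4, 1), df_target = 2), "rank")
})

test_that("base-learner fit equals the direct penalized least-squares form", {
  set.seed(8)
  # u = 0 gives the zero fit
  K <- random_psd(8, jitter = 0.5)
  bl <- kernel_base_learner(K, "p", df_target = 3)
  z <- fit_base_learner(bl, rep(0, 8))
  expect_equal(z$gamma_hat, rep(0, 8))
  expect_equal(z$rss, 0)

  # interpolation limit: df near rank makes lambda ~ 0 and the fit exact
  bli <- kernel_base_learner(K, "p", df_target = 8 - 1e-7, df_method = "trace")
  u <- rnorm(8)
  expect_equal(fit_base_learner(bli, u)$fitted, u, tolerance = 1e-4)

  # dual-form oracle: gamma = (K'K + lambda K)^{-1} K'u on full-rank kernels
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    K <- random_psd(n, jitter = 1)
    bl <- kernel_base_learner(K, "p", df_target = 3)
    u <- rnorm(n)
    direct <- solve(crossprod(K) + bl$lambda * K, crossprod(K, u))
    expect_equal(fit_base_learner(bl, u)$fitted, drop(K %*% direct),
                 tolerance = 1e-8)
  }
})

test_that("boosting selects, updates and accounts per the algorithm", {
  st <- tiny_study(seed = 10)
  # m_stop = 0: offset only
  f0 <- boost(st$y, st$bl, m_stop = 0)
  expect_equal(unname(fitted(f0)), rep(mean(st$y), length(st$y)))
  expect_identical(selected_pathways(f0), character(0))
  expect_true(all(f0$fhat == 0))

  # single near-interpolating learner at nu = 1: one step fits u exactly
  set.seed(3)
  K <- random_psd(40, jitter = 1)
  bl1 <- list(kernel_base_learner(K, "only", df_target = 40 - 1e-7,
                                  df_method = "trace"))
  y <- rbinom(40, 1, 0.5)
  f1 <- boost(y, bl1, m_stop = 1, nu = 1)
  u1 <- y - rep(mean(y), 40)
  expect_equal(f1$eta_train, f1$eta_offset + u1, tolerance = 1e-4)

  # accounting identity and monotone training risk along the path
  for (m in c(1, 5, 25)) {
    fm <- boost(st$y, st$bl, m_stop = m, nu = 0.1)
    expect_equal(fm$eta_train, fm$eta_offset + rowSums(fm$fhat),
                 tolerance = 1e-10)
    expect_true(all(diff(fm$risk_path) <= 1e-12))
    # unselected pathways keep identically zero estimates
    unsel <- setdiff(fm$pathway_ids, selected_pathways(fm))
    expect_true(all(fm$fhat[, unsel] == 0))
    expect_lte(length(selected_pathways(fm)), m)
  }

  # weak-learner contract: every selected fit beats the zero fit
  f <- boost(st$y, st$bl, m_stop = 10)
  eta <- f$eta_offset
  for (m in seq_len(10)) {
    u <- negative_gradient(st$y, eta)
    best <- f$selection_path[m]
    ft <- fit_base_learner(f$learners[[best]], u)
    expect_lt(ft$rss, sum(u^2))
    eta <- eta + f$nu * ft$fitted
  }
  expect_equal(eta, f$eta_train, tolerance = 1e-10)
})

test_that("selection path maps to pathway sets", {
  st <- tiny_study(seed = 12)
  f <- boost(st$y, st$bl, m_stop = 8)
  manual <- f$pathway_ids[sort(unique(f$selection_path))]
  expect_identical(selected_pathways(f), manual)
})

test_that("stopping iteration is the smallest minimizer of the risk curve", {
  curve <- c(10, 9, 8, 7.5, 7.2, 7.0, 6.9, 6.5, 6.8, 7, 7.1)  # min at m = 7
  expect_identical(kernboost:::choose_mstop(curve), 7L)
  tied <- c(5, 4, 3, 2, 3, 4, 3, 2.5, 2.2, 2, 3)              # ties at 3 and 9
  expect_identical(kernboost:::choose_mstop(tied), 3L)
})

test_that("subsampling tuner stays small on pure-noise phenotypes", {
  ms <- integer(6)
  for (i in seq_along(ms)) {
    st <- tiny_study(n = 140, P = 4, seed = 100 + i)
    cv <- tune_mstop(st$y, st$bl, m_max = 30, n_folds = 6, seed = 200 + i)
    expect_identical(cv$m_stop_opt, kernboost:::choose_mstop(cv$mean_risk))
    ms[i] <- cv$m_stop_opt
  }
  expect_lte(stats::median(ms), 15)
  expect_gte(sum(ms == 0), 1)
})

test_that("tuner rejects degenerate stratification", {
  st <- tiny_study(seed = 13)
  y <- c(rep(0, length(st$y) - 1), 1)
  expect_error(tune_mstop(y, st$bl, m_max = 5, n_folds = 3, fraction = 0.5),
               "lack one of the classes")
})

test_that("prediction reproduces training fits and honors covariates", {
  st <- tiny_study(seed = 14)
  f <- boost(st$y, st$bl, m_stop = 15)
  p <- predict_proba(f, Z_new = st$Z)
  expect_equal(p, unname(fitted(f)), tolerance = 1e-10)

  # empty model predicts the constant offset probability
  f0 <- boost(st$y, st$bl, m_stop = 0)
  expect_equal(predict_proba(f0, Z_new = st$Z[1:5, ]),
               rep(mean(st$y), 5))

  # a new individual with genotypes of training individual i gets its f_p
  pnew <- predict_proba(f, Z_new = st$Z[7, , drop = FALSE])
  expect_equal(pnew, unname(fitted(f))[7], tolerance = 1e-10)

  # covariate offset: missing covariates must error
  X <- matrix(rnorm(length(st$y)), dimnames = list(NULL, "age"))
  fx <- boost(st$y, st$bl, X = X, m_stop = 3)
  expect_error(predict_proba(fx, Z_new = st$Z), "covariate")
  px <- predict_proba(fx, Z_new = st$Z, X_new = X)
  expect_equal(px, unname(fitted(fx)), tolerance = 1e-10)
})
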