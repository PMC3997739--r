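# Independent oracle: regularized maxent objective, evaluated directly.
maxent_obj <- function(lambda, X_pres, X_bg, beta) {
  eta <- drop(X_bg %*% lambda)
  mx <- max(eta)
  logZ <- mx + log(sum(exp(eta - mx)))
  logZ - sum(lambda * colMeans(X_pres)) + sum(beta * abs(lambda))
}

# The single-binary-feature problem: background split n1/n0, presence
# fraction p1 with feature value 1.
binary_problem <- function(n_bg = 1000, bg_frac = 0.5, m = 100, p_frac = 0.8) {
  n1 <- round(n_bg * bg_frac); m1 <- round(m * p_frac)
  X_bg <- matrix(rep(c(1, 0), c(n1, n_bg - n1)), ncol = 1)
  X_pres <- matrix(rep(c(1, 0), c(m1, m - m1)), ncol = 1)
  list(X_pres = X_pres, X_bg = X_bg)
}

test_that("feature classes are enabled by presence sample size", {
  set.seed(8)
  bg <- data.frame(a = stats::runif(100), b = stats::runif(100))
  cls <- function(m) unique(vapply(build_features(bg, m), `[[`,
                                   character(1), "class"))
  expect_setequal(cls(5), "linear")
  expect_setequal(cls(12), c("linear", "quadratic"))
  expect_setequal(cls(40), c("linear", "quadratic", "hinge"))
  expect_setequal(cls(203), c("linear", "quadratic", "hinge", "product"))
  # constant variable contributes nothing
  bg$c <- 1
  expect_warning(fe <- build_features(bg, 12), "constant")
  expect_false("c" %in% vapply(fe, `[[`, character(1), "var"))
  # scaled features live in [0, 1] on the background
  fe2 <- build_features(bg[, 1:2], 100)
  X <- feature_matrix(fe2, bg[, 1:2])
  expect_true(all(X >= 0 & X <= 1))
})

test_that("no-signal data yields the null model: lambda 0, gain 0, HSI 0.5", {
  set.seed(9)
  bg <- matrix(stats::runif(400), ncol = 2)
  colnames(bg) <- c("f1", "f2")
  fit <- fit_maxent(bg, bg, beta = 0.05)  # presence distribution == background
  expect_true(all(fit$lambda == 0))
  expect_equal(fit$gain, 0)
  expect_equal(logistic_output(fit, bg), rep(0.5, nrow(bg)))
  expect_equal(fit$H, log(nrow(bg)))
})

test_that("single binary feature recovers lambda = ln 4 and the hand gain", {
  pb <- binary_problem()
  fit <- fit_maxent(pb$X_pres, pb$X_bg, beta = 0)
  # independent 1-D numeric solve of the moment condition
  lam_star <- stats::uniroot(function(l) 0.5 * exp(l) / (0.5 * exp(l) + 0.5) - 0.8,
                             c(0, 5), tol = 1e-12)$root
  expect_equal(lam_star, log(4), tolerance = 1e-9)
  expect_equal(unname(fit$lambda), log(4), tolerance = 1e-3)
  # hand-evaluated gain: 0.8 ln 1.6 + 0.2 ln 0.4
  expect_equal(fit$gain, 0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-3)
  expect_equal(training_gain(fit, pb$X_pres), fit$gain, tolerance = 1e-10)
})

test_that("with beta = 0.05 the fitted moment gap sits exactly at beta", {
  pb <- binary_problem()
  fit <- fit_maxent(pb$X_pres, pb$X_bg, beta = 0.05, convergence = 1e-9)
  q <- predict(fit, pb$X_bg, type = "raw")
  gap <- abs(sum(q * pb$X_bg[, 1]) - 0.8)
  expect_equal(gap, 0.05, tolerance = 1e-4)
  # grid-search oracle: our optimizer attains the 1-D minimum
  grid <- seq(0, 3, by = 1e-3)
  objs <- vapply(grid, maxent_obj, numeric(1), X_pres = pb$X_pres,
                 X_bg = pb$X_bg, beta = 0.05)
  expect_lte(maxent_obj(fit$lambda, pb$X_pres, pb$X_bg, 0.05),
             min(objs) + 1e-6)
})

test_that("normalization, monotone objective, and logistic identities hold", {
  set.seed(10)
  n <- 300
  bg <- data.frame(a = stats::runif(n), b = stats::rnorm(n))
  pres <- data.frame(a = stats::runif(40, 0.4, 1), b = stats::rnorm(40, 0.5))
  fe <- build_features(bg, 40)
  fit <- fit_maxent(feature_matrix(fe, pres), feature_matrix(fe, bg),
                    features = fe)
  q <- predict(fit, feature_matrix(fe, bg), type = "raw")
  expect_equal(sum(q), 1, tolerance = 1e-10)
  expect_true(all(diff(fit$objective) <= 1e-12))
  expect_true(fit$H >= 0 && fit$H <= log(n))
  expect_gte(fit$gain, 0)
  # HSI = eHq / (1 + eHq) identity and limits
  eHq <- predict(fit, feature_matrix(fe, bg), type = "exp")
  hsi <- logistic_output(fit, feature_matrix(fe, bg))
  expect_equal(hsi, eHq / (1 + eHq))
  expect_equal(3 / (1 + 3), 0.75)  # the e^H q = 3 algebraic point
  expect_true(all(hsi > 0 & hsi < 1))
})

test_that("gain is monotone in beta and in nested feature sets", {
  set.seed(12)
  n <- 400
  bg <- data.frame(a = stats::runif(n), b = stats::runif(n))
  pres <- data.frame(a = stats::rbeta(60, 4, 2), b = stats::runif(60))
  fe <- build_features(bg, 60)
  Xp <- feature_matrix(fe, pres); Xb <- feature_matrix(fe, bg)
  gains <- vapply(c(0.2, 0.1, 0.05, 0.01, 0),
                  function(b) fit_maxent(Xp, Xb, beta = b)$gain, numeric(1))
  expect_true(all(diff(gains) >= -1e-8))
  # nested features at beta = 0: more features never lose gain
  fe_lin <- build_features(bg, 60, classes = "linear")
  g1 <- fit_maxent(feature_matrix(fe_lin, pres), feature_matrix(fe_lin, bg),
                   beta = 0)$gain
  fe_lq <- build_features(bg, 60, classes = c("linear", "quadratic"))
  g2 <- fit_maxent(feature_matrix(fe_lq, pres), feature_matrix(fe_lq, bg),
                   beta = 0)$gain
  expect_gte(g2, g1 - 1e-6)
})

test_that("KKT moment matching holds against a 2-feature grid-search oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 200; m <- 30
    X_bg <- cbind(stats::runif(n), stats::runif(n))
    X_pres <- cbind(stats::rbeta(m, 3, 1.5), stats::runif(m))
    beta <- c(0.03, 0.03)
    fit <- fit_maxent(X_pres, X_bg, beta = beta, convergence = 1e-9)
    q <- predict(fit, X_bg, type = "raw")
    gap <- abs(colSums(q * X_bg) - colMeans(X_pres))
    expect_true(all(gap <= beta + 1e-4))
    active <- fit$lambda != 0
    expect_true(all(abs(gap[active] - beta[active]) < 1e-3))
    # coarse 2-D grid + our solution: no grid point beats the fit
    grid <- as.matrix(expand.grid(seq(-3, 3, 0.1), seq(-3, 3, 0.1)))
    objs <- apply(grid, 1, maxent_obj, X_pres = X_pres, X_bg = X_bg,
                  beta = beta)
    expect_lte(maxent_obj(fit$lambda, X_pres, X_bg, beta), min(objs) + 1e-6)
  }
})

test_that("jack-knife ranks a true driver above noise and handles 1 variable", {
  set.seed(14)
  n <- 500
  bg <- data.frame(temperature = stats::runif(n, 2, 10),
                   noise = stats::runif(n))
  # presences drawn from suitability driven by temperature only
  w <- exp(1.2 * scale(bg$temperature))
  pres_idx <- sample.int(n, 120, replace = TRUE, prob = w)
  pres <- bg[pres_idx, ]
  te_idx <- sample.int(n, 60, replace = TRUE, prob = w)
  jk <- jackknife_importance(pres, bg, test_pres_env = bg[te_idx, ])
  full <- attr(jk, "full_gain")
  expect_gte(jk$gain_with_only[jk$variable == "temperature"], 0.9 * full)
  expect_lte(jk$gain_with_only[jk$variable == "noise"], 0.1 * full)
  expect_lt(abs(jk$auc_with_only[jk$variable == "noise"] - 0.5), 0.05)
  expect_equal(jk$variable[1], "temperature")
  # single variable: the "without" model is the null model, gain 0
  jk1 <- jackknife_importance(pres["temperature"], bg["temperature"])
  expect_equal(jk1$gain_without, 0)
})
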