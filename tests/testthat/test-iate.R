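test_that("AIPW pseudo-outcome matches the closed form", {
  # y=1, z=1, m0=m1=0, ps=0.5 -> tau = 2
  expect_equal(pseudo_outcome_aipw(1, 1, 0.5, 0, 0), 2)
  expect_equal(pseudo_outcome_aipw(1, 0, 0.5, 0, 0), -2)
  # correct outcome models: residual terms vanish and tau = m1 - m0 exactly
  set.seed(1)
  n <- 50
  m0 <- rnorm(n); ite <- rnorm(n); m1 <- m0 + ite
  z <- rbinom(n, 1, 0.5)
  y <- ifelse(z == 1, m1, m0)
  expect_equal(pseudo_outcome_aipw(y, z, runif(n, 0.2, 0.8), m0, m1), ite)
  expect_error(pseudo_outcome_aipw(1, 1, 1, 0, 0), "strictly inside")
})

test_that("AIPW pseudo-outcomes are unbiased for the ATE on generator data", {
  d <- simulate_cre_data(20000, 10, 0, 2, 3, seed = 21)
  est <- estimate_iate(d$y, d$z, d$X, method = "aipw", seed = 22)
  se <- sd(est$tau_hat) / sqrt(length(d$y))
  expect_lt(abs(mean(est$tau_hat) - mean(d$ite)), 3 * se)
})

test_that("AIPW is doubly robust: either nuisance correct suffices", {
  d <- simulate_cre_data(20000, 10, 0, 2, 3, seed = 23)
  baseline <- as.numeric(d$X %*% rep(1, 10))  # the generator's linear outcome model
  n <- length(d$y)
  # correct ps (0.5), garbage outcome models
  t1 <- pseudo_outcome_aipw(d$y, d$z, rep(0.5, n), rep(0, n), rep(0, n))
  # wrong ps, correct outcome models
  t2 <- pseudo_outcome_aipw(d$y, d$z, rep(0.3, n), baseline, baseline + d$ite)
  for (tau in list(t1, t2)) {
    se <- sd(tau) / sqrt(n)
    expect_lt(abs(mean(tau) - mean(d$ite)), 3.5 * se)
  }
})

test_that("propensity estimation is clipped, cross-fitted and guarded", {
  d <- simulate_cre_data(2000, 10, 0, 2, 3, seed = 31)
  # constant learner reproduces the treated fraction (per training fold)
  ps <- estimate_propensity(d$X, d$z, learner = "constant", seed = 1)
  expect_true(all(abs(ps - mean(d$z)) < 0.05))
  expect_lte(length(unique(ps)), 2L)  # one value per fold under K = 2
  # unconfounded data: flexible learner stays near 0.5
  ps2 <- estimate_propensity(d$X, d$z, learner = "gbm", seed = 2)
  expect_lt(mean(abs(ps2 - 0.5)), 0.1)
  expect_true(all(ps2 >= 0.01 & ps2 <= 0.99))
  expect_error(estimate_propensity(d$X, rep(1, 2000)), "degenerate")
  expect_error(estimate_propensity(d$X, d$z, clip_eps = 0.7), "clip_eps")
})

test_that("propensity learner recovers a linear-logistic truth", {
  d <- simulate_cre_data(5000, 10, 0, 2, 3, confounding = "lin", seed = 32)
  truth <- plogis(-1 + d$X[, 1] + d$X[, 2])
  ps <- estimate_propensity(d$X, d$z, learner = "gbm", seed = 33)
  expect_lt(mean(abs(ps - truth)), 0.1)
})

test_that("meta-learners reduce to the difference in means with an intercept-only learner", {
  d <- simulate_cre_data(800, 10, 0, 2, 3, seed = 41)
  dm <- mean(d$y[d$z == 1]) - mean(d$y[d$z == 0])
  tauT <- meta_learner_iate(d$X, d$y, d$z, "tlearner", learner_y = "constant")
  expect_equal(unique(tauT), dm)
  tauX <- meta_learner_iate(d$X, d$y, d$z, "xlearner", learner_y = "constant",
                            ps_hat = rep(0.5, 800))
  expect_equal(unique(tauX), dm)
})

test_that("T-learner with a saturated learner matches cell-wise differences of means", {
  set.seed(42)
  n <- 4000
  X <- matrix(rbinom(2 * n, 1, 0.5), n, 2, dimnames = list(NULL, c("x1", "x2")))
  z <- rbinom(n, 1, 0.5)
  y <- 1 + X[, 1] + z * (2 * X[, 2]) + rnorm(n)
  tau <- meta_learner_iate(X, y, z, "tlearner", learner_y = saturated_learner())
  # oracle: stratified difference of means per covariate pattern
  key <- paste(X[, 1], X[, 2])
  cell <- tapply(seq_len(n), key, function(i) {
    mean(y[i][z[i] == 1]) - mean(y[i][z[i] == 0])
  })
  expect_equal(unname(tau), unname(as.numeric(cell[key])))
})

test_that("X-learner with ps = 0.5 averages the two imputation arms equally", {
  set.seed(43)
  n <- 500
  X <- matrix(rbinom(2 * n, 1, 0.5), n, 2, dimnames = list(NULL, c("x1", "x2")))
  z <- rbinom(n, 1, 0.5)
  y <- X[, 1] + z * X[, 2] + rnorm(n)
  lrn <- saturated_learner()
  tau <- meta_learner_iate(X, y, z, "xlearner", learner_y = lrn,
                           ps_hat = rep(0.5, n))
  # reconstruct the two arms by hand with the same deterministic learner
  f0 <- lrn$fit(X[z == 0, , drop = FALSE], y[z == 0])
  f1 <- lrn$fit(X[z == 1, , drop = FALSE], y[z == 1])
  d1 <- y[z == 1] - lrn$predict(f0, X[z == 1, , drop = FALSE])
  d0 <- lrn$predict(f1, X[z == 0, , drop = FALSE]) - y[z == 0]
  g1 <- lrn$fit(X[z == 1, , drop = FALSE], d1)
  g0 <- lrn$fit(X[z == 0, , drop = FALSE], d0)
  oracle <- 0.5 * lrn$predict(g0, X) + 0.5 * lrn$predict(g1, X)
  expect_equal(tau, oracle)
})

test_that("estimate_iate dispatches and validates", {
  d <- simulate_cre_data(400, 10, 0, 1, 2, seed = 51)
  est <- estimate_iate(d$y, d$z, d$X, method = "slearner",
                       learner_y = "linear", seed = 52)
  expect_s3_class(est, "cre_iate")
  expect_length(est$tau_hat, 400)
  # custom function estimator
  est2 <- estimate_iate(d$y, d$z, d$X, method = function(y, z, X) rep(1, length(y)))
  expect_equal(est2$method, "user")
  expect_true(all(est2$tau_hat == 1))
  expect_error(estimate_iate(d$y, d$z, d$X, method = "causal_forest"))
  expect_error(estimate_iate(d$y, d$z, d$X, learner_y = "nope"), "unknown learner")
})
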