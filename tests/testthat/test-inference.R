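test_that("honest split partitions exactly and reproducibly", {
  s <- honest_split(5000, 0.5, seed = 81)
  expect_length(s$discovery, 2500)
  expect_length(s$inference, 2500)
  expect_length(intersect(s$discovery, s$inference), 0)
  expect_setequal(c(s$discovery, s$inference), 1:5000)
  expect_identical(s, honest_split(5000, 0.5, seed = 81))
  # ceiling allocation and boundary errors
  expect_length(honest_split(11, 0.5, seed = 1)$discovery, 6)
  expect_error(honest_split(10, 0.999, seed = 1), "empty")
  expect_error(honest_split(100, 0), "ratio_dis")
})

test_that("the decomposition fit is exact on noiseless linear data", {
  # 0 rules: intercept-only OLS is the mean
  tau <- c(1, 2, 3, 6)
  f <- fit_decomposition(matrix(numeric(0), 4, 0), tau)
  expect_equal(f$ate, mean(tau))
  # tau = 2 + 3 r recovered exactly
  r <- c(0, 1, 0, 1, 1, 0)
  f2 <- fit_decomposition(matrix(r, ncol = 1), 2 + 3 * r)
  expect_equal(f2$ate, 2)
  expect_equal(unname(f2$aate), 3)
})

test_that("least squares agrees with an explicit normal-equations solve", {
  set.seed(82)
  for (i in 1:25) {
    n <- sample(30:80, 1); M <- sample(1:5, 1)
    R <- matrix(rbinom(n * M, 1, 0.5), n, M)
    keep <- causalrules:::full_rank_columns(R)
    R <- R[, keep, drop = FALSE]
    tau <- rnorm(n)
    f <- fit_decomposition(R, tau)
    A <- cbind(1, R)
    beta <- solve(t(A) %*% A, t(A) %*% tau)
    expect_equal(c(f$ate, unname(f$aate)), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("collinear columns are dropped in favour of earlier ones", {
  set.seed(83)
  r <- rbinom(200, 1, 0.5)
  R <- cbind(a = r, b = 1 - r, c = rbinom(200, 1, 0.5))  # b = 1 - a with intercept
  expect_warning(f <- fit_decomposition(R, rnorm(200)), "collinear")
  expect_equal(f$kept, c(1L, 3L))
})

test_that("bootstrap intervals degenerate correctly on exact linear data", {
  set.seed(84)
  r <- rbinom(100, 1, 0.5)
  tau <- 2 + 3 * r
  b <- bootstrap_inference(matrix(r, ncol = 1), tau, n_boot = 50, seed = 85)
  expect_equal(unname(b$ci_high - b$ci_low), c(0, 0))
  expect_equal(unname(b$pvalue), c(0, 0))
  expect_equal(unname(b$estimate), c(2, 3))
})

test_that("bootstrap intervals bracket the estimate and respect alpha ordering", {
  set.seed(86)
  r1 <- rbinom(400, 1, 0.5); r2 <- rbinom(400, 1, 0.5)
  tau <- 1 + 2 * r1 - r2 + rnorm(400)
  R <- cbind(r1, r2)
  b <- bootstrap_inference(R, tau, n_boot = 200, alpha = 0.05, seed = 87)
  expect_true(all(b$ci_low <= b$estimate & b$estimate <= b$ci_high))
  b10 <- bootstrap_inference(R, tau, n_boot = 200, alpha = 0.10, seed = 87)
  expect_true(all(b10$ci_high - b10$ci_low <= b$ci_high - b$ci_low + 1e-9))
  expect_error(bootstrap_inference(R, tau, n_boot = 1), "n_boot")
})

test_that("p-value pruning drops null rules and keeps real ones", {
  set.seed(88)
  n <- 1000
  r_true <- rbinom(n, 1, 0.5)
  r_null <- rbinom(n, 1, 0.5)
  tau <- 1 + 4 * r_true + rnorm(n)
  R <- cbind(a = r_true, b = r_null)
  pr <- causalrules:::prune_rules_by_pvalue(R, tau, t_pvalue = 0.05,
                                            n_boot = 100, alpha = 0.05, seed = 89)
  expect_equal(pr$kept, 1L)
  # t_pvalue = 1: no pruning possible
  pr1 <- causalrules:::prune_rules_by_pvalue(R, tau, t_pvalue = 1,
                                             n_boot = 100, alpha = 0.05, seed = 90)
  expect_equal(pr1$kept, c(1L, 2L))
  expect_error(causalrules:::prune_rules_by_pvalue(R, tau, t_pvalue = 0,
                                                   n_boot = 100, alpha = 0.05),
               "t_pvalue")
})

test_that("prediction enumerates the decomposition exactly at p = 3", {
  d <- simulate_cre_data(1600, 10, 0, 2, 5, seed = 91)
  fit <- suppressWarnings(cre(d$y, d$z, d$X, ite = d$ite, seed = 92))
  expect_gte(fit$M[["final"]], 1L)
  X_new <- all_patterns(3)
  # embed into the training schema (10 covariates)
  X_full <- cbind(X_new, matrix(0, nrow(X_new), 7,
                                dimnames = list(NULL, paste0("x", 4:10))))
  pred <- predict(fit, X_full)
  oracle <- rep(fit$ate, nrow(X_full))
  for (m in seq_along(fit$rules))
    oracle <- oracle + fit$aate[[m]] * evaluate_rule(fit$rules[[m]], X_full)
  expect_equal(pred, oracle)
  # rows satisfying no rule sit exactly at the ATE
  none <- rowSums(vapply(fit$rules, function(r) evaluate_rule(r, X_full),
                         integer(nrow(X_full)))) == 0
  expect_true(any(none))
  expect_true(all(pred[none] == fit$ate))
  expect_error(predict(fit, X_new), "unknown covariates")
})
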