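#' Cross-fitted propensity score estimation
#'
#' Estimates the probability of treatment given covariates with a base learner
#' (see [base_learners]) under K-fold cross-fitting, so each unit's prediction
#' comes from a model not trained on it, and clips the result away from 0 and
#' 1 for stable inverse weighting.
#'
#' @param X covariate matrix.
#' @param z binary treatment vector.
#' @param learner learner spec (classification task); default `"gbm"`.
#' @param clip_eps clipping bound in `(0, 0.5)`; predictions are forced into
#'   `[clip_eps, 1 - clip_eps]`.
#' @param n_folds number of cross-fitting folds (>= 2).
#' @param seed optional integer seed for the fold assignment and any learner
#'   randomness.
#' @return numeric vector of clipped propensity scores.
#' @export
estimate_propensity <- function(X, z, learner = "gbm", clip_eps = 0.01,
                                n_folds = 2, seed = NULL) {
  X <- as_covariate_matrix(X)
  check_binary(z, "z")
  if (!is.numeric(clip_eps) || clip_eps <= 0 || clip_eps >= 0.5)
    stop("clip_eps must be in (0, 0.5)")
  if (all(z == 1) || all(z == 0))
    stop("degenerate design: all units ", if (all(z == 1)) "treated" else "control")
  if (!is.null(seed)) set.seed(seed)
  lrn <- resolve_learner(learner, "classification")
  ps <- crossfit_predict(lrn, X, z, X, n_folds)
  pmin(pmax(ps, clip_eps), 1 - clip_eps)
}

# K-fold cross-fitting: train on the complement of each fold, predict the fold.
# train_subset restricts the training rows (e.g. one treatment arm) while
# predictions still cover every row of newX.
crossfit_predict <- function(lrn, X, y, newX, n_folds, train_subset = NULL) {
  n <- nrow(X)
  if (n_folds < 2) stop("n_folds must be >= 2")
  folds <- sample(rep_len(seq_len(n_folds), n))
  out <- numeric(nrow(newX))
  for (k in seq_len(n_folds)) {
    train <- which(folds != k)
    if (!is.null(train_subset)) train <- intersect(train, train_subset)
    if (length(train) < 2 || length(unique(y[train])) < 1)
      stop("degenerate design: fewer than 2 training observations in a fold")
    model <- lrn$fit(X[train, , drop = FALSE], y[train])
    test <- which(folds == k)
    out[test] <- lrn$predict(model, newX[test, , drop = FALSE])
  }
  out
}

# cross-fitted arm-specific outcome regressions m0(x) = E[y | z=0, x] and
# m1(x) = E[y | z=1, x], predicted for every unit
estimate_outcome_models <- function(X, y, z, learner = "gbm", n_folds = 2) {
  lrn <- resolve_learner(learner, "regression")
  if (sum(z == 0) < 2 || sum(z == 1) < 2)
    stop("degenerate design: a treatment arm has fewer than 2 observations")
  m0 <- crossfit_predict(lrn, X, y, X, n_folds, train_subset = which(z == 0))
  m1 <- crossfit_predict(lrn, X, y, X, n_folds, train_subset = which(z == 1))
  list(m0 = m0, m1 = m1)
}

#' AIPW pseudo-outcome
#'
#' The augmented inverse-probability-weighted (doubly robust) pseudo-outcome
#' \deqn{\hat\tau_i = \hat m_1(x_i) - \hat m_0(x_i)
#'   + z_i \frac{y_i - \hat m_1(x_i)}{\hat e(x_i)}
#'   - (1 - z_i) \frac{y_i - \hat m_0(x_i)}{1 - \hat e(x_i)},}
#' whose conditional mean is the CATE whenever either the propensity model or
#' the outcome models are correct.
#'
#' @param y outcome vector.
#' @param z binary treatment vector.
#' @param ps_hat propensity scores, strictly inside (0, 1).
#' @param m0_hat,m1_hat outcome-model predictions for the control and treated
#'   arm.
#' @return numeric vector of per-unit pseudo-outcomes.
#' @export
pseudo_outcome_aipw <- function(y, z, ps_hat, m0_hat, m1_hat) {
  n <- length(y)
  stopifnot(length(z) == n, length(ps_hat) == n,
            length(m0_hat) == n, length(m1_hat) == n)
  check_binary(z, "z")
  if (any(ps_hat <= 0 | ps_hat >= 1))
    stop("ps_hat must lie strictly inside (0, 1); clip before calling")
  m1_hat - m0_hat + z * (y - m1_hat) / ps_hat - (1 - z) * (y - m0_hat) / (1 - ps_hat)
}

#' Meta-learner IATE estimation
#'
#' Plug-in estimators of the individual treatment effect built from generic
#' outcome regressions:
#' * S-learner: one model on `(X, z)`; `tau(x) = f(x, 1) - f(x, 0)`.
#' * T-learner: separate models per arm; `tau(x) = f1(x) - f0(x)`.
#' * X-learner: per-arm imputed individual effects regressed in a second
#'   stage, combined as `e(x) tau0(x) + (1 - e(x)) tau1(x)`.
#'
#' @param X covariate matrix.
#' @param y outcome vector.
#' @param z binary treatment vector.
#' @param method `"slearner"`, `"tlearner"` or `"xlearner"`.
#' @param learner_y learner spec for the outcome regressions.
#' @param ps_hat propensity scores; required as the X-learner's combination
#'   weights (defaults to the treated fraction when omitted).
#' @param seed optional integer seed.
#' @return numeric vector of IATE estimates.
#' @export
meta_learner_iate <- function(X, y, z, method = c("slearner", "tlearner", "xlearner"),
                              learner_y = "gbm", ps_hat = NULL, seed = NULL) {
  method <- match.arg(method)
  X <- as_covariate_matrix(X)
  check_binary(z, "z")
  if (!is.null(seed)) set.seed(seed)
  lrn <- resolve_learner(learner_y, "regression")
  if (method != "slearner" && (sum(z == 0) < 2 || sum(z == 1) < 2))
    stop("degenerate design: a treatment arm has fewer than 2 observations")
  switch(method,
    slearner = {
      Xz <- cbind(X, z = z)
      model <- lrn$fit(Xz, y)
      lrn$predict(model, cbind(X, z = 1)) - lrn$predict(model, cbind(X, z = 0))
    },
    tlearner = {
      f0 <- lrn$fit(X[z == 0, , drop = FALSE], y[z == 0])
      f1 <- lrn$fit(X[z == 1, , drop = FALSE], y[z == 1])
      lrn$predict(f1, X) - lrn$predict(f0, X)
    },
    xlearner = {
      f0 <- lrn$fit(X[z == 0, , drop = FALSE], y[z == 0])
      f1 <- lrn$fit(X[z == 1, , drop = FALSE], y[z == 1])
      d1 <- y[z == 1] - lrn$predict(f0, X[z == 1, , drop = FALSE])
      d0 <- lrn$predict(f1, X[z == 0, , drop = FALSE]) - y[z == 0]
      g1 <- lrn$fit(X[z == 1, , drop = FALSE], d1)
      g0 <- lrn$fit(X[z == 0, , drop = FALSE], d0)
      if (is.null(ps_hat)) ps_hat <- rep(mean(z), nrow(X))
      ps_hat * lrn$predict(g0, X) + (1 - ps_hat) * lrn$predict(g1, X)
    })
}

#' Estimate individual treatment effects
#'
#' Dispatcher over the package's IATE estimators. `"aipw"` (the default)
#' cross-fits propensity and arm-specific outcome models and returns the
#' doubly robust pseudo-outcome of [pseudo_outcome_aipw()]; the meta-learner
#' methods delegate to [meta_learner_iate()]. A function supplied as `method`
#' is called as `method(y, z, X)` and must return a numeric vector of length
#' `nrow(X)`.
#'
#' @inheritParams meta_learner_iate
#' @param method one of `"aipw"`, `"slearner"`, `"tlearner"`, `"xlearner"`, or
#'   a function.
#' @param learner_ps learner spec for the propensity model.
#' @param clip_eps propensity clipping bound.
#' @param n_folds cross-fitting folds for nuisance models.
#' @return list of class `"cre_iate"` with `tau_hat`, `method`, and (when
#'   estimated) `ps_hat`, `m0_hat`, `m1_hat`.
#' @export
estimate_iate <- function(y, z, X, method = "aipw", learner_y = "gbm",
                          learner_ps = "gbm", clip_eps = 0.01, n_folds = 2,
                          seed = NULL) {
  X <- as_covariate_matrix(X)
  check_binary(z, "z")
  stopifnot(length(y) == length(z), length(y) == nrow(X))
  if (!is.null(seed)) set.seed(seed)
  if (is.function(method)) {
    tau <- as.numeric(method(y, z, X))
    if (length(tau) != length(y)) stop("custom IATE estimator returned wrong length")
    return(structure(list(tau_hat = tau, method = "user"), class = "cre_iate"))
  }
  method <- match.arg(method, c("aipw", "slearner", "tlearner", "xlearner"))
  if (method == "aipw") {
    ps <- estimate_propensity(X, z, learner_ps, clip_eps, n_folds)
    m <- estimate_outcome_models(X, y, z, learner_y, n_folds)
    tau <- pseudo_outcome_aipw(y, z, ps, m$m0, m$m1)
    structure(list(tau_hat = tau, method = method, ps_hat = ps,
                   m0_hat = m$m0, m1_hat = m$m1), class = "cre_iate")
  } else if (method == "xlearner") {
    ps <- estimate_propensity(X, z, learner_ps, clip_eps, n_folds)
    tau <- meta_learner_iate(X, y, z, method, learner_y, ps_hat = ps)
    structure(list(tau_hat = tau, method = method, ps_hat = ps), class = "cre_iate")
  } else {
    tau <- meta_learner_iate(X, y, z, method, learner_y)
    structure(list(tau_hat = tau, method = method), class = "cre_iate")
  }
}

check_binary <- function(z, name) {
  if (anyNA(z) || !all(z %in% c(0, 1)))
    stop(name, " must be a binary 0/1 vector without missing values")
  invisible(TRUE)
}
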