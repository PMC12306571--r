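#' Base learners for nuisance estimation
#'
#' Propensity scores and outcome regressions are fitted through a small
#' registry of base learners sharing one fit/predict contract, so that any of
#' them (or a user-supplied learner) can stand behind the AIPW pseudo-outcome
#' and the meta-learners.
#'
#' Shipped learners:
#' * `"constant"` — intercept only (the sample mean / prevalence);
#' * `"linear"` — least squares for regression, logistic regression for
#'   classification;
#' * `"logistic"` — logistic regression (classification only);
#' * `"gbm"` — gradient-boosted trees (xgboost), the default;
#' * `"rf"` — random forest (ranger).
#'
#' A learner spec is either a name from the registry, a list
#' `list(name = , settings = list(...))` whose settings override the learner's
#' defaults (passed through to the backing package), or a custom learner
#' `list(fit = function(X, y) model, predict = function(model, X) numeric)`.
#' For classification tasks `y` is 0/1 and predictions are probabilities.
#'
#' @param spec a learner spec as above.
#' @param task `"regression"` or `"classification"`.
#' @return internally, a list with `fit` and `predict` closures.
#' @name base_learners
NULL

resolve_learner <- function(spec, task = c("regression", "classification")) {
  task <- match.arg(task)
  settings <- list()
  if (is.list(spec) && !is.null(spec$fit) && !is.null(spec$predict)) {
    stopifnot(is.function(spec$fit), is.function(spec$predict))
    return(list(fit = spec$fit, predict = spec$predict))
  }
  if (is.list(spec)) {
    if (is.null(spec$name)) stop("learner spec list needs a 'name' or fit/predict pair")
    settings <- spec$settings %||% list()
    spec <- spec$name
  }
  if (!is.character(spec) || length(spec) != 1L)
    stop("unrecognized learner spec")
  switch(spec,
    constant = learner_constant(task),
    linear   = learner_linear(task),
    logistic = {
      if (task != "classification") stop("'logistic' learner is classification-only")
      learner_linear("classification")
    },
    gbm = learner_gbm(task, settings),
    rf  = learner_rf(task, settings),
    stop("unknown learner '", spec, "'; registered: constant, linear, logistic, gbm, rf")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

learner_constant <- function(task) {
  list(fit = function(X, y) mean(y),
       predict = function(model, X) rep(model, nrow(X)))
}

learner_linear <- function(task) {
  if (task == "regression") {
    list(
      fit = function(X, y) {
        fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
        fit$coefficients
      },
      predict = function(model, X) {
        beta <- ifelse(is.na(model), 0, model)
        as.numeric(cbind(1, X) %*% beta)
      })
  } else {
    list(
      fit = function(X, y) {
        fit <- suppressWarnings(
          stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                         family = stats::binomial()))
        fit$coefficients
      },
      predict = function(model, X) {
        beta <- ifelse(is.na(model), 0, model)
        stats::plogis(as.numeric(cbind(1, X) %*% beta))
      })
  }
}

learner_gbm <- function(task, settings = list()) {
  defaults <- list(nrounds = 100, eta = 0.1, max_depth = 3,
                   min_child_weight = 10, subsample = 1, nthread = 1)
  pars <- utils::modifyList(defaults, settings)
  nrounds <- pars$nrounds; pars$nrounds <- NULL
  pars$objective <- if (task == "regression") "reg:squarederror" else "binary:logistic"
  list(
    fit = function(X, y) {
      dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
      xgboost::xgb.train(params = pars, data = dm, nrounds = nrounds, verbose = 0)
    },
    predict = function(model, X) {
      as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1)))
    })
}

learner_rf <- function(task, settings = list()) {
  defaults <- list(num.trees = 200, min.node.size = if (task == "regression") 5 else 10)
  pars <- utils::modifyList(defaults, settings)
  list(
    fit = function(X, y) {
      df <- data.frame(.y = y, X, check.names = FALSE)
      args <- c(list(formula = .y ~ ., data = df, num.threads = 1,
                     probability = task == "classification",
                     seed = sample.int(.Machine$integer.max, 1)),
                pars)
      if (task == "classification") args$data$.y <- factor(y, levels = c(0, 1))
      do.call(ranger::ranger, args)
    },
    predict = function(model, X) {
      pr <- predict(model, data = data.frame(X, check.names = FALSE),
                    num.threads = 1)$predictions
      if (is.matrix(pr)) as.numeric(pr[, "1"]) else as.numeric(pr)
    })
}
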