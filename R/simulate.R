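#' Canonical rule template for synthetic CATE decompositions
#'
#' The generator's ground truth is a fixed template of up to four decision
#' rules with alternating-sign AATEs of magnitude `effect_size`:
#'
#' 1. `x1 = 1 & x2 = 1` with AATE `+effect_size`
#' 2. `x5 = 1 & x6 = 1` with AATE `-effect_size`
#' 3. `x4 = 1` with AATE `+effect_size`
#' 4. `x5 = 1 & x7 = 1 & x8 = 1` with AATE `-effect_size`
#'
#' The first `n_rules` entries are used. Conditions are expressed as
#' `xj > 0.5`, which on binary covariates is exactly `xj = 1` and carries over
#' unchanged to continuous covariates in `[0, 1]`.
#'
#' @param n_rules number of rules in the decomposition, in 1..4.
#' @param effect_size nonnegative magnitude of each rule's AATE.
#' @return list with `rules` (list of [new_rule()] objects) and `aates`
#'   (numeric vector of the same length).
#' @export
cre_rule_template <- function(n_rules, effect_size) {
  if (!is.numeric(n_rules) || length(n_rules) != 1L || !n_rules %in% 1:4)
    stop("n_rules must be an integer in 1..4")
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size) || effect_size < 0)
    stop("effect_size must be a nonnegative finite number")
  all_rules <- list(
    new_rule(c("x1", "x2"), c(">", ">"), c(0.5, 0.5)),
    new_rule(c("x5", "x6"), c(">", ">"), c(0.5, 0.5)),
    new_rule("x4", ">", 0.5),
    new_rule(c("x5", "x7", "x8"), c(">", ">", ">"), c(0.5, 0.5, 0.5))
  )
  signs <- c(1, -1, 1, -1)
  list(rules = all_rules[seq_len(n_rules)],
       aates = signs[seq_len(n_rules)] * effect_size)
}

# largest covariate index referenced by the template
template_max_index <- function(n_rules) c(2L, 6L, 6L, 8L)[n_rules]

#' Simulate a dataset whose CATE is a known rule decomposition
#'
#' Generates an observational-style dataset `(y, z, X)` together with the true
#' individual treatment effect `ite`, built so that the CATE equals exactly the
#' sum of `n_rules` decision-rule contributions from [cre_rule_template()].
#' Every downstream stage of the pipeline can therefore be scored against a
#' known truth.
#'
#' Covariate rows are drawn from a Gaussian copula with exchangeable latent
#' correlation `rho`; binary covariates threshold the latent normals at 0
#' (marginal probability 0.5), continuous ones map them through the standard
#' normal CDF onto `[0, 1]`. Treatment is Bernoulli with propensity 0.5 under
#' `confounding = "no"`, `plogis(-1 + x1 + x2)` under `"lin"`, and
#' `plogis(-1 + x1 * x2 + x3)` under `"nonlin"`. The continuous outcome is
#' `y = X b + z * ite + eps` with `b = 1` and standard normal noise; a binary
#' outcome thresholds that latent outcome at its median.
#'
#' @param n number of individuals.
#' @param p number of covariates; must cover the covariates the rule template
#'   uses (`p >= 2, 6, 6, 8` for `n_rules = 1..4`).
#' @param rho exchangeable latent correlation between covariates, in `[0, 1)`.
#' @param n_rules number of decision rules decomposing the CATE, in 1..4.
#' @param effect_size magnitude of each rule's AATE.
#' @param binary_covariates logical; binary (0/1) or continuous (`[0,1]`)
#'   covariates.
#' @param binary_outcome logical; binary or continuous outcome.
#' @param confounding one of `"no"`, `"lin"`, `"nonlin"`.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   datasets.
#' @return A list of class `"cre_data"`: `y`, `z`, `X`, `ite`, plus the ground
#'   truth `true_rules`, `true_aates` and `ate_true = mean(ite)`.
#' @examples
#' d <- simulate_cre_data(n = 500, p = 10, n_rules = 2, effect_size = 5, seed = 1)
#' table(d$ite)
#' @export
simulate_cre_data <- function(n, p = 10, rho = 0, n_rules = 2, effect_size = 2,
                              binary_covariates = TRUE, binary_outcome = FALSE,
                              confounding = c("no", "lin", "nonlin"),
                              seed = NULL) {
  confounding <- match.arg(confounding)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n >= 2,
            is.numeric(p), length(p) == 1L, is.finite(p), p >= 1,
            is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.logical(binary_covariates), is.logical(binary_outcome))
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  template <- cre_rule_template(n_rules, effect_size)  # validates n_rules/effect_size
  if (p < template_max_index(n_rules))
    stop("p = ", p, " too small for the ", n_rules, "-rule template (needs p >= ",
         template_max_index(n_rules), ")")
  if (confounding != "no" && p < 3)
    stop("confounded designs need p >= 3")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); p <- as.integer(p)

  # Gaussian copula with exchangeable correlation: Z = sqrt(rho) g + sqrt(1-rho) E
  g <- rnorm(n)
  Z <- sqrt(rho) * g + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  X <- if (binary_covariates) (Z > 0) + 0 else pnorm(Z)
  colnames(X) <- paste0("x", seq_len(p))

  ps <- switch(confounding,
    no     = rep(0.5, n),
    lin    = plogis(-1 + X[, 1] + X[, 2]),
    nonlin = plogis(-1 + X[, 1] * X[, 2] + X[, 3]))
  z <- rbinom(n, 1L, ps)

  R <- vapply(template$rules, function(r) evaluate_rule(r, X), integer(n))
  ite <- as.numeric(matrix(R, nrow = n) %*% template$aates)

  baseline <- as.numeric(X %*% rep(1, p))
  y_latent <- baseline + z * ite + rnorm(n)
  y <- if (binary_outcome) as.numeric(y_latent > median(y_latent)) else y_latent

  structure(list(y = y, z = z, X = X, ite = ite,
                 true_rules = template$rules, true_aates = template$aates,
                 ate_true = mean(ite)),
            class = "cre_data")
}

#' @export
print.cre_data <- function(x, ...) {
  cat("Synthetic CATE-decomposition dataset\n")
  cat(sprintf("  n = %d, p = %d, treated fraction = %.3f\n",
              length(x$y), ncol(x$X), mean(x$z)))
  cat(sprintf("  true ATE = %.4f over %d rule(s):\n", x$ate_true,
              length(x$true_rules)))
  for (m in seq_along(x$true_rules))
    cat(sprintf("    %+g * [%s]\n", x$true_aates[m], rule_text(x$true_rules[[m]])))
  invisible(x)
}
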