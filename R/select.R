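#' LASSO support of the rule regression
#'
#' Runs an L1-penalized regression (with intercept) of the IATE estimates on
#' the rule indicator matrix and returns the indices of the rules with
#' nonzero coefficients. Columns are centred and scaled internally before
#' fitting; zero-variance columns can never enter the support.
#'
#' The penalty is chosen one of three ways: a numeric `lambda` is used as
#' given; `lambda = "auto"` picks the `lambda.min` value of a seeded 5-fold
#' cross-validation; when `q` is supplied, the support is the set of
#' variables that become active anywhere on the regularization path before
#' the active set first exceeds `q` variables — the per-subsample selection
#' used by stability selection, matching the "q variables entered" reading
#' under which the per-family error bound is stated.
#'
#' @param R rule indicator matrix (n x M).
#' @param tau_hat IATE estimates, length n.
#' @param lambda `"auto"` or a nonnegative penalty value; ignored when `q`
#'   is given.
#' @param q optional cap on the number of active variables.
#' @return integer vector of selected column indices (possibly empty).
#' @export
lasso_support <- function(R, tau_hat, lambda = "auto", q = NULL) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == length(tau_hat))
  if (is.numeric(lambda) && lambda < 0) stop("lambda must be >= 0")
  M <- ncol(R)
  if (M == 0L) return(integer(0))
  sds <- apply(R, 2L, stats::sd)
  live <- which(sds > 0)
  if (length(live) == 0L || stats::sd(tau_hat) == 0) return(integer(0))
  if (!is.null(q) && q < 1) return(integer(0))

  if (length(live) == 1L) {
    # glmnet needs >= 2 columns; a single candidate enters iff it is selected
    # by the same criterion a tiny path would apply
    if (!is.null(q)) return(live)
    fit <- stats::lm(tau_hat ~ R[, live])
    p <- summary(fit)$coefficients[2, 4]
    return(if (is.finite(p) && p < 0.05) live else integer(0))
  }

  Rs <- scale(R[, live, drop = FALSE])
  if (!is.null(q)) {
    fit <- glmnet::glmnet(Rs, tau_hat, alpha = 1, standardize = FALSE)
    ok <- which(fit$df <= q)
    if (length(ok) == 0L) return(integer(0))
    entered <- rowSums(abs(as.matrix(fit$beta)[, ok, drop = FALSE])) > 0
    return(live[which(entered)])
  } else if (identical(lambda, "auto")) {
    cv <- glmnet::cv.glmnet(Rs, tau_hat, alpha = 1, standardize = FALSE,
                            nfolds = 5)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  } else {
    fit <- glmnet::glmnet(Rs, tau_hat, alpha = 1, standardize = FALSE)
    beta <- as.numeric(stats::predict(fit, s = lambda,
                                      type = "coefficients", exact = FALSE))[-1]
  }
  live[which(beta != 0)]
}

#' Stability selection of decision rules
#'
#' Repeats [lasso_support()] on `B` random subsamples (without replacement,
#' size `ceiling(subsample * n)`) and records for each rule the fraction of
#' subsamples in which it is selected.
#'
#' * `"vanilla"`: each subsample's LASSO path is followed until 10 rules are
#'   active; rules with selection frequency at least `cutoff` are kept.
#' * `"error_control"`: each subsample's LASSO is capped at
#'   `q = ceiling(sqrt(pfer * (2 * cutoff - 1) * M))` active variables, the
#'   value for which the stability-selection bound
#'   `E(V) <= q^2 / ((2 * cutoff - 1) * M)` keeps the expected number of
#'   false selections below `pfer`; frequencies are then thresholded at
#'   `cutoff` as in the vanilla mode.
#' * `"no"`: a single [lasso_support()] run on the full data with a
#'   cross-validated penalty; frequencies are 0/1.
#'
#' @param R rule indicator matrix (n x M).
#' @param tau_hat IATE estimates.
#' @param mode `"vanilla"`, `"error_control"` or `"no"`.
#' @param B number of subsamples.
#' @param subsample subsampling fraction in (0, 1).
#' @param cutoff selection-frequency threshold in (0.5, 1].
#' @param pfer target per-family error rate (error_control mode).
#' @param seed optional integer seed.
#' @return list of class `"cre_selection"`: `selected` (indices),
#'   `frequencies`, `mode`, `cutoff`, `pfer`, `B`, `subsample`.
#' @export
stability_selection <- function(R, tau_hat, mode = c("vanilla", "error_control", "no"),
                                B = 50, subsample = 0.05, cutoff = 0.9,
                                pfer = 0.1, seed = NULL) {
  mode <- match.arg(mode)
  R <- as.matrix(R)
  n <- nrow(R); M <- ncol(R)
  stopifnot(length(tau_hat) == n)
  if (!is.null(seed)) set.seed(seed)
  result <- function(freq, selected) {
    structure(list(selected = selected, frequencies = freq, mode = mode,
                   cutoff = cutoff, pfer = pfer, B = B, subsample = subsample),
              class = "cre_selection")
  }
  if (M == 0L) return(result(numeric(0), integer(0)))

  if (mode == "no") {
    sel <- lasso_support(R, tau_hat, lambda = "auto")
    freq <- as.numeric(seq_len(M) %in% sel)
    return(result(freq, sel))
  }

  if (cutoff <= 0.5 || cutoff > 1)
    stop("cutoff must be in (0.5, 1]")
  if (subsample <= 0 || subsample >= 1) stop("subsample must be in (0, 1)")
  if (B < 1) stop("B must be >= 1")
  m_sub <- ceiling(subsample * n)
  if (m_sub < 10)
    stop("subsample size ", m_sub, " too small (< 10 observations); ",
         "increase 'subsample' or n")
  q <- if (mode == "error_control")
    max(1L, ceiling(sqrt(pfer * (2 * cutoff - 1) * M))) else 10L

  counts <- numeric(M)
  for (b in seq_len(B)) {
    idx <- sample.int(n, m_sub)
    if (length(unique(tau_hat[idx])) < 2)
      stop("subsample has fewer than 2 distinct tau_hat values; ",
           "increase 'subsample'")
    sel <- lasso_support(R[idx, , drop = FALSE], tau_hat[idx], q = q)
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / B
  result(freq, which(freq >= cutoff))
}

#' @export
print.cre_selection <- function(x, ...) {
  cat(sprintf("Stability selection (%s): %d of %d rules selected (cutoff %.2f, B = %d)\n",
              x$mode, length(x$selected), length(x$frequencies), x$cutoff, x$B))
  invisible(x)
}
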