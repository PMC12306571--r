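#' Honest sample split
#'
#' Partitions the observation indices uniformly at random into a discovery
#' sample (rule generation and selection) and an inference sample (effect
#' estimation), so no observation contributes to both steps.
#'
#' @param n number of observations.
#' @param ratio_dis fraction allocated to discovery, in (0, 1); the discovery
#'   sample has `ceiling(ratio_dis * n)` observations.
#' @param seed optional integer seed.
#' @return list with integer index vectors `discovery` and `inference`
#'   (disjoint, exhaustive, each non-empty).
#' @export
honest_split <- function(n, ratio_dis = 0.5, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  if (ratio_dis <= 0 || ratio_dis >= 1) stop("ratio_dis must be in (0, 1)")
  n_dis <- ceiling(ratio_dis * n)
  if (n_dis < 1 || n_dis >= n)
    stop("ratio_dis = ", ratio_dis, " leaves an empty discovery or inference sample")
  if (!is.null(seed)) set.seed(seed)
  dis <- sort(sample.int(n, n_dis))
  list(discovery = dis, inference = setdiff(seq_len(n), dis))
}

#' Fit the CATE linear decomposition by least squares
#'
#' Ordinary least squares of the IATE estimates on the selected rule
#' indicators with an intercept: the intercept estimates the ATE and the
#' slopes the AATEs. If the design is collinear, later (lower-importance)
#' columns are dropped with a warning until the design has full rank.
#'
#' @param R rule indicator matrix on the inference sample (n x M, M may be 0).
#' @param tau_hat IATE estimates on the inference sample.
#' @return list with `ate`, `aate` (named by rule text when `R` has column
#'   names) and `kept` (indices of the columns retained after the
#'   collinearity guard).
#' @export
fit_decomposition <- function(R, tau_hat) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == length(tau_hat) || ncol(R) == 0L)
  kept <- full_rank_columns(R)
  if (length(kept) < ncol(R))
    warning("dropped ", ncol(R) - length(kept),
            " collinear rule column(s) from the decomposition")
  Rk <- R[, kept, drop = FALSE]
  A <- cbind(`(ATE)` = 1, Rk)
  fit <- stats::lm.fit(A, tau_hat)
  beta <- fit$coefficients
  if (anyNA(beta)) stop("degenerate design: rank-deficient after column pruning")
  list(ate = unname(beta[1L]), aate = beta[-1L], kept = kept)
}

# greedily keep columns (in given order) while the intercept-augmented design
# stays full rank
full_rank_columns <- function(R) {
  if (ncol(R) == 0L) return(integer(0))
  kept <- integer(0)
  A <- matrix(1, nrow(R), 1L)
  for (j in seq_len(ncol(R))) {
    cand <- cbind(A, R[, j])
    if (qr(cand)$rank == ncol(cand)) {
      A <- cand
      kept <- c(kept, j)
    }
  }
  kept
}

#' Bootstrap inference for the decomposition coefficients
#'
#' Resamples rows of `(R, tau_hat)` with replacement, refits the
#' decomposition on each replicate, and reports percentile confidence
#' intervals plus two-sided p-values from the normal approximation with the
#' bootstrap standard error. A rank-deficient replicate is redrawn up to 10
#' times, then skipped with a warning. In the degenerate case of an exact
#' linear relationship the bootstrap distribution collapses: intervals have
#' zero width and p-values are 0 for nonzero coefficients.
#'
#' @param R rule indicator matrix (inference sample).
#' @param tau_hat IATE estimates (inference sample).
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param alpha two-sided miscoverage level; intervals are at level
#'   `1 - alpha`.
#' @param seed optional integer seed.
#' @return list with vectors `estimate`, `ci_low`, `ci_high`, `pvalue`, `se`
#'   over the coefficients (intercept `"(ATE)"` first), and `n_used`
#'   replicates retained.
#' @export
bootstrap_inference <- function(R, tau_hat, n_boot = 200, alpha = 0.05,
                                seed = NULL) {
  R <- as.matrix(R)
  n <- length(tau_hat)
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  point <- fit_decomposition(R, tau_hat)
  Rk <- R[, point$kept, drop = FALSE]
  est <- c(`(ATE)` = point$ate, point$aate)
  k <- length(est)
  draws <- matrix(NA_real_, n_boot, k)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    coefs <- NULL
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      A <- cbind(1, Rk[idx, , drop = FALSE])
      if (qr(A)$rank < ncol(A)) next
      coefs <- stats::lm.fit(A, tau_hat[idx])$coefficients
      break
    }
    if (is.null(coefs) || anyNA(coefs)) { skipped <- skipped + 1L; next }
    draws[b, ] <- coefs
  }
  if (skipped > 0L)
    warning(skipped, " bootstrap replicate(s) skipped after repeated rank deficiency")
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  if (nrow(draws) < 2) stop("fewer than 2 usable bootstrap replicates")
  ci <- apply(draws, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  se <- apply(draws, 2L, stats::sd)
  pv <- ifelse(se > 0, 2 * stats::pnorm(-abs(est / se)),
               as.numeric(est == 0))
  list(estimate = est, ci_low = stats::setNames(ci[1L, ], names(est)),
       ci_high = stats::setNames(ci[2L, ], names(est)),
       pvalue = stats::setNames(pv, names(est)),
       se = stats::setNames(se, names(est)), n_used = nrow(draws))
}

# iterate: drop rules with p-value above t_pvalue, refit and re-bootstrap,
# until every surviving rule is significant or none remain. Returns the kept
# rule positions (into the original rule list) plus the final fit/inference.
prune_rules_by_pvalue <- function(R, tau_hat, t_pvalue, n_boot, alpha, seed = NULL) {
  if (t_pvalue <= 0 || t_pvalue > 1) stop("t_pvalue must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  active <- seq_len(ncol(R))
  repeat {
    Rs <- R[, active, drop = FALSE]
    boot <- bootstrap_inference(Rs, tau_hat, n_boot = n_boot, alpha = alpha)
    fitk <- fit_decomposition(Rs, tau_hat)
    active <- active[fitk$kept]            # collinearity guard may drop columns
    pv_rules <- boot$pvalue[-1L]
    if (length(active) == 0L || all(pv_rules <= t_pvalue))
      return(list(kept = active, fit = fitk, boot = boot))
    active <- active[pv_rules <= t_pvalue]
    if (length(active) == 0L) {
      boot <- bootstrap_inference(R[, active, drop = FALSE], tau_hat,
                                  n_boot = n_boot, alpha = alpha)
      fitk <- fit_decomposition(R[, active, drop = FALSE], tau_hat)
      return(list(kept = active, fit = fitk, boot = boot))
    }
  }
}
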