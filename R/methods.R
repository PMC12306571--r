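#' @export
print.cre <- function(x, ...) {
  cat("Causal rule ensemble\n")
  cat(sprintf("  n = %d (%d discovery / %d inference)\n",
              x$n, x$n_discovery, x$n_inference))
  cat(sprintf("  rules: %d candidates -> %d selected -> %d final\n",
              x$M["candidates"], x$M["selected"], x$M["final"]))
  cat(sprintf("  ATE = %.4f [%.4f, %.4f]\n", x$ate,
              x$cate$ci_low[1], x$cate$ci_high[1]))
  if (x$M["final"] > 0) {
    cat("  AATEs:\n")
    for (i in seq_along(x$rules))
      cat(sprintf("    %+.4f  %s\n", x$aate[i], names(x$aate)[i]))
  } else {
    cat("  0 rules in the decomposition (ATE-only model)\n")
  }
  invisible(x)
}

#' Summarize a causal rule ensemble fit
#'
#' Prints the rule counts at each pipeline stage, the ATE with its bootstrap
#' confidence interval, and one row per final rule with its AATE, confidence
#' interval and p-value. `summarize()` is an alias for `summary()` on `"cre"`
#' objects.
#'
#' @param object,x a `"cre"` fit.
#' @param ... unused.
#' @return invisibly, the CATE decomposition table (data frame).
#' @export
summary.cre <- function(object, ...) {
  structure(list(fit = object), class = "summary.cre")
}

#' @rdname summary.cre
#' @export
print.summary.cre <- function(x, ...) {
  fit <- x$fit
  level <- 100 * (1 - fit$alpha)
  cat("Causal rule ensemble: CATE decomposition\n")
  cat(sprintf("  observations: %d (%d discovery, %d inference)\n",
              fit$n, fit$n_discovery, fit$n_inference))
  cat(sprintf("  decision rules: %d extracted, %d selected, %d final\n",
              fit$M["candidates"], fit$M["selected"], fit$M["final"]))
  cat(sprintf("  ATE: %.4f  [%g%% CI %.4f, %.4f]\n\n", fit$ate, level,
              fit$cate$ci_low[1], fit$cate$ci_high[1]))
  if (fit$M["final"] == 0) {
    cat("  0 rules in the decomposition (ATE-only model)\n")
  } else {
    tab <- fit$cate[-1L, , drop = FALSE]
    rownames(tab) <- NULL
    print(format(tab, digits = 4))
  }
  invisible(fit$cate)
}

#' @rdname summary.cre
#' @export
summarize <- function(object, ...) UseMethod("summarize")

#' @rdname summary.cre
#' @export
summarize.cre <- function(object, ...) {
  print(summary(object, ...))
}

#' @export
coef.cre <- function(object, ...) {
  c("(ATE)" = object$ate, object$aate)
}

#' Predict conditional average treatment effects
#'
#' Applies the fitted linear decomposition to new covariate rows:
#' `ate + sum_m aate_m * r_m(x)`.
#'
#' @param object a `"cre"` fit.
#' @param newdata covariate matrix or data frame containing every covariate
#'   the final rules reference.
#' @param ... unused.
#' @return numeric vector of CATE estimates, one per row of `newdata`.
#' @export
predict.cre <- function(object, newdata, ...) {
  X <- as_covariate_matrix(newdata)
  out <- rep(object$ate, nrow(X))
  for (m in seq_along(object$rules))
    out <- out + object$aate[[m]] * evaluate_rule(object$rules[[m]], X)
  out
}

#' @export
residuals.cre <- function(object, ...) {
  stop("residuals are not retained: the decomposition is fit on the ",
       "held-out inference sample's IATE estimates")
}

#' Export the decomposition in plot order
#'
#' Returns the final rules ordered from the most vulnerable subgroup (highest
#' AATE) to the least, with their confidence bounds — the table behind the
#' range bar plot. Ties in the AATE break by rule text. The ATE and the
#' confidence level are attached as attributes `"ate"` and `"level"` for the
#' plot header.
#'
#' @param object a `"cre"` fit.
#' @return data frame with columns `rule`, `aate`, `ci_low`, `ci_high`.
#' @export
export_plot_data <- function(object) {
  stopifnot(inherits(object, "cre"))
  tab <- object$cate[-1L, , drop = FALSE]
  tab <- data.frame(rule = tab$rule, aate = tab$estimate,
                    ci_low = tab$ci_low, ci_high = tab$ci_high,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$aate, tab$rule, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "ate") <- object$ate
  attr(tab, "level") <- 1 - object$alpha
  tab
}

#' Range bar plot of the CATE decomposition
#'
#' Draws each final rule's AATE estimate with its bootstrap confidence
#' interval as a horizontal range bar, ordered from the highest AATE (most
#' vulnerable subgroup) down, with the ATE reported in the title.
#'
#' @param x a `"cre"` fit.
#' @param ... passed to [graphics::plot.default()].
#' @return invisibly, the [export_plot_data()] table.
#' @export
plot.cre <- function(x, ...) {
  tab <- export_plot_data(x)
  if (nrow(tab) == 0L) {
    message("no rules to plot (ATE-only model)")
    return(invisible(tab))
  }
  ypos <- rev(seq_len(nrow(tab)))
  old <- graphics::par(mar = c(4.5, 14, 3, 1))
  on.exit(graphics::par(old))
  xlim <- range(0, tab$ci_low, tab$ci_high)
  graphics::plot(tab$aate, ypos, xlim = xlim, ylim = c(0.5, nrow(tab) + 0.5),
                 pch = 19, yaxt = "n", xlab = "AATE", ylab = "",
                 main = sprintf("CATE decomposition (ATE = %.3f, %g%% CI)",
                                attr(tab, "ate"), 100 * attr(tab, "level")),
                 ...)
  graphics::segments(tab$ci_low, ypos, tab$ci_high, ypos, lwd = 2)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  graphics::axis(2, at = ypos, labels = tab$rule, las = 1, cex.axis = 0.8)
  invisible(tab)
}
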