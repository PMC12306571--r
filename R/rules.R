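#' Decision rules
#'
#' A decision rule is a conjunction of threshold conditions on covariates,
#' evaluated row-wise as a 0/1 indicator. Rules are the unit of
#' interpretability in the CATE decomposition: each selected rule defines a
#' subgroup whose deviation from the average treatment effect is measured by
#' its AATE coefficient.
#'
#' `new_rule()` builds a rule from parallel vectors of variable names,
#' operators (`"<="` or `">"`) and thresholds, canonicalizing as it goes: per
#' variable the conditions are intersected (the smallest `<=` threshold and the
#' largest `>` threshold are binding), and a conjunction whose region is empty
#' is rejected with `NULL`.
#'
#' @param var character vector of covariate names.
#' @param op character vector of operators, each `"<="` or `">"`.
#' @param threshold numeric vector of finite thresholds.
#' @return An object of class `"cre_rule"`, or `NULL` if the conjunction is
#'   contradictory (empty region).
#' @examples
#' r <- new_rule(c("x1", "x2"), c(">", ">"), c(0.5, 0.5))
#' rule_text(r)
#' @export
new_rule <- function(var, op, threshold) {
  stopifnot(length(var) == length(op), length(op) == length(threshold))
  if (length(var) == 0L) stop("a decision rule needs at least one condition")
  if (!all(op %in% c("<=", ">"))) stop("operators must be '<=' or '>'")
  if (!all(is.finite(threshold))) stop("thresholds must be finite")
  uv <- unique(var)
  cv <- character(0); co <- character(0); ct <- numeric(0)
  for (v in uv) {
    idx <- which(var == v)
    le <- threshold[idx][op[idx] == "<="]
    gt <- threshold[idx][op[idx] == ">"]
    lo <- if (length(gt)) max(gt) else -Inf   # v > lo
    hi <- if (length(le)) min(le) else Inf    # v <= hi
    if (lo >= hi) return(NULL)                # empty region
    if (is.finite(lo)) { cv <- c(cv, v); co <- c(co, ">"); ct <- c(ct, lo) }
    if (is.finite(hi)) { cv <- c(cv, v); co <- c(co, "<="); ct <- c(ct, hi) }
  }
  ord <- order(cv, co, method = "radix")
  structure(list(var = cv[ord], op = co[ord], threshold = ct[ord]),
            class = "cre_rule")
}

#' @rdname new_rule
#' @param rule a `"cre_rule"` object.
#' @export
rule_text <- function(rule) {
  paste(sprintf("%s%s%s", rule$var, rule$op,
                vapply(rule$threshold, function(t)
                  formatC(t, format = "g", digits = 7, width = 1), "")),
        collapse = " & ")
}

# canonical deduplication key; order-invariant because conditions are sorted
rule_key <- function(rule) rule_text(rule)

rule_depth <- function(rule) length(unique(rule$var))

#' @rdname new_rule
#' @param text a rule string as produced by `rule_text()`, e.g.
#'   `"x1>0.5 & x2<=0.3"`.
#' @export
parse_rule <- function(text) {
  parts <- strsplit(trimws(text), "\\s*&\\s*")[[1]]
  m <- regmatches(parts, regexec("^([^<>]+?)\\s*(<=|>)\\s*(-?[0-9.eE+-]+)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse rule condition: ", parts[bad][1])
  new_rule(vapply(m, `[`, "", 2L), vapply(m, `[`, "", 3L),
           as.numeric(vapply(m, `[`, "", 4L)))
}

#' @export
print.cre_rule <- function(x, ...) {
  cat("<rule> ", rule_text(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a decision rule on a covariate matrix
#'
#' Returns the 0/1 indicator of all the rule's conditions holding, one entry
#' per row of `X`. The mean of the indicator is the rule's support.
#'
#' @param rule a `"cre_rule"` object.
#' @param X numeric matrix or data frame with named covariate columns.
#' @return integer vector of 0/1, length `nrow(X)`.
#' @export
evaluate_rule <- function(rule, X) {
  X <- as_covariate_matrix(X)
  missing <- setdiff(rule$var, colnames(X))
  if (length(missing))
    stop("rule references unknown covariates: ", paste(missing, collapse = ", "))
  ind <- rep(TRUE, nrow(X))
  for (j in seq_along(rule$var)) {
    xj <- X[, rule$var[j]]
    ind <- ind & if (rule$op[j] == "<=") xj <= rule$threshold[j] else xj > rule$threshold[j]
  }
  as.integer(ind)
}

#' Build the rule indicator matrix
#'
#' Evaluates each rule on `X` and binds the indicators into the n-by-M design
#' matrix used for selection and inference. Constant columns (support 0 or 1)
#' violate the design contract and raise an error; upstream filtering removes
#' them.
#'
#' @param rules list of `"cre_rule"` objects.
#' @param X covariate matrix.
#' @return integer matrix with one column per rule, named by `rule_text()`.
#' @export
build_rule_matrix <- function(rules, X) {
  X <- as_covariate_matrix(X)
  if (length(rules) == 0L) {
    R <- matrix(integer(0), nrow = nrow(X), ncol = 0L)
    return(R)
  }
  R <- vapply(rules, function(r) evaluate_rule(r, X), integer(nrow(X)))
  R <- matrix(R, nrow = nrow(X))
  colnames(R) <- vapply(rules, rule_text, "")
  supp <- colMeans(R)
  if (any(supp == 0 | supp == 1))
    stop("constant rule indicator column: ",
         paste(colnames(R)[supp == 0 | supp == 1], collapse = "; "))
  R
}

# coerce X to a named numeric matrix (x1..xp defaults), rejecting NAs
as_covariate_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X)) stop("covariate matrix contains missing values")
  X
}

# which columns of X are binary 0/1
binary_columns <- function(X) {
  apply(X, 2L, function(col) all(col %in% c(0, 1)))
}
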