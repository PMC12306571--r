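#' Read a dataset from CSV
#'
#' Expects a header row with columns `y`, `z` and then the covariates (any
#' additional `ite` column is returned as well). Missing values and
#' non-binary treatment codes are rejected with row/column diagnostics rather
#' than imputed.
#'
#' @param path CSV file path.
#' @return list with `y`, `z`, `X` (named matrix) and `ite` (`NULL` when
#'   absent).
#' @export
read_cre_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("y", "z"))
    if (!col %in% names(df)) stop("column '", col, "' missing from ", path)
  if (anyNA(df)) {
    bad <- which(is.na(df), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", bad[1L], ", column '", names(df)[bad[2L]], "'")
  }
  z <- df$z
  if (!all(z %in% c(0, 1))) {
    bad <- which(!z %in% c(0, 1))[1L]
    stop("non-binary treatment value '", z[bad], "' at row ", bad)
  }
  ite <- if ("ite" %in% names(df)) as.numeric(df$ite) else NULL
  xcols <- setdiff(names(df), c("y", "z", "ite"))
  if (length(xcols) == 0L) stop("no covariate columns found in ", path)
  X <- as_covariate_matrix(df[, xcols, drop = FALSE])
  list(y = as.numeric(df$y), z = as.integer(z), X = X, ite = ite)
}

#' Write a simulated dataset to CSV (plus ground-truth sidecar)
#'
#' Writes `y`, `z`, the covariates and the true `ite` as one CSV, and the
#' generator's true rules and AATEs to a JSON sidecar `<path>.truth.json`.
#'
#' @param data a `"cre_data"` object from [simulate_cre_data()].
#' @param path output CSV path.
#' @return invisibly, the sidecar path.
#' @export
write_cre_dataset <- function(data, path) {
  stopifnot(inherits(data, "cre_data"))
  df <- data.frame(y = data$y, z = data$z, data$X, ite = data$ite,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(
    list(true_rules = vapply(data$true_rules, rule_text, ""),
         true_aates = data$true_aates, ate_true = data$ate_true),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Serialize / restore a fit
#'
#' `write_cre_result()` writes the full result as JSON (`<path>`) and the
#' CATE decomposition table as CSV (`<path basename>.csv`); the JSON
#' round-trips through `read_cre_result()` into an object that supports
#' `predict()`, `summary()` and `export_plot_data()`.
#'
#' @param object a `"cre"` fit.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_cre_result <- function(object, path) {
  stopifnot(inherits(object, "cre"))
  mp <- object$method_params
  if (is.function(mp$ite_method)) mp$ite_method <- "user"
  payload <- list(
    M = as.list(object$M),
    ate = object$ate,
    rules = vapply(object$rules, rule_text, ""),
    aate = unname(object$aate),
    cate = object$cate,
    frequencies = object$frequencies,
    method_params = mp,
    hyper_params = object$hyper_params,
    seed = object$seed,
    n = object$n, n_discovery = object$n_discovery,
    n_inference = object$n_inference, alpha = object$alpha)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  csv <- sub("\\.json$", "", path)
  utils::write.csv(object$cate, paste0(csv, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_cre_result
#' @export
read_cre_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- lapply(p$rules, parse_rule)
  hp <- p$hyper_params
  # JSON null -> absent key; restore the documented NULL defaults
  for (key in c("intervention_vars", "offset"))
    if (is.null(hp[[key]])) hp[key] <- list(NULL)
  structure(list(
    M = unlist(p$M),
    ate = p$ate,
    rules = rules,
    aate = stats::setNames(as.numeric(p$aate), vapply(rules, rule_text, "")),
    cate = as.data.frame(p$cate),
    frequencies = as.numeric(p$frequencies),
    method_params = p$method_params, hyper_params = hp,
    seed = p$seed, n = p$n, n_discovery = p$n_discovery,
    n_inference = p$n_inference, alpha = p$alpha,
    call = quote(read_cre_result())),
    class = "cre")
}
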