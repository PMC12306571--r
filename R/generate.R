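#' Fit the fit-the-fit tree ensemble
#'
#' Discovery-step candidate generation starts from a gradient-boosted ensemble
#' of shallow regression trees fit to the IATE estimates (the fit-the-fit
#' approach): the trees chase the heterogeneity in `tau_hat`, and their split
#' paths become candidate decision rules.
#'
#' @param X covariate matrix (discovery sample).
#' @param tau_hat IATE estimates aligned with `X`.
#' @param ntrees number of boosting rounds.
#' @param max_depth maximum tree depth (= maximum rule length).
#' @param node_size minimum observations per node.
#' @param seed optional integer seed (subsampling between rounds).
#' @return object of class `"cre_ensemble"` wrapping the booster plus the
#'   covariate schema.
#' @export
fit_tree_ensemble <- function(X, tau_hat, ntrees = 20, max_depth = 3,
                              node_size = 20, seed = NULL) {
  X <- as_covariate_matrix(X)
  stopifnot(length(tau_hat) == nrow(X), ntrees >= 1, max_depth >= 1, node_size >= 1)
  if (!all(is.finite(tau_hat))) stop("tau_hat must be finite")
  if (!is.null(seed)) set.seed(seed)
  dm <- xgboost::xgb.DMatrix(X, label = tau_hat, nthread = 1)
  params <- list(max_depth = max_depth, eta = 0.1, min_child_weight = node_size,
                 subsample = 0.7, objective = "reg:squarederror", nthread = 1,
                 seed = sample.int(.Machine$integer.max, 1))
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = ntrees, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(X),
                 binary = binary_columns(X)),
            class = "cre_ensemble")
}

#' Extract candidate decision rules from a tree ensemble
#'
#' Every root-to-node path of every tree — internal nodes included, so all
#' prefixes of the leaf paths — becomes a candidate rule. Conditions are
#' canonicalized (per-variable interval intersection, fixed ordering),
#' thresholds on binary covariates are snapped to 0.5, and exact duplicates
#' are removed by the canonical rule key.
#'
#' @param ensemble a `"cre_ensemble"` from [fit_tree_ensemble()].
#' @return list of distinct `"cre_rule"` objects (possibly empty, e.g. for a
#'   constant target).
#' @export
extract_candidate_rules <- function(ensemble) {
  stopifnot(inherits(ensemble, "cre_ensemble"))
  tab <- as.data.frame(xgboost::xgb.model.dt.tree(model = ensemble$booster))
  rules_from_tree_table(tab, ensemble$binary)
}

# tab: one row per node with Tree, ID, Feature ("Leaf" for leaves), Split,
# Yes/No child IDs. binary: named logical, which features are 0/1.
rules_from_tree_table <- function(tab, binary) {
  rules <- list()
  keys <- character(0)
  add_rule <- function(var, op, thr) {
    thr <- ifelse(binary[var], 0.5, thr)
    r <- new_rule(var, op, thr)
    if (is.null(r)) return(invisible(NULL))
    k <- rule_key(r)
    if (!k %in% keys) {
      keys[[length(keys) + 1L]] <<- k
      rules[[length(rules) + 1L]] <<- r
    }
    invisible(NULL)
  }
  for (tree_id in unique(tab$Tree)) {
    tt <- tab[tab$Tree == tree_id, , drop = FALSE]
    rownames(tt) <- tt$ID
    root <- tt$ID[tt$Node == min(tt$Node)]
    # depth-first walk accumulating the path's conditions
    walk <- function(id, var, op, thr) {
      node <- tt[id, ]
      if (length(var) > 0) add_rule(var, op, thr)
      if (is.na(node$Feature) || node$Feature == "Leaf") return(invisible(NULL))
      walk(node$Yes, c(var, node$Feature), c(op, "<="), c(thr, node$Split))
      walk(node$No,  c(var, node$Feature), c(op, ">"),  c(thr, node$Split))
    }
    walk(root, character(0), character(0), numeric(0))
  }
  rules
}

# two-group-means error functional: MSE of predicting tau_hat by the means
# inside and outside the rule's region
rule_mse <- function(ind, tau_hat) {
  if (all(ind == 1) || all(ind == 0)) return(mean((tau_hat - mean(tau_hat))^2))
  pred <- ifelse(ind == 1, mean(tau_hat[ind == 1]), mean(tau_hat[ind == 0]))
  mean((tau_hat - pred)^2)
}

#' Prune weak trailing conditions from a rule
#'
#' Iteratively drops a rule's last condition while doing so costs less than a
#' relative error increase of `t_decay`, where the error is the mean squared
#' error of predicting `tau_hat` by the rule's two group means. The relative
#' increase is `(err_pruned - err_full) / max(err_full, 1e-6)`. A
#' single-condition rule is returned unchanged, and `t_decay <= 0` disables
#' pruning.
#'
#' @param rule a `"cre_rule"`.
#' @param X covariate matrix.
#' @param tau_hat IATE estimates.
#' @param t_decay decay threshold (Example defaults use 0.025).
#' @return the (possibly shortened) rule.
#' @export
prune_rule_decay <- function(rule, X, tau_hat, t_decay = 0.025) {
  stopifnot(inherits(rule, "cre_rule"))
  if (t_decay <= 0) return(rule)
  X <- as_covariate_matrix(X)
  repeat {
    k <- length(rule$var)
    if (k < 2L) return(rule)
    err_full <- rule_mse(evaluate_rule(rule, X), tau_hat)
    pruned <- new_rule(rule$var[-k], rule$op[-k], rule$threshold[-k])
    if (is.null(pruned)) return(rule)
    err_pruned <- rule_mse(evaluate_rule(pruned, X), tau_hat)
    if ((err_pruned - err_full) / max(err_full, 1e-6) < t_decay) rule <- pruned
    else return(rule)
  }
}

# importance: absolute MSE reduction of the two-group-means predictor over
# the global-mean predictor
rule_importance <- function(ind_matrix, tau_hat) {
  base <- mean((tau_hat - mean(tau_hat))^2)
  apply(ind_matrix, 2L, function(ind) base - rule_mse(ind, tau_hat))
}

#' Filter candidate rules by support, redundancy and count
#'
#' Applies the three discovery-step filters in order: (i) rules whose support
#' on `X` falls outside `[t_ext, 1 - t_ext]` are dropped (too rare or too
#' generic to describe a subgroup); (ii) scanning in decreasing importance,
#' any rule whose indicator correlates with an already-retained rule's
#' indicator with `|cor| >= t_corr` is dropped (`t_corr = 1` removes only
#' exact duplicates and complements); (iii) only the `max_rules` most
#' important survivors are kept. Importance is the reduction in MSE of the
#' rule's two-group-means predictor of `tau_hat` over the global mean; ties
#' break toward shorter rules, then toward rules with fewer complemented
#' (`<=`) conditions — so between a rule and an equally informative
#' complement the affirmative subgroup is kept — then lexicographic rule
#' text.
#'
#' @param rules list of `"cre_rule"` candidates.
#' @param X covariate matrix.
#' @param tau_hat IATE estimates (for importance), aligned with `X`.
#' @param t_ext support threshold in `[0, 0.5)`.
#' @param t_corr correlation threshold in `(0, 1]`.
#' @param max_rules maximum number of rules retained.
#' @return filtered list of rules, in decreasing importance order.
#' @export
filter_rules <- function(rules, X, tau_hat, t_ext = 0.025, t_corr = 1,
                         max_rules = 100) {
  if (t_ext < 0 || t_ext >= 0.5) stop("t_ext must be in [0, 0.5)")
  if (t_corr <= 0 || t_corr > 1) stop("t_corr must be in (0, 1]")
  if (max_rules < 1) stop("max_rules must be >= 1")
  if (length(rules) == 0L) return(rules)
  X <- as_covariate_matrix(X)
  ind <- vapply(rules, function(r) evaluate_rule(r, X), integer(nrow(X)))
  ind <- matrix(ind, nrow = nrow(X))
  supp <- colMeans(ind)
  keep <- supp >= max(t_ext, .Machine$double.eps) & supp <= 1 - max(t_ext, .Machine$double.eps)
  keep <- keep & supp > 0 & supp < 1            # constant columns never survive
  rules <- rules[keep]; ind <- ind[, keep, drop = FALSE]
  if (length(rules) == 0L) return(rules)

  imp <- rule_importance(ind, tau_hat)
  depth <- vapply(rules, function(r) length(r$var), 1L)
  n_le <- vapply(rules, function(r) sum(r$op == "<="), 1L)
  keys <- vapply(rules, rule_key, "")
  ord <- order(-imp, depth, n_le, keys, method = "radix")

  retained <- integer(0)
  for (j in ord) {
    if (length(retained)) {
      cors <- abs(suppressWarnings(stats::cor(ind[, j], ind[, retained, drop = FALSE])))
      if (any(cors >= t_corr - 1e-12, na.rm = TRUE)) next
    }
    retained <- c(retained, j)
  }
  if (length(retained) > max_rules) retained <- retained[seq_len(max_rules)]
  rules[retained]
}
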