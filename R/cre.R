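default_method_params <- function() {
  list(ratio_dis = 0.5, ite_method = "aipw", learner_ps = "gbm",
       learner_y = "gbm", clip_eps = 0.01, n_folds = 2)
}

default_hyper_params <- function() {
  list(intervention_vars = NULL, offset = NULL, ntrees = 20, node_size = 20,
       max_rules = 100, max_depth = 3, t_decay = 0.025, t_ext = 0.025,
       t_corr = 1, t_pvalue = 0.05, stability_selection = "vanilla",
       cutoff = 0.9, pfer = 0.1, B = 50, subsample = 0.05,
       alpha = 0.05, n_boot = 200)
}

resolve_params <- function(user, defaults, what) {
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop(what, " must be a list")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user, keep.null = TRUE)
}

# one top-level seed deterministically derives independent per-stage seeds
derive_seeds <- function(seed, stages) {
  if (is.null(seed)) return(stats::setNames(as.list(rep(list(NULL), length(stages))), stages))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(as.list(sample.int(2^31 - 2, length(stages))), stages)
}

#' Causal rule ensemble
#'
#' Fits an interpretable decomposition of the conditional average treatment
#' effect,
#' \deqn{\tau(x) = \bar\tau + \sum_{m=1}^{M} \alpha_m \, r_m(x),}
#' where \eqn{\bar\tau} is the average treatment effect (ATE), each
#' \eqn{r_m} is a decision rule (a conjunction of threshold conditions on
#' covariates) defining a subgroup, and \eqn{\alpha_m} is that subgroup's
#' additive average treatment effect (AATE).
#'
#' The procedure is honest: observations are split once into a discovery and
#' an inference sample and each is used in only one step. On the discovery
#' sample, individual treatment effects are estimated ([estimate_iate()]), a
#' gradient-boosted tree ensemble is fit to them and its split paths become
#' candidate rules ([fit_tree_ensemble()], [extract_candidate_rules()]),
#' which are decay-pruned and filtered ([prune_rule_decay()],
#' [filter_rules()]) and then screened by LASSO-based stability selection
#' ([stability_selection()]). On the inference sample, the IATEs are
#' re-estimated and regressed on the selected rule indicators by least
#' squares ([fit_decomposition()]); bootstrap percentile intervals and
#' p-values ([bootstrap_inference()]) feed an iterative p-value pruning of
#' insignificant rules.
#'
#' When `ite` is supplied, internal IATE estimation is skipped in both steps
#' and the given vector is split alongside the data. Alternatively,
#' `method_params$ite_method` may be a function `f(y, z, X)` called
#' separately on each half; the `X` it receives carries the row names of the
#' original covariate matrix so a precomputed vector can be indexed.
#'
#' @param y outcome vector (continuous or binary).
#' @param z binary treatment vector.
#' @param X covariate matrix or data frame (columns named `x1..xp` when
#'   unnamed).
#' @param method_params list overriding any of: `ratio_dis` (0.5),
#'   `ite_method` ("aipw"), `learner_ps` ("gbm"), `learner_y` ("gbm"),
#'   `clip_eps` (0.01), `n_folds` (2).
#' @param hyper_params list overriding any of: `intervention_vars` (NULL =
#'   all covariates), `offset` (NULL; accepted and echoed, not used),
#'   `ntrees` (20), `node_size` (20), `max_rules` (100), `max_depth` (3),
#'   `t_decay` (0.025), `t_ext` (0.025), `t_corr` (1), `t_pvalue` (0.05),
#'   `stability_selection` ("vanilla"), `cutoff` (0.9), `pfer` (0.1), `B`
#'   (50), `subsample` (0.05), `alpha` (0.05), `n_boot` (200).
#' @param ite optional vector of individual treatment effect estimates that
#'   bypasses internal estimation.
#' @param seed optional integer seed; the same seed reproduces the result
#'   bit-identically.
#' @param verbose logical; print stage-level progress lines.
#' @return An object of class `"cre"`: `M` (rule counts at the candidate,
#'   selected and final stages), `ate`, `rules` (final `"cre_rule"` objects),
#'   `aate`, `cate` (data frame with estimate, CI bounds and p-value, the ATE
#'   in the first row), `method_params`, `hyper_params` (resolved), `seed`.
#' @examples
#' d <- simulate_cre_data(n = 1000, p = 10, n_rules = 2, effect_size = 5, seed = 7)
#' fit <- cre(d$y, d$z, d$X, ite = d$ite, seed = 7)
#' fit
#' @export
cre <- function(y, z, X, method_params = list(), hyper_params = list(),
                ite = NULL, seed = NULL, verbose = FALSE) {
  X <- as_covariate_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(length(z) == n, nrow(X) == n)
  check_binary(z, "z")
  if (anyNA(y)) stop("y contains missing values")
  if (!is.null(ite)) {
    ite <- as.numeric(ite)
    if (length(ite) != n) stop("ite must have length n")
    if (anyNA(ite)) stop("ite contains missing values")
  }
  mp <- resolve_params(method_params, default_method_params(), "method_params")
  hp <- resolve_params(hyper_params, default_hyper_params(), "hyper_params")
  if (!is.null(hp$intervention_vars)) {
    missing <- setdiff(hp$intervention_vars, colnames(X))
    if (length(missing))
      stop("intervention_vars not in X: ", paste(missing, collapse = ", "))
  }
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(n))
  say <- function(...) if (verbose) message(sprintf(...))

  seeds <- derive_seeds(seed, c("split", "iate_dis", "trees", "stability",
                                "iate_inf", "boot"))

  split <- honest_split(n, mp$ratio_dis, seed = seeds$split)
  dis <- split$discovery; inf <- split$inference
  say("honest split: %d discovery / %d inference", length(dis), length(inf))

  tau_for <- function(idx, stage_seed) {
    if (!is.null(ite)) return(ite[idx])
    est <- estimate_iate(y[idx], z[idx], X[idx, , drop = FALSE],
                         method = mp$ite_method, learner_y = mp$learner_y,
                         learner_ps = mp$learner_ps, clip_eps = mp$clip_eps,
                         n_folds = mp$n_folds, seed = stage_seed)
    est$tau_hat
  }

  ## --- discovery ---
  tau_dis <- tau_for(dis, seeds$iate_dis)
  X_dis <- X[dis, , drop = FALSE]
  X_trees <- if (is.null(hp$intervention_vars)) X_dis
             else X_dis[, hp$intervention_vars, drop = FALSE]
  ens <- fit_tree_ensemble(X_trees, tau_dis, ntrees = hp$ntrees,
                           max_depth = hp$max_depth, node_size = hp$node_size,
                           seed = seeds$trees)
  candidates <- extract_candidate_rules(ens)
  M_candidates <- length(candidates)
  say("candidate rules extracted: %d", M_candidates)

  if (M_candidates > 0L) {
    pruned <- lapply(candidates, function(r)
      prune_rule_decay(r, X_dis, tau_dis, t_decay = hp$t_decay))
    keys <- vapply(pruned, rule_key, "")
    pruned <- pruned[!duplicated(keys)]
    candidates <- filter_rules(pruned, X_dis, tau_dis, t_ext = hp$t_ext,
                               t_corr = hp$t_corr, max_rules = hp$max_rules)
  }
  say("candidates after decay pruning and filtering: %d", length(candidates))

  if (length(candidates) > 0L) {
    R_dis <- build_rule_matrix(candidates, X_dis)
    sel <- stability_selection(R_dis, tau_dis, mode = hp$stability_selection,
                               B = hp$B, subsample = hp$subsample,
                               cutoff = hp$cutoff, pfer = hp$pfer,
                               seed = seeds$stability)
    selected_rules <- candidates[sel$selected]
  } else {
    sel <- NULL
    selected_rules <- list()
  }
  M_selected <- length(selected_rules)
  say("rules after stability selection: %d", M_selected)

  ## --- inference ---
  tau_inf <- tau_for(inf, seeds$iate_inf)
  X_inf <- X[inf, , drop = FALSE]

  # rules degenerate on the inference half cannot be estimated there
  if (M_selected > 0L) {
    supp <- vapply(selected_rules, function(r) mean(evaluate_rule(r, X_inf)), 0)
    degenerate <- supp == 0 | supp == 1
    if (any(degenerate)) {
      warning(sum(degenerate), " selected rule(s) constant on the inference ",
              "sample were dropped")
      selected_rules <- selected_rules[!degenerate]
    }
  }

  if (length(selected_rules) > 0L) {
    R_inf <- build_rule_matrix(selected_rules, X_inf)
    pruned <- prune_rules_by_pvalue(R_inf, tau_inf, t_pvalue = hp$t_pvalue,
                                    n_boot = hp$n_boot, alpha = hp$alpha,
                                    seed = seeds$boot)
    final_rules <- selected_rules[pruned$kept]
    fit <- pruned$fit; boot <- pruned$boot
  } else {
    final_rules <- list()
    R0 <- matrix(integer(0), nrow = length(inf), ncol = 0L)
    fit <- fit_decomposition(R0, tau_inf)
    boot <- bootstrap_inference(R0, tau_inf, n_boot = hp$n_boot,
                                alpha = hp$alpha, seed = seeds$boot)
  }
  M_final <- length(final_rules)
  if (M_final == 0L)
    warning("no decision rules survived; returning an ATE-only decomposition")
  say("final rules after p-value pruning: %d", M_final)

  rule_names <- vapply(final_rules, rule_text, "")
  cate <- data.frame(
    rule = c("(ATE)", rule_names),
    estimate = unname(boot$estimate),
    ci_low = unname(boot$ci_low),
    ci_high = unname(boot$ci_high),
    se = unname(boot$se),
    pvalue = unname(boot$pvalue),
    stringsAsFactors = FALSE)

  structure(list(
    M = c(candidates = M_candidates, selected = M_selected, final = M_final),
    ate = fit$ate,
    rules = final_rules,
    aate = stats::setNames(unname(fit$aate), rule_names),
    cate = cate,
    frequencies = if (!is.null(sel)) sel$frequencies else numeric(0),
    method_params = mp, hyper_params = hp, seed = seed,
    n = n, n_discovery = length(dis), n_inference = length(inf),
    alpha = hp$alpha, call = match.call()),
    class = "cre")
}
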