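test_that("tree ensembles respect depth limits and a constant target yields no rules", {
  d <- simulate_cre_data(1000, 10, 0, 2, 5, seed = 61)
  ens <- fit_tree_ensemble(d$X, d$ite, ntrees = 20, max_depth = 3,
                           node_size = 20, seed = 62)
  rules <- extract_candidate_rules(ens)
  expect_gt(length(rules), 0)
  depths <- vapply(rules, function(r) length(r$var), 1L)
  expect_true(all(depths <= 3))
  # thresholds on binary covariates snap to 0.5
  thr <- unlist(lapply(rules, `[[`, "threshold"))
  expect_true(all(thr == 0.5))
  # constant target: no splits anywhere
  ens0 <- fit_tree_ensemble(d$X, rep(1.7, 1000), seed = 63)
  expect_length(extract_candidate_rules(ens0), 0)
})

test_that("all path prefixes of a tree become canonical deduplicated rules", {
  # hand-built single tree: root splits x1 at 0.5, left child splits x2 at 0.5
  tab <- data.frame(
    Tree = 0L, Node = 0:4, ID = paste0("0-", 0:4),
    Feature = c("x1", "x2", "Leaf", "Leaf", "Leaf"),
    Split = c(0.5, 0.5, NA, NA, NA),
    Yes = c("0-1", "0-3", NA, NA, NA),
    No = c("0-2", "0-4", NA, NA, NA))
  binary <- c(x1 = FALSE, x2 = FALSE)
  rules <- causalrules:::rules_from_tree_table(tab, binary)
  expect_setequal(
    vapply(rules, rule_text, ""),
    c("x1<=0.5", "x1>0.5", "x1<=0.5 & x2<=0.5", "x1<=0.5 & x2>0.5"))
  # two identical trees: same rule set (dedup by canonical key)
  tab2 <- tab; tab2$Tree <- 1L; tab2$ID <- paste0("1-", 0:4)
  tab2$Yes <- sub("^0-", "1-", tab2$Yes); tab2$No <- sub("^0-", "1-", tab2$No)
  rules2 <- causalrules:::rules_from_tree_table(rbind(tab, tab2), binary)
  expect_equal(rule_set_text(rules2), rule_set_text(rules))
})

test_that("repeated splits on one variable canonicalize to the binding interval", {
  tab <- data.frame(
    Tree = 0L, Node = 0:2, ID = paste0("0-", 0:2),
    Feature = c("x3", "Leaf", "x3"), Split = c(0.2, NA, 0.7),
    Yes = c("0-1", NA, NA), No = c("0-2", NA, NA))
  tab <- rbind(tab, data.frame(Tree = 0L, Node = 3:4, ID = paste0("0-", 3:4),
                               Feature = "Leaf", Split = NA, Yes = NA, No = NA))
  tab$Yes[3] <- "0-3"; tab$No[3] <- "0-4"
  rules <- causalrules:::rules_from_tree_table(tab, c(x3 = FALSE))
  expect_true("x3>0.7" %in% vapply(rules, rule_text, ""))
  expect_false(any(grepl("x3>0.2 & x3>0.7", vapply(rules, rule_text, ""))))
})

test_that("true rule regions appear among candidates when the target is the ite", {
  d <- simulate_cre_data(2000, 10, 0, 2, 5, seed = 64)
  ens <- fit_tree_ensemble(d$X, d$ite, seed = 65)
  got <- rule_set_text(extract_candidate_rules(ens))
  expect_true(all(rule_set_text(d$true_rules) %in% got))
})

test_that("decay pruning strips irrelevant trailing conditions", {
  d <- simulate_cre_data(4000, 10, 0, 1, 5, seed = 66)
  tau <- d$ite + rnorm(4000, sd = 0.5)
  # true signal is x1&x2; x9 is noise appended to the rule
  bloated <- new_rule(c("x1", "x2", "x9"), c(">", ">", "<="), c(0.5, 0.5, 0.5))
  pruned <- prune_rule_decay(bloated, d$X, tau, t_decay = 0.025)
  expect_equal(rule_text(pruned), "x1>0.5 & x2>0.5")
  # a relevant condition is kept
  true_rule <- new_rule(c("x1", "x2"), c(">", ">"), c(0.5, 0.5))
  expect_equal(rule_text(prune_rule_decay(true_rule, d$X, tau)),
               "x1>0.5 & x2>0.5")
  # t_decay = 0 disables pruning; single conditions are no-ops
  expect_identical(prune_rule_decay(bloated, d$X, tau, t_decay = 0), bloated)
  single <- new_rule("x1", ">", 0.5)
  expect_identical(prune_rule_decay(single, d$X, tau), single)
})

test_that("filters enforce support, redundancy and count in order", {
  set.seed(67)
  n <- 1000
  X <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  X[, 6] <- rbinom(n, 1, 0.01)  # rare covariate -> rare rule
  tau <- 3 * (X[, 1] * X[, 2]) + rnorm(n)
  rules <- list(
    new_rule(c("x1", "x2"), c(">", ">"), c(0.5, 0.5)),   # informative
    new_rule("x3", ">", 0.5),                            # noise
    new_rule("x3", ">", 0.5),                            # duplicate indicator
    new_rule("x3", "<=", 0.5),                           # complement, |cor| = 1
    new_rule("x6", ">", 0.5))                            # support ~ 0.01
  filt <- filter_rules(rules, X, tau, t_ext = 0.025, t_corr = 1, max_rules = 100)
  txt <- vapply(filt, rule_text, "")
  expect_false("x6>0.5" %in% txt)                 # support filter
  expect_equal(sum(grepl("^x3", txt)), 1L)        # dedup + complement removal
  expect_equal(txt[1], "x1>0.5 & x2>0.5")         # importance ordering
  # max_rules keeps the top of the importance order
  filt1 <- filter_rules(rules, X, tau, max_rules = 1)
  expect_equal(vapply(filt1, rule_text, ""), "x1>0.5 & x2>0.5")
  # monotonicity: raising t_ext or lowering max_rules never enlarges the set
  for (t_ext in c(0, 0.05, 0.2, 0.4)) {
    n_now <- length(filter_rules(rules, X, tau, t_ext = t_ext))
    if (exists("n_prev")) expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  expect_error(filter_rules(rules, X, tau, t_ext = 0.6), "t_ext")
  expect_error(filter_rules(rules, X, tau, t_corr = 0), "t_corr")
})
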