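# small fixtures built in code, shared across test files

# binary covariate matrix enumerating all 2^p patterns
all_patterns <- function(p) {
  X <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# a "saturated" user learner: predicts the mean of y within each distinct
# covariate pattern seen in training (exact on small discrete designs)
saturated_learner <- function() {
  list(
    fit = function(X, y) {
      key <- apply(X, 1, paste, collapse = ",")
      means <- tapply(y, key, mean)
      list(means = means, fallback = mean(y))
    },
    predict = function(model, X) {
      key <- apply(X, 1, paste, collapse = ",")
      out <- as.numeric(model$means[key])
      ifelse(is.na(out), model$fallback, out)
    })
}

rule_set_text <- function(rules) sort(vapply(rules, rule_text, ""))
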