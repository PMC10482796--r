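#' Posterior belief in a theory after k significant results (Bayesian inference)
#'
#' Normative posterior probability that a theory is true after observing `k`
#' statistically significant results in `n` independent experiments, each run
#' at significance level `alpha` with power `power` when the theory is true.
#' Under the theory each experiment is significant with probability `power`;
#' under the null, with probability `alpha`.  The binomial coefficients cancel
#' between numerator and denominator, so the posterior depends on the data
#' only through `k`:
#'
#' \deqn{P(H_A \mid k) = \frac{(1-\beta)^k \beta^{n-k} \pi}
#'   {(1-\beta)^k \beta^{n-k} \pi + \alpha^k (1-\alpha)^{n-k} (1-\pi)}}
#'
#' where \eqn{1-\beta} is the power and \eqn{\pi} the prior.  With a 50/50
#' prior the prior terms drop out.
#'
#' @param k number of significant results, integer in `0..n` (vectorised)
#' @param n total number of experiments, positive integer
#' @param power per-experiment power, in (0, 1)
#' @param alpha per-experiment significance level, in (0, 1)
#' @param prior prior probability that the theory is true, in (0, 1)
#' @return posterior probability (same length as `k`), in (0, 1)
#' @examples
#' # two of four experiments significant at 50% power: belief rises to 0.965
#' bayes_posterior_belief(2, 4, power = 0.5)
#' bayes_posterior_belief(0:4, 4, power = 0.5)
#' @export
bayes_posterior_belief <- function(k, n, power, alpha = 0.05, prior = 0.5) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop_invalid("`n` must be a positive integer")
  }
  check_k(k, n)
  check_prob_open(power, "power")
  check_prob_open(alpha, "alpha")
  check_prob_open(prior, "prior")
  # log scale: alpha^k underflows long before it matters here, but the log
  # form keeps large-n uses safe
  la <- k * log(power) + (n - k) * log1p(-power) + log(prior)
  l0 <- k * log(alpha) + (n - k) * log1p(-alpha) + log1p(-prior)
  1 / (1 + exp(l0 - la))
}

#' Deterministic vote counting (DVC)
#'
#' Belief 1 if the proportion of significant results exceeds 0.5, belief 0 if
#' it falls below 0.5, and a 50/50 belief at exactly half.  The dichotomous
#' reading of significance tests, applied to a set of studies.
#'
#' @inheritParams bayes_posterior_belief
#' @return predicted belief: 0, 0.5 or 1
#' @examples
#' dvc_predict(0:4, 4)
#' @export
dvc_predict <- function(k, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop_invalid("`n` must be a positive integer")
  }
  check_k(k, n)
  p <- k / n
  ifelse(p > 0.5, 1, ifelse(p < 0.5, 0, 0.5))
}

#' Proportional vote counting (PVC)
#'
#' Belief equal to the proportion of significant results, k/n.
#'
#' @inheritParams bayes_posterior_belief
#' @return predicted belief in \[0, 1\]
#' @examples
#' pvc_predict(0:4, 4)
#' @export
pvc_predict <- function(k, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop_invalid("`n` must be a positive integer")
  }
  check_k(k, n)
  k / n
}

#' Averaging prior belief and significance (APBS)
#'
#' Belief equal to the average of the prior belief in the theory and the
#' proportion of significant results, (prior + k/n) / 2.
#'
#' @inheritParams bayes_posterior_belief
#' @return predicted belief in (0, 1)
#' @examples
#' apbs_predict(0:4, 4)
#' @export
apbs_predict <- function(k, n, prior = 0.5) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop_invalid("`n` must be a positive integer")
  }
  check_k(k, n)
  check_prob_open(prior, "prior")
  (prior + k / n) / 2
}

#' Strategy models
#'
#' A strategy model maps the number of significant results k to a predicted
#' belief in the theory.  Four strategies are considered: `"BI"` (normative
#' Bayesian inference), `"DVC"` (deterministic vote counting), `"PVC"`
#' (proportional vote counting) and `"APBS"` (averaging prior belief and
#' significance).  `alpha` and `power` are used only by BI; `prior` only by
#' BI and APBS.
#'
#' @param name one of `"BI"`, `"DVC"`, `"PVC"`, `"APBS"`
#' @param alpha significance level, in (0, 1)
#' @param power per-experiment power, in (0, 1)
#' @param prior prior belief that the theory is true, in (0, 1)
#' @param n_experiments number of replication experiments per scenario
#' @return an object of class `strategy_model`
#' @examples
#' m <- strategy_model("BI", power = 0.5)
#' model_predictions(m, 0:4)
#' @export
strategy_model <- function(name, alpha = 0.05, power = 0.5, prior = 0.5,
                           n_experiments = 4) {
  name <- match.arg(name, model_names())
  check_prob_open(alpha, "alpha")
  if (name == "BI") check_prob_open(power, "power")
  check_prob_open(prior, "prior")
  if (!is.numeric(n_experiments) || length(n_experiments) != 1 ||
      n_experiments < 1 || n_experiments != floor(n_experiments)) {
    stop_invalid("`n_experiments` must be a positive integer")
  }
  structure(
    list(name = name, alpha = alpha, power = power, prior = prior,
         n_experiments = as.integer(n_experiments)),
    class = "strategy_model"
  )
}

#' @rdname strategy_model
#' @export
model_names <- function() c("BI", "DVC", "PVC", "APBS")

#' The standard set of four strategy models
#'
#' @inheritParams strategy_model
#' @return a named list of four `strategy_model` objects (BI, DVC, PVC, APBS)
#' @export
strategy_models <- function(power = 0.5, alpha = 0.05, prior = 0.5,
                            n_experiments = 4) {
  nm <- model_names()
  stats::setNames(
    lapply(nm, strategy_model, alpha = alpha, power = power, prior = prior,
           n_experiments = n_experiments),
    nm
  )
}

#' @export
print.strategy_model <- function(x, ...) {
  cat(sprintf("<strategy_model> %s (alpha = %g, power = %g, prior = %g, N = %d)\n",
              x$name, x$alpha, x$power, x$prior, x$n_experiments))
  invisible(x)
}

#' Predicted beliefs of a strategy model over scenarios
#'
#' Predictions depend only on each scenario's number of significant results
#' k (and the model's parameters); the composition of significant results
#' (direct vs conceptual replication) and any participant role are ignored by
#' all four models.
#'
#' @param model a [strategy_model()]
#' @param scenarios either a data frame with a `k` column (e.g. rows of
#'   [scenario_designs()]) or a numeric vector of k values
#' @return numeric vector of predicted beliefs, one per scenario, in input
#'   order
#' @examples
#' model_predictions(strategy_model("APBS"), scenario_designs())
#' @export
model_predictions <- function(model, scenarios) {
  if (!inherits(model, "strategy_model")) {
    stop_invalid("`model` must be a strategy_model")
  }
  k <- if (is.data.frame(scenarios)) scenarios$k else scenarios
  if (length(k) == 0) stop_invalid("`scenarios` must be non-empty")
  n <- model$n_experiments
  switch(model$name,
    BI   = bayes_posterior_belief(k, n, model$power, model$alpha, model$prior),
    DVC  = dvc_predict(k, n),
    PVC  = pvc_predict(k, n),
    APBS = apbs_predict(k, n, model$prior)
  )
}

#' Posterior odds implied by a posterior model probability
#'
#' With a uniform prior over candidate models, a posterior probability p for
#' one model corresponds to posterior odds p / (1 - p) against the other
#' models combined; the strong-classification threshold of 0.75 therefore
#' corresponds to odds of 3.
#'
#' @param posterior posterior probability, in \[0, 1)
#' @return posterior odds
#' @examples
#' posterior_odds(0.75)
#' @export
posterior_odds <- function(posterior) {
  if (!is.numeric(posterior) || anyNA(posterior) ||
      any(posterior < 0) || any(posterior >= 1)) {
    stop_invalid("`posterior` must be in [0, 1)")
  }
  posterior / (1 - posterior)
}
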