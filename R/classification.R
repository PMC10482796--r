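#' Root mean squared error between predicted and observed beliefs
#'
#' \deqn{RMSE = \sqrt{\frac{1}{j}\sum_{i=1}^{j}(m_i - d_i)^2}}
#' where j is the number of responses, m the model's predicted beliefs and d
#' the participant's stated beliefs.  Missing observations must be removed
#' pairwise beforehand; j may be smaller than 4 for participants with one or
#' two missing responses.
#'
#' @param predicted,observed numeric vectors of equal length j >= 1, entries
#'   in \[0, 1\]
#' @return non-negative RMSE
#' @examples
#' rmse(c(0.5, 0.5), c(0.3, 0.7))
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    stop_invalid("`predicted` and `observed` must be non-empty and of equal length")
  }
  if (anyNA(predicted) || anyNA(observed)) {
    stop_invalid("remove missing values pairwise before calling rmse()")
  }
  sqrt(mean((predicted - observed)^2))
}

#' RMSE of the benchmark heuristic
#'
#' The benchmark heuristic is a horizontal line at the participant's own
#' average belief.  Its RMSE equals the population standard deviation of the
#' responses; it is data-dependent, unlike the four strategy models, and a
#' candidate model is only assigned if it fits strictly better than this
#' benchmark.
#'
#' @param observed non-empty numeric vector of beliefs in \[0, 1\]
#' @return non-negative RMSE (0 iff the responses are constant)
#' @examples
#' benchmark_rmse(c(0.30, 0.60, 0.70, 1.00))  # mean 0.65, RMSE 0.25
#' @export
benchmark_rmse <- function(observed) {
  if (length(observed) == 0 || anyNA(observed)) {
    stop_invalid("`observed` must be non-empty with no missing values")
  }
  rmse(rep(mean(observed), length(observed)), observed)
}

#' Truncated-normal response density on \[0, 1\]
#'
#' Density at `x` of a normal distribution with mean `mu` and standard
#' deviation `sigma`, truncated (renormalised) to \[0, 1\].  `mu` is a
#' strategy model's predicted belief and may sit on the boundary (DVC and
#' PVC predict exactly 0 or 1 at k = 0 or k = n): the same renormalisation
#' applies, leaving a half-normal shape.
#'
#' @param x evaluation point(s) in \[0, 1\]
#' @param mu centre of the untruncated normal (typically in \[0, 1\])
#' @param sigma standard deviation before truncation, > 0 (the random
#'   decision error)
#' @param log if `TRUE`, return the log density
#' @return (log) density values; the density integrates to 1 over \[0, 1\]
#' @examples
#' truncated_normal_density(0.5, mu = 0.5, sigma = 0.1)
#' integrate(truncated_normal_density, 0, 1, mu = 0, sigma = 0.1)
#' @export
truncated_normal_density <- function(x, mu, sigma, log = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_invalid("`x` must lie in [0, 1]")
  }
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma <= 0)) {
    stop_invalid("`sigma` must be > 0")
  }
  # log-scale normaliser; for mu within a few sigma of [0,1] the plain
  # difference of CDFs is exact, and that is the regime the classifier uses
  z <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
  ld <- stats::dnorm(x, mu, sigma, log = TRUE) - log(z)
  if (log) ld else exp(ld)
}

# inverse-CDF sampler for the same family (vectorised over mu)
rtruncnorm <- function(n, mu, sigma, lower = 0, upper = 1) {
  plo <- stats::pnorm(lower, mu, sigma)
  phi <- stats::pnorm(upper, mu, sigma)
  x <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sigma)
  pmin(pmax(x, lower), upper)
}

#' Noise specification for classification
#'
#' The classifier's random decision error sigma is either fixed a priori
#' (0.10 by default) or estimated from the data as q, the cohort average of
#' each participant's lowest RMSE across the four strategy models.
#'
#' @param mode `"fixed"` or `"q"`
#' @param sigma the fixed sigma (ignored when `mode = "q"`), > 0
#' @return an object of class `noise_spec`
#' @examples
#' noise_spec()            # fixed sigma = 0.10
#' noise_spec("q")         # sigma estimated from the screened sample
#' @export
noise_spec <- function(mode = c("fixed", "q"), sigma = 0.10) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.numeric(sigma) || length(sigma) != 1 ||
                          is.na(sigma) || sigma <= 0)) {
    stop_invalid("`sigma` must be a single positive value")
  }
  structure(list(mode = mode, sigma = if (mode == "fixed") sigma else NA_real_),
            class = "noise_spec")
}

#' Likelihood of a participant's responses under a strategy model
#'
#' Product over the participant's non-missing responses of the
#' truncated-normal density of the stated belief, centred at the model's
#' predicted belief for that scenario's k, with standard deviation `sigma`.
#'
#' @param record a [participant_record()]
#' @param model a [strategy_model()]; for BI in study style 1 the model is
#'   expected to carry the participant's reported power (see
#'   [classify_participant()], which constructs per-participant models)
#' @param sigma random decision error, > 0
#' @param log if `TRUE`, return the log likelihood
#' @return (log) likelihood, strictly positive (finite log)
#' @export
model_likelihood <- function(record, model, sigma, log = FALSE) {
  if (!inherits(record, "participant_record")) {
    stop_invalid("`record` must be a participant_record")
  }
  if (isTRUE(attr(model, "power_missing"))) {
    abort("BI likelihood requested but the participant's reported power is missing",
          "replibelief_missing_power")
  }
  obs <- observed_responses(record)
  if (nrow(obs) < 1) stop_invalid("record has no usable responses")
  mu <- model_predictions(model, obs$k)
  ll <- sum(truncated_normal_density(obs$belief, mu, sigma, log = TRUE))
  if (log) ll else exp(ll)
}

#' Posterior model probabilities for one participant
#'
#' Bayesian model comparison over the four strategy models: the posterior
#' probability of model i is its prior times its likelihood, normalised over
#' the four models.  Likelihoods are accumulated in log space and normalised
#' with log-sum-exp, so posteriors remain well-defined when all likelihoods
#' underflow on the linear scale.
#'
#' @param record a [participant_record()]
#' @param models named list of the four strategy models (default: built from
#'   the record, using its reported power for BI in study style 1)
#' @param sigma random decision error, > 0
#' @param model_priors prior model probabilities, summing to 1 (default
#'   uniform, 0.25 each)
#' @param alpha,prior per-experiment significance level and prior belief in
#'   the theory, used when `models` is `NULL`
#' @return named numeric vector of posterior probabilities (BI, DVC, PVC,
#'   APBS), summing to 1
#' @examples
#' rec <- participant_record("p", c(1, 2, 4, 6), c(0.25, 0.375, 0.50, 0.625))
#' posterior_model_probs(rec, sigma = 0.1)  # APBS fits exactly
#' @export
posterior_model_probs <- function(record, models = NULL, sigma = 0.10,
                                  model_priors = NULL, alpha = 0.05,
                                  prior = 0.5) {
  models <- models %||% models_for_record(record, alpha = alpha, prior = prior)
  nm <- names(models)
  model_priors <- model_priors %||% rep(1 / length(models), length(models))
  if (length(model_priors) != length(models) ||
      abs(sum(model_priors) - 1) > 1e-9 || any(model_priors < 0)) {
    stop_invalid("`model_priors` must be non-negative and sum to 1")
  }
  ll <- vapply(models, model_likelihood, numeric(1),
               record = record, sigma = sigma, log = TRUE)
  lp <- ll + log(model_priors)
  post <- exp(lp - log_sum_exp(lp))
  stats::setNames(post / sum(post), nm)
}

#' Weak monotonicity screen
#'
#' A response pattern is regular if the stated beliefs, ordered by ascending
#' number of significant results k, never decrease (ties allowed).
#' Participants failing this screen are labelled "irregular" and excluded
#' from strategy classification, since all four candidate models predict
#' beliefs non-decreasing in k.
#'
#' @param record a [participant_record()] with at least 2 non-missing
#'   responses
#' @return `TRUE` if the pattern is weakly monotone in k
#' @examples
#' is_weakly_monotone(participant_record("p", c(1, 2, 4, 6),
#'                                       c(0.2, 0.2, 0.5, 0.9)))
#' @export
is_weakly_monotone <- function(record) {
  obs <- observed_responses(record)
  if (nrow(obs) < 2) {
    abort("fewer than 2 usable responses", "replibelief_insufficient_data")
  }
  all(diff(obs$belief) >= 0)
}

#' Average minimum model misfit, q
#'
#' For each participant, take the lowest RMSE across the four strategy
#' models; q is the mean of those minima over the cohort.  It measures the
#' average misfit of participants with their best-fitting model and serves
#' as a data-driven value for the random decision error sigma.
#'
#' @param records non-empty list of [participant_record()] objects, already
#'   screened (every record must support all four models: >= 1 usable
#'   response, reported power present where BI needs it)
#' @param alpha,prior model parameters passed to the per-participant BI model
#' @return q >= 0
#' @export
estimate_q <- function(records, alpha = 0.05, prior = 0.5) {
  if (length(records) == 0) stop_invalid("`records` must be non-empty")
  mins <- vapply(records, function(rec) {
    min(model_rmses(rec, models_for_record(rec, alpha, prior)))
  }, numeric(1))
  mean(mins)
}

# RMSE of each of the four models against a record's observed responses
model_rmses <- function(record, models) {
  obs <- observed_responses(record)
  if (isTRUE(attr(models$BI, "power_missing"))) {
    abort("BI RMSE requested but the participant's reported power is missing",
          "replibelief_missing_power")
  }
  vapply(models, function(m) rmse(model_predictions(m, obs$k), obs$belief),
         numeric(1))
}

# screening applied before classification; returns NA_character_ if the
# record passes, otherwise the exclusion reason
screen_record <- function(record) {
  if (n_observed(record) < 2) return("too_many_missing")
  if (!is_weakly_monotone(record)) return("non_monotone")
  if (record$study_style == 1 && is.na(record$reported_power)) {
    return("missing_power")
  }
  NA_character_
}

#' Classify one participant's strategy
#'
#' Applies the full per-participant procedure: screening (3+ of 4 responses
#' missing; non-monotone "irregular" patterns; missing self-reported power
#' in study style 1), posterior model probabilities at decision error
#' `sigma`, per-model and benchmark RMSEs, and the weak and strong labels.
#'
#' The weak label is the model with the highest posterior probability
#' (required to be at least 0.25), provided its RMSE is strictly lower than
#' the benchmark heuristic's and the maximum is not tied; otherwise the
#' participant is unassigned with a reason (`worse_than_benchmark`, `tie`,
#' `low_posterior`).  The strong label additionally requires that model's
#' posterior to exceed 0.75 (posterior odds of at least 3 against the other
#' models combined); otherwise `posterior_not_above_0.75`.
#'
#' @param record a [participant_record()]
#' @param sigma random decision error, > 0
#' @param alpha,prior per-experiment significance level and prior belief used
#'   by the BI (and APBS) predictions
#' @param model_priors prior model probabilities (default uniform)
#' @return an object of class `classification_result`: a list with
#'   `participant_id`, `excluded`, `exclusion_reason`, `posteriors`,
#'   `rmses`, `benchmark_rmse`, `weak_label`, `weak_reason`,
#'   `strong_label`, `strong_reason`
#' @examples
#' rec <- participant_record("p", c(1, 2, 4, 6), c(0.25, 0.375, 0.50, 0.625))
#' classify_participant(rec, sigma = 0.10)
#' @export
classify_participant <- function(record, sigma = 0.10, alpha = 0.05,
                                 prior = 0.5, model_priors = NULL) {
  if (!inherits(record, "participant_record")) {
    stop_invalid("`record` must be a participant_record")
  }
  res <- list(
    participant_id = record$participant_id,
    excluded = FALSE, exclusion_reason = NA_character_,
    posteriors = NULL, rmses = NULL, benchmark_rmse = NA_real_,
    weak_label = NA_character_, weak_reason = NA_character_,
    strong_label = NA_character_, strong_reason = NA_character_
  )
  reason <- screen_record(record)
  if (!is.na(reason)) {
    res$excluded <- TRUE
    res$exclusion_reason <- reason
    return(structure(res, class = "classification_result"))
  }
  models <- models_for_record(record, alpha = alpha, prior = prior)
  obs <- observed_responses(record)
  res$posteriors <- posterior_model_probs(record, models, sigma,
                                          model_priors = model_priors)
  res$rmses <- model_rmses(record, models)
  res$benchmark_rmse <- benchmark_rmse(obs$belief)

  post <- res$posteriors
  top <- max(post)
  cand <- names(post)[post >= top - 1e-12]
  if (length(cand) > 1) {
    res$weak_reason <- "tie"
  } else if (top < 0.25) {
    res$weak_reason <- "low_posterior"
  } else if (res$rmses[[cand]] >= res$benchmark_rmse) {
    res$weak_reason <- "worse_than_benchmark"
  } else {
    res$weak_label <- cand
  }
  if (is.na(res$weak_label)) {
    res$strong_reason <- res$weak_reason
  } else if (post[[res$weak_label]] > 0.75) {
    res$strong_label <- res$weak_label
  } else {
    res$strong_reason <- "posterior_not_above_0.75"
  }
  structure(res, class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s\n", x$participant_id))
  if (x$excluded) {
    cat(sprintf("  excluded (%s)\n", x$exclusion_reason))
  } else {
    cat("  posteriors:",
        paste(sprintf("%s %.3f", names(x$posteriors), x$posteriors),
              collapse = ", "), "\n")
    cat(sprintf("  weak: %s  strong: %s\n",
                x$weak_label %||% NA,
                if (is.na(x$strong_label))
                  sprintf("unassigned (%s)", x$strong_reason)
                else x$strong_label))
  }
  invisible(x)
}

result_row <- function(res) {
  post <- res$posteriors %||% stats::setNames(rep(NA_real_, 4), model_names())
  rm_  <- res$rmses %||% stats::setNames(rep(NA_real_, 4), model_names())
  data.frame(
    participant_id = res$participant_id,
    excluded = res$excluded,
    exclusion_reason = res$exclusion_reason,
    posterior_BI = post[["BI"]], posterior_DVC = post[["DVC"]],
    posterior_PVC = post[["PVC"]], posterior_APBS = post[["APBS"]],
    rmse_BI = rm_[["BI"]], rmse_DVC = rm_[["DVC"]],
    rmse_PVC = rm_[["PVC"]], rmse_APBS = rm_[["APBS"]],
    benchmark_rmse = res$benchmark_rmse,
    weak_label = res$weak_label, weak_reason = res$weak_reason,
    strong_label = res$strong_label, strong_reason = res$strong_reason,
    stringsAsFactors = FALSE
  )
}

category_summary <- function(results, label_col, n_total) {
  cats <- c(model_names(), "unassigned", "irregular", "excluded_other")
  lab <- ifelse(results$excluded,
                ifelse(results$exclusion_reason == "non_monotone",
                       "irregular", "excluded_other"),
                ifelse(is.na(results[[label_col]]), "unassigned",
                       results[[label_col]]))
  counts <- vapply(cats, function(cc) sum(lab == cc), integer(1))
  list(counts = counts, proportions = counts / n_total)
}

#' Classify a cohort of participants
#'
#' Runs the screening and per-participant classification over a cohort and
#' tabulates the weak and strong category frequencies.  With
#' `noise = noise_spec("q")`, the decision error is first estimated as q on
#' the screened (analyzed) sample, then every participant is classified with
#' sigma = q.  The `k_subset` argument reproduces the sensitivity analyses
#' restricting to participants who faced k = 0-3 (scenario 1 in their set)
#' or k = 1-4 (scenario 8).
#'
#' @param x a response table data frame (see [read_response_table()]) or a
#'   list of [participant_record()] objects
#' @param noise a [noise_spec()]
#' @param k_subset `"all"`, `"k0to3"` or `"k1to4"`
#' @param alpha,prior model parameters (see [classify_participant()])
#' @return an object of class `cohort_classification`: a list with
#'   `results` (one row per participant), `summary` (weak/strong counts and
#'   proportions over BI, DVC, PVC, APBS, unassigned, irregular,
#'   excluded_other), `sigma`, `sigma_mode`, `q`, `k_subset`, `n_total`,
#'   `n_analyzed`
#' @export
classify_cohort <- function(x, noise = noise_spec(), k_subset = c("all", "k0to3", "k1to4"),
                            alpha = 0.05, prior = 0.5) {
  k_subset <- match.arg(k_subset)
  records <- if (is.data.frame(x)) records_from_table(x) else x
  if (length(records) == 0) stop_invalid("cohort must be non-empty")
  if (!inherits(noise, "noise_spec")) stop_invalid("`noise` must be a noise_spec")

  if (k_subset != "all") {
    anchor <- if (k_subset == "k0to3") 1L else 8L
    keep <- vapply(records, function(r) anchor %in% r$responses$scenario_id,
                   logical(1))
    records <- records[keep]
    if (length(records) == 0) {
      abort("no participants left after k-subset restriction",
            "replibelief_degenerate_sample")
    }
  }
  n_total <- length(records)

  reasons <- vapply(records, screen_record, character(1))
  analyzed <- records[is.na(reasons)]
  if (length(analyzed) == 0) {
    abort("no participants pass screening", "replibelief_degenerate_sample")
  }

  q <- estimate_q(analyzed, alpha = alpha, prior = prior)
  sigma <- if (noise$mode == "q") q else noise$sigma
  if (sigma <= 0) {
    # a noise-free cohort yields q = 0; fall back to a vanishingly small
    # sigma so the truncated-normal likelihood stays defined
    sigma <- 1e-6
  }

  results <- do.call(rbind, lapply(records, function(rec) {
    result_row(classify_participant(rec, sigma = sigma, alpha = alpha,
                                    prior = prior))
  }))
  rownames(results) <- NULL

  structure(list(
    results = results,
    summary = list(
      weak = category_summary(results, "weak_label", n_total),
      strong = category_summary(results, "strong_label", n_total)
    ),
    sigma = sigma, sigma_mode = noise$mode, q = q, k_subset = k_subset,
    n_total = n_total, n_analyzed = length(analyzed)
  ), class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("<cohort_classification> %d participants (%d analyzed), sigma = %.4g (%s), k subset: %s\n",
              x$n_total, x$n_analyzed, x$sigma,
              if (x$sigma_mode == "q") "estimated q" else "fixed", x$k_subset))
  tab <- rbind(weak = x$summary$weak$counts, strong = x$summary$strong$counts)
  print(tab)
  invisible(x)
}
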