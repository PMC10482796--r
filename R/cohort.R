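#' Cohort simulation configuration
#'
#' Settings for the synthetic-cohort generator, which emulates the
#' eight-scenario vignette design with known ground-truth strategies.
#' Defaults mirror the vignette studies: four scenarios per participant (one
#' from each of the pairs \{1,8\}, \{2,3\}, \{4,5\}, \{6,7\}), truncated-normal
#' decision noise around the true strategy's predictions, and for study
#' style 1 a self-reported power drawn from a normal with mean 0.67 and SD
#' 0.20 truncated to (0.05, 1\].
#'
#' @param n_participants cohort size, positive integer
#' @param mixture_weights named non-negative weights over `BI`, `DVC`,
#'   `PVC`, `APBS`, summing to 1; the strategy of each non-irregular
#'   participant is drawn from this mixture
#' @param sigma_sim decision noise SD used to generate responses, > 0
#' @param study_style 1 (power self-reported) or 2 (power 0.5 in the
#'   vignette)
#' @param irregular_fraction probability that a participant is an
#'   "irregular" uniform-random responder instead of a strategy follower
#' @param missing_fraction per-response probability of a missing belief
#' @param power_mean,power_sd moments of the (pre-truncation) normal from
#'   which study-style-1 self-reported power is drawn
#' @param round_percent if `TRUE`, beliefs are rounded to whole percentage
#'   points, mimicking the survey slider; default records full precision
#' @param noise_family `"truncnorm"` (the classifier's assumed family;
#'   default) or `"uniform"` (a mis-specification probe: uniform noise of the
#'   same SD around the prediction, clamped to \[0, 1\])
#' @param condition optional condition label copied onto every participant
#' @param seed integer RNG seed recorded in the config; `simulate_cohort()`
#'   sets it before drawing
#' @return an object of class `cohort_config`
#' @examples
#' cohort_config(100, sigma_sim = 0.05, seed = 1)
#' @export
cohort_config <- function(n_participants,
                          mixture_weights = c(BI = 0.25, DVC = 0.25,
                                              PVC = 0.25, APBS = 0.25),
                          sigma_sim = 0.10, study_style = 2,
                          irregular_fraction = 0, missing_fraction = 0,
                          power_mean = 0.67, power_sd = 0.20,
                          round_percent = FALSE,
                          noise_family = c("truncnorm", "uniform"),
                          condition = NA_character_, seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 1 || n_participants != floor(n_participants)) {
    stop_invalid("`n_participants` must be a positive integer")
  }
  if (is.null(names(mixture_weights)) ||
      !setequal(names(mixture_weights), model_names())) {
    stop_invalid("`mixture_weights` must be named BI, DVC, PVC, APBS")
  }
  mixture_weights <- mixture_weights[model_names()]
  if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-9) {
    stop_invalid("`mixture_weights` must be non-negative and sum to 1")
  }
  if (!is.numeric(sigma_sim) || sigma_sim <= 0) {
    stop_invalid("`sigma_sim` must be > 0")
  }
  if (!study_style %in% c(1, 2)) stop_invalid("`study_style` must be 1 or 2")
  for (f in c("irregular_fraction", "missing_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_invalid(sprintf("`%s` must be in [0, 1]", f))
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    mixture_weights = mixture_weights,
    sigma_sim = sigma_sim,
    study_style = as.integer(study_style),
    irregular_fraction = irregular_fraction,
    missing_fraction = missing_fraction,
    power_mean = power_mean, power_sd = power_sd,
    round_percent = isTRUE(round_percent),
    noise_family = match.arg(noise_family),
    condition = as.character(condition),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

#' Draw one participant's scenario set
#'
#' Samples exactly one scenario uniformly from each of the pairs \{2,3\}
#' (k = 1), \{4,5\} (k = 2), \{6,7\} (k = 3) and \{1,8\} (k = 0 or 4), as in
#' the vignette design: every participant faces k = 1, 2, 3 plus either
#' k = 0 or k = 4.
#'
#' @return a data frame of four rows of [scenario_designs()], ordered by
#'   scenario_id
#' @examples
#' set.seed(1); sample_scenario_set()
#' @export
sample_scenario_set <- function() {
  ids <- c(
    if (stats::runif(1) < 0.5) 1L else 8L,
    if (stats::runif(1) < 0.5) 2L else 3L,
    if (stats::runif(1) < 0.5) 4L else 5L,
    if (stats::runif(1) < 0.5) 6L else 7L
  )
  designs <- scenario_designs()
  designs[designs$scenario_id %in% ids, , drop = FALSE]
}

# power reported by a study-style-1 participant
draw_reported_power <- function(config) {
  rtruncnorm(1, config$power_mean, config$power_sd, lower = 0.05, upper = 1)
}

apply_instrument <- function(belief, config) {
  if (config$round_percent) round(belief * 100) / 100 else belief
}

#' Simulate one strategy-following participant
#'
#' Draws a scenario set, a reported power (study style 1 only), and four
#' beliefs from the decision-noise distribution centred at the true model's
#' predicted belief for each scenario's k.  Each response is independently
#' blanked with probability `missing_fraction`.
#'
#' @param true_model `"BI"`, `"DVC"`, `"PVC"` or `"APBS"`
#' @param config a [cohort_config()]
#' @param participant_id identifier for the new record
#' @return a [participant_record()] with attribute `true_model`
#' @export
simulate_participant <- function(true_model, config, participant_id = "sim") {
  true_model <- match.arg(true_model, model_names())
  scen <- sample_scenario_set()
  power <- if (config$study_style == 1) draw_reported_power(config) else NA_real_
  model <- strategy_model(true_model,
                          power = if (config$study_style == 1) power else 0.5)
  mu <- model_predictions(model, scen$k)
  belief <- switch(config$noise_family,
    truncnorm = rtruncnorm(4, mu, config$sigma_sim),
    uniform = {
      # same SD as the truncated-normal channel: half-width sigma * sqrt(3)
      half <- config$sigma_sim * sqrt(3)
      pmin(pmax(mu + stats::runif(4, -half, half), 0), 1)
    }
  )
  belief <- apply_instrument(belief, config)
  if (config$missing_fraction > 0) {
    belief[stats::runif(4) < config$missing_fraction] <- NA_real_
  }
  rec <- participant_record(participant_id, scen$scenario_id, belief,
                            reported_power = power,
                            study_style = config$study_style,
                            condition = config$condition)
  attr(rec, "true_model") <- true_model
  rec
}

#' Simulate one irregular (uniform-random) responder
#'
#' Beliefs are drawn independently and uniformly on \[0, 1\], so the pattern
#' is weakly monotone in k only by chance (probability 1/24 for four
#' distinct k values).  Models the study's observed irregular responders,
#' whose generating process is otherwise uncharacterised.
#'
#' @inheritParams simulate_participant
#' @return a [participant_record()] with attribute `true_model =
#'   "irregular"`
#' @export
simulate_irregular_participant <- function(config, participant_id = "sim") {
  scen <- sample_scenario_set()
  power <- if (config$study_style == 1) draw_reported_power(config) else NA_real_
  belief <- apply_instrument(stats::runif(4), config)
  if (config$missing_fraction > 0) {
    belief[stats::runif(4) < config$missing_fraction] <- NA_real_
  }
  rec <- participant_record(participant_id, scen$scenario_id, belief,
                            reported_power = power,
                            study_style = config$study_style,
                            condition = config$condition)
  attr(rec, "true_model") <- "irregular"
  rec
}

#' Simulate a full cohort with known ground truth
#'
#' Each participant is an irregular responder with probability
#' `irregular_fraction`, otherwise a strategy follower with strategy drawn
#' from `mixture_weights`.  Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()]
#' @return an object of class `simulated_cohort`: a list with `responses`
#'   (the long response table, the same dialect [classify_cohort()] reads),
#'   `ground_truth` (participant_id, true_model), `records` (the
#'   [participant_record()] list) and `config`
#' @examples
#' cohort <- simulate_cohort(cohort_config(20, sigma_sim = 0.05, seed = 42))
#' head(cohort$responses)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_invalid("`config` must be a cohort_config")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  is_irregular <- stats::runif(n) < config$irregular_fraction
  strategies <- sample(model_names(), n, replace = TRUE,
                       prob = config$mixture_weights)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- if (is_irregular[i]) {
      simulate_irregular_participant(config, ids[i])
    } else {
      simulate_participant(strategies[i], config, ids[i])
    }
  }
  names(records) <- ids
  true_model <- ifelse(is_irregular, "irregular", strategies)
  responses <- do.call(rbind, lapply(records, function(rec) {
    data.frame(
      participant_id = rec$participant_id,
      study_style = rec$study_style,
      condition = rec$condition,
      scenario_id = rec$responses$scenario_id,
      k = rec$responses$k,
      direct_significant = scenario_designs()$direct_significant[rec$responses$scenario_id],
      belief_pct = rec$responses$belief * 100,
      reported_power = rec$reported_power,
      stringsAsFactors = FALSE
    )
  }))
  rownames(responses) <- NULL
  structure(list(
    responses = responses,
    ground_truth = data.frame(participant_id = ids, true_model = true_model,
                              stringsAsFactors = FALSE),
    records = records,
    config = config
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d participants (study style %d, sigma_sim = %g, seed = %s)\n",
              x$config$n_participants, x$config$study_style,
              x$config$sigma_sim,
              if (is.null(x$config$seed)) "none" else x$config$seed))
  print(table(x$ground_truth$true_model))
  invisible(x)
}
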