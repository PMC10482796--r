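# Shared fixtures: tiny in-code builders for records and cohorts.

# a complete record covering k = 0..3 (scenarios 1,2,4,6) or 1..4 (2,4,6,8)
make_record <- function(beliefs, ids = c(1, 2, 4, 6), id = "p1",
                        power = NA_real_, style = 2) {
  participant_record(id, ids, beliefs, reported_power = power,
                     study_style = style)
}

# noise-free follower of a strategy over a fixed scenario set
exact_follower <- function(model_name, ids = c(1, 2, 4, 6), id = "p1",
                           power = 0.5, style = 2) {
  m <- strategy_model(model_name, power = power)
  k <- scenario_designs()$k[ids]
  make_record(model_predictions(m, k), ids = ids, id = id,
              power = if (style == 1) power else NA_real_, style = style)
}

# long response table for a set of records (the classify_cohort input dialect)
table_from_records <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
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
}

# independent truncated-normal moments by quadrature (oracle)
tnorm_moments <- function(mu, sigma) {
  z <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma) / z,
                         0, 1, rel.tol = 1e-12)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma) / z,
                         0, 1, rel.tol = 1e-12)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}
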