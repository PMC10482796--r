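#' Participant record
#'
#' One participant's responses to the four vignette scenarios they were
#' shown: for each scenario, their stated belief in the theory as a
#' proportion in \[0, 1\] (the survey's 0-100% slider divided by 100), plus
#' the self-reported statistical power (study style 1 only) and an optional
#' condition label.
#'
#' @param participant_id identifier (coerced to character)
#' @param scenario_id integer vector of scenario ids in 1..8, no duplicates;
#'   a complete record holds one scenario from each of the pairs \{1,8\},
#'   \{2,3\}, \{4,5\}, \{6,7\}
#' @param belief stated beliefs as proportions in \[0, 1\], `NA` for missing;
#'   same length as `scenario_id`
#' @param reported_power self-reported power in (0, 1\], or `NA`; used by the
#'   BI model in study style 1
#' @param study_style 1 (power self-reported) or 2 (power 0.5 stated in the
#'   vignette)
#' @param condition optional condition label (e.g. author/reviewer,
#'   preregistration/regular)
#' @return an object of class `participant_record`
#' @examples
#' participant_record("p1", c(1, 2, 4, 6), c(0.25, 0.38, 0.50, 0.62))
#' @export
participant_record <- function(participant_id, scenario_id, belief,
                               reported_power = NA_real_, study_style = 2,
                               condition = NA_character_) {
  scenario_id <- as.integer(scenario_id)
  if (length(scenario_id) == 0 || anyNA(scenario_id) ||
      !all(scenario_id %in% 1:8)) {
    stop_invalid("`scenario_id` must be integers in 1..8")
  }
  if (anyDuplicated(scenario_id)) {
    stop_invalid("at most one response per scenario_id")
  }
  if (length(belief) != length(scenario_id)) {
    stop_invalid("`belief` and `scenario_id` must have equal length")
  }
  belief <- as.numeric(belief)
  ok <- is.na(belief) | (belief >= 0 & belief <= 1)
  if (!all(ok)) stop_invalid("non-missing beliefs must lie in [0, 1]")
  if (!study_style %in% c(1, 2)) stop_invalid("`study_style` must be 1 or 2")
  if (!is.na(reported_power) &&
      (reported_power <= 0 || reported_power > 1)) {
    stop_invalid("`reported_power` must be in (0, 1] or NA")
  }
  responses <- data.frame(
    scenario_id = scenario_id,
    k = scenario_k(scenario_id),
    belief = belief
  )
  structure(
    list(
      participant_id = as.character(participant_id),
      responses = responses,
      reported_power = as.numeric(reported_power),
      study_style = as.integer(study_style),
      condition = as.character(condition)
    ),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s (study style %d%s)\n",
              x$participant_id, x$study_style,
              if (is.na(x$reported_power)) ""
              else sprintf(", reported power %.2f", x$reported_power)))
  print(x$responses, row.names = FALSE)
  invisible(x)
}

# non-missing responses, ordered by ascending k
observed_responses <- function(record) {
  obs <- record$responses[!is.na(record$responses$belief), , drop = FALSE]
  obs[order(obs$k), , drop = FALSE]
}

n_observed <- function(record) sum(!is.na(record$responses$belief))

#' Build participant records from a response table
#'
#' Converts the long response-table format (one row per participant x
#' scenario, beliefs on the 0-100% scale) into a list of
#' [participant_record()] objects.  See [read_response_table()] for the
#' column dialect.
#'
#' @param tab data frame with columns `participant_id`, `study_style`,
#'   `condition`, `scenario_id`, `belief_pct`, `reported_power`
#' @return named list of `participant_record` objects, in order of first
#'   appearance
#' @export
records_from_table <- function(tab) {
  needed <- c("participant_id", "scenario_id", "belief_pct")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop_invalid(paste("response table lacks column(s):",
                       paste(miss, collapse = ", ")))
  }
  ids <- unique(as.character(tab$participant_id))
  recs <- lapply(ids, function(id) {
    rows <- tab[as.character(tab$participant_id) == id, , drop = FALSE]
    participant_record(
      participant_id = id,
      scenario_id = rows$scenario_id,
      belief = rows$belief_pct / 100,
      reported_power = if ("reported_power" %in% names(rows))
        rows$reported_power[1] else NA_real_,
      study_style = if ("study_style" %in% names(rows))
        rows$study_style[1] else 2,
      condition = if ("condition" %in% names(rows))
        as.character(rows$condition[1]) else NA_character_
    )
  })
  stats::setNames(recs, ids)
}

# The four strategy models evaluated for one participant: BI uses the
# participant's reported power in study style 1 and the vignette's 0.5 in
# study style 2.  Returns NULL for BI's power when it is needed but missing;
# model_likelihood() signals that case.
models_for_record <- function(record, alpha = 0.05, prior = 0.5,
                              n_experiments = 4) {
  power <- if (record$study_style == 1) record$reported_power else 0.5
  mods <- strategy_models(power = if (is.na(power)) 0.5 else power,
                          alpha = alpha, prior = prior,
                          n_experiments = n_experiments)
  attr(mods$BI, "power_missing") <- is.na(power)
  mods
}
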