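# Pipeline stages: simulate -> classify -> report, plus the end-to-end
# strategy-recovery experiment.  Each run_* function works on in-memory
# objects and, when `out_dir` is given, writes CSV/JSON outputs plus a
# metadata record (config echo + seed + version) and logs one structured
# line per stage so the exclusion cascade is auditable.

log_stage <- function(fmt, ...) message(sprintf(paste0("[replibelief] ", fmt), ...))

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort(sprintf("cannot create output directory: %s", out_dir),
          "replibelief_io_error")
  }
  invisible(out_dir)
}

#' Simulate a cohort and write the response files
#'
#' @param config a [cohort_config()]
#' @param out_dir output directory; created if needed.  Writes
#'   `responses.csv`, `ground_truth.csv` and `metadata.json`
#' @return the [simulate_cohort()] object, invisibly
#' @export
run_simulate <- function(config, out_dir) {
  ensure_dir(out_dir)
  cohort <- simulate_cohort(config)
  write_response_table(cohort$responses, file.path(out_dir, "responses.csv"))
  utils::write.csv(cohort$ground_truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  write_metadata(file.path(out_dir, "metadata.json"), "simulate", config)
  log_stage("simulate: %d participants -> %s", config$n_participants, out_dir)
  invisible(cohort)
}

#' Classify a response table and write classification outputs
#'
#' @param responses a response table data frame, a path to one, or a
#'   [simulate_cohort()] object
#' @param noise a [noise_spec()]
#' @param k_subset `"all"`, `"k0to3"` or `"k1to4"`
#' @param out_dir optional output directory; writes `classification.csv`,
#'   `summary.json` and `metadata.json`
#' @param alpha,prior model parameters (see [classify_participant()])
#' @return the [classify_cohort()] object, invisibly when writing
#' @export
run_classify <- function(responses, noise = noise_spec(),
                         k_subset = "all", out_dir = NULL,
                         alpha = 0.05, prior = 0.5) {
  tab <- resolve_responses(responses)
  cls <- classify_cohort(tab, noise = noise, k_subset = k_subset,
                         alpha = alpha, prior = prior)
  ex <- table(cls$results$exclusion_reason[cls$results$excluded])
  log_stage("classify: %d in, %d excluded (%s), %d analyzed; sigma = %.4g (%s)",
            cls$n_total, sum(cls$results$excluded),
            if (length(ex)) paste(names(ex), ex, sep = "=", collapse = ", ")
            else "none",
            cls$n_analyzed, cls$sigma, cls$sigma_mode)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    utils::write.csv(cls$results, file.path(out_dir, "classification.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      summary_json(cls),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_metadata(file.path(out_dir, "metadata.json"), "classify",
                   extra = list(noise_mode = cls$sigma_mode,
                                sigma = cls$sigma, q = cls$q,
                                k_subset = cls$k_subset))
  }
  invisible(cls)
}

# frequency summary keyed by (classification mode, sigma mode, k subset)
summary_json <- function(cls) {
  list(
    sigma_mode = cls$sigma_mode, sigma = cls$sigma, q = cls$q,
    k_subset = cls$k_subset, n_total = cls$n_total,
    n_analyzed = cls$n_analyzed,
    weak = list(counts = as.list(cls$summary$weak$counts),
                proportions = as.list(cls$summary$weak$proportions)),
    strong = list(counts = as.list(cls$summary$strong$counts),
                  proportions = as.list(cls$summary$strong$proportions))
  )
}

resolve_responses <- function(responses) {
  if (inherits(responses, "simulated_cohort")) return(responses$responses)
  if (is.character(responses) && length(responses) == 1) {
    return(read_response_table(responses))
  }
  if (is.data.frame(responses)) return(validate_response_table(responses))
  stop_invalid("`responses` must be a data frame, a file path, or a simulated_cohort")
}

#' Summary report: belief by k, category histogram, accuracy
#'
#' Produces the descriptive outputs of the analysis: (a) mean (SD) belief in
#' the theory in percentages for every number of significant results k, and
#' for k = 1-3 split by composition (direct replication A' significant vs
#' conceptual replication B significant); (b) the weak/strong categorization
#' histogram data; (c) an accuracy summary, the per-participant RMSE between
#' stated beliefs and the normative Bayesian predictions (reported power in
#' study style 1, power 0.5 in study style 2).
#'
#' @param classification a [classify_cohort()] result (or `NULL` to skip the
#'   histogram section)
#' @param responses a response table (data frame, path, or
#'   [simulate_cohort()])
#' @param out_dir optional output directory; writes `report.json`
#' @return a list with `belief_by_k`, `belief_by_composition`, `categories`,
#'   `accuracy`
#' @export
run_report <- function(classification = NULL, responses, out_dir = NULL) {
  tab <- resolve_responses(responses)

  by_k <- do.call(rbind, lapply(sort(unique(tab$k)), function(kk) {
    b <- tab$belief_pct[tab$k == kk & !is.na(tab$belief_pct)]
    data.frame(k = kk, n = length(b),
               mean_belief_pct = if (length(b)) mean(b) else NA_real_,
               sd_belief_pct = if (length(b) > 1) stats::sd(b) else NA_real_)
  }))

  comp_rows <- tab[tab$k %in% 1:3 & !is.na(tab$belief_pct), , drop = FALSE]
  direct <- scenario_designs()$direct_significant[comp_rows$scenario_id]
  by_comp <- do.call(rbind, lapply(1:3, function(kk) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(d) {
      b <- comp_rows$belief_pct[comp_rows$k == kk & direct == d]
      data.frame(k = kk,
                 composition = if (d) "direct_significant" else "conceptual_significant",
                 n = length(b),
                 mean_belief_pct = if (length(b)) mean(b) else NA_real_,
                 sd_belief_pct = if (length(b) > 1) stats::sd(b) else NA_real_)
    }))
  }))

  records <- records_from_table(tab)
  acc <- vapply(records, function(rec) {
    obs <- observed_responses(rec)
    if (nrow(obs) == 0) return(NA_real_)
    power <- if (rec$study_style == 1) rec$reported_power else 0.5
    if (is.na(power)) return(NA_real_)
    rmse(bayes_posterior_belief(obs$k, 4, power), obs$belief)
  }, numeric(1))
  accuracy <- list(
    n = sum(!is.na(acc)),
    mean_rmse_vs_bayes = if (any(!is.na(acc))) mean(acc, na.rm = TRUE) else NA_real_,
    sd_rmse_vs_bayes = if (sum(!is.na(acc)) > 1) stats::sd(acc, na.rm = TRUE) else NA_real_
  )

  categories <- if (!is.null(classification)) {
    summary_json(classification)
  }

  n_usable <- sum(!is.na(tab$belief_pct))
  log_stage("report: %d response rows (%d with stated beliefs), %d participants",
            nrow(tab), n_usable, length(records))
  if (n_usable == 0) log_stage("report: zero analyzable responses")

  rep_obj <- list(belief_by_k = by_k, belief_by_composition = by_comp,
                  categories = categories, accuracy = accuracy)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    jsonlite::write_json(rep_obj, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  rep_obj
}

#' Strategy-recovery experiment
#'
#' Simulates a cohort with known ground-truth strategies, classifies it, and
#' cross-tabulates true strategy against assigned label for both weak and
#' strong classification, together with per-strategy and overall recovery
#' rates (the proportion of strategy followers whose true strategy is
#' assigned).
#'
#' @param config a [cohort_config()]
#' @param noise a [noise_spec()] for the classification stage
#' @param k_subset passed to [classify_cohort()]
#' @param out_dir optional output directory; writes `recovery.json` plus the
#'   simulate/classify outputs
#' @return a list with `confusion` (weak/strong contingency tables of
#'   true_model x label), `recovery` (per-strategy and overall rates),
#'   `classification`, `cohort`
#' @export
run_recover <- function(config, noise = noise_spec(), k_subset = "all",
                        out_dir = NULL) {
  cohort <- if (is.null(out_dir)) simulate_cohort(config)
            else run_simulate(config, file.path(out_dir, "simulated"))
  cls <- run_classify(cohort, noise = noise, k_subset = k_subset,
                      out_dir = if (is.null(out_dir)) NULL
                                else file.path(out_dir, "classified"))
  truth <- cohort$ground_truth
  res <- merge(cls$results, truth, by = "participant_id", sort = TRUE)

  label_of <- function(col) {
    ifelse(res$excluded,
           ifelse(res$exclusion_reason == "non_monotone", "irregular",
                  "excluded"),
           ifelse(is.na(res[[col]]), "unassigned", res[[col]]))
  }
  lab_levels <- c(model_names(), "unassigned", "irregular", "excluded")
  confusion <- lapply(c(weak = "weak_label", strong = "strong_label"),
                      function(col) {
    table(true_model = factor(res$true_model,
                              levels = c(model_names(), "irregular")),
          assigned = factor(label_of(col), levels = lab_levels))
  })
  # recovery is conditional on surviving the screening: a follower whose
  # noisy responses happen to be non-monotone is screened out as irregular
  # before the classifier ever sees them, so it cannot be recovered
  recovery <- lapply(confusion, function(tab) {
    screen_cols <- c("irregular", "excluded")
    assign_cols <- setdiff(lab_levels, screen_cols)
    followers <- model_names()[rowSums(tab[model_names(), , drop = FALSE]) > 0]
    n_analyzed <- vapply(followers, function(m)
      sum(tab[m, assign_cols]), numeric(1))
    per <- vapply(followers, function(m)
      if (n_analyzed[[m]] > 0) tab[m, m] / n_analyzed[[m]] else NA_real_,
      numeric(1))
    hits <- sum(vapply(followers, function(m) tab[m, m], numeric(1)))
    list(per_strategy = as.list(per),
         overall = if (sum(n_analyzed) > 0) hits / sum(n_analyzed) else NA_real_,
         n_followers = sum(tab[model_names(), ]),
         n_followers_analyzed = sum(n_analyzed),
         screened_out_fraction = if (sum(tab[model_names(), ]) > 0)
           sum(tab[model_names(), screen_cols]) / sum(tab[model_names(), ])
         else NA_real_)
  })

  log_stage("recover: overall strong recovery %.3f, weak %.3f",
            recovery$strong$overall, recovery$weak$overall)
  out <- list(confusion = confusion, recovery = recovery,
              classification = cls, cohort = cohort)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(recovery = recovery,
           confusion = lapply(confusion, function(tt)
             as.data.frame.matrix(unclass(tt)))),
      file.path(out_dir, "recovery.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
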