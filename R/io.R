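#' Read and validate a response table
#'
#' The response-table dialect is a CSV with one row per participant x
#' scenario and columns `participant_id`, `study_style`, `condition`,
#' `scenario_id`, `k`, `direct_significant`, `belief_pct` (0-100, may be
#' blank), `reported_power` (0-1, may be blank).  Rows are validated
#' individually; malformed rows are reported with their file line numbers
#' before the read aborts.
#'
#' @param path CSV file path
#' @return a validated data frame
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("response table not found: %s", path), "replibelief_io_error")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_response_table(tab, source = path)
}

validate_response_table <- function(tab, source = "response table") {
  needed <- c("participant_id", "scenario_id", "belief_pct")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop_invalid(sprintf("%s lacks column(s): %s", source,
                         paste(miss, collapse = ", ")))
  }
  bad <- function(cond) which(cond)
  problems <- character(0)
  line <- function(i) i + 1L  # header occupies line 1

  i <- bad(!tab$scenario_id %in% 1:8)
  if (length(i)) problems <- c(problems, sprintf(
    "line %d: scenario_id %s not in 1..8", line(i), tab$scenario_id[i]))
  i <- bad(!is.na(tab$belief_pct) & (tab$belief_pct < 0 | tab$belief_pct > 100))
  if (length(i)) problems <- c(problems, sprintf(
    "line %d: belief_pct %s outside [0, 100]", line(i), tab$belief_pct[i]))
  if ("reported_power" %in% names(tab)) {
    i <- bad(!is.na(tab$reported_power) &
               (tab$reported_power <= 0 | tab$reported_power > 1))
    if (length(i)) problems <- c(problems, sprintf(
      "line %d: reported_power %s outside (0, 1]", line(i),
      tab$reported_power[i]))
  }
  if ("k" %in% names(tab)) {
    ok <- tab$scenario_id %in% 1:8
    expect_k <- rep(NA_integer_, nrow(tab))
    expect_k[ok] <- scenario_designs()$k[tab$scenario_id[ok]]
    i <- bad(ok & !is.na(tab$k) & tab$k != expect_k)
    if (length(i)) problems <- c(problems, sprintf(
      "line %d: k = %s inconsistent with scenario %s", line(i), tab$k[i],
      tab$scenario_id[i]))
  }
  if (length(problems)) {
    abort(sprintf("%s: %d malformed row(s)\n%s", source, length(problems),
                  paste(utils::head(problems, 20), collapse = "\n")),
          "replibelief_io_error")
  }
  tab
}

#' Write a response table
#'
#' @param tab response table data frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_response_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

# metadata record written next to every pipeline output
write_metadata <- function(path, command, config = NULL, extra = list()) {
  meta <- c(list(
    command = command,
    package = "replibelief",
    version = as.character(utils::packageVersion("replibelief")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), if (!is.null(config)) list(config = unclass(config)), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
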