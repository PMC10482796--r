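#' The eight vignette scenarios
#'
#' Each scenario presents the outcomes of four replication experiments
#' (A', B, C, D) of an original significant experiment A.  A' is a direct
#' replication (same method as the original); B, C and D are conceptual
#' replications.  The eight scenarios span k = 0 to 4 significant results,
#' and for k = 1, 2, 3 come in pairs differing only in whether the direct
#' replication (A') or the first conceptual replication (B) is significant.
#'
#' @return A data frame with one row per scenario and columns
#'   \describe{
#'     \item{scenario_id}{integer 1-8}
#'     \item{pattern}{significance pattern over (A', B, C, D); \code{"X"} =
#'       significant, \code{"O"} = non-significant}
#'     \item{k}{number of significant results (0-4)}
#'     \item{direct_significant}{\code{TRUE} iff A', the direct replication,
#'       was significant}
#'   }
#' @examples
#' scenario_designs()
#' @export
scenario_designs <- function() {
  pattern <- c("OOOO", "XOOO", "OXOO", "XOXO", "OXXO", "XOXX", "OXXX", "XXXX")
  sig <- t(vapply(strsplit(pattern, ""), function(p) p == "X", logical(4)))
  data.frame(
    scenario_id = 1:8,
    pattern = pattern,
    k = as.integer(rowSums(sig)),
    direct_significant = sig[, 1],
    stringsAsFactors = FALSE
  )
}

# k for a vector of scenario ids, with validation
scenario_k <- function(scenario_id) {
  if (anyNA(scenario_id) || !all(scenario_id %in% 1:8)) {
    stop_invalid("`scenario_id` must be in 1..8")
  }
  scenario_designs()$k[scenario_id]
}
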