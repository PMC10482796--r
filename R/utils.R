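# Internal condition helpers: every user-facing validation failure carries a
# condition class so callers (and tests) can distinguish failure modes.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "replibelief_error")))
}

stop_invalid <- function(msg) abort(msg, "replibelief_invalid_argument")

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x >= 1)) {
    stop_invalid(sprintf("`%s` must be in the open interval (0, 1)", name))
  }
  invisible(x)
}

check_k <- function(k, n) {
  if (!is.numeric(k) || anyNA(k) || any(k != floor(k)) || any(k < 0) || any(k > n)) {
    stop_invalid(sprintf("`k` must be an integer count in [0, %d]", n))
  }
  invisible(k)
}

# log(sum(exp(x))) without overflow/underflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
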