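# Classed conditions so the CLI can map failures to distinct exit codes.

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("polyadd_domain_error", "polyadd_error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("polyadd_usage_error", "polyadd_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("polyadd_numerical_error", "polyadd_error")))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number", name)
  invisible(x)
}

check_probability <- function(p, name = "p", allow_one = FALSE) {
  check_scalar(p, name)
  hi_ok <- if (allow_one) p <= 1 else p < 1
  if (p < 0 || !hi_ok)
    stop_domain("`%s` must be in [0, %s), got %g", name,
                if (allow_one) "1]" else "1", p)
  invisible(p)
}

check_count <- function(k, name = "k", min = 1L) {
  if (!is.numeric(k) || length(k) < 1L || any(!is.finite(k)) ||
      any(k != floor(k)) || any(k < min))
    stop_domain("`%s` must be integer(s) >= %d", name, min)
  invisible(as.integer(k))
}
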