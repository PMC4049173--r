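# Structured error conditions. Every user-facing failure mode carries a
# class so callers (and tests) can distinguish configuration errors,
# input-validation errors, and metrics that are undefined for the data.

zt_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "zebratrain_error", "error")))
}

stop_invalid_config <- function(msg, ...) zt_stop("zt_invalid_config", msg, ...)
stop_validation <- function(msg, ...) zt_stop("zt_validation_error", msg, ...)
stop_undefined_metric <- function(msg, ...) zt_stop("zt_undefined_metric", msg, ...)
stop_invalid_input <- function(msg, ...) zt_stop("zt_invalid_input", msg, ...)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE,
                         stop_fun = stop_invalid_config) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fun(sprintf("`%s` must be a single finite number", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_fun(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}
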