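#' Classed conditions used across the engine
#'
#' Transient, user-fixable faults (missing credential, unreachable resource,
#' missing input file) are signalled as *blocking* conditions so the engine
#' can park the affected task in status `"blocked"` instead of failing it.
#' Everything else uses ordinary classed errors.
#'
#' @name flowbench-conditions
#' @keywords internal
NULL

#' Signal a blocking fault
#'
#' Raises a condition of class `fb_blocked`. The engine catches it during any
#' task lifecycle stage and moves the task to status `"blocked"`; the fault is
#' resumable once the cause (credential, reachability, missing file) is fixed.
#'
#' @param reason Human-readable description of the fault.
#' @param ... Additional fields attached to the condition.
#' @return Does not return; signals a condition.
#' @export
signal_blocked <- function(reason, ...) {
  cond <- structure(
    class = c("fb_blocked", "fb_condition", "error", "condition"),
    list(message = reason, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Test whether a condition is a blocking fault
#' @param x A condition object.
#' @return `TRUE` for conditions raised by [signal_blocked()].
#' @export
is_blocked <- function(x) inherits(x, "fb_blocked")

fb_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "fb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_config     <- function(msg, ...) fb_stop(msg, "fb_config_error", ...)
stop_validation <- function(msg, ...) fb_stop(msg, "fb_validation_error", ...)
stop_notfound   <- function(msg, ...) fb_stop(msg, "fb_notfound_error", ...)
stop_pattern    <- function(msg, ...) fb_stop(msg, "fb_pattern_error", ...)
stop_auth       <- function(msg, ...) fb_stop(msg, "fb_auth_error", ...)
stop_contract   <- function(msg, ...) fb_stop(msg, "fb_contract_error", ...)
stop_state      <- function(msg, ...) fb_stop(msg, "fb_state_error", ...)

# simulated graceful-shutdown signal used by the crash/resume test harness
fb_crash <- function(at) {
  stop(structure(
    class = c("fb_crash", "fb_condition", "error", "condition"),
    list(message = sprintf("simulated shutdown at checkpoint '%s'", at),
         call = NULL, at = at)
  ))
}

#' @keywords internal
is_crash <- function(x) inherits(x, "fb_crash")

`%||%` <- function(a, b) if (is.null(a)) b else a
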