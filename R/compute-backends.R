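#' Bundled compute backends
#'
#' A compute backend implements the execution contract: `submit(job)` returns
#' an opaque handle, `poll(handle)` reports `queued`, `running`,
#' `done` (with exit code) or `lost`, and `cancel(handle)` withdraws the
#' work. Scheduling is the backend's business — the engine only stages data,
#' submits, polls and reacts. Two backends ship with the package:
#'
#' * `localexec` — runs the command directly as a subprocess with the task
#'   scratch directory as working directory, capturing stdout/stderr.
#' * `mockq` — a simulated remote queue standing in for batch schedulers:
#'   configurable queueing latency (`latency_polls`) and transient-fault
#'   injection (`lose_attempts` makes the first attempts report `lost`), plus
#'   an unreachability flag on the descriptor. Execution itself is delegated
#'   to the same subprocess mechanics once the simulated queue releases the
#'   job.
#'
#' @name compute-backends
#' @keywords internal
NULL

exec_subprocess <- function(job) {
  res <- processx::run(
    command = job$command[1],
    args = if (length(job$command) > 1L) job$command[-1] else character(0),
    wd = job$wd,
    env = c(Sys.getenv(), job$env),
    error_on_status = FALSE,
    stdout = job$stdout_path,
    stderr = job$stderr_path
  )
  res$status
}

compute_localexec <- function(descriptor) {
  be <- new.env(parent = emptyenv())
  be$descriptor <- descriptor
  be$handles <- new.env(parent = emptyenv())
  be$nexth <- 0L
  be$submit <- function(job) {
    if (!descriptor$reachable)
      signal_blocked(sprintf("compute backend '%s' unreachable", descriptor$id),
                     backend_id = descriptor$id)
    be$nexth <- be$nexth + 1L
    h <- sprintf("localexec-%d", be$nexth)
    exit <- exec_subprocess(job)
    be$handles[[h]] <- list(state = "done", exit_code = exit)
    h
  }
  be$poll <- function(h) {
    st <- be$handles[[h]]
    if (is.null(st)) list(state = "lost", exit_code = NA_integer_) else st
  }
  be$cancel <- function(h) {
    if (!is.null(be$handles[[h]])) rm(list = h, envir = be$handles)
    invisible(TRUE)
  }
  class(be) <- "fb_compute_backend"
  be
}

compute_mockq <- function(descriptor) {
  opts <- descriptor$options %||% list()
  latency <- as.integer(opts$latency_polls %||% 1L)
  lose <- as.integer(opts$lose_attempts %||% 0L)
  be <- new.env(parent = emptyenv())
  be$descriptor <- descriptor
  be$handles <- new.env(parent = emptyenv())
  be$attempts <- new.env(parent = emptyenv())  # task_id -> submissions seen
  be$nexth <- 0L
  be$submit <- function(job) {
    if (!descriptor$reachable)
      signal_blocked(sprintf("compute backend '%s' unreachable", descriptor$id),
                     backend_id = descriptor$id)
    tid <- job$task_id %||% "anon"
    seen <- (be$attempts[[tid]] %||% 0L) + 1L
    be$attempts[[tid]] <- seen
    be$nexth <- be$nexth + 1L
    h <- sprintf("mockq-%d", be$nexth)
    be$handles[[h]] <- list(job = job, polls = 0L,
                            lost = seen <= lose, done = FALSE,
                            exit_code = NA_integer_)
    h
  }
  be$poll <- function(h) {
    st <- be$handles[[h]]
    if (is.null(st)) return(list(state = "lost", exit_code = NA_integer_))
    if (st$done) return(list(state = "done", exit_code = st$exit_code))
    st$polls <- st$polls + 1L
    if (st$lost) {
      be$handles[[h]] <- st
      return(list(state = "lost", exit_code = NA_integer_))
    }
    if (st$polls <= latency) {
      be$handles[[h]] <- st
      return(list(state = if (st$polls < latency) "queued" else "running",
                  exit_code = NA_integer_))
    }
    st$exit_code <- exec_subprocess(st$job)
    st$done <- TRUE
    be$handles[[h]] <- st
    list(state = "done", exit_code = st$exit_code)
  }
  be$cancel <- function(h) {
    if (!is.null(be$handles[[h]])) rm(list = h, envir = be$handles)
    invisible(TRUE)
  }
  class(be) <- "fb_compute_backend"
  be
}

#' Build the compute-backend table from a registry
#'
#' @param registry An `fb_registry`.
#' @return An environment mapping backend id to backend object, with a
#'   parallel `descriptors` table (mutable, so reachability can be toggled at
#'   run time for fault-injection).
#' @export
compute_manager <- function(registry) {
  cm <- new.env(parent = emptyenv())
  cm$descriptors <- new.env(parent = emptyenv())
  cm$instances <- new.env(parent = emptyenv())
  for (b in registry$backends) {
    if (b$kind != "compute") next
    factory <- .fb_plugins$compute[[b$scheme]]
    if (is.null(factory))
      stop_config(sprintf("no compute plug-in for scheme '%s'", b$scheme))
    desc <- as.environment(b)
    cm$descriptors[[b$id]] <- desc
    cm$instances[[b$id]] <- factory(desc)
  }
  class(cm) <- "fb_compute_manager"
  cm
}
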