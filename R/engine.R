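#' The workflow engine
#'
#' The engine accepts workflow descriptions (an ordered list of jobs, each a
#' tool invocation whose file inputs may point at the output of an earlier
#' job), persists them *before* any processing (write-ahead submission), and
#' then drives them through rounds of dependency resolution: a job becomes
#' ready when every referenced earlier job is complete and every referenced
#' input file exists on its storage backend; a ready job is expanded into
#' concrete tasks (one per matching file for a batchable parameter, one per
#' minimum-edit-distance pair when two batchable parameters take different
#' file types); each task is staged in, executed on its compute backend,
#' staged out and cleaned up, with every transition persisted and logged.
#' Processing continues until every job is complete or in an error state, at
#' which point the workflow is marked `complete` or `error`; transient faults
#' (missing credential, unreachable backend, missing input file) park work in
#' the resumable `blocked` state instead.
#'
#' @name engine
#' @keywords internal
NULL

TASK_STAGES <- c("stage_in", "exec", "stage_out", "finalize")

task_transitions <- list(
  pending     = c("ready", "blocked", "error"),
  ready       = c("staging_in", "running", "staging_out", "complete",
                  "blocked", "error"),
  staging_in  = c("running", "blocked", "error"),
  running     = c("staging_out", "blocked", "error"),
  staging_out = c("complete", "blocked", "error"),
  blocked     = c("pending", "ready", "staging_in", "running", "staging_out",
                  "error"),
  complete    = character(0),
  error       = character(0)
)

job_transitions <- list(
  pending  = c("ready", "blocked", "error"),
  ready    = c("running", "blocked", "error"),
  running  = c("complete", "blocked", "error"),
  blocked  = c("pending", "running", "error"),
  complete = character(0),
  error    = character(0)
)

#' Open (or create) an engine root
#'
#' The root directory holds the SQLite state store, the task scratch area
#' (`work/`), the default results location (`results/`) and the fixture
#' nonce ledger. Reopening an existing root restores the persisted state:
#' stale leases are released and tasks interrupted mid-lifecycle are
#' re-offered at their last incomplete stage.
#'
#' @param root Directory for all engine state.
#' @param registry An `fb_registry`, a config path/string for
#'   [load_registry()], or `NULL` to reuse the registry stored in the root.
#' @param options Named list overriding engine defaults: `retry_max` (3),
#'   `backoff_base` (seconds, 0.05), `poll_interval` (0.01),
#'   `lease_seconds` (300), `chunk_size` (1 MiB), `chunk_ceiling` (8 MiB).
#' @return An engine context of class `fb_engine`.
#' @export
engine_open <- function(root, registry = NULL, options = list()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  root <- normalizePath(root)
  ctx <- new.env(parent = emptyenv())
  ctx$root <- root
  ctx$db_path <- file.path(root, "store.sqlite")
  ctx$con <- store_open(ctx$db_path)
  store_init(ctx$con)

  if (!is.null(registry)) {
    reg <- if (inherits(registry, "fb_registry")) registry else load_registry(registry)
    DBI::dbExecute(ctx$con, "DELETE FROM registry_doc")
    DBI::dbExecute(ctx$con, "INSERT INTO registry_doc VALUES (?)",
                   params = list(to_json(registry_to_list(reg))))
  } else {
    doc <- DBI::dbGetQuery(ctx$con, "SELECT doc FROM registry_doc")$doc
    if (!length(doc))
      stop_config("no registry stored in this engine root; pass one to engine_open()")
    reg <- load_registry(from_json(doc[1]))
  }
  ctx$registry <- reg

  # implicit unrooted local-filesystem backend for scratch and default results
  if (!"engine-local" %in% names(reg$backends)) {
    reg$backends[["engine-local"]] <- list(
      id = "engine-local", kind = "storage", scheme = "file", endpoint = "",
      requires_credential = FALSE, reachable = TRUE, options = list())
    ctx$registry <- reg
  }
  ctx$sm <- storage_manager(ctx$registry)
  ctx$cm <- compute_manager(ctx$registry)
  ctx$localfs <- ctx$sm$instances[["engine-local"]] %||%
    storage_localfs(list(id = "engine-local", scheme = "file", endpoint = "",
                         requires_credential = FALSE, reachable = TRUE))
  ctx$vault <- credential_vault(ctx$con)
  ctx$work_root <- file.path(root, "work")
  ctx$results_uri <- uri("file", "", file.path(root, "results"))
  dir.create(ctx$work_root, showWarnings = FALSE)
  dir.create(file.path(root, "results"), showWarnings = FALSE)
  ctx$clock <- function() as.numeric(Sys.time())
  ctx$sleep <- function(s) if (s > 0) Sys.sleep(s)
  defaults <- list(retry_max = 3L, backoff_base = 0.05, poll_interval = 0.01,
                   lease_seconds = 300, chunk_size = 2^20,
                   chunk_ceiling = 8 * 2^20,
                   nonce_ledger = file.path(root, "nonce-ledger.txt"))
  defaults[names(options)] <- options
  ctx$options <- defaults
  ctx$crash_after <- NULL

  # resume normalisation: release leases, re-offer interrupted tasks at their
  # last incomplete lifecycle stage
  DBI::dbExecute(ctx$con,
    "UPDATE tasks SET lease_owner = NULL, lease_until = NULL
     WHERE status NOT IN ('complete','error')")
  DBI::dbExecute(ctx$con,
    "UPDATE tasks SET status = 'ready'
     WHERE status IN ('staging_in','running','staging_out')")

  class(ctx) <- "fb_engine"
  ctx
}

#' Close an engine context
#' @param ctx An engine context.
#' @return Invisibly, `NULL`.
#' @export
engine_close <- function(ctx) {
  vault_lock(ctx$vault)
  if (DBI::dbIsValid(ctx$con))
    try(suppressWarnings(DBI::dbDisconnect(ctx$con)), silent = TRUE)
  invisible(NULL)
}

#' @export
print.fb_engine <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM workflows")$n
  cat(sprintf("<engine> root %s: %d workflow(s), %d tool(s)\n",
              x$root, n, length(x$registry$tools)))
  invisible(x)
}

#' Toggle a backend's reachability flag
#'
#' Mock backends model outages through this flag; an unreachable backend
#' blocks (rather than fails) the tasks that need it.
#'
#' @param ctx An engine context.
#' @param backend_id Backend id from the registry.
#' @param reachable Logical.
#' @return Invisibly, `ctx`.
#' @export
engine_set_reachable <- function(ctx, backend_id, reachable) {
  hit <- FALSE
  for (mgr in list(ctx$sm, ctx$cm)) {
    d <- mgr$descriptors[[backend_id]]
    if (!is.null(d)) { d$reachable <- reachable; hit <- TRUE }
  }
  if (!hit) stop_notfound(sprintf("unknown backend '%s'", backend_id))
  invisible(ctx)
}

checkpoint <- function(ctx, at) {
  if (!is.null(ctx$crash_after)) {
    ctx$crash_after <- ctx$crash_after - 1L
    if (ctx$crash_after <= 0L) {
      ctx$crash_after <- NULL
      fb_crash(at)
    }
  }
  invisible(NULL)
}

# --- submission ------------------------------------------------------------

parse_workflow_request <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (file.exists(x)) jsonlite::fromJSON(x, simplifyVector = FALSE)
         else jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (!is.list(x)) stop_validation("workflow request must be a list or JSON document")
  x
}

#' Validate a workflow request against the registry
#'
#' @param ctx An engine context.
#' @param request A workflow request (list or JSON).
#' @return A character vector of diagnostics; empty when the request is valid.
#' @export
validate_request <- function(ctx, request) {
  reg <- ctx$registry
  bad <- character(0)
  user <- request$user
  if (!is.character(user) || length(user) != 1L || !nzchar(user))
    return("request has no user")
  grant <- reg$users[[user]]
  if (is.null(grant)) return(sprintf("unknown user '%s'", user))
  jobs <- request$jobs
  if (!is.list(jobs) || length(jobs) == 0L)
    return("request must contain at least one job")
  for (i in seq_along(jobs)) {
    j <- jobs[[i]]
    tag <- sprintf("job %d", i - 1L)
    tool <- reg$tools[[j$tool %||% ""]]
    if (is.null(tool)) {
      bad <- c(bad, sprintf("%s: unknown tool '%s'", tag, j$tool %||% "<missing>"))
      next
    }
    if (!tool$name %in% grant$tools) {
      bad <- c(bad, sprintf("%s: tool '%s' not granted to user '%s'",
                            tag, tool$name, user))
      next
    }
    if (!tool$exec_backend %in% grant$backends)
      bad <- c(bad, sprintf("%s: backend '%s' not granted to user '%s'",
                            tag, tool$exec_backend, user))
    args <- j$args %||% list()
    extra <- setdiff(names(args), names(tool$params))
    if (length(extra))
      bad <- c(bad, sprintf("%s: unknown parameter '%s' for tool '%s'",
                            tag, extra[1], tool$name))
    for (pn in names(tool$params)) {
      p <- tool$params[[pn]]
      a <- args[[pn]]
      if (is.null(a)) {
        if (p$mandatory && is.null(p$default))
          bad <- c(bad, sprintf("%s: mandatory parameter '%s' not supplied",
                                tag, pn))
        next
      }
      if (is.list(a) && !is.null(a$from_job)) {
        if (p$source_kind != "previous-job-output") {
          bad <- c(bad, sprintf(
            "%s: parameter '%s' does not accept previous-job references", tag, pn))
        } else {
          k <- a$from_job
          if (!is.numeric(k) || k < 0 || k >= (i - 1L))
            bad <- c(bad, sprintf(
              "%s: from_job must reference a strictly earlier job (got %s)",
              tag, format(k)))
          if (!is.null(a$pattern))
            tryCatch(glob_to_regex(a$pattern), error = function(e)
              bad <<- c(bad, sprintf("%s: invalid pattern override: %s",
                                     tag, conditionMessage(e))))
        }
      } else if (p$source_kind == "user-literal") {
        if (!(is.character(a) || is.numeric(a)) || length(a) != 1L)
          bad <- c(bad, sprintf("%s: parameter '%s' expects a literal value",
                                tag, pn))
      } else {
        ok <- tryCatch({ uri_parse(as.character(a)); TRUE },
                       error = function(e) FALSE)
        if (!ok)
          bad <- c(bad, sprintf("%s: parameter '%s' expects a URI, got '%s'",
                                tag, pn, format(a)))
      }
    }
    nb <- sum(vapply(names(tool$params), function(pn)
      tool$params[[pn]]$batchable && !is.null(args[[pn]]), logical(1)))
    if (nb > 2L)
      bad <- c(bad, sprintf("%s: at most two batchable parameters may be bound", tag))
  }
  bad
}

#' Submit a workflow
#'
#' Validates the request, persists it (workflow and all job records) in one
#' transaction, and returns the new workflow id *before any processing
#' happens* — acceptance is decoupled from execution, so a returned id only
#' guarantees the workflow is durably queued. Drive it with [advance()] or
#' [drive()].
#'
#' @param ctx An engine context.
#' @param request A workflow request: a list (or JSON string/file) with
#'   fields `user`, optional `name` and `metadata`, and `jobs` — an ordered
#'   list of `{tool, args}` where each arg is a literal, a URI string, or a
#'   previous-job reference `{"from_job": k}` (0-based index of an earlier
#'   job, optional `"pattern"` narrowing which of its outputs apply).
#' @return The integer workflow id.
#' @export
submit_workflow <- function(ctx, request) {
  request <- parse_workflow_request(request)
  diags <- validate_request(ctx, request)
  if (length(diags))
    stop_validation(paste0("workflow rejected:\n  ",
                           paste(diags, collapse = "\n  ")),
                    diagnostics = diags)
  now <- ctx$clock()
  DBI::dbExecute(ctx$con, "BEGIN IMMEDIATE")
  ok <- FALSE
  tryCatch({
    DBI::dbExecute(ctx$con,
      "INSERT INTO workflows (name, user, status, created_at, metadata, request)
       VALUES (?,?,?,?,?,?)",
      params = list(request$name %||% NA_character_, request$user, "pending",
                    now, to_json(request$metadata %||% list()),
                    to_json(request)))
    wf_id <- DBI::dbGetQuery(ctx$con, "SELECT last_insert_rowid() AS id")$id
    if (is.null(request$name))
      DBI::dbExecute(ctx$con, "UPDATE workflows SET name = ? WHERE id = ?",
                     params = list(sprintf("workflow-%d", wf_id), wf_id))
    for (i in seq_along(request$jobs)) {
      j <- request$jobs[[i]]
      DBI::dbExecute(ctx$con,
        "INSERT INTO jobs (workflow_id, idx, tool, status, args)
         VALUES (?,?,?,?,?)",
        params = list(wf_id, i - 1L, j$tool, "pending",
                      to_json(j$args %||% list())))
    }
    DBI::dbExecute(ctx$con, "COMMIT")
    ok <- TRUE
  }, finally = if (!ok) DBI::dbExecute(ctx$con, "ROLLBACK"))
  checkpoint(ctx, sprintf("submitted wf %d", wf_id))
  as.integer(wf_id)
}

# --- row helpers -----------------------------------------------------------

wf_row <- function(ctx, id) {
  r <- db_row(ctx$con, "SELECT * FROM workflows WHERE id = ?", id)
  if (is.null(r)) stop_notfound(sprintf("unknown workflow %s", id))
  r
}
job_row <- function(ctx, id) {
  r <- db_row(ctx$con, "SELECT * FROM jobs WHERE id = ?", id)
  if (is.null(r)) stop_notfound(sprintf("unknown job %s", id))
  r
}
task_row <- function(ctx, id) {
  r <- db_row(ctx$con, "SELECT * FROM tasks WHERE id = ?", id)
  if (is.null(r)) stop_notfound(sprintf("unknown task %s", id))
  r
}

#' Workflow, job and task state accessors
#'
#' @param ctx An engine context.
#' @param workflow_id,task_id Identifiers.
#' @return `workflow_status()`: the workflow's status string; `job_table()`
#'   and `task_table()`: data frames of the workflow's jobs/tasks;
#'   `syslog_table()`: the append-only timestamped log of a task.
#' @export
workflow_status <- function(ctx, workflow_id) wf_row(ctx, workflow_id)$status

#' @rdname workflow_status
#' @export
job_table <- function(ctx, workflow_id) {
  DBI::dbGetQuery(ctx$con,
    "SELECT id, idx, tool, status, blocked_from, reason FROM jobs
     WHERE workflow_id = ? ORDER BY idx", params = list(workflow_id))
}

#' @rdname workflow_status
#' @export
task_table <- function(ctx, workflow_id) {
  DBI::dbGetQuery(ctx$con,
    "SELECT id, job_id, status, stage, attempt, exit_code, reason,
            command, outputs
     FROM tasks WHERE workflow_id = ? ORDER BY id", params = list(workflow_id))
}

#' @rdname workflow_status
#' @export
syslog_table <- function(ctx, task_id) {
  DBI::dbGetQuery(ctx$con,
    "SELECT ts, message FROM syslog WHERE task_id = ? ORDER BY id",
    params = list(task_id))
}

# --- status reporting ------------------------------------------------------

#' Report a task status change or log message
#'
#' Status transitions are checked against the task state machine
#' (`pending → ready → staging_in → running → staging_out → complete`; any
#' non-terminal state may move to `blocked` and return to its prior state on
#' resume; anything may move to `error`; `complete` and `error` are
#' terminal). An illegal transition is a contract violation, not a user
#' error. The change is persisted before the call returns. The syslog is
#' append-only and timestamped.
#'
#' @param ctx An engine context.
#' @param task_id Task id.
#' @param new_status Target status.
#' @param reason Optional reason recorded with the change.
#' @param message Log line for `report_syslog()`.
#' @return Invisibly, the new status (or `NULL` for syslog).
#' @export
report_status <- function(ctx, task_id, new_status, reason = NULL) {
  t <- task_row(ctx, task_id)
  if (identical(t$status, new_status)) return(invisible(new_status))
  allowed <- task_transitions[[t$status]]
  if (!new_status %in% allowed)
    stop_contract(sprintf("illegal task transition %s -> %s (task %s)",
                          t$status, new_status, task_id))
  blocked_from <- if (new_status == "blocked") t$status else NA_character_
  DBI::dbExecute(ctx$con,
    "UPDATE tasks SET status = ?, blocked_from = ?, reason = ? WHERE id = ?",
    params = list(new_status, blocked_from,
                  reason %||% t$reason %||% NA_character_, task_id))
  report_syslog(ctx, task_id, sprintf("status: %s -> %s%s", t$status, new_status,
    if (!is.null(reason)) paste0(" (", reason, ")") else ""))
  invisible(new_status)
}

#' @rdname report_status
#' @export
report_syslog <- function(ctx, task_id, message) {
  DBI::dbExecute(ctx$con,
    "INSERT INTO syslog (task_id, ts, message) VALUES (?,?,?)",
    params = list(task_id, ctx$clock(), message))
  invisible(NULL)
}

job_set_status <- function(ctx, job_id, new_status, reason = NULL) {
  j <- job_row(ctx, job_id)
  if (identical(j$status, new_status)) return(invisible(new_status))
  allowed <- job_transitions[[j$status]]
  if (!new_status %in% allowed)
    stop_contract(sprintf("illegal job transition %s -> %s (job %s)",
                          j$status, new_status, job_id))
  blocked_from <- if (new_status == "blocked") j$status else NA_character_
  DBI::dbExecute(ctx$con,
    "UPDATE jobs SET status = ?, blocked_from = ?, reason = ? WHERE id = ?",
    params = list(new_status, blocked_from, reason %||% NA_character_, job_id))
  invisible(new_status)
}

# --- dependency resolution -------------------------------------------------

job_file_args <- function(tool, args) {
  # named list: param -> arg, for params that take files
  out <- list()
  for (pn in names(tool$params)) {
    p <- tool$params[[pn]]
    if (p$source_kind == "user-literal") next
    a <- args[[pn]]
    if (!is.null(a)) out[[pn]] <- a
  }
  out
}

# resolve one job's file inputs to concrete URIs; raises fb_blocked for
# missing files / unreachable backends / missing credentials
resolve_job_inputs <- function(ctx, job) {
  wf <- wf_row(ctx, job$workflow_id)
  tool <- ctx$registry$tools[[job$tool]]
  args <- from_json(job$args) %||% list()
  resolved <- list()
  for (pn in names(job_file_args(tool, args))) {
    p <- tool$params[[pn]]
    a <- args[[pn]]
    if (is.list(a) && !is.null(a$from_job)) {
      parent <- db_row(ctx$con,
        "SELECT * FROM jobs WHERE workflow_id = ? AND idx = ?",
        job$workflow_id, as.integer(a$from_job))
      outs <- vapply(from_json(parent$outputs) %||% list(),
                     function(o) o$uri, "")
      pats <- if (!is.null(a$pattern)) a$pattern else p$accepts
      outs <- outs[vapply(outs, function(u) matches_any(uri_basename(u), pats),
                          logical(1))]
      for (u in outs)
        if (is.na(st_exists(ctx$sm, u, ctx$vault, wf$user)))
          signal_blocked(sprintf("input file missing: %s", u))
      resolved[[pn]] <- unname(outs)
    } else {
      u <- uri_parse(as.character(a))
      kind <- st_exists(ctx$sm, u, ctx$vault, wf$user)
      if (is.na(kind))
        signal_blocked(sprintf("input file missing: %s", format(u)))
      if (kind == "dir") {
        ls_df <- st_list(ctx$sm, u, ctx$vault, wf$user)
        nm <- ls_df$name[ls_df$kind == "file"]
        nm <- nm[vapply(nm, matches_any, logical(1), patterns = p$accepts)]
        resolved[[pn]] <- vapply(sort(nm), function(n)
          format(uri_join(u, n)), "")
      } else {
        resolved[[pn]] <- format(u)
      }
    }
  }
  lapply(resolved, function(v) unname(v[order(basename(v))]))
}

#' Find the jobs whose dependencies are satisfied
#'
#' A pending job becomes ready when every job it references has finished
#' executing and every input file it references is present on its storage
#' backend. A job referencing a failed upstream job moves to `error`; a job
#' whose inputs cannot be checked or are missing moves to `blocked` (a
#' transient, resumable condition). A job is never offered as ready twice:
#' readiness transitions it out of `pending`.
#'
#' @param ctx An engine context.
#' @param workflow_id Workflow id.
#' @return Integer vector of job ids that just became ready.
#' @export
resolve_ready_jobs <- function(ctx, workflow_id) {
  jobs <- DBI::dbGetQuery(ctx$con,
    "SELECT * FROM jobs WHERE workflow_id = ? ORDER BY idx",
    params = list(workflow_id))
  ready <- integer(0)
  for (i in seq_len(nrow(jobs))) {
    j <- as.list(jobs[i, ])
    if (j$status != "pending") next
    args <- from_json(j$args) %||% list()
    parent_idx <- unique(unlist(lapply(args, function(a)
      if (is.list(a) && !is.null(a$from_job)) as.integer(a$from_job))))
    if (length(parent_idx)) {
      pstat <- jobs$status[match(parent_idx, jobs$idx)]
      if (any(pstat == "error")) {
        job_set_status(ctx, j$id, "error",
                       reason = "upstream job failed")
        next
      }
      if (!all(pstat == "complete")) next
    }
    res <- tryCatch({ resolve_job_inputs(ctx, j); "ok" },
                    fb_blocked = function(e) conditionMessage(e))
    if (!identical(res, "ok")) {
      job_set_status(ctx, j$id, "blocked", reason = res)
      next
    }
    job_set_status(ctx, j$id, "ready")
    ready <- c(ready, j$id)
  }
  as.integer(ready)
}

# --- command rendering -----------------------------------------------------

#' Render a tool invocation into an argument vector
#'
#' Produces the exact token list that will be executed — values are passed as
#' discrete argument tokens, never through a shell, so spaces and shell
#' metacharacters in values survive verbatim. The program template is split
#' on whitespace; `{param}` placeholders are substituted in place and consume
#' their parameter. All remaining parameters are emitted in declared order as
#' switch token (when non-empty) followed by the value token(s); an unbound
#' optional parameter is omitted entirely, an unbound mandatory parameter
#' (with no default) is a rendering error naming the parameter.
#'
#' @param tool A tool spec from the registry.
#' @param bound_args Named list mapping parameter names to value character
#'   vectors (file parameters may carry several staged paths).
#' @return Character vector of argument tokens, starting with the program.
#' @examples
#' reg <- load_registry(list(schema_version = 1,
#'   backends = list(list(id = "l", kind = "compute", scheme = "localexec",
#'                        endpoint = "")),
#'   tools = list(list(name = "wc", program = "wc", exec_backend = "l",
#'     params = list(list(name = "infile", switch = "-i", mandatory = TRUE,
#'                        accepts = list("*.txt"), source_kind = "input-file")),
#'     produces = list("*.out"))),
#'   users = list()))
#' render_command(reg$tools$wc, list(infile = "a.txt"))
#' @export
render_command <- function(tool, bound_args) {
  for (pn in names(tool$params)) {
    p <- tool$params[[pn]]
    if (is.null(bound_args[[pn]]) && !is.null(p$default))
      bound_args[[pn]] <- as.character(p$default)
    if (p$mandatory && is.null(bound_args[[pn]]))
      fb_stop(sprintf("cannot render command for tool '%s': mandatory parameter '%s' unbound",
                      tool$name, pn), "fb_render_error", param = pn)
  }
  tokens <- strsplit(tool$program, "[[:space:]]+")[[1]]
  consumed <- character(0)
  out <- character(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^\\{([A-Za-z0-9_]+)\\}$", tok))[[1]]
    if (length(m)) {
      pn <- m[2]
      out <- c(out, as.character(bound_args[[pn]]))
      consumed <- c(consumed, pn)
    } else if (grepl("\\{[A-Za-z0-9_]+\\}", tok)) {
      holes <- gsub("[{}]", "",
                    regmatches(tok, gregexpr("\\{[A-Za-z0-9_]+\\}", tok))[[1]])
      for (pn in holes) {
        tok <- gsub(paste0("\\{", pn, "\\}"),
                    as.character(bound_args[[pn]])[1], tok)
        consumed <- c(consumed, pn)
      }
      out <- c(out, tok)
    } else {
      out <- c(out, tok)
    }
  }
  for (pn in names(tool$params)) {
    if (pn %in% consumed) next
    vals <- bound_args[[pn]]
    if (is.null(vals)) next
    for (v in as.character(vals)) {
      if (nzchar(tool$params[[pn]]$switch))
        out <- c(out, tool$params[[pn]]$switch)
      out <- c(out, v)
    }
  }
  out
}

output_location_uri <- function(ctx, tool, workflow_id, job_idx) {
  tmpl <- tool$output_location
  if (is.null(tmpl))
    return(uri_join(ctx$results_uri, sprintf("wf%d", workflow_id),
                    sprintf("j%d", job_idx)))
  s <- gsub("{workflow}", sprintf("wf%d", workflow_id), tmpl, fixed = TRUE)
  s <- gsub("{job}", sprintf("j%d", job_idx), s, fixed = TRUE)
  uri_parse(s)
}

# --- task generation -------------------------------------------------------

#' Expand a ready job into its batch of tasks
#'
#' A job with no batchable file parameter yields exactly one task. One
#' batchable parameter with *n* matching files fans out into *n* tasks, one
#' per file. Two batchable parameters are joined with [pair_inputs()]
#' (minimum total Levenshtein distance over basenames) into one task per
#' pair; unpaired leftovers are logged on the job, never silently dropped.
#' Zero matching files on a mandatory batchable parameter is a job error
#' (`"no input satisfies pattern"`), not a silent empty fan-out. Every task
#' gets a fully rendered command (no unresolved placeholders), its stage-in
#' list and its stage-out destination.
#'
#' @param ctx An engine context.
#' @param job_id Job id (must be ready).
#' @param resolved_inputs Optional pre-resolved named list mapping file
#'   parameters to URI vectors; resolved from the job's arguments when `NULL`.
#' @return Integer vector of created task ids (empty on job error).
#' @export
generate_tasks <- function(ctx, job_id, resolved_inputs = NULL) {
  j <- job_row(ctx, job_id)
  if (!j$status %in% c("ready", "pending"))
    stop_state(sprintf("job %s is not ready (status %s)", job_id, j$status))
  wf <- wf_row(ctx, j$workflow_id)
  tool <- ctx$registry$tools[[j$tool]]
  args <- from_json(j$args) %||% list()
  resolved <- resolved_inputs %||% resolve_job_inputs(ctx, j)

  literals <- list()
  for (pn in names(tool$params)) {
    p <- tool$params[[pn]]
    if (p$source_kind != "user-literal") next
    a <- args[[pn]] %||% p$default
    if (!is.null(a)) literals[[pn]] <- as.character(a)
  }

  file_params <- names(resolved)
  batch_params <- file_params[vapply(file_params, function(pn)
    isTRUE(tool$params[[pn]]$batchable), logical(1))]

  fail_job <- function(pn) {
    pats <- tool$params[[pn]]$accepts
    job_set_status(ctx, job_id, "error",
      reason = sprintf("no input satisfies pattern %s for parameter '%s'",
                       paste(sprintf("'%s'", pats), collapse = "/"), pn))
    integer(0)
  }
  for (pn in file_params)
    if (length(resolved[[pn]]) == 0L &&
        (tool$params[[pn]]$mandatory || pn %in% batch_params))
      return(fail_job(pn))

  bindings <- list()
  leftover_note <- NULL
  if (length(batch_params) == 0L) {
    bindings[[1]] <- resolved
  } else if (length(batch_params) == 1L) {
    bp <- batch_params
    for (f in resolved[[bp]]) {
      b <- resolved
      b[[bp]] <- f
      bindings[[length(bindings) + 1L]] <- b
    }
  } else {
    bp1 <- batch_params[1]; bp2 <- batch_params[2]
    a_uris <- resolved[[bp1]]; b_uris <- resolved[[bp2]]
    pairing <- pair_inputs(basename(a_uris), basename(b_uris))
    if (length(pairing$leftovers))
      leftover_note <- sprintf("unpaired input file(s): %s",
                               paste(pairing$leftovers, collapse = ", "))
    for (k in seq_len(nrow(pairing$pairs))) {
      b <- resolved
      ua <- a_uris[match(pairing$pairs$a[k], basename(a_uris))]
      ub <- b_uris[match(pairing$pairs$b[k], basename(b_uris))]
      a_uris <- a_uris[-match(pairing$pairs$a[k], basename(a_uris))]
      b_uris <- b_uris[-match(pairing$pairs$b[k], basename(b_uris))]
      b[[bp1]] <- ua; b[[bp2]] <- ub
      bindings[[length(bindings) + 1L]] <- b
    }
  }

  out_uri <- output_location_uri(ctx, tool, j$workflow_id, j$idx)
  task_ids <- integer(0)
  bound_record <- NULL
  for (b in bindings) {
    stage_in <- list()
    staged <- list()
    used_names <- character(0)
    for (pn in names(b)) {
      uris <- b[[pn]]
      paths <- character(0)
      for (u in uris) {
        nm <- uri_basename(u)
        if (nm %in% used_names) nm <- sprintf("%d-%s", length(used_names), nm)
        used_names <- c(used_names, nm)
        stage_in[[length(stage_in) + 1L]] <- list(src = format(uri_parse(u)),
                                                  name = nm)
        paths <- c(paths, file.path("in", nm))
      }
      staged[[pn]] <- paths
    }
    cmd <- render_command(tool, c(literals, staged))
    DBI::dbExecute(ctx$con,
      "INSERT INTO tasks (job_id, workflow_id, status, stage, attempt,
                          command, stage_in, stage_out)
       VALUES (?,?,?,?,0,?,?,?)",
      params = list(job_id, j$workflow_id, "ready", "stage_in",
                    to_json(cmd), to_json(stage_in),
                    to_json(list(dst = format(out_uri)))))
    task_ids <- c(task_ids,
                  DBI::dbGetQuery(ctx$con, "SELECT last_insert_rowid() AS id")$id)
    if (is.null(bound_record)) bound_record <- c(literals, lapply(b, as.list))
  }
  DBI::dbExecute(ctx$con,
    "UPDATE jobs SET tool_json = ?, bound_args = ? WHERE id = ?",
    params = list(to_json(tool), to_json(c(literals, resolved)), job_id))
  job_set_status(ctx, job_id, "running")
  if (!is.null(leftover_note)) {
    DBI::dbExecute(ctx$con, "UPDATE jobs SET reason = ? WHERE id = ?",
                   params = list(leftover_note, job_id))
    for (tid in task_ids) report_syslog(ctx, tid, leftover_note)
  }
  as.integer(task_ids)
}

# --- task execution --------------------------------------------------------

#' Lease the tasks that are ready for execution
#'
#' Pull-based hand-off to the compute layer: each ready task is returned
#' exactly once across concurrent pollers — a returned task carries a lease
#' and is not offered again until the lease expires without progress.
#'
#' @param ctx An engine context.
#' @param workflow_id Restrict to one workflow (`NULL` for all).
#' @param worker Identifier of the polling worker.
#' @param lease_seconds Lease duration.
#' @return Integer vector of leased task ids.
#' @export
poll_ready_tasks <- function(ctx, workflow_id = NULL, worker = "worker-1",
                             lease_seconds = NULL) {
  lease_seconds <- lease_seconds %||% ctx$options$lease_seconds
  now <- ctx$clock()
  sql <- "SELECT id FROM tasks WHERE status = 'ready'
          AND (lease_until IS NULL OR lease_until < ?)"
  params <- list(now)
  if (!is.null(workflow_id)) {
    sql <- paste(sql, "AND workflow_id = ?")
    params <- c(params, list(workflow_id))
  }
  ids <- DBI::dbGetQuery(ctx$con, paste(sql, "ORDER BY id"), params = params)$id
  for (id in ids)
    DBI::dbExecute(ctx$con,
      "UPDATE tasks SET lease_owner = ?, lease_until = ? WHERE id = ?",
      params = list(worker, now + lease_seconds, id))
  as.integer(ids)
}

task_scratch <- function(ctx, t)
  file.path(ctx$work_root, sprintf("wf%d", t$workflow_id), sprintf("t%d", t$id))

set_task_stage <- function(ctx, task_id, stage)
  DBI::dbExecute(ctx$con, "UPDATE tasks SET stage = ? WHERE id = ?",
                 params = list(stage, task_id))

#' Run one leased task through its lifecycle
#'
#' Executes the remaining lifecycle stages of the task: create the scratch
#' area and stage in every input; submit the rendered command to the tool's
#' compute backend (working directory = scratch) and monitor it; on exit 0
#' stage the declared outputs (and captured stdout/stderr) out to the tool's
#' output location and remove the scratch area; on a nonzero exit mark the
#' task `error`, keep the scratch area for diagnosis and record the captured
#' stderr in the syslog. A transient fault at any stage (missing credential,
#' unreachable backend, backend losing the task more than `retry_max` times)
#' parks the task in `blocked`; resuming restarts the last incomplete stage —
#' never a completed one, so a command is executed exactly once per completed
#' attempt.
#'
#' @param ctx An engine context.
#' @param task_id A task id returned by [poll_ready_tasks()].
#' @return The resulting task status: `"complete"`, `"error"` or `"blocked"`.
#' @export
run_task <- function(ctx, task_id) {
  t <- task_row(ctx, task_id)
  if (t$status %in% c("complete", "error")) return(t$status)
  wf <- wf_row(ctx, t$workflow_id)
  j <- job_row(ctx, t$job_id)
  tool <- from_json(j$tool_json)
  scratch <- task_scratch(ctx, t)
  stage <- t$stage
  # a restored root may lack the scratch area; restart from stage-in
  if (stage != "stage_in" && !dir.exists(file.path(scratch, "in")))
    stage <- "stage_in"

  for (s in TASK_STAGES[match(stage, TASK_STAGES):length(TASK_STAGES)]) {
    checkpoint(ctx, sprintf("task %d %s", task_id, s))
    out <- tryCatch(
      switch(s,
        stage_in  = task_stage_in(ctx, task_id, wf, tool, scratch),
        exec      = task_exec(ctx, task_id, wf, tool, scratch),
        stage_out = task_stage_out(ctx, task_id, wf, tool, scratch),
        finalize  = task_finalize(ctx, task_id, scratch)),
      fb_blocked = function(e) {
        report_status(ctx, task_id, "blocked", reason = conditionMessage(e))
        DBI::dbExecute(ctx$con,
          "UPDATE tasks SET attempt = 0, lease_owner = NULL,
                            lease_until = NULL WHERE id = ?",
          params = list(task_id))
        "blocked"
      })
    if (identical(out, "blocked") || identical(out, "error")) return(out)
  }
  "complete"
}

task_stage_in <- function(ctx, task_id, wf, tool, scratch) {
  report_status(ctx, task_id, "staging_in")
  t <- task_row(ctx, task_id)
  dir.create(file.path(scratch, "in"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(scratch, "log"), showWarnings = FALSE)
  pairs <- from_json(t$stage_in) %||% list()
  for (p in pairs) {
    src <- uri_parse(p$src)
    sbe <- storage_gate(ctx$sm, src, ctx$vault, wf$user)
    pump_copy(sbe, src$path, ctx$localfs, file.path(scratch, "in", p$name),
              ctx$options$chunk_size, ctx$options$chunk_ceiling)
  }
  report_syslog(ctx, task_id, sprintf("staged in %d file(s)", length(pairs)))
  set_task_stage(ctx, task_id, "exec")
  NULL
}

task_exec <- function(ctx, task_id, wf, tool, scratch) {
  report_status(ctx, task_id, "running")
  t <- task_row(ctx, task_id)
  be <- ctx$cm$instances[[tool$exec_backend]]
  if (is.null(be))
    stop_config(sprintf("compute backend '%s' not registered", tool$exec_backend))
  cmd <- unlist(from_json(t$command))
  job <- list(command = cmd, wd = scratch,
              env = c(FB_NONCE_LEDGER = ctx$options$nonce_ledger,
                      FB_TASK_ID = as.character(task_id)),
              stdout_path = file.path(scratch, "log", "stdout.txt"),
              stderr_path = file.path(scratch, "log", "stderr.txt"),
              task_id = as.character(task_id))
  attempt <- t$attempt
  repeat {
    attempt <- attempt + 1L
    DBI::dbExecute(ctx$con, "UPDATE tasks SET attempt = ? WHERE id = ?",
                   params = list(attempt, task_id))
    handle <- be$submit(job)   # fb_blocked propagates to run_task()
    res <- be$poll(handle)
    while (res$state %in% c("queued", "running")) {
      ctx$sleep(ctx$options$poll_interval)
      res <- be$poll(handle)
    }
    if (res$state == "lost") {
      report_syslog(ctx, task_id,
        sprintf("backend '%s' lost the task (attempt %d)", tool$exec_backend,
                attempt))
      if (attempt > ctx$options$retry_max)
        signal_blocked(sprintf(
          "backend '%s' lost the task %d time(s); giving up until resumed",
          tool$exec_backend, attempt))
      ctx$sleep(ctx$options$backoff_base * 2^(attempt - 1L))
      next
    }
    DBI::dbExecute(ctx$con,
      "UPDATE tasks SET exit_code = ?, stdout_ref = ?, stderr_ref = ? WHERE id = ?",
      params = list(res$exit_code,
                    format(uri("file", "", file.path(scratch, "log", "stdout.txt"))),
                    format(uri("file", "", file.path(scratch, "log", "stderr.txt"))),
                    task_id))
    report_syslog(ctx, task_id,
                  sprintf("command exited with code %d", res$exit_code))
    if (res$exit_code != 0L) {
      errf <- file.path(scratch, "log", "stderr.txt")
      if (file.exists(errf)) {
        tail_lines <- utils::tail(readLines(errf, warn = FALSE), 5L)
        if (length(tail_lines))
          report_syslog(ctx, task_id,
                        paste("stderr:", paste(tail_lines, collapse = " | ")))
      }
      report_syslog(ctx, task_id,
                    sprintf("scratch preserved for diagnosis: %s", scratch))
      report_status(ctx, task_id, "error",
                    reason = sprintf("exit code %d", res$exit_code))
      return("error")
    }
    set_task_stage(ctx, task_id, "stage_out")
    return(NULL)
  }
}

task_stage_out <- function(ctx, task_id, wf, tool, scratch) {
  report_status(ctx, task_id, "staging_out")
  t <- task_row(ctx, task_id)
  dst <- uri_parse(from_json(t$stage_out)$dst)
  dbe <- storage_gate(ctx$sm, dst, ctx$vault, wf$user)
  dbe$mkdir(dst$path)
  files <- sort(setdiff(list.files(scratch), c("in", "log")))
  files <- files[file.exists(file.path(scratch, files)) &
                 !dir.exists(file.path(scratch, files))]
  produced <- files[vapply(files, matches_any, logical(1),
                           patterns = tool$produces)]
  outputs <- list()
  for (f in produced) {
    rep <- pump_copy(ctx$localfs, file.path(scratch, f),
                     dbe, file.path(dst$path, f),
                     ctx$options$chunk_size, ctx$options$chunk_ceiling)
    outputs[[length(outputs) + 1L]] <- list(
      name = f, uri = format(uri_join(dst, f)),
      sha256 = rep$sha256, bytes = rep$bytes)
  }
  # captured streams are kept alongside the results
  dbe$mkdir(file.path(dst$path, "logs"))
  refs <- list(stdout = "stdout.txt", stderr = "stderr.txt")
  for (nm in names(refs)) {
    lf <- file.path(scratch, "log", refs[[nm]])
    if (!file.exists(lf)) next
    dp <- file.path(dst$path, "logs", sprintf("t%d.%s", task_id, nm))
    pump_copy(ctx$localfs, lf, dbe, dp,
              ctx$options$chunk_size, ctx$options$chunk_ceiling)
    DBI::dbExecute(ctx$con,
      sprintf("UPDATE tasks SET %s_ref = ? WHERE id = ?", nm),
      params = list(format(uri(dst$scheme, dst$host, dp, dst$user)), task_id))
  }
  DBI::dbExecute(ctx$con, "UPDATE tasks SET outputs = ? WHERE id = ?",
                 params = list(to_json(outputs), task_id))
  report_syslog(ctx, task_id,
                sprintf("staged out %d output file(s) to %s", length(outputs),
                        format(dst)))
  set_task_stage(ctx, task_id, "finalize")
  NULL
}

task_finalize <- function(ctx, task_id, scratch) {
  unlink(scratch, recursive = TRUE)
  report_syslog(ctx, task_id, "scratch area cleaned up")
  report_status(ctx, task_id, "complete")
  NULL
}

# --- folding and driving ---------------------------------------------------

fold_jobs <- function(ctx, workflow_id) {
  jobs <- DBI::dbGetQuery(ctx$con,
    "SELECT id, status FROM jobs WHERE workflow_id = ?", params = list(workflow_id))
  for (i in seq_len(nrow(jobs))) {
    if (!jobs$status[i] %in% c("running")) next
    tt <- DBI::dbGetQuery(ctx$con,
      "SELECT id, status, outputs FROM tasks WHERE job_id = ?",
      params = list(jobs$id[i]))
    if (nrow(tt) == 0L) next
    if (any(tt$status == "error")) {
      job_set_status(ctx, jobs$id[i], "error", reason = "task failed")
    } else if (any(tt$status == "blocked")) {
      blocked_reason <- db_row(ctx$con,
        "SELECT reason FROM tasks WHERE job_id = ? AND status='blocked' LIMIT 1",
        jobs$id[i])$reason
      job_set_status(ctx, jobs$id[i], "blocked", reason = blocked_reason)
    } else if (all(tt$status == "complete")) {
      outs <- do.call(c, lapply(tt$outputs, function(o) from_json(o) %||% list()))
      DBI::dbExecute(ctx$con, "UPDATE jobs SET outputs = ? WHERE id = ?",
                     params = list(to_json(outs %||% list()), jobs$id[i]))
      job_set_status(ctx, jobs$id[i], "complete")
    }
  }
}

fold_workflow <- function(ctx, workflow_id) {
  st <- DBI::dbGetQuery(ctx$con,
    "SELECT status FROM jobs WHERE workflow_id = ?", params = list(workflow_id))$status
  wf <- wf_row(ctx, workflow_id)
  new <- if (all(st == "complete")) "complete"
    else if (all(st %in% c("complete", "error"))) "error"
    else if (any(st == "blocked")) "blocked"
    else if (any(st != "pending")) "running"
    else wf$status
  if (!identical(new, wf$status)) {
    fin <- if (new %in% c("complete", "error")) ctx$clock() else NA_real_
    DBI::dbExecute(ctx$con,
      "UPDATE workflows SET status = ?, finished_at = ? WHERE id = ?",
      params = list(new, fin, workflow_id))
  }
  new
}

#' Advance a workflow by one scheduling round
#'
#' One round: resume anything blocked (back to its prior state), resolve
#' newly ready jobs, expand them into tasks, lease and run every ready task,
#' then fold task statuses into job statuses and job statuses into the
#' workflow status. Advancing a terminal workflow is a no-op.
#'
#' @param ctx An engine context.
#' @param workflow_id Workflow id.
#' @return The workflow status after the round.
#' @export
advance <- function(ctx, workflow_id) {
  wf <- wf_row(ctx, workflow_id)
  if (wf$status %in% c("complete", "error")) return(wf$status)
  checkpoint(ctx, sprintf("advance wf %d", workflow_id))

  # resume blocked work
  bt <- DBI::dbGetQuery(ctx$con,
    "SELECT id, blocked_from FROM tasks WHERE workflow_id = ? AND status = 'blocked'",
    params = list(workflow_id))
  for (i in seq_len(nrow(bt))) {
    report_status(ctx, bt$id[i], "ready")
    DBI::dbExecute(ctx$con,
      "UPDATE tasks SET lease_owner = NULL, lease_until = NULL WHERE id = ?",
      params = list(bt$id[i]))
  }
  bj <- DBI::dbGetQuery(ctx$con,
    "SELECT id, blocked_from FROM jobs WHERE workflow_id = ? AND status = 'blocked'",
    params = list(workflow_id))
  for (i in seq_len(nrow(bj)))
    job_set_status(ctx, bj$id[i],
                   if (identical(bj$blocked_from[i], "running")) "running" else "pending")

  for (jid in resolve_ready_jobs(ctx, workflow_id)) {
    tryCatch(generate_tasks(ctx, jid),
             fb_blocked = function(e)
               job_set_status(ctx, jid, "blocked", reason = conditionMessage(e)))
  }
  repeat {
    ids <- poll_ready_tasks(ctx, workflow_id)
    if (!length(ids)) break
    for (id in ids) run_task(ctx, id)
  }
  fold_jobs(ctx, workflow_id)
  fold_workflow(ctx, workflow_id)
}

#' Drive a workflow until it is terminal or stalled
#'
#' Repeats [advance()] until the workflow reaches `complete` or `error`, or
#' until a round changes nothing (which happens when the only remaining work
#' is blocked on a fault that has not been cleared — fix the fault, e.g.
#' [vault_unlock()] or [engine_set_reachable()], and call `drive()` again).
#'
#' @param ctx An engine context.
#' @param workflow_id Workflow id.
#' @param max_rounds Safety bound on scheduling rounds.
#' @return The final workflow status.
#' @export
drive <- function(ctx, workflow_id, max_rounds = 10000L) {
  fingerprint <- function() {
    paste(c(
      DBI::dbGetQuery(ctx$con,
        "SELECT status FROM jobs WHERE workflow_id = ? ORDER BY id",
        params = list(workflow_id))$status,
      DBI::dbGetQuery(ctx$con,
        "SELECT status || stage FROM tasks WHERE workflow_id = ? ORDER BY id",
        params = list(workflow_id))[[1]]),
      collapse = "|")
  }
  prev <- NULL
  for (i in seq_len(max_rounds)) {
    st <- advance(ctx, workflow_id)
    if (st %in% c("complete", "error")) return(st)
    cur <- fingerprint()
    if (identical(cur, prev)) return(st)
    prev <- cur
  }
  workflow_status(ctx, workflow_id)
}
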