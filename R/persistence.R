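#' Durable engine state
#'
#' All workflow/job/task state, the syslog, credentials (ciphertext only) and
#' the registry-as-run live in a single-file embedded SQLite database under
#' the engine root. Every state transition is written before it is
#' acknowledged, which is what gives the engine its write-ahead submission
#' guarantee and crash-safe resume: reopening the root restores the exact
#' persisted state, stale leases are released, and interrupted tasks restart
#' from their last incomplete lifecycle stage. Result payloads never live in
#' the store — only URIs and checksums are recorded.
#'
#' @name persistence
#' @keywords internal
NULL

FB_SCHEMA_VERSION <- 1L

store_open <- function(path) {
  con <- suppressWarnings(DBI::dbConnect(RSQLite::SQLite(), path))
  tryCatch({
    DBI::dbExecute(con, "PRAGMA journal_mode=WAL")
    DBI::dbExecute(con, "PRAGMA synchronous=NORMAL")
  }, error = function(e) {
    try(DBI::dbDisconnect(con), silent = TRUE)
    stop_state(sprintf("state store unreadable: %s", conditionMessage(e)))
  })
  con
}

store_init <- function(con) {
  has_meta <- tryCatch("meta" %in% DBI::dbListTables(con), error = function(e) {
    stop_state(sprintf("state store unreadable: %s", conditionMessage(e)))
  })
  if (has_meta) {
    ver <- tryCatch(
      DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key='schema_version'")$value,
      error = function(e) stop_state(sprintf("state store unreadable: %s",
                                             conditionMessage(e))))
    if (!length(ver) || !identical(as.integer(ver), FB_SCHEMA_VERSION))
      stop_state(sprintf(
        "state store schema version %s does not match supported version %d",
        if (length(ver)) ver else "<missing>", FB_SCHEMA_VERSION))
    return(invisible(con))
  }
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', ?)",
                 params = list(as.character(FB_SCHEMA_VERSION)))
  DBI::dbExecute(con, "CREATE TABLE registry_doc (doc TEXT)")
  DBI::dbExecute(con, "CREATE TABLE workflows (
      id INTEGER PRIMARY KEY AUTOINCREMENT,
      name TEXT, user TEXT, status TEXT,
      created_at REAL, finished_at REAL,
      metadata TEXT, request TEXT)")
  DBI::dbExecute(con, "CREATE TABLE jobs (
      id INTEGER PRIMARY KEY AUTOINCREMENT,
      workflow_id INTEGER, idx INTEGER, tool TEXT, status TEXT,
      blocked_from TEXT, reason TEXT,
      args TEXT, tool_json TEXT, bound_args TEXT, outputs TEXT)")
  DBI::dbExecute(con, "CREATE TABLE tasks (
      id INTEGER PRIMARY KEY AUTOINCREMENT,
      job_id INTEGER, workflow_id INTEGER,
      status TEXT, blocked_from TEXT, stage TEXT,
      attempt INTEGER DEFAULT 0,
      command TEXT, stage_in TEXT, stage_out TEXT, outputs TEXT,
      exit_code INTEGER, reason TEXT,
      stdout_ref TEXT, stderr_ref TEXT,
      lease_owner TEXT, lease_until REAL)")
  DBI::dbExecute(con, "CREATE TABLE syslog (
      id INTEGER PRIMARY KEY AUTOINCREMENT,
      task_id INTEGER, ts REAL, message TEXT)")
  ensure_cred_table(con)
  invisible(con)
}

to_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                digits = NA))
}
from_json <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(NULL)
  jsonlite::fromJSON(x, simplifyVector = FALSE)
}

db_row <- function(con, sql, ...) {
  df <- DBI::dbGetQuery(con, sql, params = list(...))
  if (nrow(df) == 0L) NULL else as.list(df[1, , drop = FALSE])
}

#' Snapshot the engine state to a file
#'
#' Flushes the write-ahead log and copies the state database to `path`. The
#' snapshot is a complete, restorable record of all workflows, jobs, tasks,
#' leases and stage markers; it contains no plaintext credentials (the RAM
#' cache is never serialised).
#'
#' @param ctx An engine context from [engine_open()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
engine_snapshot <- function(ctx, path) {
  DBI::dbExecute(ctx$con, "PRAGMA wal_checkpoint(TRUNCATE)")
  if (!file.copy(ctx$db_path, path, overwrite = TRUE))
    stop_state(sprintf("could not write snapshot to %s", path))
  invisible(path)
}

#' Restore an engine from a snapshot
#'
#' Installs the snapshot as the state database of `root` and opens the
#' engine there. Stale leases are released and interrupted tasks resume from
#' their last incomplete lifecycle stage on the next [advance()].
#'
#' @param snapshot Path to a snapshot file from [engine_snapshot()].
#' @param root Engine root directory to restore into.
#' @param ... Passed to [engine_open()].
#' @return An engine context.
#' @export
engine_restore <- function(snapshot, root, ...) {
  if (!file.exists(snapshot))
    stop_notfound(sprintf("no such snapshot: %s", snapshot))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  file.copy(snapshot, file.path(root, "store.sqlite"), overwrite = TRUE)
  engine_open(root, ...)
}

#' Search stored workflows
#'
#' Filters are conjunctive; omitted filters match everything. Summaries are
#' returned newest first.
#'
#' @param ctx An engine context.
#' @param name Exact workflow name.
#' @param created_from,created_to Numeric epoch-seconds bounds on submission
#'   time (inclusive).
#' @param metadata Named list; workflows must carry every given key with the
#'   given value.
#' @return Data frame with columns `id`, `name`, `user`, `status`,
#'   `created_at`, `finished_at`.
#' @export
query_workflows <- function(ctx, name = NULL, created_from = NULL,
                            created_to = NULL, metadata = NULL) {
  df <- DBI::dbGetQuery(ctx$con,
    "SELECT id, name, user, status, created_at, finished_at, metadata
     FROM workflows ORDER BY id DESC")
  keep <- rep(TRUE, nrow(df))
  if (!is.null(name)) keep <- keep & df$name == name
  if (!is.null(created_from)) keep <- keep & df$created_at >= created_from
  if (!is.null(created_to)) keep <- keep & df$created_at <= created_to
  if (!is.null(metadata)) {
    keep <- keep & vapply(df$metadata, function(m) {
      md <- from_json(m)
      all(vapply(names(metadata), function(k)
        identical(md[[k]], metadata[[k]]), logical(1)))
    }, logical(1))
  }
  out <- df[keep, c("id", "name", "user", "status", "created_at",
                    "finished_at"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full provenance record of a workflow
#'
#' Everything needed to audit or identically re-run the workflow: the
#' original request, and for each job the tool spec as-run (captured from the
#' registry at expansion time), the bound parameter values, the input file
#' URIs, every rendered task command, and the output URIs with their
#' checksums. A record of a non-terminal workflow is flagged `final = FALSE`.
#'
#' @param ctx An engine context.
#' @param workflow_id Workflow id.
#' @return A nested list; see Details.
#' @export
provenance <- function(ctx, workflow_id) {
  wf <- db_row(ctx$con, "SELECT * FROM workflows WHERE id = ?", workflow_id)
  if (is.null(wf)) stop_notfound(sprintf("unknown workflow %s", workflow_id))
  jobs <- DBI::dbGetQuery(ctx$con,
    "SELECT * FROM jobs WHERE workflow_id = ? ORDER BY idx", params = list(workflow_id))
  tasks <- DBI::dbGetQuery(ctx$con,
    "SELECT * FROM tasks WHERE workflow_id = ? ORDER BY id", params = list(workflow_id))
  job_recs <- lapply(seq_len(nrow(jobs)), function(i) {
    j <- as.list(jobs[i, ])
    jt <- tasks[tasks$job_id == j$id, , drop = FALSE]
    task_recs <- lapply(seq_len(nrow(jt)), function(k) {
      t <- as.list(jt[k, ])
      cmd <- unlist(from_json(t$command))
      list(task_id = t$id, status = t$status,
           command = cmd,
           command_string = paste(cmd, collapse = " "),
           stage_in = vapply(from_json(t$stage_in) %||% list(),
                             function(p) p$src, ""),
           exit_code = t$exit_code,
           outputs = from_json(t$outputs) %||% list(),
           attempt = t$attempt)
    })
    list(index = j$idx, tool = j$tool, status = j$status,
         tool_as_run = from_json(j$tool_json),
         bound_args = from_json(j$bound_args),
         input_uris = unique(unlist(lapply(task_recs, `[[`, "stage_in"))),
         outputs = from_json(j$outputs) %||% list(),
         tasks = task_recs)
  })
  list(workflow = list(id = wf$id, name = wf$name, user = wf$user,
                       status = wf$status, created_at = wf$created_at,
                       finished_at = wf$finished_at,
                       metadata = from_json(wf$metadata)),
       final = wf$status %in% c("complete", "error"),
       request = from_json(wf$request),
       jobs = job_recs)
}

#' Resubmit a workflow from its provenance
#'
#' Submits a fresh workflow built from the stored original request; with
#' deterministic tools the rerun reproduces the original outputs.
#'
#' @param ctx An engine context.
#' @param workflow_id The workflow to reuse.
#' @return The new workflow id.
#' @export
resubmit <- function(ctx, workflow_id) {
  wf <- db_row(ctx$con, "SELECT request FROM workflows WHERE id = ?", workflow_id)
  if (is.null(wf)) stop_notfound(sprintf("unknown workflow %s", workflow_id))
  submit_workflow(ctx, from_json(wf$request))
}
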