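dump_state <- function(ctx) {
  lapply(c("workflows", "jobs", "tasks", "syslog"), function(tb)
    DBI::dbGetQuery(ctx$con, paste("SELECT * FROM", tb, "ORDER BY id")))
}

linear_request <- function(n = 3L, input = "mem://data/in/seq01.fa",
                           name = "run-A") {
  jobs <- list(list(tool = "pick", args = list(infile = input)))
  for (i in seq_len(n - 1L))
    jobs[[i + 1L]] <- list(tool = if (i %% 2) "mask" else "predict",
                           args = list(infile = list(from_job = i - 1L)))
  list(name = name, user = "alice", metadata = list(project = "x"),
       jobs = jobs)
}

test_that("an acknowledged submission survives an immediate crash", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  id <- submit_workflow(fx$ctx, linear_request())
  # crash: abandon the context without any advance
  engine_close(fx$ctx)

  ctx2 <- engine_open(fx$root)
  withr::defer(engine_close(ctx2))
  expect_equal(workflow_status(ctx2, id), "pending")
  expect_equal(nrow(job_table(ctx2, id)), 3L)
  expect_true(all(job_table(ctx2, id)$status == "pending"))
})

test_that("snapshot of an idle engine restores to deep equality", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  submit_workflow(fx$ctx, linear_request(name = "idle"))
  before <- dump_state(fx$ctx)
  snap <- file.path(fx$base, "snap.sqlite")
  engine_snapshot(fx$ctx, snap)

  ctx2 <- engine_restore(snap, file.path(fx$base, "restored"))
  withr::defer(engine_close(ctx2))
  expect_identical(dump_state(ctx2), before)
})

test_that("a truncated snapshot refuses to load, with no partial state", {
  fx <- local_toolkit_engine()
  snap <- file.path(fx$base, "snap.sqlite")
  engine_snapshot(fx$ctx, snap)
  writeBin(readBin(snap, "raw", 100), snap)
  expect_error(engine_restore(snap, file.path(fx$base, "r2")),
               class = "fb_state_error")
})

test_that("killing mid-run resumes without re-executing completed work", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  id <- submit_workflow(fx$ctx, linear_request(3L))

  # run until job 1 is complete, then crash at the next lifecycle checkpoint
  jt <- job_table(fx$ctx, id)
  generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
  for (t in poll_ready_tasks(fx$ctx, id)) run_task(fx$ctx, t)
  flowbench:::fold_jobs(fx$ctx, id)
  expect_equal(job_table(fx$ctx, id)$status[1], "complete")

  fx$ctx$crash_after <- 3L
  crashed <- tryCatch({ drive(fx$ctx, id); FALSE },
                      fb_crash = function(e) TRUE)
  expect_true(crashed)
  engine_close(fx$ctx)

  ctx2 <- engine_open(fx$root)
  withr::defer(engine_close(ctx2))
  expect_equal(drive(ctx2, id), "complete")

  led <- nonce_ledger(ctx2)
  tt <- task_table(ctx2, id)
  # every completed task's command ran exactly once
  for (tid in tt$id[tt$status == "complete"])
    expect_equal(sum(led$task_id == as.character(tid)), 1L)
})

test_that("kill-at-random-point fuzz reproduces the uninterrupted outputs", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 2)

  baseline_id <- submit_workflow(fx$ctx, linear_request(5L, name = "base"))
  expect_equal(drive(fx$ctx, baseline_id), "complete")
  baseline <- output_digests(fx$ctx, baseline_id)$sha256

  set.seed(101)
  for (trial in 1:8) {
    root <- file.path(fx$base, sprintf("fuzz%02d", trial))
    ctx <- engine_open(root, registry = fx$reg)
    fixture_dataset(ctx, "mem://data/in", seed = 7, n_files = 2)
    id <- submit_workflow(ctx, linear_request(5L, name = "fuzz"))
    ctx$crash_after <- sample(1:25, 1)
    st <- tryCatch(drive(ctx, id), fb_crash = function(e) "crashed")
    engine_close(ctx)

    ctx2 <- engine_open(root)
    # the in-memory data backend died with the process; re-seed it
    fixture_dataset(ctx2, "mem://data/in", seed = 7, n_files = 2)
    expect_equal(drive(ctx2, id), "complete")
    expect_equal(output_digests(ctx2, id)$sha256, baseline)
    led <- nonce_ledger(ctx2)
    tt <- task_table(ctx2, id)
    for (tid in tt$id[tt$status == "complete"])
      expect_equal(sum(led$task_id == as.character(tid)), 1L)
    engine_close(ctx2)
  }
})

test_that("workflows are searchable by name, date and metadata", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  t0 <- 1000
  fx$ctx$clock <- function() t0
  ida <- submit_workflow(fx$ctx, list(name = "run-A", user = "alice",
    metadata = list(project = "x", lab = "north"),
    jobs = list(list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")))))
  t0 <- 2000
  idb <- submit_workflow(fx$ctx, list(name = "run-B", user = "alice",
    metadata = list(project = "y"),
    jobs = list(list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")))))

  expect_equal(query_workflows(fx$ctx, name = "run-A")$id, ida)
  expect_equal(query_workflows(fx$ctx, metadata = list(project = "y"))$id, idb)
  expect_equal(query_workflows(fx$ctx,
                               metadata = list(project = "x", lab = "north"))$id,
               ida)
  expect_equal(query_workflows(fx$ctx, created_from = 1500)$id, idb)
  expect_equal(query_workflows(fx$ctx, created_to = 1500)$id, ida)
  # empty filter: all, newest first
  expect_equal(query_workflows(fx$ctx)$id, c(idb, ida))
  # conjunction that excludes everything
  expect_equal(nrow(query_workflows(fx$ctx, name = "run-A",
                                    created_from = 1500)), 0L)
})

test_that("provenance is complete and supports identical resubmission", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  id <- submit_workflow(fx$ctx, linear_request(3L))
  expect_equal(drive(fx$ctx, id), "complete")

  prov <- provenance(fx$ctx, id)
  expect_true(prov$final)
  expect_length(prov$jobs, 3L)
  expect_equal(vapply(prov$jobs, `[[`, "", "tool"),
               c("pick", "mask", "predict"))
  # every task command string appears, with its bound args and input URIs
  for (j in prov$jobs) {
    expect_false(is.null(j$tool_as_run))
    expect_gt(length(j$bound_args), 0L)
    expect_gt(length(j$input_uris), 0L)
    for (t in j$tasks) {
      expect_gt(nchar(t$command_string), 0L)
      expect_false(grepl("\\{", t$command_string))  # no unresolved holes
    }
  }
  # machine check: the commands recorded in the store all appear in provenance
  all_cmds <- unlist(lapply(prov$jobs, function(j)
    vapply(j$tasks, `[[`, "", "command_string")))
  db_cmds <- vapply(task_table(fx$ctx, id)$command, function(c)
    paste(unlist(jsonlite::fromJSON(c)), collapse = " "), "")
  expect_setequal(unname(db_cmds), all_cmds)

  id2 <- resubmit(fx$ctx, id)
  expect_false(id2 == id)
  expect_equal(drive(fx$ctx, id2), "complete")
  expect_equal(output_digests(fx$ctx, id2)$sha256,
               output_digests(fx$ctx, id)$sha256)
})

test_that("provenance of a running workflow is flagged non-final", {
  fx <- local_toolkit_engine()
  fixture_dataset(fx$ctx, "mem://data/in", seed = 7, n_files = 1)
  id <- submit_workflow(fx$ctx, linear_request(3L))
  generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
  prov <- provenance(fx$ctx, id)
  expect_false(prov$final)
  expect_error(provenance(fx$ctx, 99999L), class = "fb_notfound_error")
})
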