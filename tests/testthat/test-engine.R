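setup_inputs <- function(ctx, n = 3L, seed = 7L, paired = FALSE) {
  fixture_dataset(ctx, "mem://data/in", seed = seed, n_files = n,
                  paired = paired)
}

test_that("submission is decoupled from processing and is write-ahead", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  wfs <- fixture_workflows("mem://data/in/seq01.fa", "mem://data/in")
  id <- submit_workflow(fx$ctx, wfs$linear)
  # accepted, persisted, but nothing has run yet
  expect_equal(workflow_status(fx$ctx, id), "pending")
  expect_equal(nrow(task_table(fx$ctx, id)), 0L)
  expect_true(all(job_table(fx$ctx, id)$status == "pending"))

  # duplicate submission is a distinct workflow (provenance keeps both)
  id2 <- submit_workflow(fx$ctx, wfs$linear)
  expect_false(id == id2)
})

test_that("invalid requests are rejected with per-job diagnostics, nothing persisted", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  before <- nrow(query_workflows(fx$ctx))
  req <- list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "nosuchtool", args = list())))
  err <- tryCatch(submit_workflow(fx$ctx, req), condition = function(e) e)
  expect_s3_class(err, "fb_validation_error")
  expect_match(conditionMessage(err), "job 1")
  expect_match(conditionMessage(err), "nosuchtool")
  expect_equal(nrow(query_workflows(fx$ctx)), before)

  # tool not granted names the offending job
  req2 <- list(user = "carol", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "mask", args = list(infile = list(from_job = 0L)))))
  err2 <- tryCatch(submit_workflow(fx$ctx, req2), condition = function(e) e)
  expect_match(conditionMessage(err2), "job 1.*mask.*not granted")

  # forward references are refused
  req3 <- list(user = "alice", jobs = list(
    list(tool = "mask", args = list(infile = list(from_job = 0L)))))
  expect_error(submit_workflow(fx$ctx, req3), "earlier job",
               class = "fb_validation_error")
})

test_that("jobs become ready only when parents finish and inputs exist", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  req <- list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "mask", args = list(infile = list(from_job = 0L))),
    list(tool = "predict", args = list(infile = list(from_job = 1L)))))
  id <- submit_workflow(fx$ctx, req)
  jt <- job_table(fx$ctx, id)

  expect_equal(resolve_ready_jobs(fx$ctx, id), jt$id[1])
  # not offered twice
  expect_length(resolve_ready_jobs(fx$ctx, id), 0L)
  generate_tasks(fx$ctx, jt$id[1])
  for (t in poll_ready_tasks(fx$ctx, id)) run_task(fx$ctx, t)
  flowbench:::fold_jobs(fx$ctx, id)
  expect_equal(resolve_ready_jobs(fx$ctx, id), jt$id[2])

  # two independent children of one parent become ready together
  req2 <- list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "mask", args = list(infile = list(from_job = 0L))),
    list(tool = "mask", args = list(infile = list(from_job = 0L)))))
  id2 <- submit_workflow(fx$ctx, req2)
  jt2 <- job_table(fx$ctx, id2)
  generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id2))
  for (t in poll_ready_tasks(fx$ctx, id2)) run_task(fx$ctx, t)
  flowbench:::fold_jobs(fx$ctx, id2)
  expect_equal(resolve_ready_jobs(fx$ctx, id2), jt2$id[2:3])
})

test_that("a missing input file blocks the job rather than failing it", {
  fx <- local_toolkit_engine()
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/ghost.fa")))))
  expect_length(resolve_ready_jobs(fx$ctx, id), 0L)
  jt <- job_table(fx$ctx, id)
  expect_equal(jt$status, "blocked")
  expect_match(jt$reason, "missing")

  # providing the file and re-driving completes the workflow
  setup_inputs(fx$ctx, 1)
  st_copy(fx$ctx$sm, "mem://data/in/seq01.fa", "mem://data/in/ghost.fa")
  expect_equal(drive(fx$ctx, id), "complete")
})

test_that("batch fan-out creates one task per matching file", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 14)
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in")),
    list(tool = "orfs", args = list(infile = list(from_job = 0L))))))
  jt <- job_table(fx$ctx, id)
  generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
  expect_equal(nrow(task_table(fx$ctx, id)), 1L)  # pick: one task, 14 files
  for (t in poll_ready_tasks(fx$ctx, id)) run_task(fx$ctx, t)
  flowbench:::fold_jobs(fx$ctx, id)
  tids <- generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
  expect_length(tids, 14L)   # one execution unit per sequence file
})

test_that("batch cardinality equals the match count for randomised file sets", {
  fx <- local_toolkit_engine()
  set.seed(31)
  for (n in sample(1:9, 3)) {
    dirname <- sprintf("mem://data/rand%d", n)
    st_mkdir(fx$ctx$sm, dirname)
    n_fa <- 0L
    for (k in seq_len(n + sample(0:3, 1))) {
      # .log files match none of pick's accepted patterns
      is_fa <- runif(1) < 0.6 || n_fa == 0L
      nm <- sprintf("%s/f%02d.%s", dirname, k, if (is_fa) "fa" else "log")
      if (is_fa) n_fa <- n_fa + 1L
      st_write(fx$ctx$sm, nm, charToRaw(">r\nACGT\n"))
    }
    id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
      list(tool = "pick", args = list(infile = dirname)),
      list(tool = "orfs", args = list(infile = list(from_job = 0L,
                                                    pattern = "*.pick.fa"))))))
    generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
    for (t in poll_ready_tasks(fx$ctx, id)) run_task(fx$ctx, t)
    flowbench:::fold_jobs(fx$ctx, id)
    tids <- generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
    # pick only copies *.fa inputs, so fan-out equals the .fa count
    expect_length(tids, n_fa)
  }
})

test_that("two batchable parameters pair by minimum edit distance", {
  fx <- local_toolkit_engine()
  st_mkdir(fx$ctx$sm, "mem://data/paired")
  for (s in c("s1", "s2", "s3")) {
    st_write(fx$ctx$sm, sprintf("mem://data/paired/%s.fa", s),
             charToRaw(sprintf(">%s\nACGT\n", s)))
    st_write(fx$ctx$sm, sprintf("mem://data/paired/%s.qual", s),
             charToRaw(sprintf(">%s\n30\n", s)))
  }
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "combine", args = list(a = "mem://data/paired",
                                       b = "mem://data/paired")))))
  tids <- generate_tasks(fx$ctx, resolve_ready_jobs(fx$ctx, id))
  expect_length(tids, 3L)
  tt <- task_table(fx$ctx, id)
  cmds <- lapply(tt$command, function(c) unlist(jsonlite::fromJSON(c)))
  for (cmd in cmds) {
    a <- basename(cmd[which(cmd == "-a") + 1L])
    b <- basename(cmd[which(cmd == "-b") + 1L])
    expect_equal(sub("\\.fa$", "", a), sub("\\.qual$", "", b))
  }
  expect_equal(drive(fx$ctx, id), "complete")
})

test_that("zero matching files is a job error, not an empty fan-out", {
  fx <- local_toolkit_engine()
  st_mkdir(fx$ctx$sm, "mem://data/none")
  st_write(fx$ctx$sm, "mem://data/none/notes.txt", charToRaw(">r\nACGT\n"))
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/none")),
    list(tool = "orfs", args = list(infile = list(from_job = 0L,
                                                  pattern = "*.none"))))))
  # the override pattern matches none of pick's outputs
  expect_equal(drive(fx$ctx, id), "error")
  jt <- job_table(fx$ctx, id)
  expect_equal(jt$status[2], "error")
  expect_match(jt$reason[2], "no input satisfies pattern")
})

test_that("commands render as discrete tokens in declared parameter order", {
  reg <- load_registry(list(schema_version = 1,
    backends = list(list(id = "l", kind = "compute", scheme = "localexec",
                         endpoint = "")),
    tools = list(list(
      name = "wc", program = "wc", exec_backend = "l",
      params = list(
        list(name = "mode", switch = "-m", mandatory = FALSE),
        list(name = "infile", switch = "-i", mandatory = TRUE,
             accepts = list("*.txt"), source_kind = "input-file")),
      produces = list("*.out"))),
    users = list()))
  tool <- reg$tools$wc

  expect_equal(render_command(tool, list(infile = "a.txt")),
               c("wc", "-i", "a.txt"))
  # optional unbound: omitted entirely, no dangling switch
  expect_false("-m" %in% render_command(tool, list(infile = "a.txt")))
  # values with spaces survive as single tokens (no shell)
  cmd <- render_command(tool, list(mode = "two words", infile = "a b.txt"))
  expect_equal(cmd, c("wc", "-m", "two words", "-i", "a b.txt"))
  # unbound mandatory names the parameter
  err <- tryCatch(render_command(tool, list(mode = "x")),
                  condition = function(e) e)
  expect_s3_class(err, "fb_render_error")
  expect_match(conditionMessage(err), "infile")
})

test_that("program templates substitute named placeholders", {
  reg <- load_registry(list(schema_version = 1,
    backends = list(list(id = "l", kind = "compute", scheme = "localexec",
                         endpoint = "")),
    tools = list(list(
      name = "conv", program = "conv {infile} --out {dest}",
      exec_backend = "l",
      params = list(
        list(name = "infile", mandatory = TRUE, accepts = list("*"),
             source_kind = "input-file"),
        list(name = "dest", mandatory = TRUE)),
      produces = list())),
    users = list()))
  expect_equal(render_command(reg$tools$conv,
                              list(infile = "x.fa", dest = "y.out")),
               c("conv", "x.fa", "--out", "y.out"))
})

test_that("advance is idempotent on terminal workflows", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")))))
  expect_equal(drive(fx$ctx, id), "complete")
  snap1 <- list(job_table(fx$ctx, id), task_table(fx$ctx, id))
  expect_equal(advance(fx$ctx, id), "complete")
  expect_identical(list(job_table(fx$ctx, id), task_table(fx$ctx, id)), snap1)
})

test_that("a failed job fails the workflow but siblings still finish", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "fail42", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "pick", args = list(infile = "mem://data/in/seq01.fa")))))
  expect_equal(drive(fx$ctx, id), "error")
  jt <- job_table(fx$ctx, id)
  expect_equal(jt$status, c("error", "complete"))
})

test_that("dependents of a failed job are marked failed upstream", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  id <- submit_workflow(fx$ctx, list(user = "alice", jobs = list(
    list(tool = "fail42", args = list(infile = "mem://data/in/seq01.fa")),
    list(tool = "mask", args = list(infile = list(from_job = 0L))))))
  expect_equal(drive(fx$ctx, id), "error")
  jt <- job_table(fx$ctx, id)
  expect_equal(jt$status[2], "error")
  expect_match(jt$reason[2], "upstream")
})

test_that("task ordering respects dependencies across randomised workflows", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 1)
  set.seed(55)
  for (trial in 1:5) {
    req <- random_dag_request(5L, "mem://data/in/seq01.fa")
    id <- submit_workflow(fx$ctx, req)
    expect_equal(drive(fx$ctx, id), "complete")
    expect_equal(assert_dag_ordering(fx$ctx, id), 0L)
  }
})

test_that("the same workflow on the same inputs is byte-deterministic", {
  fx <- local_toolkit_engine()
  setup_inputs(fx$ctx, 3)
  wfs <- fixture_workflows("mem://data/in/seq01.fa", "mem://data/in")
  id1 <- submit_workflow(fx$ctx, wfs$batch)
  id2 <- submit_workflow(fx$ctx, wfs$batch)
  expect_equal(drive(fx$ctx, id1), "complete")
  expect_equal(drive(fx$ctx, id2), "complete")
  d1 <- output_digests(fx$ctx, id1)
  d2 <- output_digests(fx$ctx, id2)
  rownames(d1) <- rownames(d2) <- NULL
  expect_identical(d1, d2)
  expect_equal(nrow(task_table(fx$ctx, id1)), nrow(task_table(fx$ctx, id2)))
})
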