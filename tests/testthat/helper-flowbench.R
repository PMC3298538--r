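# Shared scaffolding: a throwaway engine wired to the fixture toolkit, plus
# the independent brute-force oracles the operation tests compare against.

local_toolkit_engine <- function(env = parent.frame(),
                                 mockq_options = list(latency_polls = 1L),
                                 options = list()) {
  base <- withr::local_tempdir(.local_envir = env)
  reg <- fixture_toolkit(file.path(base, "kit"), mockq_options = mockq_options)
  ctx <- engine_open(file.path(base, "root"), registry = reg, options = options)
  withr::defer(engine_close(ctx), envir = env)
  list(ctx = ctx, reg = reg, base = base,
       kit = file.path(base, "kit"), root = file.path(base, "root"))
}

# digests of every staged-out output, for byte-identity comparisons
output_digests <- function(ctx, workflow_id) {
  prov <- provenance(ctx, workflow_id)
  rows <- do.call(rbind, lapply(prov$jobs, function(j) {
    if (length(j$outputs) == 0L) return(NULL)
    data.frame(job = j$index,
               name = vapply(j$outputs, `[[`, "", "name"),
               sha256 = vapply(j$outputs, `[[`, "", "sha256"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(data.frame(job = integer(0), name = character(0),
                                       sha256 = character(0)))
  rows[order(rows$job, rows$name), , drop = FALSE]
}

# naive exponential-time edit distance, the oracle for levenshtein()
lev_naive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0L else 1L
  min(lev_naive(substr(a, 2, nchar(a)), b) + 1L,
      lev_naive(a, substr(b, 2, nchar(b))) + 1L,
      lev_naive(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

# exhaustive minimum assignment cost over all injections of the smaller
# group into the larger, the oracle for pair_inputs()
pair_bruteforce_cost <- function(A, B) {
  swap <- length(A) > length(B)
  S <- if (swap) B else A
  L <- if (swap) A else B
  d <- outer(S, L, Vectorize(function(x, y) utils::adist(x, y)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_along(L))) {
    sel <- p[seq_along(S)]
    cost <- sum(d[cbind(seq_along(S), sel)])
    if (cost < best) best <- cost
  }
  best
}

# independent character-walking glob matcher (no regex), the oracle for
# glob_to_regex()/match_files()
glob_match_naive <- function(name, pattern) {
  n <- strsplit(name, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  rec <- function(i, j) {
    if (j > length(p)) return(i > length(n))
    ch <- p[j]
    if (ch == "*") {
      for (k in i:(length(n) + 1L)) if (rec(k, j + 1L)) return(TRUE)
      return(FALSE)
    }
    if (i > length(n)) return(FALSE)
    if (ch == "?") return(rec(i + 1L, j + 1L))
    if (ch == "[") {
      k <- j + 1L
      neg <- FALSE
      if (k <= length(p) && p[k] %in% c("!", "^")) { neg <- TRUE; k <- k + 1L }
      members <- character(0)
      first <- TRUE
      while (k <= length(p) && (p[k] != "]" || first)) {
        if (k + 2L <= length(p) && p[k + 1L] == "-" && p[k + 2L] != "]") {
          rng <- utf8ToInt(p[k]):utf8ToInt(p[k + 2L])
          members <- c(members, vapply(rng, intToUtf8, ""))
          k <- k + 3L
        } else {
          members <- c(members, p[k])
          k <- k + 1L
        }
        first <- FALSE
      }
      hit <- n[i] %in% members
      if (neg) hit <- !hit
      if (!hit) return(FALSE)
      return(rec(i + 1L, k + 1L))
    }
    if (ch == n[i]) return(rec(i + 1L, j + 1L))
    FALSE
  }
  rec(1L, 1L)
}

random_names <- function(n, len = c(3L, 10L),
                         alphabet = c(letters, LETTERS, 0:9, ".", "_", "-")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample(len[1]:len[2], 1L), replace = TRUE),
          collapse = ""), "")
}

# a random tree-or-DAG workflow over the fixture tools: job 0 picks the
# input file; later jobs reference one random earlier job (mask/predict) or
# two (merge, fan-in)
random_dag_request <- function(n_jobs = 5L, input_uri, user = "alice") {
  jobs <- list(list(tool = "pick", args = list(infile = input_uri)))
  for (i in seq_len(n_jobs - 1L)) {
    if (i >= 2L && stats::runif(1) < 0.3) {
      parents <- sample(0:(i - 1L), 2L)
      jobs[[i + 1L]] <- list(tool = "merge",
                             args = list(a = list(from_job = parents[1]),
                                         b = list(from_job = parents[2])))
    } else {
      jobs[[i + 1L]] <- list(tool = sample(c("mask", "predict"), 1L),
                             args = list(infile = list(
                               from_job = sample(0:(i - 1L), 1L))))
    }
  }
  list(name = sprintf("dag-%d", sample.int(1e6, 1L)), user = user, jobs = jobs)
}

# ordering check: no task of a job may start executing before every task of
# each referenced earlier job has *finished* executing. Task starts come
# from the execution nonce ledger (nanosecond wall clock stamped by the tool
# itself); parent finishes come from the engine syslog entry written when
# the command exits.
assert_dag_ordering <- function(ctx, workflow_id) {
  led <- nonce_ledger(ctx)
  jt <- job_table(ctx, workflow_id)
  tt <- task_table(ctx, workflow_id)
  req <- jsonlite::fromJSON(
    DBI::dbGetQuery(ctx$con, "SELECT request FROM workflows WHERE id = ?",
                    params = list(workflow_id))$request,
    simplifyVector = FALSE)
  finish_time <- function(task_ids) {
    ts <- unlist(lapply(task_ids, function(id) {
      sl <- syslog_table(ctx, id)
      sl$ts[grepl("^command exited", sl$message)]
    }))
    if (length(ts)) max(ts) else NA_real_
  }
  violations <- 0L
  for (i in seq_along(req$jobs)) {
    args <- req$jobs[[i]]$args
    parents <- unlist(lapply(args, function(a)
      if (is.list(a) && !is.null(a$from_job)) a$from_job))
    if (is.null(parents)) next
    my_tasks <- tt$id[tt$job_id == jt$id[i]]
    my_start <- min(led$ts[led$task_id %in% as.character(my_tasks)] / 1e9,
                    Inf)
    for (p in parents) {
      p_tasks <- tt$id[tt$job_id == jt$id[p + 1L]]
      p_finish <- finish_time(p_tasks)
      if (is.finite(my_start) && !is.na(p_finish) && my_start < p_finish)
        violations <- violations + 1L
    }
  }
  violations
}
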