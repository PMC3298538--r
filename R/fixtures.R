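#' Synthetic toolkit, datasets and use-case workflows
#'
#' Everything the engine runs in its tests is generated here, hermetically:
#' a set of small deterministic shell tools standing in for the usual
#' annotation programs (repeat masking, gene prediction, GFF reformatting,
#' ORF extraction, motif classification), a seeded pseudo-FASTA dataset
#' generator, and three ready-made workflow documents exercising linear
#' chaining, batch fan-out and mixed-backend execution. The stand-ins are
#' pure text transforms with documented semantics, so expected outputs can
#' be computed by an independent oracle; none of them touch the network and
#' all are deterministic given their inputs.
#'
#' Tool semantics (each tool loops over its staged input files and writes
#' its outputs to the task working directory; `<stem>` is the input basename
#' minus its last extension):
#'
#' * `pick` — identity copy, `<stem>.pick.fa` (the "select file" step).
#' * `mask` — lowercases the vowels `A E I O U` on sequence (non-header)
#'   lines, `<stem>.mask.fa` (repeat-masking stand-in).
#' * `predict -k K` — extracts maximal uppercase runs of length >= K (default
#'   3) from sequence lines as new records `<stem>_pN`, `<stem>.pred.fa`
#'   (gene-prediction stand-in).
#' * `tognff` — one tab-separated row `stem, record, length, "feature"` per
#'   record, `<stem>.gff` (format-conversion stand-in).
#' * `orfs` — splits a multi-record file into one `<stem>_rNNN.orf` file per
#'   record (ORF-extraction stand-in).
#' * `classify -m MOTIF` — keeps the records whose sequence contains MOTIF
#'   (default `ACCA`), `<stem>.hit.orf` (classifier stand-in).
#' * `upper` — uppercases the whole file, `<stem>.up.txt`.
#' * `combine -a A -b B` — concatenates a paired `.fa`/`.qual` couple,
#'   `<stem-of-A>.comb.txt` (exercises minimum-edit-distance pairing).
#' * `merge -a A -b B` — concatenates the outputs of two upstream jobs,
#'   `<stem-of-A>.merge.fa` (exercises fan-in dependencies).
#' * `fail42` — writes a diagnostic to stderr and exits 42.
#' * `sleepy -s S` — sleeps S seconds then copies input to
#'   `<stem>.slept.txt`.
#'
#' Every tool appends a nonce line (`tool task-id pid timestamp`) to the file
#' named by `FB_NONCE_LEDGER`, which is how the tests prove each completed
#' task's command ran exactly once.
#'
#' @name fixtures
#' @keywords internal
NULL

fixture_script <- function(name, body) {
  paste0("#!/bin/sh\n",
         "# deterministic fixture tool '", name, "'\n",
         "if [ -n \"$FB_NONCE_LEDGER\" ]; then\n",
         "  echo \"", name, " ${FB_TASK_ID:--} $$ $(date +%s%N)\" >> \"$FB_NONCE_LEDGER\"\n",
         "fi\n",
         body, "\n")
}

fixture_tool_bodies <- function() {
  loop <- function(inner) paste0(
    "for f in \"$@\"; do\n  b=`basename \"$f\"`; s=${b%.*}\n", inner, "\ndone")
  list(
    pick = loop("  cp \"$f\" \"./$s.pick.fa\""),
    mask = loop("  sed '/^>/!y/AEIOU/aeiou/' \"$f\" > \"$s.mask.fa\""),
    predict = paste0(
      "k=3\nif [ \"$1\" = \"-k\" ]; then k=\"$2\"; shift 2; fi\n",
      loop(paste0("  awk '!/^>/' \"$f\" | grep -oE \"[A-Z]{$k,}\" | ",
                  "awk -v s=\"$s\" '{printf \">%s_p%d\\n%s\\n\", s, NR, $0}' ",
                  "> \"$s.pred.fa\""))),
    tognff = loop(paste0(
      "  awk -v s=\"$s\" 'BEGIN{OFS=\"\\t\"} ",
      "/^>/{if(h!=\"\")print s,h,len,\"feature\"; h=substr($0,2); len=0; next} ",
      "{len+=length($0)} END{if(h!=\"\")print s,h,len,\"feature\"}' ",
      "\"$f\" > \"$s.gff\"")),
    orfs = loop(paste0(
      "  awk -v s=\"$s\" '/^>/{i++; fn=sprintf(\"%s_r%03d.orf\", s, i)} ",
      "{print >> fn}' \"$f\"")),
    classify = paste0(
      "m=ACCA\nif [ \"$1\" = \"-m\" ]; then m=\"$2\"; shift 2; fi\n",
      loop(paste0(
        "  awk -v m=\"$m\" 'function fl(){if(h!=\"\"&&index(seq,m)>0)",
        "{print h;print seq}} /^>/{fl();h=$0;seq=\"\";next}{seq=seq $0} ",
        "END{fl()}' \"$f\" > \"$s.hit.orf\""))),
    upper = loop("  tr '[:lower:]' '[:upper:]' < \"$f\" > \"$s.up.txt\""),
    combine = paste0(
      "a=\"\"; bb=\"\"\n",
      "while [ $# -gt 0 ]; do\n",
      "  case \"$1\" in\n    -a) a=\"$2\"; shift 2;;\n",
      "    -b) bb=\"$2\"; shift 2;;\n    *) shift;;\n  esac\ndone\n",
      "ba=`basename \"$a\"`; s=${ba%.*}\n",
      "cat \"$a\" \"$bb\" > \"$s.comb.txt\""),
    merge = paste0(
      "a=\"\"; bb=\"\"\n",
      "while [ $# -gt 0 ]; do\n",
      "  case \"$1\" in\n    -a) a=\"$2\"; shift 2;;\n",
      "    -b) bb=\"$2\"; shift 2;;\n    *) shift;;\n  esac\ndone\n",
      "ba=`basename \"$a\"`; s=${ba%.*}\n",
      "cat \"$a\" \"$bb\" > \"$s.merge.fa\""),
    fail42 = "echo 'deterministic fixture failure' >&2\nexit 42",
    sleepy = paste0(
      "d=0\nif [ \"$1\" = \"-s\" ]; then d=\"$2\"; shift 2; fi\n",
      "sleep \"$d\"\n",
      loop("  cp \"$f\" \"./$s.slept.txt\""))
  )
}

fixture_tool_specs <- function(bin) {
  p <- function(name, ...) c(list(name = name), list(...))
  tool <- function(name, params, produces, backend = "localexec")
    list(name = name, program = file.path(bin, name), exec_backend = backend,
         params = params, produces = as.list(produces))
  list(
    tool("pick", list(p("infile", mandatory = TRUE,
                        accepts = list("*.fa", "*.txt", "*.qual"),
                        source_kind = "input-file")), "*.pick.fa"),
    tool("mask", list(p("infile", mandatory = TRUE, accepts = list("*.fa"),
                        source_kind = "previous-job-output")), "*.mask.fa"),
    tool("predict", list(p("k", switch = "-k", default = "3"),
                         p("infile", mandatory = TRUE, accepts = list("*.fa"),
                           source_kind = "previous-job-output")), "*.pred.fa"),
    tool("tognff", list(p("infile", mandatory = TRUE,
                          accepts = list("*.fa", "*.up.txt"),
                          source_kind = "previous-job-output")), "*.gff"),
    tool("orfs", list(p("infile", mandatory = TRUE, accepts = list("*.fa"),
                        batchable = TRUE,
                        source_kind = "previous-job-output")), "*.orf"),
    tool("classify", list(p("m", switch = "-m", default = "ACCA"),
                          p("infile", mandatory = TRUE, accepts = list("*.orf"),
                            batchable = TRUE,
                            source_kind = "previous-job-output")), "*.hit.orf"),
    tool("upper", list(p("infile", mandatory = TRUE, accepts = list("*"),
                         source_kind = "previous-job-output")),
         "*.up.txt", backend = "mockq"),
    tool("combine", list(p("a", switch = "-a", mandatory = TRUE,
                           accepts = list("*.fa"), batchable = TRUE,
                           source_kind = "input-file"),
                         p("b", switch = "-b", mandatory = TRUE,
                           accepts = list("*.qual"), batchable = TRUE,
                           source_kind = "input-file")), "*.comb.txt"),
    tool("merge", list(p("a", switch = "-a", mandatory = TRUE,
                         accepts = list("*.fa"),
                         source_kind = "previous-job-output"),
                       p("b", switch = "-b", mandatory = TRUE,
                         accepts = list("*.fa"),
                         source_kind = "previous-job-output")), "*.merge.fa"),
    tool("fail42", list(p("infile", mandatory = TRUE, accepts = list("*"),
                          source_kind = "input-file")), character(0)),
    tool("sleepy", list(p("s", switch = "-s", default = "0"),
                        p("infile", mandatory = TRUE, accepts = list("*"),
                          source_kind = "input-file")), "*.slept.txt")
  )
}

#' Emit the fixture toolkit
#'
#' Writes the fixture tool executables into `dest/bin/`, plus a complete
#' registry config (`dest/registry.json`) wiring them to the bundled
#' `localexec` and `mockq` compute backends, a local-filesystem storage
#' backend and an in-memory storage backend (`mem://data/...`), with user
#' `alice` granted everything and `carol` granted only `pick`.
#'
#' @param dest Writable directory.
#' @param mockq_options Options list for the mock queue backend
#'   (`latency_polls`, `lose_attempts`).
#' @return The loaded `fb_registry`, invisibly; the config path is
#'   `file.path(dest, "registry.json")`.
#' @export
fixture_toolkit <- function(dest, mockq_options = list(latency_polls = 1L)) {
  bin <- file.path(dest, "bin")
  dir.create(bin, recursive = TRUE, showWarnings = FALSE)
  bodies <- fixture_tool_bodies()
  for (nm in names(bodies)) {
    path <- file.path(bin, nm)
    writeLines(fixture_script(nm, bodies[[nm]]), path)
    Sys.chmod(path, "0755")
  }
  tools <- fixture_tool_specs(normalizePath(bin))
  tool_names <- vapply(tools, `[[`, "", "name")
  cfg <- list(
    schema_version = 1L,
    backends = list(
      list(id = "localexec", kind = "compute", scheme = "localexec",
           endpoint = ""),
      list(id = "mockq", kind = "compute", scheme = "mockq", endpoint = "",
           options = mockq_options),
      list(id = "localfiles", kind = "storage", scheme = "file",
           endpoint = ""),
      list(id = "memdata", kind = "storage", scheme = "mem",
           endpoint = "data")),
    tools = tools,
    users = list(
      list(name = "alice", tools = as.list(tool_names),
           backends = list("localexec", "mockq", "localfiles", "memdata")),
      list(name = "carol", tools = list("pick"),
           backends = list("localexec", "localfiles")))
  )
  reg <- load_registry(cfg)
  write_registry(reg, file.path(dest, "registry.json"))
  invisible(reg)
}

#' Generate a seeded pseudo-FASTA dataset on a storage backend
#'
#' Writes `n_files` text files of FASTA-like records (uppercase `ACGT`
#' alphabet) under `dir_uri`. Regeneration with the same seed is
#' byte-identical. With `paired = TRUE` every `<stem>.fa` gets a matching
#' `<stem>.qual` file of per-base integer scores, for exercising
#' minimum-edit-distance input pairing.
#'
#' @param sm A storage manager (or an engine context, whose manager is used).
#' @param dir_uri Directory URI to populate.
#' @param seed Integer seed; the manifest is a pure function of the seed and
#'   shape parameters.
#' @param n_files Number of `.fa` files.
#' @param records_per_file Records per file.
#' @param len_range Length range (min, max) of each record's sequence.
#' @param paired Also emit matching `.qual` files.
#' @param prefix File-name prefix.
#' @return Manifest data frame: `name`, `bytes`, `sha256`.
#' @export
fixture_dataset <- function(sm, dir_uri, seed = 7L, n_files = 14L,
                            records_per_file = 2L, len_range = c(40L, 80L),
                            paired = FALSE, prefix = "seq") {
  if (inherits(sm, "fb_engine")) sm <- sm$sm
  if (n_files > 0) st_mkdir(sm, dir_uri)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  names <- character(0); bytes <- numeric(0); digests <- character(0)
  emit <- function(fname, content) {
    u <- uri_join(uri_parse(dir_uri), fname)
    st_write(sm, u, charToRaw(content))
    names <<- c(names, fname)
    bytes <<- c(bytes, nchar(content, type = "bytes"))
    digests <<- c(digests, st_digest(sm, u))
  }
  for (i in seq_len(n_files)) {
    stem <- sprintf("%s%02d", prefix, i)
    seqs <- lapply(seq_len(records_per_file), function(r)
      paste(sample(c("A", "C", "G", "T"),
                   sample(len_range[1]:len_range[2], 1L),
                   replace = TRUE), collapse = ""))
    fa <- paste(vapply(seq_along(seqs), function(r)
      sprintf(">%s_r%d\n%s", stem, r, seqs[[r]]), ""), collapse = "\n")
    emit(paste0(stem, ".fa"), paste0(fa, "\n"))
    if (paired) {
      qual <- paste(vapply(seq_along(seqs), function(r)
        sprintf(">%s_r%d\n%s", stem, r,
                paste(sample(10:40, nchar(seqs[[r]]), replace = TRUE),
                      collapse = " ")), ""), collapse = "\n")
      emit(paste0(stem, ".qual"), paste0(qual, "\n"))
    }
  }
  data.frame(name = names, bytes = bytes, sha256 = digests,
             stringsAsFactors = FALSE)
}

#' The three reference workflow documents
#'
#' Builds the workflow requests the test-bed runs end to end:
#'
#' 1. *linear annotation chain* — select file, mask repeats, predict genes,
#'    reformat to a feature table (4 jobs, each consuming the previous job's
#'    output);
#' 2. *batched prediction* — select a directory of sequence files, split each
#'    into per-record files (batch fan-out: one task per file), classify each
#'    record file by motif (3 jobs, batchable middle and final stages);
#' 3. *mixed-backend chain* — select, uppercase on the mock queue backend,
#'    reformat locally (3 jobs across two compute backends).
#'
#' @param input_file_uri URI of a single multi-record `.fa` file (cases 1
#'   and 3).
#' @param input_dir_uri URI of a directory of `.fa` files (case 2).
#' @param user Submitting user.
#' @return Named list of three workflow request lists
#'   (`linear`, `batch`, `mixed`).
#' @export
fixture_workflows <- function(input_file_uri, input_dir_uri, user = "alice") {
  list(
    linear = list(
      name = "usecase-linear", user = user,
      metadata = list(project = "annotation", case = "linear"),
      jobs = list(
        list(tool = "pick", args = list(infile = input_file_uri)),
        list(tool = "mask", args = list(infile = list(from_job = 0L))),
        list(tool = "predict", args = list(infile = list(from_job = 1L))),
        list(tool = "tognff", args = list(infile = list(from_job = 2L))))),
    batch = list(
      name = "usecase-batch", user = user,
      metadata = list(project = "annotation", case = "batch"),
      jobs = list(
        list(tool = "pick", args = list(infile = input_dir_uri)),
        list(tool = "orfs", args = list(infile = list(from_job = 0L))),
        list(tool = "classify", args = list(infile = list(from_job = 1L))))),
    mixed = list(
      name = "usecase-mixed", user = user,
      metadata = list(project = "proteomics", case = "mixed"),
      jobs = list(
        list(tool = "pick", args = list(infile = input_file_uri)),
        list(tool = "upper", args = list(infile = list(from_job = 0L))),
        list(tool = "tognff", args = list(infile = list(from_job = 1L)))))
  )
}

#' Read the fixture nonce ledger
#'
#' @param ctx An engine context.
#' @return Data frame with one row per recorded tool execution: `tool`,
#'   `task_id`, `pid`, and the execution timestamp `ts` (nanosecond epoch).
#' @export
nonce_ledger <- function(ctx) {
  path <- ctx$options$nonce_ledger
  if (!file.exists(path))
    return(data.frame(tool = character(0), task_id = character(0),
                      pid = character(0), ts = numeric(0),
                      stringsAsFactors = FALSE))
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, " ", fixed = TRUE)
  data.frame(tool = vapply(parts, `[[`, "", 1L),
             task_id = vapply(parts, `[[`, "", 2L),
             pid = vapply(parts, `[[`, "", 3L),
             ts = as.numeric(vapply(parts, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}
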