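# flowbench

A desk-scale scientific workflow engine for R, modelled on the three-tier
middleware systems used to chain bioinformatics tools across heterogeneous
compute and storage resources. `flowbench` separates the three concerns those
systems separate — *declarative tool administration*, *workflow processing*,
and *resource access* — but packs them into a single in-process library with
an embedded SQLite store, so the full behaviour (dynamic dependency
resolution, batch fan-out, pluggable backends, encrypted credentials,
crash-safe resume) is testable on a laptop.

## Who it is for

Anyone who needs to chain command-line analysis tools (sequence annotation,
ORF extraction, format conversion, …) into reproducible pipelines without
hand-writing driver scripts: tools are added by editing a JSON/YAML config,
never by writing code; users submit a high-level description of the whole
pipeline and the engine works out, at run time, which files feed which step.

## The core machinery

* **Declarative registry** — every tool is a record: command template,
  ordered parameters, *file types* (unix-style glob patterns such as
  `*.fa`), the compute backend to run on, and where results go.
* **Dynamic dependency resolution** — a job may declare its input as "the
  output of job *k*", before those files exist. A job becomes ready when all
  referenced jobs are complete and all referenced files are present; any
  upstream file matching the parameter's pattern can satisfy it.
* **Batch fan-out** — a batchable parameter with *n* matching files expands
  into *n* tasks, one command execution per file.
* **Minimum-edit-distance pairing** — when a tool takes two file types
  (say `.fa` + `.qual`), files are paired by minimising the total
  Levenshtein distance between their names:
  `d(a,b) = min(insertions + deletions + substitutions)`, with the exact
  minimum-cost assignment computed for realistic batch sizes.
* **Pluggable backends** — storage (`file://`, `mem://`) and compute
  (`localexec`, `mockq`) are plug-ins dispatched by URI scheme; copies
  between backends stream through a bounded buffer (≤ 8 MiB in flight,
  nothing spooled to disk).
* **Credential vault** — per-(user, backend) secrets encrypted with
  AES-256-CBC under a password-derived key (bcrypt PBKDF) and an
  HMAC-SHA256 authentication tag; decrypted secrets live only in RAM. A
  missing credential *blocks* the task (resumable) instead of failing it.
* **Crash-safe persistence** — every transition is written to SQLite before
  it is acknowledged; a restarted engine resumes each interrupted task at
  its last incomplete lifecycle stage, never re-running completed work.

## Worked example

```r
library(flowbench)

base <- tempfile("demo")
reg  <- fixture_toolkit(file.path(base, "kit"))   # 11 toy tools + registry
ctx  <- engine_open(file.path(base, "root"), registry = reg)

# 14 seeded pseudo-FASTA files on the in-memory backend
fixture_dataset(ctx, "mem://data/in", seed = 7, n_files = 14)

# select-file -> split-into-records (fan-out) -> motif classification
wf <- fixture_workflows("mem://data/in/seq01.fa", "mem://data/in")$batch
id <- submit_workflow(ctx, wf)   # returns before any processing
workflow_status(ctx, id)
#> [1] "pending"

drive(ctx, id)
#> [1] "complete"

tt <- task_table(ctx, id)
table(tt$status)
#>
#> complete
#>       43
nrow(tt[tt$job_id == job_table(ctx, id)$id[2], ])   # one task per file
#> [1] 14
```

The 43 tasks are: 1 (select 14 files) + 14 (`orfs`, one per file) + 28
(`classify`, one per record file produced upstream). `provenance(ctx, id)`
returns the complete audit record — every tool as-run, every bound argument,
every input URI, every rendered command, and every output with its SHA-256 —
and `resubmit(ctx, id)` re-runs the workflow identically from that record.

A command-line client wraps the same API (`inst/cli/flowbench`):

```sh
flowbench init kit/registry.json
flowbench login alice
flowbench submit wf.json
flowbench drive 1 && flowbench fetch 1 results/
flowbench ls mem://data/in
```

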