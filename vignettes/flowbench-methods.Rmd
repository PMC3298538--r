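---
title: "flowbench: engine design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowbench: engine design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`flowbench` is a self-contained re-creation, at desk scale, of the
architecture used by three-tier scientific workflow middleware: a
declarative administration layer, an event-driven engine that accepts
workflows and resolves their file dependencies dynamically, and a resource
layer that abstracts storage and execution behind pluggable backends. This
vignette records the model, the tunable parameters, the numerical and
design choices made where the architecture left them open, and what the
hermetic test-bed does and does not demonstrate.

## The execution model

A **workflow** is an ordered list of **jobs**; each job names a registered
tool and binds its parameters to literals, file URIs, or references to an
earlier job's output (`{"from_job": k}`, 0-based, strictly earlier). Each
job expands at run time into one or more **tasks** — concrete command
executions with their own stage-in list, scratch area and stage-out
destination. Submission is decoupled from processing: `submit_workflow()`
persists the request (workflow and job records, in one SQLite transaction)
and returns an id before anything runs. This write-ahead ordering is what
makes the acknowledgement durable: a crash immediately after submission
leaves a `pending` workflow that a restarted engine will process.

Dependency resolution is deliberately *dynamic*. A job that consumes the
output of job *k* does not know its input filenames at submission time;
when job *k* completes, its recorded outputs are filtered through the
consuming parameter's file-type patterns and only then are tasks created.
A job is ready exactly when (a) every referenced job is `complete` and (b)
every referenced input file exists on its storage backend.

### File types, fan-out and pairing

File types are unix-style filename globs (`*`, `?`, `[...]`; case-sensitive,
applied to basenames, no `**`). The dialect is the narrowest common one:
anything fancier (brace expansion, recursive globs) invites configuration
ambiguity in tool records. The translator is written in the package and
checked in the tests against an independent character-walking matcher.

Fan-out rules, where the architecture is silent, were fixed as follows:

* one batchable parameter with *n* matching files → *n* tasks;
* two batchable parameters → one task per pair chosen to minimise the
  **total Levenshtein distance** between basenames;
* zero matching files on a mandatory or batchable parameter → job `error`
  with the diagnostic `no input satisfies pattern …`. A silent empty
  fan-out would hide user mistakes, so it is never allowed;
* a *non*-batchable file parameter binds **all** matching files as repeated
  `switch value` tokens in a single command ("select files" semantics);
* more than two batchable parameters is rejected at validation, since the
  pairing criterion is defined for two groups.

The pairing itself is an assignment problem. For groups whose larger side
has ≤ 12 members (every realistic batch) the exact minimum-cost assignment
is computed by dynamic programming over subsets (`O(n·2^m)` states), with
ties broken toward the lexicographically smallest pair list so the result
is reproducible; beyond that a greedy nearest-pair fallback with the same
tie-break is used. Unpaired leftovers from the longer group are reported on
the job and logged, never silently dropped — the job only errors if a
mandatory parameter ends up unfilled. The Levenshtein implementation is the
standard two-row unit-cost dynamic programme; the tests verify it against
naive recursion (lengths ≤ 6) and against `utils::adist`, and verify
pairing cost against an exhaustive-permutation oracle for all group sizes
up to 6.

### The task state machine

Tasks move through
`pending → ready → staging_in → running → staging_out → complete`, with two
escapes: any non-terminal state may move to `blocked`, and anything may move
to `error`. `complete` and `error` are terminal. `blocked` is reserved for
*transient, user-fixable* faults — missing credential, unreachable backend,
missing input file, a backend repeatedly losing the task — and is resumable:
on the next drive round a blocked task returns to `ready` with its stage
marker intact and re-enters the stage it was parked in. Two additional
resume transitions (`ready → running`, `ready → staging_out`,
`ready → complete`) exist solely so a restarted engine can re-enter a task
at its last incomplete stage; they are the stage-restart arm of the
`blocked → prior state` rule. Illegal transitions (e.g.
`complete → running`) raise a contract error: they indicate an engine bug,
not a user mistake.

Failure semantics follow the POSIX convention: task success ⇔ exit code 0.
A nonzero exit is deterministic, so it is **not retried**; stdout/stderr are
captured, the tail of stderr is copied into the append-only syslog, and the
scratch area is preserved for diagnosis. Transient backend faults (`lost`
submissions) are retried up to `retry_max` (default 3) attempts with
exponential backoff (`backoff_base` seconds, default 0.05, doubling), after
which the task blocks rather than errs. One failed job does not cancel its
siblings; jobs that *depend* on a failed job are marked `error` with the
reason `upstream job failed`, and the workflow becomes `error` once every
job is terminal.

## Storage, streaming and URIs

Every location is a URI `scheme://[user@]host[/path]`; the scheme selects
the backend. Paths are normalised at parse time and may not escape the
root through `..`. Bundled backends are the local filesystem (`file://`,
optionally rooted at the descriptor's endpoint) and a named in-memory
filesystem (`mem://name/…`) that stands in for remote stores in tests. New
schemes register a factory; nothing in the engine changes (this is asserted
by a test that plugs in a mock scheme).

Copying between backends goes through a producer/consumer pump: the source
reader yields chunks (default 1 MiB, clamped to a `chunk_ceiling` of 8 MiB)
that are written straight to the destination; at most one chunk is in
flight and no intermediate spool file is ever created. The observable
contract — bounded in-flight bytes, zero spool files, checksum-identical
destination — is what the tests instrument and assert; the transfer report
records bytes, SHA-256 of the destination, and the peak buffered chunk.
`mkdir` creates parents (task scratch needs nested directories), copy
overwrites an existing destination (stage-out must be re-runnable after a
resume), and rename is provided as copy-then-delete because it is not a
backend primitive.

## Credentials

Secrets are filed per (user, backend) and stored only in authenticated
ciphertext: AES-256-CBC under a 64-byte key derived with `bcrypt_pbkdf`
(per-record random 16-byte salt; cost parameter `rounds`, default 8, stored
with the record), split into a 32-byte cipher key and a 32-byte HMAC-SHA256
key used encrypt-then-MAC over salt‖IV‖ciphertext. A wrong password or a
single flipped ciphertext byte fails authentication; plaintext is never
emitted on failure and never persisted at all — decrypted secrets live in a
RAM cache populated by `vault_unlock()` and cleared by `vault_lock()`.
Records may carry an optional TTL in seconds; an expired record behaves as
never stored. The vault password is the user's login password in the CLI
(`login` unlocks), but the API keeps the two separable.

The central behavioural rule is **blocked-not-failed**: `vault_get()` for a
credential that is not unlocked raises the blocking condition, and the
engine maps it to task/job status `blocked`. Unlocking and driving again
completes the same workflow with each command having executed exactly once
— the end-to-end scenario is in both the test suite and the acceptance
script.

## Persistence, crash safety and resume granularity

All state — workflows, jobs, tasks (with stage markers, attempt counts and
leases), the append-only syslog, credential ciphertexts, and the registry
as-run — lives in one SQLite file under the engine root, written in WAL
mode with every transition persisted before it is acknowledged.
`engine_snapshot()` checkpoints the WAL and copies the file;
`engine_restore()` (or simply reopening the root) validates the schema
version, refuses corrupt files outright, releases stale leases and
re-offers interrupted tasks.

Resume granularity is the **lifecycle stage**: a task interrupted during
stage-in restarts stage-in; one interrupted after execution but before
stage-out re-runs only stage-out (its outputs persist in scratch), never
the command. The crash points simulated in the tests are the engine's own
checkpoints at stage entries — the model is a graceful shutdown that
serialises in-flight work, which is what makes "each completed task's
command executed exactly once" a guarantee rather than a probability.
Byte-level transfer resume was deliberately not implemented; stages are
small at this scale and idempotent stage restarts are simpler to reason
about. A restored root that has lost its scratch area falls back to
restarting the task from stage-in.

Provenance is recorded as the workflow runs: the tool spec captured at
expansion time, every bound argument, every input URI, every rendered
command, and every output with byte count and SHA-256. The record is
sufficient to resubmit the workflow identically (`resubmit()`), and
workflow summaries are searchable by name, date range and arbitrary
metadata tags (conjunctive filters, newest first).

## The command-line client

The CLI is a thin client: every verb calls exported package functions and
holds no engine logic (a test greps the client source for store access).
Verbs cover session login/logout, tool listing, file/inline submission,
monitoring, driving, fetching (with checksum verification against
provenance; an errored workflow yields its partial outputs with a warning),
URI file management, and credential management. All structured output is
available as `--json` with the same fields as the human tables. Exit codes:
0 success, 1 user error, 2 validation, 3 blocked, 4 internal. Secrets are
prompted, never taken from `argv`; the environment-variable escape hatch
for unattended use is disabled unless `FLOWBENCH_ALLOW_ENV_PASSWORD=1`.

## The synthetic test-bed

Real annotation binaries would break hermeticity, so the fixture toolkit
emits small deterministic shell tools whose semantics are simple text
transforms with documented rules (vowel-masking for repeat masking,
uppercase-run extraction for gene prediction, record splitting for ORF
extraction, motif filtering for classification, and deliberate failure /
delay / fan-in utilities). Expected outputs are therefore computable by
independent oracles in the test tree. Each tool stamps a nonce line
(tool, task id, pid, nanosecond clock) into a ledger, which is how the
tests prove execution-exactly-once and dependency ordering.

The dataset generator emits seeded pseudo-FASTA files (uppercase `ACGT`,
2 records of 40–80 bases per file by default) — enough structure for every
pattern-matching, batching and pairing behaviour to be exercised, and
regeneration from a seed is byte-identical. Default shapes mirror the
reference scenarios at desk scale: the batched use case runs over **14**
sequence files (one execution unit per sequence container), the crash and
ordering studies use **5-job** workflows, fuzzing uses **50** seeded
trials, the vault study uses **1000** random secret/password pairs, and the
streaming study copies **100 MiB**. These sizes are the package's study
conditions, fixed in the tests and the acceptance script.

What passing tests do *not* show about real deployments: the generated
sequences are not biologically realistic; the in-memory backend has none of
the latency, partial-failure or permission behaviour of networked storage
(the mock queue injects only coarse latency/loss); all components run in
one process, so the decoupling and lease contracts are exercised logically
rather than across machines; and the simulated crashes occur at stage
checkpoints, not at arbitrary instructions (a `kill -9` between a
command's side effect and its record could still duplicate one execution —
the paper trail would show it via the nonce ledger).

## Known limitations

* No conditionals, loops or sub-workflows — the workflow language is a
  deliberate straight-line DAG; fan-in exists only through multi-parameter
  tools.
* Only two batchable parameters per tool (the pairing criterion is
  pairwise).
* No real SSH/grid/cloud drivers are bundled; the plug-in contract and the
  mock backends stand in for them.
* Single-process scheduling; leases make multi-worker pulls safe in
  principle but no worker pool ships with the package.
* Rename is copy+delete, so it is not atomic on any backend.
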