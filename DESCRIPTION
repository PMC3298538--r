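Package: flowbench
Title: Desk-Scale Scientific Workflow Engine with Pluggable Storage and
    Compute Backends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow engine for chaining command-line
    analysis tools into pipelines, in the style of three-tier scientific
    workflow middleware. Tools are registered declaratively (command
    template, parameters, accepted and produced file-type glob patterns,
    execution backend); workflows are submitted as JSON documents and
    driven through dynamic file-dependency resolution, batch fan-out over
    matching files, and minimum-edit-distance pairing of multi-type
    inputs. Storage and execution are pluggable behind URI schemes, with
    bundled local-filesystem, in-memory, direct-subprocess and
    mock-queue backends. Credentials are held in an AES-encrypted vault
    unlocked by a password-derived key; a missing credential blocks
    rather than fails a task. All state lives in an embedded SQLite
    store, giving write-ahead submission, full provenance, and
    crash-safe resumable execution. A command-line client covers
    submission, monitoring, file management and result fetching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    openssl,
    processx,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
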