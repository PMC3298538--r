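#' Scheme-dispatched data services
#'
#' All file operations take URIs and dispatch purely on the URI scheme to a
#' registered storage backend. Copying between two backends streams the data
#' through a bounded in-flight buffer — a producer/consumer channel in which
#' at most one chunk (default 1 MiB, never more than the configured ceiling)
#' is held in memory and nothing is ever spooled to an intermediate file.
#'
#' @name storage
#' @keywords internal
NULL

#' Build a storage manager from a registry
#'
#' Instantiates one backend object per storage descriptor in the registry and
#' dispatches URIs to them by scheme (and, when several backends share a
#' scheme, by matching the URI host against the descriptor's endpoint or id).
#'
#' @param registry An `fb_registry`.
#' @return An object of class `fb_storage_manager`.
#' @export
storage_manager <- function(registry) {
  sm <- new.env(parent = emptyenv())
  sm$descriptors <- new.env(parent = emptyenv())
  sm$instances <- new.env(parent = emptyenv())
  for (b in registry$backends) {
    if (b$kind != "storage") next
    factory <- .fb_plugins$storage[[b$scheme]]
    if (is.null(factory))
      stop_config(sprintf("no storage plug-in for scheme '%s'", b$scheme))
    desc <- as.environment(b)   # mutable descriptor (reachability can be toggled)
    sm$descriptors[[b$id]] <- desc
    sm$instances[[b$id]] <- factory(desc)
  }
  class(sm) <- "fb_storage_manager"
  sm
}

#' Resolve a URI to its storage backend
#' @param sm A storage manager.
#' @param u An `fb_uri` or URI string.
#' @return The backend object serving the URI.
#' @export
storage_resolve <- function(sm, u) {
  u <- uri_parse(u)
  ids <- ls(sm$instances)
  hits <- ids[vapply(ids, function(i)
    sm$descriptors[[i]]$scheme == u$scheme, logical(1))]
  if (length(hits) == 0L)
    stop_config(sprintf("no storage backend registered for scheme '%s'", u$scheme))
  if (length(hits) > 1L) {
    by_host <- hits[vapply(hits, function(i) {
      d <- sm$descriptors[[i]]
      identical(d$endpoint, u$host) || identical(d$id, u$host)
    }, logical(1))]
    if (length(by_host)) hits <- by_host
  }
  sm$instances[[hits[1]]]
}

# gate an operation on reachability and credentials; raises fb_blocked
storage_gate <- function(sm, u, vault = NULL, as_user = NULL) {
  be <- storage_resolve(sm, u)
  d <- be$descriptor
  if (!d$reachable)
    signal_blocked(sprintf("backend '%s' unreachable", d$id),
                   backend_id = d$id)
  if (isTRUE(d$requires_credential)) {
    if (is.null(vault) || is.null(as_user) ||
        !vault_has(vault, as_user, d$id))
      signal_blocked(sprintf("credential missing for backend '%s'", d$id),
                     backend_id = d$id)
  }
  be
}

#' Storage operations on URIs
#'
#' `st_list()` returns a directory listing sorted by name; `st_mkdir()`
#' creates a directory (and any missing parents); `st_delete()` removes a
#' file or directory (`recursive = TRUE` for non-empty directories);
#' `st_exists()` returns `"file"`, `"dir"` or `NA`; `st_read()`/`st_write()`
#' read and write whole raw payloads; `st_digest()` returns the SHA-256 of a
#' file's content. Operations on a backend that is unreachable or whose
#' credential is not unlocked raise a blocking condition, not an error.
#'
#' @param sm A storage manager from [storage_manager()].
#' @param u Target `fb_uri` or URI string.
#' @param vault Optional credential vault.
#' @param as_user User whose credentials gate access.
#' @param recursive Allow deleting a non-empty directory.
#' @param payload Raw vector to write.
#' @return See individual descriptions.
#' @export
st_list <- function(sm, u, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  be$list(u$path)
}

#' @rdname st_list
#' @export
st_mkdir <- function(sm, u, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  be$mkdir(u$path)
}

#' @rdname st_list
#' @export
st_delete <- function(sm, u, recursive = FALSE, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  be$delete(u$path, recursive = recursive)
}

#' @rdname st_list
#' @export
st_exists <- function(sm, u, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  be$exists(u$path)
}

#' @rdname st_list
#' @export
st_read <- function(sm, u, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  h <- be$read_open(u$path)
  on.exit(h$close())
  acc <- list()
  repeat {
    chunk <- h$read(2^20)
    if (is.null(chunk)) break
    acc[[length(acc) + 1L]] <- chunk
  }
  if (length(acc)) do.call(c, acc) else raw(0)
}

#' @rdname st_list
#' @export
st_write <- function(sm, u, payload, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  h <- be$write_open(u$path)
  if (length(payload)) h$write(payload)
  h$close()
  invisible(u)
}

#' @rdname st_list
#' @export
st_digest <- function(sm, u, vault = NULL, as_user = NULL) {
  u <- uri_parse(u)
  be <- storage_gate(sm, u, vault, as_user)
  be$digest(u$path)
}

#' Streaming copy between storage backends
#'
#' Copies `src` to `dst`, possibly across backends, by pumping bounded chunks
#' from the source reader straight into the destination writer: at most one
#' chunk is in flight, no intermediate spool file is ever written, and the
#' chunk size is capped by `chunk_ceiling` (8 MiB by default). On failure the
#' partially written destination is cleaned up. The transfer report carries
#' the byte count, the SHA-256 checksum of the destination, and the peak
#' number of buffered bytes observed.
#'
#' @param sm A storage manager.
#' @param src,dst Source and destination URIs (must differ).
#' @param chunk_size Chunk size in bytes (default 1 MiB).
#' @param chunk_ceiling Hard upper bound on the in-flight buffer (default
#'   8 MiB); `chunk_size` is clamped to it.
#' @param vault,as_user Credential gate, as in [st_list()].
#' @return A list: `bytes`, `sha256`, `peak_buffer_bytes`, `chunks`.
#' @export
st_copy <- function(sm, src, dst, chunk_size = 2^20, chunk_ceiling = 8 * 2^20,
                    vault = NULL, as_user = NULL) {
  src <- uri_parse(src); dst <- uri_parse(dst)
  if (identical(format(src), format(dst)))
    fb_stop(sprintf("copy onto itself rejected: %s", format(src)),
            "fb_storage_error")
  sbe <- storage_gate(sm, src, vault, as_user)
  dbe <- storage_gate(sm, dst, vault, as_user)
  pump_copy(sbe, src$path, dbe, dst$path, chunk_size, chunk_ceiling)
}

# the streaming producer/consumer channel shared by st_copy() and the task
# stage-in/stage-out paths: one bounded chunk in flight, nothing spooled
pump_copy <- function(sbe, spath, dbe, dpath, chunk_size = 2^20,
                      chunk_ceiling = 8 * 2^20) {
  chunk_size <- min(chunk_size, chunk_ceiling)
  reader <- sbe$read_open(spath)
  writer <- dbe$write_open(dpath)
  bytes <- 0; peak <- 0; chunks <- 0L
  ok <- FALSE
  tryCatch({
    repeat {
      chunk <- reader$read(chunk_size)
      if (is.null(chunk)) break
      peak <- max(peak, length(chunk))
      bytes <- bytes + length(chunk)
      chunks <- chunks + 1L
      writer$write(chunk)
    }
    writer$close()
    ok <- TRUE
  }, finally = {
    reader$close()
    if (!ok && !is.null(writer$abort)) writer$abort()
  })
  list(bytes = bytes, sha256 = dbe$digest(dpath),
       peak_buffer_bytes = peak, chunks = chunks)
}

#' Rename a file
#'
#' Rename is not a backend primitive; it is provided as copy-then-delete.
#'
#' @param sm A storage manager.
#' @param src,dst URIs.
#' @param vault,as_user Credential gate.
#' @return The transfer report of the underlying copy.
#' @export
st_rename <- function(sm, src, dst, vault = NULL, as_user = NULL) {
  rep <- st_copy(sm, src, dst, vault = vault, as_user = as_user)
  st_delete(sm, src, vault = vault, as_user = as_user)
  rep
}
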