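#' Bundled storage backends
#'
#' A storage backend services one URI scheme and implements the five data
#' services: directory listing, copy (as chunked reader/writer endpoints),
#' delete, directory creation, plus existence/size/digest helpers. Two
#' backends ship with the package: `file` (local filesystem, optionally
#' rooted at the descriptor's endpoint) and `mem` (a named in-memory
#' filesystem, useful for hermetic tests and as a stand-in for remote
#' stores). New schemes are added with [register_storage_scheme()]; nothing
#' in the engine changes.
#'
#' @name storage-backends
#' @keywords internal
NULL

# hex digest as a plain string, whether openssl hashed a raw vector or a
# streamed connection
sha256_hex <- function(x) {
  h <- openssl::sha256(x)
  if (is.raw(h)) paste(as.character(h), collapse = "")
  else as.character(unclass(h))
}

# --- local filesystem ------------------------------------------------------

storage_localfs <- function(descriptor) {
  root <- descriptor$endpoint %||% ""
  real <- function(path) {
    if (nzchar(root)) file.path(root, sub("^/", "", path)) else path
  }
  be <- new.env(parent = emptyenv())
  be$descriptor <- descriptor
  be$scheme <- descriptor$scheme

  be$exists <- function(path) {
    p <- real(path)
    if (dir.exists(p)) "dir" else if (file.exists(p)) "file" else NA_character_
  }
  be$list <- function(path) {
    p <- real(path)
    if (!dir.exists(p)) stop_notfound(sprintf("no such directory: %s", path))
    nm <- sort(list.files(p, all.files = FALSE))
    info <- file.info(file.path(p, nm))
    data.frame(name = nm,
               kind = ifelse(info$isdir, "dir", "file"),
               size = ifelse(info$isdir, 0, info$size),
               mtime = as.numeric(info$mtime),
               stringsAsFactors = FALSE)
  }
  be$mkdir <- function(path) {
    p <- real(path)
    if (file.exists(p) && !dir.exists(p))
      fb_stop(sprintf("cannot mkdir over existing file: %s", path), "fb_storage_error")
    dir.create(p, recursive = TRUE, showWarnings = FALSE)
    invisible(TRUE)
  }
  be$delete <- function(path, recursive = FALSE) {
    p <- real(path)
    if (dir.exists(p)) {
      if (!recursive && length(list.files(p, all.files = TRUE, no.. = TRUE)))
        fb_stop(sprintf("directory not empty: %s", path), "fb_storage_error")
      unlink(p, recursive = TRUE)
    } else if (file.exists(p)) {
      unlink(p)
    } else {
      stop_notfound(sprintf("no such path: %s", path))
    }
    invisible(TRUE)
  }
  be$size <- function(path) {
    p <- real(path)
    if (!file.exists(p)) stop_notfound(sprintf("no such file: %s", path))
    file.size(p)
  }
  be$read_open <- function(path) {
    p <- real(path)
    if (!file.exists(p) || dir.exists(p))
      stop_notfound(sprintf("no such file: %s", path))
    con <- file(p, "rb")
    list(read = function(n) {
      chunk <- readBin(con, "raw", n)
      if (length(chunk) == 0L) NULL else chunk
    }, close = function() close(con))
  }
  be$write_open <- function(path) {
    p <- real(path)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    con <- file(p, "wb")
    list(write = function(chunk) writeBin(chunk, con),
         close = function() close(con),
         abort = function() { close(con); unlink(p) })
  }
  be$digest <- function(path) {
    p <- real(path)
    if (!file.exists(p)) stop_notfound(sprintf("no such file: %s", path))
    con <- file(p, "rb")
    on.exit(try(close(con), silent = TRUE))
    sha256_hex(con)
  }
  class(be) <- "fb_storage_backend"
  be
}

# --- in-memory filesystem --------------------------------------------------

storage_mem <- function(descriptor) {
  files <- new.env(parent = emptyenv())   # path -> list of raw chunks
  dirs <- new.env(parent = emptyenv())    # path -> TRUE
  dirs[["/"]] <- TRUE
  clock0 <- as.numeric(Sys.time())
  mtimes <- new.env(parent = emptyenv())

  add_dirs <- function(path) {
    while (path != "/") {
      dirs[[path]] <- TRUE
      path <- dirname(path)
    }
  }
  content <- function(path) {
    chunks <- files[[path]]
    if (length(chunks) == 0L) raw(0) else do.call(c, chunks)
  }

  be <- new.env(parent = emptyenv())
  be$descriptor <- descriptor
  be$scheme <- descriptor$scheme

  be$exists <- function(path) {
    if (!is.null(files[[path]])) "file"
    else if (isTRUE(dirs[[path]])) "dir"
    else NA_character_
  }
  be$list <- function(path) {
    if (is.na(be$exists(path)) || !is.null(files[[path]]))
      stop_notfound(sprintf("no such directory: %s", path))
    prefix <- if (path == "/") "/" else paste0(path, "/")
    direct <- function(keys) {
      hit <- keys[startsWith(keys, prefix)]
      rest <- substring(hit, nchar(prefix) + 1L)
      hit[!grepl("/", rest, fixed = TRUE)]
    }
    fkeys <- direct(ls(files))
    dkeys <- setdiff(direct(ls(dirs)), path)
    df <- data.frame(
      name = basename(c(fkeys, dkeys)),
      kind = c(rep("file", length(fkeys)), rep("dir", length(dkeys))),
      size = c(vapply(fkeys, function(k) length(content(k)), numeric(1)),
               rep(0, length(dkeys))),
      mtime = c(vapply(fkeys, function(k) mtimes[[k]] %||% clock0, numeric(1)),
                rep(clock0, length(dkeys))),
      stringsAsFactors = FALSE)
    df[order(df$name), , drop = FALSE]
  }
  be$mkdir <- function(path) {
    if (!is.null(files[[path]]))
      fb_stop(sprintf("cannot mkdir over existing file: %s", path), "fb_storage_error")
    add_dirs(path)
    invisible(TRUE)
  }
  be$delete <- function(path, recursive = FALSE) {
    if (!is.null(files[[path]])) {
      rm(list = path, envir = files)
    } else if (isTRUE(dirs[[path]])) {
      prefix <- paste0(path, "/")
      under <- c(ls(files)[startsWith(ls(files), prefix)],
                 ls(dirs)[startsWith(ls(dirs), prefix)])
      if (!recursive && length(under))
        fb_stop(sprintf("directory not empty: %s", path), "fb_storage_error")
      rm(list = intersect(under, ls(files)), envir = files)
      rm(list = c(intersect(under, ls(dirs)), path), envir = dirs)
    } else {
      stop_notfound(sprintf("no such path: %s", path))
    }
    invisible(TRUE)
  }
  be$size <- function(path) {
    if (is.null(files[[path]])) stop_notfound(sprintf("no such file: %s", path))
    length(content(path))
  }
  be$read_open <- function(path) {
    if (is.null(files[[path]])) stop_notfound(sprintf("no such file: %s", path))
    buf <- content(path)
    pos <- 0L
    list(read = function(n) {
      if (pos >= length(buf)) return(NULL)
      end <- min(pos + n, length(buf))
      chunk <- buf[(pos + 1L):end]
      pos <<- end
      chunk
    }, close = function() invisible(NULL))
  }
  be$write_open <- function(path) {
    add_dirs(dirname(path))
    acc <- list()
    list(write = function(chunk) acc[[length(acc) + 1L]] <<- chunk,
         close = function() {
           files[[path]] <- acc
           mtimes[[path]] <- as.numeric(Sys.time())
         },
         abort = function() invisible(NULL))
  }
  be$digest <- function(path) {
    if (is.null(files[[path]])) stop_notfound(sprintf("no such file: %s", path))
    sha256_hex(content(path))
  }
  class(be) <- "fb_storage_backend"
  be
}

#' Wrap a storage backend with transfer instrumentation
#'
#' Records, in `backend$stats`, the number of chunks and bytes read and
#' written through the backend and the largest single chunk seen. Used to
#' verify the streaming-copy contract (bounded in-flight buffer, no spooling).
#'
#' @param backend A storage backend object.
#' @return The same backend, with instrumented `read_open`/`write_open` and a
#'   `stats` environment (`bytes_read`, `bytes_written`, `max_chunk`,
#'   `chunks`).
#' @export
storage_instrumented <- function(backend) {
  stats <- new.env(parent = emptyenv())
  stats$bytes_read <- 0; stats$bytes_written <- 0
  stats$max_chunk <- 0; stats$chunks <- 0
  ro <- backend$read_open; wo <- backend$write_open
  backend$read_open <- function(path) {
    h <- ro(path)
    list(read = function(n) {
      chunk <- h$read(n)
      if (!is.null(chunk)) {
        stats$bytes_read <- stats$bytes_read + length(chunk)
        stats$max_chunk <- max(stats$max_chunk, length(chunk))
        stats$chunks <- stats$chunks + 1
      }
      chunk
    }, close = h$close)
  }
  backend$write_open <- function(path) {
    h <- wo(path)
    list(write = function(chunk) {
      stats$bytes_written <- stats$bytes_written + length(chunk)
      stats$max_chunk <- max(stats$max_chunk, length(chunk))
      h$write(chunk)
    }, close = h$close, abort = h$abort)
  }
  backend$stats <- stats
  backend
}
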