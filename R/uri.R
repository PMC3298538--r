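#' Scheme-addressed resource locations
#'
#' Every file the engine touches is addressed by a URI of the form
#' `scheme://[user@]host[/path]`; the scheme selects the storage (or compute)
#' backend that services the operation. Two bundled schemes are
#' `file:///abs/path` (local filesystem, empty host) and `mem://name/path`
#' (named in-memory filesystem). Paths are normalised at construction: `//`
#' collapses, `.` segments are dropped, and any path that still escapes the
#' root through `..` after normalisation is rejected.
#'
#' @param scheme URI scheme, e.g. `"file"` or `"mem"`.
#' @param host Host (or in-memory store name); may be `""`.
#' @param path Absolute path component, beginning with `/`.
#' @param user Optional user component.
#' @return An object of class `fb_uri`.
#' @examples
#' u <- uri_parse("mem://data/in/seq1.fa")
#' u$scheme
#' format(u)
#' @export
uri <- function(scheme, host = "", path = "/", user = NULL) {
  if (!nzchar(scheme)) stop_validation("URI scheme must be non-empty")
  structure(
    list(scheme = scheme, user = user, host = host,
         path = normalize_uri_path(path)),
    class = "fb_uri"
  )
}

#' Parse a URI string
#'
#' @param x A URI string such as `"ssh://alice@host.example/data/x.fa"`, or an
#'   `fb_uri` (returned unchanged).
#' @return An `fb_uri` object.
#' @export
uri_parse <- function(x) {
  if (inherits(x, "fb_uri")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_validation("URI must be a single string")
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9+.-]*)://(([^/@]+)@)?([^/]*)(/.*)?$", x))[[1]]
  if (length(m) == 0L)
    stop_validation(sprintf("malformed URI: '%s'", x))
  uri(scheme = m[2],
      user = if (nzchar(m[4])) m[4] else NULL,
      host = m[5],
      path = if (nzchar(m[6])) m[6] else "/")
}

normalize_uri_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path))
    stop_validation("URI path must be a single string")
  if (!startsWith(path, "/")) path <- paste0("/", path)
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs) & segs != "."]
  out <- character(0)
  for (s in segs) {
    if (s == "..") {
      if (length(out) == 0L)
        stop_validation(sprintf("URI path escapes root: '%s'", path))
      out <- out[-length(out)]
    } else {
      out <- c(out, s)
    }
  }
  paste0("/", paste(out, collapse = "/"))
}

#' @export
format.fb_uri <- function(x, ...) {
  auth <- if (is.null(x$user)) x$host else paste0(x$user, "@", x$host)
  paste0(x$scheme, "://", auth, if (x$path == "/") "" else x$path)
}

#' @export
print.fb_uri <- function(x, ...) {
  cat("<uri> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.fb_uri <- function(x, ...) format(x)

#' Append path components to a URI
#' @param u An `fb_uri` or URI string.
#' @param ... Character path components to append.
#' @return A new `fb_uri`.
#' @export
uri_join <- function(u, ...) {
  u <- uri_parse(u)
  parts <- unlist(list(...), use.names = FALSE)
  uri(u$scheme, u$host, paste(c(u$path, parts), collapse = "/"), u$user)
}

#' Basename / parent of a URI path
#' @param u An `fb_uri` or URI string.
#' @return `uri_basename()`: the final path component; `uri_parent()`: an
#'   `fb_uri` addressing the containing directory.
#' @export
uri_basename <- function(u) basename(uri_parse(u)$path)

#' @rdname uri_basename
#' @export
uri_parent <- function(u) {
  u <- uri_parse(u)
  uri(u$scheme, u$host, dirname(u$path), u$user)
}
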