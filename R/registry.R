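#' Tool and backend registry
#'
#' The administration layer of the engine is purely declarative: a single
#' config document with `tools`, `backends` and `users` sections describes
#' every runnable program (command template, ordered parameters, accepted and
#' produced file-type patterns, execution backend, result location), every
#' storage/compute backend, and per-user access grants. Adding a tool is a
#' config edit, never a code change. JSON is canonical; YAML is accepted.
#' The schema is strict: unknown keys are rejected, since silent typos in
#' tool configs are the main admin hazard.
#'
#' @name registry
#' @keywords internal
NULL

.fb_plugins <- new.env(parent = emptyenv())

#' Register a storage or compute scheme plug-in
#'
#' Backends are pluggable: a scheme is served by a factory function taking the
#' backend descriptor and returning a backend object. The bundled schemes are
#' `file` and `mem` (storage) and `localexec` and `mockq` (compute); third
#' parties can add e.g. an SFTP driver without touching the engine.
#'
#' @param scheme URI scheme (storage) or backend kind id (compute).
#' @param factory Function of one argument (the backend descriptor).
#' @return Invisibly, the scheme name.
#' @export
register_storage_scheme <- function(scheme, factory) {
  .fb_plugins$storage[[scheme]] <- factory
  invisible(scheme)
}

#' @rdname register_storage_scheme
#' @export
register_compute_scheme <- function(scheme, factory) {
  .fb_plugins$compute[[scheme]] <- factory
  invisible(scheme)
}

supported_schemes <- function(kind) names(.fb_plugins[[kind]])

known_keys <- list(
  top     = c("schema_version", "tools", "backends", "users"),
  backend = c("id", "kind", "scheme", "endpoint", "requires_credential",
              "reachable", "options"),
  tool    = c("name", "program", "exec_backend", "output_location",
              "params", "produces"),
  param   = c("name", "switch", "mandatory", "accepts", "batchable",
              "source_kind", "default"),
  user    = c("name", "tools", "backends")
)

check_keys <- function(x, what, where) {
  extra <- setdiff(names(x), known_keys[[what]])
  if (length(extra))
    stop_config(sprintf("unknown %s key(s) %s in %s", what,
                        paste(sprintf("'%s'", extra), collapse = ", "), where))
}

#' Load and validate a registry config
#'
#' @param config_source Path to a `.json`/`.yaml`/`.yml` file, a JSON string,
#'   or an already-parsed list.
#' @return A validated object of class `fb_registry` with tools in declaration
#'   order and all cross-references (exec backends, grants) resolved.
#' @examples
#' cfg <- list(schema_version = 1,
#'   backends = list(list(id = "localexec", kind = "compute",
#'                        scheme = "localexec", endpoint = "")),
#'   tools = list(list(name = "wordcount", program = "wc",
#'                     exec_backend = "localexec",
#'                     params = list(list(name = "infile", mandatory = TRUE,
#'                                        accepts = list("*.txt"),
#'                                        source_kind = "input-file")),
#'                     produces = list("*.out"))),
#'   users = list(list(name = "alice", tools = list("wordcount"),
#'                     backends = list("localexec"))))
#' reg <- load_registry(cfg)
#' names(reg$tools)
#' @export
load_registry <- function(config_source) {
  x <- read_config_document(config_source)
  check_keys(x, "top", "config root")
  ver <- x$schema_version
  if (is.null(ver) || !identical(as.integer(ver), 1L))
    stop_config(sprintf("unrecognised schema_version '%s' (supported: 1)",
                        ver %||% "<missing>"))

  backends <- lapply(x$backends %||% list(), parse_backend)
  ids <- vapply(backends, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_config(sprintf("duplicate backend id '%s'", ids[duplicated(ids)][1]))
  names(backends) <- ids

  tools <- lapply(x$tools %||% list(), parse_tool, backends = backends)
  tnames <- vapply(tools, `[[`, "", "name")
  if (anyDuplicated(tnames))
    stop_config(sprintf("duplicate tool name '%s'", tnames[duplicated(tnames)][1]))
  names(tools) <- tnames

  users <- lapply(x$users %||% list(), parse_user,
                  tool_names = tnames, backend_ids = ids)
  unames <- vapply(users, `[[`, "", "name")
  if (anyDuplicated(unames))
    stop_config(sprintf("duplicate user '%s'", unames[duplicated(unames)][1]))
  names(users) <- unames

  structure(list(schema_version = 1L, tools = tools, backends = backends,
                 users = users),
            class = "fb_registry")
}

read_config_document <- function(src) {
  if (is.list(src)) return(src)
  if (!is.character(src) || length(src) != 1L)
    stop_config("config source must be a path, a JSON string, or a list")
  if (file.exists(src)) {
    ext <- tolower(tools::file_ext(src))
    if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(src))
    return(jsonlite::fromJSON(src, simplifyVector = FALSE))
  }
  jsonlite::fromJSON(src, simplifyVector = FALSE)
}

parse_backend <- function(b) {
  check_keys(b, "backend", sprintf("backend '%s'", b$id %||% "<unnamed>"))
  for (f in c("id", "kind", "scheme"))
    if (!is.character(b[[f]] %||% NULL) || !nzchar(b[[f]]))
      stop_config(sprintf("backend field '%s' missing or empty in backend '%s'",
                          f, b$id %||% "<unnamed>"))
  if (!b$kind %in% c("storage", "compute"))
    stop_config(sprintf("backend '%s': kind must be storage or compute", b$id))
  if (!b$scheme %in% supported_schemes(b$kind))
    stop_config(sprintf(
      "backend '%s': no registered %s plug-in for scheme '%s'",
      b$id, b$kind, b$scheme))
  list(id = b$id, kind = b$kind, scheme = b$scheme,
       endpoint = b$endpoint %||% "",
       requires_credential = isTRUE(b$requires_credential),
       reachable = !isFALSE(b$reachable),
       options = b$options %||% list())
}

parse_param <- function(p, tool) {
  check_keys(p, "param", sprintf("param '%s' of tool '%s'",
                                 p$name %||% "<unnamed>", tool))
  if (!is.character(p$name %||% NULL) || !nzchar(p$name))
    stop_config(sprintf("param without a name in tool '%s'", tool))
  accepts <- as.character(unlist(p$accepts %||% list()))
  for (pat in accepts) glob_to_regex(pat)   # validates
  sk <- p$source_kind %||% "user-literal"
  if (!sk %in% c("user-literal", "previous-job-output", "input-file"))
    stop_config(sprintf("param '%s' of tool '%s': invalid source_kind '%s'",
                        p$name, tool, sk))
  batchable <- isTRUE(p$batchable)
  if (batchable && length(accepts) == 0L)
    stop_config(sprintf(
      "param '%s' of tool '%s': batchable requires non-empty accepts",
      p$name, tool))
  if (sk == "previous-job-output" && length(accepts) == 0L)
    stop_config(sprintf(
      "param '%s' of tool '%s': previous-job-output requires accepts patterns",
      p$name, tool))
  list(name = p$name, switch = p$switch %||% "",
       mandatory = isTRUE(p$mandatory), accepts = accepts,
       batchable = batchable, source_kind = sk,
       default = p$default %||% NULL)
}

parse_tool <- function(t, backends) {
  check_keys(t, "tool", sprintf("tool '%s'", t$name %||% "<unnamed>"))
  for (f in c("name", "program", "exec_backend"))
    if (!is.character(t[[f]] %||% NULL) || !nzchar(t[[f]]))
      stop_config(sprintf("tool field '%s' missing or empty in tool '%s'",
                          f, t$name %||% "<unnamed>"))
  be <- backends[[t$exec_backend]]
  if (is.null(be))
    stop_config(sprintf("tool '%s': exec_backend '%s' is not a registered backend",
                        t$name, t$exec_backend))
  if (be$kind != "compute")
    stop_config(sprintf("tool '%s': exec_backend '%s' is not a compute backend",
                        t$name, t$exec_backend))
  params <- lapply(t$params %||% list(), parse_param, tool = t$name)
  pnames <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(pnames))
    stop_config(sprintf("tool '%s': duplicate param '%s'", t$name,
                        pnames[duplicated(pnames)][1]))
  names(params) <- pnames
  # every {placeholder} in the program template must name exactly one param
  holes <- regmatches(t$program, gregexpr("\\{[A-Za-z0-9_]+\\}", t$program))[[1]]
  holes <- gsub("[{}]", "", holes)
  bad <- setdiff(holes, pnames)
  if (length(bad))
    stop_config(sprintf("tool '%s': program placeholder '{%s}' has no matching param",
                        t$name, bad[1]))
  produces <- as.character(unlist(t$produces %||% list()))
  for (pat in produces) glob_to_regex(pat)
  list(name = t$name, program = t$program, exec_backend = t$exec_backend,
       output_location = t$output_location %||% NULL,
       params = params, produces = produces)
}

parse_user <- function(u, tool_names, backend_ids) {
  check_keys(u, "user", sprintf("user '%s'", u$name %||% "<unnamed>"))
  if (!is.character(u$name %||% NULL) || !nzchar(u$name))
    stop_config("user without a name in config")
  tl <- as.character(unlist(u$tools %||% list()))
  bl <- as.character(unlist(u$backends %||% list()))
  bad_t <- setdiff(tl, tool_names)
  if (length(bad_t))
    stop_config(sprintf("user '%s': grant references unknown tool '%s'",
                        u$name, bad_t[1]))
  bad_b <- setdiff(bl, backend_ids)
  if (length(bad_b))
    stop_config(sprintf("user '%s': grant references unknown backend '%s'",
                        u$name, bad_b[1]))
  list(name = u$name, tools = tl, backends = bl)
}

#' @export
print.fb_registry <- function(x, ...) {
  cat(sprintf("<registry> %d tool(s), %d backend(s), %d user(s)\n",
              length(x$tools), length(x$backends), length(x$users)))
  if (length(x$tools))
    cat(" tools:", paste(names(x$tools), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a registry back to its config form
#'
#' `registry_to_list()` produces the plain-list document; loading it with
#' [load_registry()] round-trips field by field. `write_registry()` writes it
#' as canonical JSON.
#'
#' @param registry An `fb_registry`.
#' @param path Output file path.
#' @return `registry_to_list()`: a list; `write_registry()`: `path`, invisibly.
#' @export
registry_to_list <- function(registry) {
  list(
    schema_version = 1L,
    backends = unname(lapply(registry$backends, function(b)
      list(id = b$id, kind = b$kind, scheme = b$scheme, endpoint = b$endpoint,
           requires_credential = b$requires_credential,
           reachable = b$reachable, options = b$options))),
    tools = unname(lapply(registry$tools, function(t)
      Filter(Negate(is.null), list(
        name = t$name, program = t$program, exec_backend = t$exec_backend,
        output_location = t$output_location,
        params = unname(lapply(t$params, function(p)
          Filter(Negate(is.null), list(
            name = p$name, switch = p$switch, mandatory = p$mandatory,
            accepts = as.list(p$accepts), batchable = p$batchable,
            source_kind = p$source_kind, default = p$default)))),
        produces = as.list(t$produces))))),
    users = unname(lapply(registry$users, function(u)
      list(name = u$name, tools = as.list(u$tools),
           backends = as.list(u$backends))))
  )
}

#' @rdname registry_to_list
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(registry_to_list(registry), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Tools granted to a user
#'
#' @param registry An `fb_registry`.
#' @param user User name.
#' @return The granted tool specs, in registry declaration order.
#' @export
tools_for_user <- function(registry, user) {
  u <- registry$users[[user]]
  if (is.null(u)) stop_notfound(sprintf("unknown user '%s'", user))
  registry$tools[names(registry$tools) %in% u$tools]
}

#' Export the tool list for a user as JSON
#'
#' Mirrors the middleware's JSON tool listing consumed by clients: each entry
#' carries the tool name, backend and full parameter metadata.
#'
#' @param registry An `fb_registry`.
#' @param user User name (`NULL` for all tools).
#' @return A JSON string.
#' @export
export_tools_json <- function(registry, user = NULL) {
  tl <- if (is.null(user)) registry$tools else tools_for_user(registry, user)
  jsonlite::toJSON(unname(lapply(tl, function(t) list(
    name = t$name, backend = t$exec_backend,
    params = unname(lapply(t$params, function(p) list(
      name = p$name, switch = p$switch, mandatory = p$mandatory,
      accepts = as.list(p$accepts), batchable = p$batchable,
      source_kind = p$source_kind))),
    produces = as.list(t$produces)))),
    auto_unbox = TRUE)
}

#' Preflight a tool against its backends
#'
#' Admin convenience: reports (without failing) whether the tool's execution
#' backend is reachable and whether any backend it needs demands a credential
#' that is not stored for the given user.
#'
#' @param registry An `fb_registry`.
#' @param tool Tool name.
#' @param vault Optional credential vault (see [credential_vault()]).
#' @param user User whose credentials are checked (default `NULL`: skip the
#'   credential check unless the vault is given).
#' @return A data frame with columns `backend_id` and `finding`; zero rows
#'   when nothing is wrong.
#' @export
validate_tool_against_backends <- function(registry, tool, vault = NULL,
                                           user = NULL) {
  t <- registry$tools[[tool]]
  if (is.null(t)) stop_notfound(sprintf("unknown tool '%s'", tool))
  be <- registry$backends[[t$exec_backend]]
  findings <- data.frame(backend_id = character(0), finding = character(0),
                         stringsAsFactors = FALSE)
  add <- function(id, msg)
    rbind(findings, data.frame(backend_id = id, finding = msg,
                               stringsAsFactors = FALSE))
  if (!be$reachable)
    findings <- add(be$id, "backend unreachable")
  if (be$requires_credential && !is.null(vault) && !is.null(user) &&
      !vault_has(vault, user, be$id, stored_ok = TRUE))
    findings <- add(be$id, "credential missing")
  findings
}
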