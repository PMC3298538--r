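#' File-type patterns: unix-style filename globs
#'
#' File types are declared as unix-style filename matching patterns
#' (`*.fa`, `seq?.txt`, `[ab]*.qual`). The dialect is deliberately narrow:
#' `*` matches any run of characters (including none), `?` any single
#' character, and `[...]` a character class (`[!...]` or `[^...]` negates;
#' ranges like `a-z` work). There is no `**`, matching is case-sensitive and
#' applies to the basename of a path.
#'
#' @param pattern A glob pattern string.
#' @return `glob_to_regex()` returns an anchored POSIX regular expression
#'   string equivalent to the glob.
#' @examples
#' glob_to_regex("*.fa")
#' match_files(c("s1.fa", "s2.fa", "notes.txt"), "*.fa")
#' @export
glob_to_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      !nzchar(pattern))
    stop_pattern("glob pattern must be a non-empty string")
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  out <- "^"
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "*") {
      out <- paste0(out, ".*")
    } else if (ch == "?") {
      out <- paste0(out, ".")
    } else if (ch == "[") {
      # scan to the closing bracket; ']' directly after '[' (or negation) is literal
      j <- i + 1L
      if (j <= n && (chars[j] == "!" || chars[j] == "^")) j <- j + 1L
      if (j <= n && chars[j] == "]") j <- j + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop_pattern(sprintf("unterminated character class in glob '%s'", pattern))
      cls <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (startsWith(cls, "!")) cls <- paste0("^", substring(cls, 2L))
      # escape regex-significant characters inside the class except '-' and leading '^'
      out <- paste0(out, "[", gsub("\\\\", "\\\\\\\\", cls), "]")
      i <- j
    } else {
      out <- paste0(out, if (grepl("[][.\\^$*+?()|{}]", ch, perl = TRUE))
        paste0("\\", ch) else ch)
    }
    i <- i + 1L
  }
  paste0(out, "$")
}

#' Select the filenames satisfying a file-type pattern
#'
#' Returns the filenames whose *basename* matches the glob, preserving the
#' input order. This is the primitive used for dependency resolution: any file
#' matching a tool parameter's pattern can satisfy that parameter.
#'
#' @param filenames Character vector of file names or paths.
#' @param pattern A glob pattern (see [glob_to_regex()]).
#' @return The matching subset of `filenames`, in input order.
#' @export
match_files <- function(filenames, pattern) {
  rx <- glob_to_regex(pattern)
  if (length(filenames) == 0L) return(character(0))
  filenames[grepl(rx, basename(filenames))]
}

# does basename(name) match any of the patterns?
matches_any <- function(name, patterns) {
  if (length(patterns) == 0L) return(TRUE)
  any(vapply(patterns, function(p) length(match_files(name, p)) > 0L, logical(1)))
}
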