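#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions and substitutions each cost
#' 1) between two strings. This is the criterion the engine uses to group
#' input files of different types into tasks: when a tool takes, say, a `.fa`
#' and a `.qual` file, the files whose names are closest in edit distance are
#' paired together.
#'
#' @param a,b Single strings.
#' @return A non-negative integer: the minimum number of single-character
#'   edits transforming `a` into `b`.
#' @examples
#' levenshtein("kitten", "sitting")
#' levenshtein("s1.fa", "s1.qual")
#' @export
levenshtein <- function(a, b) {
  if (!is.character(a) || length(a) != 1L || is.na(a) ||
      !is.character(b) || length(b) != 1L || is.na(b))
    stop_validation("levenshtein() expects two single strings")
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0L:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

lev_matrix <- function(a, b) {
  out <- matrix(0L, length(a), length(b), dimnames = list(a, b))
  for (i in seq_along(a))
    for (j in seq_along(b))
      out[i, j] <- levenshtein(a[i], b[j])
  out
}

#' Pair input files of two types by minimum total edit distance
#'
#' Produces a one-to-one pairing over `min(|A|, |B|)` pairs that minimises the
#' *total* Levenshtein distance between paired names. For groups whose larger
#' side has at most `exact_limit` members the minimum is found exactly
#' (subset dynamic programming over the smaller-side assignment); above that a
#' greedy nearest-pair strategy is used, since real batches are small. Among
#' equally cheap assignments the lexicographically smallest pair list wins.
#' Unpaired leftovers from the longer group are reported, never silently
#' dropped.
#'
#' @param group_a,group_b Non-empty character vectors of file names.
#' @param exact_limit Largest group size for which the exact assignment is
#'   computed (default 12).
#' @return A list of class `fb_pairing` with elements `pairs` (data frame with
#'   columns `a`, `b`, `distance`, sorted by `a`), `total_distance`,
#'   `leftovers` (unpaired names) and `method` (`"exact"` or `"greedy"`).
#' @examples
#' pair_inputs(c("s1.fa", "s2.fa"), c("s2.qual", "s1.qual"))
#' @export
pair_inputs <- function(group_a, group_b, exact_limit = 12L) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_validation("pair_inputs() requires two non-empty groups")
  A <- sort(group_a); B <- sort(group_b)
  exact <- max(length(A), length(B)) <= exact_limit
  res <- if (exact) pair_exact(A, B) else pair_greedy(A, B)
  paired_a <- res$pairs$a; paired_b <- res$pairs$b
  leftovers <- c(setdiff_multi(A, paired_a), setdiff_multi(B, paired_b))
  structure(
    list(pairs = res$pairs, total_distance = sum(res$pairs$distance),
         leftovers = leftovers, method = if (exact) "exact" else "greedy"),
    class = "fb_pairing"
  )
}

#' @export
print.fb_pairing <- function(x, ...) {
  cat(sprintf("<pairing> %d pair(s), total distance %d (%s)\n",
              nrow(x$pairs), x$total_distance, x$method))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  if (length(x$leftovers))
    cat("unpaired:", paste(x$leftovers, collapse = ", "), "\n")
  invisible(x)
}

# multiset difference preserving duplicates
setdiff_multi <- function(x, drop) {
  for (d in drop) {
    i <- match(d, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

# exact min-cost assignment; A and B sorted. Pairs every member of the
# smaller group. DP over (position in A, bitmask of used B) with a skip
# budget of |A| - |B| when A is longer.
pair_exact <- function(A, B) {
  d <- lev_matrix(A, B)
  n <- length(A); m <- length(B)
  max_skip <- max(0L, n - m)
  memo <- new.env(parent = emptyenv())
  n_used <- function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
  cost <- function(i, mask) {
    if (i > n) return(0)
    key <- paste0(i, ":", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    used <- n_used(mask)
    skips_used <- (i - 1L) - used
    best <- Inf
    if (used < m) {
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          v <- d[i, j] + cost(i + 1L, bitwOr(mask, bit))
          if (v < best) best <- v
        }
      }
    }
    if (skips_used < max_skip) {
      v <- cost(i + 1L, mask)
      if (v < best) best <- v
    }
    memo[[key]] <- best
    best
  }
  total <- cost(1L, 0L)
  # lexicographically minimal reconstruction: pair the earliest a with the
  # smallest b that preserves optimality; skip only when pairing cannot
  pa <- character(0); pb <- character(0); pd <- integer(0)
  mask <- 0L
  for (i in seq_len(n)) {
    remaining <- cost(i, mask)
    chosen <- NA_integer_
    if (n_used(mask) < m) {
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L &&
            d[i, j] + cost(i + 1L, bitwOr(mask, bit)) == remaining) {
          chosen <- j
          break
        }
      }
    }
    if (!is.na(chosen)) {
      pa <- c(pa, A[i]); pb <- c(pb, B[chosen]); pd <- c(pd, d[i, chosen])
      mask <- bitwOr(mask, bitwShiftL(1L, chosen - 1L))
    }
  }
  list(pairs = data.frame(a = pa, b = pb, distance = pd,
                          stringsAsFactors = FALSE))
}

pair_greedy <- function(A, B) {
  d <- lev_matrix(A, B)
  pa <- character(0); pb <- character(0); pd <- integer(0)
  avail_a <- rep(TRUE, length(A)); avail_b <- rep(TRUE, length(B))
  for (k in seq_len(min(length(A), length(B)))) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in which(avail_a)) {
      for (j in which(avail_b)) {
        if (d[i, j] < best ||
            (d[i, j] == best && (A[i] < A[bi] || (A[i] == A[bi] && B[j] < B[bj])))) {
          best <- d[i, j]; bi <- i; bj <- j
        }
      }
    }
    pa <- c(pa, A[bi]); pb <- c(pb, B[bj]); pd <- c(pd, best)
    avail_a[bi] <- FALSE; avail_b[bj] <- FALSE
  }
  ord <- order(pa, pb)
  list(pairs = data.frame(a = pa[ord], b = pb[ord], distance = pd[ord],
                          stringsAsFactors = FALSE))
}
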