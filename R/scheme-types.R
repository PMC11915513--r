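#' Construct a single search
#'
#' A search is the atomic unit of a search scheme: a triplet consisting of a
#' part order \code{pi}, a vector of cumulative lower error bounds \code{L}
#' and a vector of cumulative upper error bounds \code{U}, all of length
#' \code{p} (the number of query parts). The part order prescribes in which
#' order the parts of a partitioned query are matched in a bidirectional
#' index; the bounds constrain the number of accumulated errors after each
#' part has been matched.
#'
#' A search is \emph{valid} when
#' \itemize{
#'   \item \code{order} is a permutation of \code{0..p-1},
#'   \item it satisfies the \emph{connectivity property}: every part index
#'     must extend the contiguous range of already-searched parts by one on
#'     the left or on the right (so the search is executable by left/right
#'     extensions in a bidirectional index),
#'   \item \code{lower} and \code{upper} are monotonously non-decreasing, and
#'   \item \code{upper[t] >= lower[t]} at every step \code{t}.
#' }
#'
#' @param order integer vector, 0-based part indices in search order.
#' @param lower integer vector, cumulative lower error bounds per step.
#' @param upper integer vector, cumulative upper error bounds per step.
#' @return An object of class \code{ss_search}.
#' @examples
#' make_search(c(1, 0, 2), c(0, 0, 0), c(0, 2, 2))
#' @export
make_search <- function(order, lower, upper) {
  order <- as.integer(order)
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  s <- structure(
    list(order = order, lower = lower, upper = upper,
         p = length(order)),
    class = "ss_search")
  bad <- validate_search(s)
  if (length(bad) > 0L)
    stop("invalid search: ", paste(bad, collapse = "; "), call. = FALSE)
  s
}

#' Validate a search triplet
#'
#' Returns a character vector of violations (empty when the search is valid).
#' Each finding names the broken rule and the offending 0-based step index.
#'
#' @param s an \code{ss_search}, or a bare list with \code{order},
#'   \code{lower}, \code{upper} entries.
#' @return character vector of human-readable findings.
#' @export
validate_search <- function(s) {
  order <- as.integer(s$order)
  lower <- as.integer(s$lower)
  upper <- as.integer(s$upper)
  p <- length(order)
  out <- character()
  if (p < 1L)
    return("empty search (p must be >= 1)")
  if (length(lower) != p || length(upper) != p)
    return(sprintf("length mismatch: order %d, lower %d, upper %d",
                   p, length(lower), length(upper)))
  if (anyNA(order) || anyNA(lower) || anyNA(upper))
    return("NA values are not allowed")
  if (!setequal(order, 0:(p - 1L)))
    out <- c(out, sprintf("order is not a permutation of 0..%d", p - 1L))
  else if (p > 1L) {
    lo <- order[1L]; hi <- order[1L]
    for (t in 2:p) {
      nxt <- order[t]
      if (nxt == hi + 1L) hi <- nxt
      else if (nxt == lo - 1L) lo <- nxt
      else {
        out <- c(out, sprintf(
          "connectivity violated at step %d: part %d is neither max+1 nor min-1",
          t - 1L, nxt))
        break
      }
    }
  }
  if (p > 1L) {
    dl <- diff(lower)
    if (any(dl < 0L))
      out <- c(out, sprintf("lower bounds not monotone at step %d",
                            which(dl < 0L)[1L]))
    du <- diff(upper)
    if (any(du < 0L))
      out <- c(out, sprintf("upper bounds not monotone at step %d",
                            which(du < 0L)[1L]))
  }
  if (any(lower < 0L))
    out <- c(out, sprintf("negative lower bound at step %d",
                          which(lower < 0L)[1L] - 1L))
  if (any(upper < lower))
    out <- c(out, sprintf("upper < lower at step %d",
                          which(upper < lower)[1L] - 1L))
  out
}

#' Construct a search scheme
#'
#' A search scheme is a named collection of searches over a common number of
#' parts \code{p}, designed to cover all distributions of at most \code{k}
#' errors over the parts (see [check_scheme()]).
#'
#' @param searches list of [make_search()] results (or bare
#'   order/lower/upper lists, which are validated here).
#' @param k maximum number of errors the scheme is meant to cover.
#' @param name label used in printing and in the JSON representation.
#' @return An object of class \code{search_scheme}.
#' @export
search_scheme <- function(searches, k, name = "scheme") {
  stopifnot(k >= 0, length(searches) >= 0)
  searches <- lapply(searches, function(s) {
    if (inherits(s, "ss_search")) s
    else make_search(s$order, s$lower, s$upper)
  })
  p <- if (length(searches)) searches[[1L]]$p else 0L
  for (s in searches)
    if (s$p != p)
      stop("all searches in a scheme must have the same number of parts",
           call. = FALSE)
  structure(
    list(name = as.character(name), k = as.integer(k), p = as.integer(p),
         searches = searches),
    class = "search_scheme")
}

#' @export
print.ss_search <- function(x, ...) {
  sep <- if (x$p > 0L && max(x$order, x$upper) > 9L) "," else ""
  fmt <- function(v) paste(v, collapse = sep)
  cat(sprintf("(%s, %s, %s)\n", fmt(x$order), fmt(x$lower), fmt(x$upper)))
  invisible(x)
}

#' @export
print.search_scheme <- function(x, ...) {
  cat(sprintf("Search scheme '%s': k = %d, p = %d, %d search(es)\n",
              x$name, x$k, x$p, length(x$searches)))
  for (i in seq_along(x$searches)) {
    cat(sprintf("  s%-2d ", i - 1L))
    print(x$searches[[i]])
  }
  invisible(x)
}

#' @export
format.search_scheme <- function(x, ...) {
  sprintf("<search_scheme '%s' k=%d p=%d |S|=%d>",
          x$name, x$k, x$p, length(x$searches))
}

# internal: searches as a set of canonical strings, for set comparisons
scheme_signature <- function(scheme) {
  sort(vapply(scheme$searches, function(s)
    paste(c(s$order, NA, s$lower, NA, s$upper), collapse = ","), ""))
}

#' Compare two schemes as sets of searches
#'
#' Two schemes are considered equal when they consist of the same searches
#' (order/lower/upper triplets), irrespective of the order in which the
#' searches are listed and of the scheme name.
#'
#' @param a,b search schemes.
#' @return logical.
#' @export
same_scheme <- function(a, b) {
  identical(scheme_signature(a), scheme_signature(b))
}
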