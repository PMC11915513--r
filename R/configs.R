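#' Enumerate error configurations
#'
#' An error configuration assigns a non-negative error count to each of the
#' \code{p} parts of a partitioned query. In \code{"exact"} mode the counts
#' sum to exactly \code{k}; in \code{"atmost"} mode (the default used for
#' completeness checking) all sums \code{0..k} are enumerated.
#'
#' The enumeration is deterministic: configurations are returned in
#' lexicographic order of their count vectors.
#'
#' @param k maximum (or exact) total number of errors, \code{k >= 0}.
#' @param p number of parts, \code{p >= 1}.
#' @param mode \code{"atmost"} (sum <= k) or \code{"exact"} (sum == k).
#' @param ceiling guard against combinatorial blow-up; an error is raised
#'   when the number of configurations would exceed it.
#' @return integer matrix with one configuration per row, \code{p} columns.
#' @examples
#' enumerate_configs(2, 3, "exact")  # 6 rows
#' enumerate_configs(2, 3, "atmost") # 10 rows
#' @export
enumerate_configs <- function(k, p, mode = c("atmost", "exact"),
                              ceiling = 5e6) {
  mode <- match.arg(mode)
  stopifnot(k >= 0, p >= 1)
  n <- if (mode == "atmost") choose(k + p, p) else choose(k + p - 1, p - 1)
  if (n > ceiling)
    stop(sprintf("enumeration of %.0f configurations exceeds ceiling %.0f",
                 n, ceiling), call. = FALSE)
  grid <- enum_atmost(as.integer(k), as.integer(p))
  if (mode == "exact")
    grid <- grid[rowSums(grid) == k, , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

# internal: all length-p vectors with non-negative entries summing to <= k,
# in lexicographic order (first part varies slowest)
enum_atmost <- function(k, p) {
  if (p == 1L)
    return(matrix(0:k, ncol = 1L))
  do.call(rbind, lapply(0:k, function(v)
    cbind(v, enum_atmost(k - v, p - 1L), deparse.level = 0L)))
}

#' Does a search cover an error configuration?
#'
#' A search covers a configuration when, for every prefix of its part order,
#' the accumulated error count lies within the search's cumulative bounds:
#' \code{lower[t] <= sum(errors[order[0..t]]) <= upper[t]} for every step
#' \code{t}.
#'
#' @param search an [make_search()] object.
#' @param config integer vector of per-part error counts (part index order,
#'   not search order), length \code{p}.
#' @return logical.
#' @examples
#' s <- make_search(c(1, 0, 2), c(0, 0, 0), c(0, 2, 2))
#' covers(s, c(1, 0, 1)) # TRUE: cumulative sums along the order are 0, 1, 2
#' @export
covers <- function(search, config) {
  if (length(config) != search$p)
    stop("configuration length does not match the search's number of parts",
         call. = FALSE)
  cum <- cumsum(config[search$order + 1L])
  all(cum >= search$lower & cum <= search$upper)
}

# internal: vectorized coverage of a configuration matrix by one search.
# configs: n x p integer matrix. Returns logical vector of length n.
covers_matrix <- function(search, configs) {
  cum <- configs[, search$order + 1L, drop = FALSE]
  if (ncol(cum) > 1L)
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1L]
  lo <- matrix(search$lower, nrow(cum), ncol(cum), byrow = TRUE)
  hi <- matrix(search$upper, nrow(cum), ncol(cum), byrow = TRUE)
  rowSums(cum < lo | cum > hi) == 0L
}

#' Coverage set of a search
#'
#' Enumerates all error configurations (for a given \code{k} and mode) that
#' the search covers.
#'
#' @inheritParams enumerate_configs
#' @param search an [make_search()] object.
#' @return integer matrix of covered configurations, one per row.
#' @export
coverage_set <- function(search, k, mode = c("atmost", "exact"),
                         ceiling = 5e6) {
  mode <- match.arg(mode)
  configs <- enumerate_configs(k, search$p, mode, ceiling)
  configs[covers_matrix(search, configs), , drop = FALSE]
}

#' Check validity, completeness and redundancy of a search scheme
#'
#' A scheme is \emph{valid} when every member search passes the
#' [make_search()] rules; \emph{complete} (for a given \code{k} and
#' enumeration mode) when every error configuration is covered by at least
#' one search; and \emph{non-redundant} when no configuration is covered by
#' more than one search. For Hamming distance a complete and non-redundant
#' scheme reports each occurrence exactly once.
#'
#' Completeness is checked over all configurations with sum at most \code{k}
#' by default ("atmost"); \code{"exact"} restricts to sum equal to \code{k}.
#'
#' @param scheme a [search_scheme()].
#' @param k maximum errors; defaults to \code{scheme$k}.
#' @inheritParams enumerate_configs
#' @return An object of class \code{scheme_report}: a list with logical
#'   flags \code{valid}, \code{complete}, \code{nonredundant} and a character
#'   vector \code{violations} containing one finding per broken rule,
#'   including a witness configuration for incompleteness/redundancy.
#' @export
check_scheme <- function(scheme, k = scheme$k, mode = c("atmost", "exact"),
                         ceiling = 5e6) {
  mode <- match.arg(mode)
  violations <- character()
  valid <- TRUE
  for (i in seq_along(scheme$searches)) {
    bad <- validate_search(scheme$searches[[i]])
    if (length(bad)) {
      valid <- FALSE
      violations <- c(violations,
                      sprintf("search %d: %s", i - 1L,
                              paste(bad, collapse = "; ")))
    }
  }
  complete <- FALSE
  nonredundant <- FALSE
  if (scheme$p >= 1L && length(scheme$searches)) {
    configs <- enumerate_configs(k, scheme$p, mode, ceiling)
    ncover <- integer(nrow(configs))
    for (s in scheme$searches)
      ncover <- ncover + covers_matrix(s, configs)
    complete <- all(ncover >= 1L)
    nonredundant <- all(ncover <= 1L)
    if (!complete) {
      w <- configs[which(ncover == 0L)[1L], ]
      violations <- c(violations, sprintf(
        "incomplete: configuration (%s) is covered by no search",
        paste(w, collapse = ",")))
    }
    if (!nonredundant) {
      w <- configs[which(ncover > 1L)[1L], ]
      violations <- c(violations, sprintf(
        "redundant: configuration (%s) is covered by %d searches",
        paste(w, collapse = ","), max(ncover)))
    }
  } else {
    violations <- c(violations,
                    "incomplete: empty scheme covers no configuration")
  }
  structure(
    list(valid = valid, complete = complete, nonredundant = nonredundant,
         violations = violations),
    class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  flag <- function(b) if (b) "yes" else "NO"
  cat(sprintf("valid: %s   complete: %s   non-redundant: %s\n",
              flag(x$valid), flag(x$complete), flag(x$nonredundant)))
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  invisible(x)
}
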