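#' Inflate per-part bounds to per-character bounds
#'
#' A search constrains accumulated errors at part boundaries only. For node
#' counting the bounds are inflated to one value per query character, laid
#' out along the search order (the characters of the first searched part
#' come first, and so on).
#'
#' For character position \code{l} (1-based) inside the \code{t}-th searched
#' part:
#' \itemize{
#'   \item edit distance: \code{hi[l] = U[t]};
#'   \item Hamming distance: \code{hi[l] = min(U[t], hi[l-1] + 1)} with
#'     \code{hi[0] = 0}, since one character can contribute at most one
#'     mismatch;
#'   \item \code{lo[l] = L[t-1]} (with \code{L[0] = 0}) for all but the final
#'     position of the part, and \code{L[t]} at the part's final position: a
#'     part's lower bound is enforceable only once the part is complete.
#' }
#'
#' @param search an [make_search()] object.
#' @param partition integer vector of part sizes, left to right (part index
#'   order), e.g. from [uniform_partition()]; must have \code{p} parts.
#' @param distance \code{"hamming"} or \code{"edit"}.
#' @return list with integer vectors \code{lo} and \code{hi}, each of length
#'   \code{sum(partition)}.
#' @export
inflate_bounds <- function(search, partition,
                           distance = c("hamming", "edit")) {
  distance <- match.arg(distance)
  partition <- as.integer(partition)
  if (length(partition) != search$p)
    stop("partition must have one size per part", call. = FALSE)
  if (any(partition < 1L))
    stop("empty parts are not allowed", call. = FALSE)
  sizes <- partition[search$order + 1L]    # sizes along the search order
  n <- sum(sizes)
  lo <- integer(n)
  hi <- integer(n)
  pos <- 0L
  prev_l <- 0L
  prev_hi <- 0L
  for (t in seq_along(sizes)) {
    for (j in seq_len(sizes[t])) {
      pos <- pos + 1L
      lo[pos] <- if (j == sizes[t]) search$lower[t] else prev_l
      hi[pos] <- if (distance == "hamming")
        min(search$upper[t], prev_hi + 1L) else search$upper[t]
      prev_hi <- hi[pos]
    }
    prev_l <- search$lower[t]
  }
  list(lo = lo, hi = hi)
}

#' Per-level, per-error node count table of a single search
#'
#' Exposes the dynamic program behind [node_count()]: \code{n[l, d]} is the
#' number of nodes of the (unconstrained-text) backtracking trie visited at
#' level \code{l} with \code{d} accumulated errors, given the search's
#' inflated bounds. The recurrence is \code{n(l, d) = n(l-1, d) + b * n(l-1,
#' d-1)} with \code{n(0, 0) = 1}, restricted at every level to the window
#' \code{lo[l] <= d <= hi[l]}. The branch factor \code{b} is
#' \code{sigma - 1} for Hamming distance (substitutions) and \code{2 *
#' sigma} for edit distance (\code{sigma - 1} substitutions, \code{sigma}
#' insertions and one deletion, each consuming one level and one error).
#'
#' @inheritParams inflate_bounds
#' @param sigma alphabet size, \code{sigma >= 2}.
#' @return numeric matrix with \code{sum(partition)} rows (levels) and
#'   columns for \code{d = 0..max(upper)}; counts are exact integers stored
#'   as doubles.
#' @export
count_table <- function(search, partition, sigma,
                        distance = c("hamming", "edit")) {
  distance <- match.arg(distance)
  stopifnot(sigma >= 2)
  b <- if (distance == "hamming") sigma - 1 else 2 * sigma
  bounds <- inflate_bounds(search, partition, distance)
  n <- length(bounds$lo)
  kmax <- max(bounds$hi)
  tab <- matrix(0, nrow = n, ncol = kmax + 1L,
                dimnames = list(NULL, 0:kmax))
  prev <- c(1, rep(0, kmax))               # level 0: one root, zero errors
  for (l in seq_len(n)) {
    cur <- prev
    if (kmax >= 1L)
      cur[2:(kmax + 1L)] <- cur[2:(kmax + 1L)] + b * prev[1:kmax]
    d <- 0:kmax
    cur[d < bounds$lo[l] | d > bounds$hi[l]] <- 0
    tab[l, ] <- cur
    prev <- cur
  }
  tab
}

#' Node count of a search scheme
#'
#' The node count is an upper bound on the number of search steps: the total
#' number of nodes of the backtracking tries traversed by all searches of
#' the scheme, assuming every branch of the trie exists (infinite text). It
#' is additive over searches and is computed by summing the [count_table()]
#' of each search.
#'
#' @param scheme a [search_scheme()].
#' @param partition integer vector of part sizes (length \code{scheme$p}).
#' @param sigma alphabet size.
#' @inheritParams inflate_bounds
#' @return numeric scalar (an exact integer for all practical inputs).
#' @examples
#' node_count(scheme_backtracking(1), 50, sigma = 4, distance = "edit")
#' # 10250
#' @export
node_count <- function(scheme, partition, sigma,
                       distance = c("hamming", "edit")) {
  distance <- match.arg(distance)
  sum(vapply(scheme$searches, function(s)
    sum(count_table(s, partition, sigma, distance)), 0))
}

#' Weighted node count of a search scheme
#'
#' The plain node count assumes every branch of the backtracking trie is
#' visited, but a concrete text of length \code{|T|} contains at most
#' \code{|T| - l} distinct l-mers, while the trie offers \code{sigma^l}
#' branches at depth \code{l}. Below the depth threshold \code{l* =
#' ceiling(log_sigma |T|)} not all branches exist, so deep levels
#' overestimate the work. The weighted node count keeps levels \code{l <=
#' l*} unweighted and scales every counted node at level \code{l > l*} by a
#' weight in \code{(0, 1]}.
#'
#' The default weight policy is \code{min(1, (text_length - l) / sigma^l)},
#' the fraction of depth-l branches a text of that length can realize. The
#' policy is pluggable: pass a \code{function(l, text_length, sigma)}
#' returning a scalar weight to substitute a different model.
#'
#' @inheritParams node_count
#' @param text_length length of the indexed text, \code{>= sum(partition)}.
#' @param policy weight policy for levels beyond the threshold, or
#'   \code{NULL} for the default.
#' @return numeric scalar; always \code{<=} the plain [node_count()], and
#'   converging to it as \code{text_length} grows.
#' @export
weighted_node_count <- function(scheme, partition, sigma,
                                distance = c("hamming", "edit"),
                                text_length, policy = NULL) {
  distance <- match.arg(distance)
  if (text_length < sum(partition))
    stop("text_length must be at least the query length", call. = FALSE)
  if (is.null(policy))
    policy <- function(l, text_length, sigma)
      min(1, max(0, text_length - l) / sigma ^ l)
  lstar <- lmer_threshold(text_length, sigma)
  total <- 0
  for (s in scheme$searches) {
    tab <- count_table(s, partition, sigma, distance)
    w <- vapply(seq_len(nrow(tab)), function(l)
      if (l <= lstar) 1 else policy(l, text_length, sigma), 0)
    total <- total + sum(rowSums(tab) * w)
  }
  total
}

#' Depth threshold of a text
#'
#' The smallest integer \code{l} with \code{sigma^l >= text_length}, i.e.
#' \code{ceiling(log_sigma text_length)}: below this depth a text cannot
#' realize all \code{sigma^l} branches of the backtracking trie.
#'
#' @param text_length text length in characters.
#' @param sigma alphabet size.
#' @return integer threshold.
#' @export
lmer_threshold <- function(text_length, sigma) {
  stopifnot(text_length >= 1, sigma >= 2)
  l <- 0L
  x <- 1
  while (x < text_length) {
    l <- l + 1L
    x <- x * sigma
  }
  l
}
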