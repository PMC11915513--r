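#' Build a bidirectional FM-index over a small text
#'
#' Indexes a text for approximate matching by left and right extension. Both
#' the text and its reverse are indexed (suffix array, Burrows-Wheeler
#' transform and cumulative rank tables), so that a matched pattern can be
#' extended by a character on either side while keeping the interval pair in
#' the two suffix orders synchronized. A single sentinel, lexicographically
#' smaller than every alphabet character, terminates the text; occurrences
#' never span it.
#'
#' The suffix arrays are built by prefix doubling (O(n log^2 n)), adequate
#' for desk-scale texts up to a few megabases.
#'
#' @param text character scalar (e.g. \code{"GATTACA"}) or integer vector of
#'   1-based character codes.
#' @param alphabet ordered character vector; every text character must be in
#'   it. Ignored when \code{text} is already integer-coded (then pass
#'   \code{sigma}).
#' @param sigma alphabet size when \code{text} is integer-coded.
#' @return An object of class \code{fm_index}.
#' @examples
#' idx <- fm_index("GATTACA")
#' fm_locate(idx, exact_search(idx, "TAC")) # 3
#' @export
fm_index <- function(text, alphabet = c("A", "C", "G", "T"), sigma = NULL) {
  if (is.character(text)) {
    stopifnot(length(text) == 1L, nchar(text) >= 1L)
    chars <- strsplit(text, "")[[1L]]
    code <- match(chars, alphabet)
    if (anyNA(code))
      stop("text contains characters outside the alphabet: ",
           paste(unique(chars[is.na(code)]), collapse = ", "),
           call. = FALSE)
    sigma <- length(alphabet)
  } else {
    code <- as.integer(text)
    if (is.null(sigma)) sigma <- max(code)
    if (length(code) < 1L || any(code < 1L) || any(code > sigma))
      stop("integer-coded text must be non-empty with codes in 1..sigma",
           call. = FALSE)
    alphabet <- if (length(alphabet) == sigma) alphabet
                else as.character(seq_len(sigma))
  }
  n <- length(code)
  fwd <- code
  rev <- code[n:1L]
  structure(
    list(n = n, sigma = as.integer(sigma), alphabet = alphabet,
         text = fwd,
         fwd = fm_tables(fwd, sigma),
         rev = fm_tables(rev, sigma)),
    class = "fm_index")
}

# internal: suffix array (0-based positions, includes the sentinel suffix),
# BWT and cumulative rank table for one direction.
# seq: integer codes 1..sigma; sentinel 0 is appended here.
fm_tables <- function(seq, sigma) {
  s <- c(seq, 0L)
  n <- length(s)
  sa <- suffix_array(s)
  # bwt[i] = character preceding suffix sa[i] (sentinel when sa[i] == 0)
  bwt <- integer(n)
  bwt[sa > 0L] <- s[sa[sa > 0L]]
  # occ[i + 1, c + 1] = number of occurrences of code c in bwt[1..i]
  occ <- matrix(0L, nrow = n + 1L, ncol = sigma + 1L)
  for (cc in 0:sigma)
    occ[-1L, cc + 1L] <- cumsum(bwt == cc)
  cnt <- tabulate(s + 1L, nbins = sigma + 1L)
  cbase <- c(0L, cumsum(cnt))[seq_len(sigma + 1L)]  # chars smaller than c
  list(sa = sa, occ = occ, cbase = cbase, n = n)
}

# internal: suffix array by prefix doubling; s is an integer vector whose
# last element (sentinel 0) is strictly smallest. Returns 0-based positions.
suffix_array <- function(s) {
  n <- length(s)
  rank <- match(s, sort(unique(s)))
  k <- 1L
  idx <- seq_len(n)
  repeat {
    rank2 <- c(rank[-seq_len(min(k, n))], rep(0L, min(k, n)))
    o <- order(rank, rank2)
    newr <- integer(n)
    newr[o[1L]] <- 1L
    for (i in 2:n)
      newr[o[i]] <- newr[o[i - 1L]] +
        (rank[o[i]] != rank[o[i - 1L]] || rank2[o[i]] != rank2[o[i - 1L]])
    rank <- newr
    if (max(rank) == n) break
    k <- 2L * k
  }
  o <- order(rank)
  as.integer(o - 1L)
}

#' The empty-pattern interval of an index
#'
#' The bidirectional interval matching the empty pattern: both directions
#' cover the full suffix order, of size \code{|text| + 1} (the sentinel
#' suffix is included by convention).
#'
#' @param index an [fm_index()].
#' @return a \code{bi_interval}: list with half-open 0-based ranges
#'   \code{lo, hi} (forward suffix order), \code{rlo, rhi} (reverse suffix
#'   order) and \code{len}, the number of text characters matched.
#' @export
fm_root <- function(index) {
  m <- index$n + 1L
  structure(list(lo = 0L, hi = m, rlo = 0L, rhi = m, len = 0L),
            class = "bi_interval")
}

#' @export
print.bi_interval <- function(x, ...) {
  cat(sprintf("bi_interval fwd [%d,%d) rev [%d,%d) len %d size %d\n",
              x$lo, x$hi, x$rlo, x$rhi, x$len, x$hi - x$lo))
  invisible(x)
}

#' Interval size
#' @param interval a \code{bi_interval}.
#' @return number of occurrences of the matched pattern.
#' @export
fm_size <- function(interval) interval$hi - interval$lo

# internal: one-direction extension. tab: fm_tables of the direction whose
# BWT we rank in; cotab irrelevant. Returns c(lo, hi, smaller) where smaller
# counts suffixes in [lo, hi) preceded by a character strictly below c.
extend_core <- function(tab, lo, hi, c) {
  occlo <- tab$occ[lo + 1L, ]
  occhi <- tab$occ[hi + 1L, ]
  nlo <- tab$cbase[c + 1L] + occlo[c + 1L]
  nhi <- tab$cbase[c + 1L] + occhi[c + 1L]
  smaller <- sum(occhi[seq_len(c)]) - sum(occlo[seq_len(c)])
  c(nlo, nhi, smaller)
}

#' Extend a bidirectional interval by one character
#'
#' \code{extend_left} prepends character \code{c} to the matched pattern,
#' \code{extend_right} appends it. Both keep the forward and reverse
#' intervals synchronized; extending an empty interval yields an empty
#' interval.
#'
#' @param index an [fm_index()].
#' @param interval a \code{bi_interval} (see [fm_root()]).
#' @param c character code in \code{1..sigma}, or a single character from
#'   the alphabet.
#' @return the extended \code{bi_interval}.
#' @export
extend_left <- function(index, interval, c) {
  c <- char_code(index, c)
  if (interval$hi <= interval$lo) return(interval)
  e <- extend_core(index$fwd, interval$lo, interval$hi, c)
  structure(list(lo = e[1L], hi = e[2L],
                 rlo = interval$rlo + e[3L],
                 rhi = interval$rlo + e[3L] + (e[2L] - e[1L]),
                 len = interval$len + 1L),
            class = "bi_interval")
}

#' @rdname extend_left
#' @export
extend_right <- function(index, interval, c) {
  c <- char_code(index, c)
  if (interval$hi <= interval$lo) return(interval)
  e <- extend_core(index$rev, interval$rlo, interval$rhi, c)
  structure(list(lo = interval$lo + e[3L],
                 hi = interval$lo + e[3L] + (e[2L] - e[1L]),
                 rlo = e[1L], rhi = e[2L],
                 len = interval$len + 1L),
            class = "bi_interval")
}

# internal
char_code <- function(index, c) {
  if (is.character(c)) {
    cc <- match(c, index$alphabet)
    if (is.na(cc))
      stop("character outside the alphabet: ", c, call. = FALSE)
    cc
  } else as.integer(c)
}

#' Locate an interval
#'
#' Maps a bidirectional interval to the 0-based start positions of the
#' matched pattern in the text.
#'
#' @param index an [fm_index()].
#' @param interval a \code{bi_interval}.
#' @return sorted integer vector of 0-based start positions.
#' @export
fm_locate <- function(index, interval) {
  if (interval$hi <= interval$lo) return(integer())
  pos <- index$fwd$sa[(interval$lo + 1L):interval$hi]
  sort(pos[pos + interval$len <= index$n])
}

#' Exact pattern search
#'
#' Matches a pattern exactly by successive right extensions.
#'
#' @param index an [fm_index()].
#' @param pattern character scalar or integer code vector.
#' @return the \code{bi_interval} of the full pattern (possibly empty).
#' @export
exact_search <- function(index, pattern) {
  code <- pattern_code(index, pattern)
  iv <- fm_root(index)
  for (c in code) {
    iv <- extend_right(index, iv, c)
    if (fm_size(iv) == 0L) break
  }
  iv
}

# internal
pattern_code <- function(index, pattern) {
  if (is.character(pattern)) {
    chars <- strsplit(pattern, "")[[1L]]
    code <- match(chars, index$alphabet)
    if (anyNA(code))
      stop("pattern contains characters outside the alphabet",
           call. = FALSE)
    code
  } else as.integer(pattern)
}
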