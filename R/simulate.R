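#' Simulate a random text
#'
#' Draws an i.i.d. uniform random string over the given alphabet, the text
#' model used throughout the package's evaluation setup. Deterministic for
#' a fixed seed.
#'
#' @param length text length in characters, \code{>= 1}.
#' @param alphabet character vector; default DNA.
#' @param seed RNG seed, or \code{NULL} to use the current RNG state.
#' @return character scalar.
#' @export
simulate_text <- function(length, alphabet = c("A", "C", "G", "T"),
                          seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}

#' Simulate reads with an exact number of errors
#'
#' Samples windows from a text and mutates each into a read at an
#' \emph{exact} distance from its origin window: \code{errors} mismatching
#' positions for Hamming distance, or \code{errors} edit operations
#' (substitution, insertion, deletion, drawn uniformly) for edit distance.
#' Random edits can cancel (e.g. two insertions that recreate a deleted
#' character), so every candidate is verified against the origin window by
#' dynamic programming and re-sampled when the achieved distance is
#' smaller; after \code{max_retries} failed attempts an error is raised.
#' Emitted reads always have exactly \code{read_length} characters (for
#' edit distance the origin window length is adjusted to compensate for
#' insertions and deletions). Deterministic for a fixed seed.
#'
#' @param text character scalar (the reference).
#' @param n number of reads.
#' @param read_length read length in characters.
#' @param errors exact distance of each read to its origin window,
#'   \code{< read_length}.
#' @param distance \code{"hamming"} or \code{"edit"}.
#' @param alphabet character vector; default DNA.
#' @param seed RNG seed, or \code{NULL}.
#' @param max_retries re-sampling budget per read.
#' @return data.frame with columns \code{read}, \code{origin_start},
#'   \code{origin_end} (0-based half-open window in \code{text}) and
#'   \code{distance} (always \code{== errors}).
#' @export
simulate_reads <- function(text, n, read_length, errors,
                           distance = c("hamming", "edit"),
                           alphabet = c("A", "C", "G", "T"),
                           seed = NULL, max_retries = 100L) {
  distance <- match.arg(distance)
  stopifnot(errors < read_length, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tlen <- nchar(text)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    got <- NULL
    for (try in seq_len(max_retries)) {
      cand <- mutate_window(text, tlen, read_length, errors, distance,
                            alphabet)
      if (cand$dist == errors) { got <- cand; break }
    }
    if (is.null(got))
      stop(sprintf(
        "could not achieve distance %d after %d attempts for read %d",
        errors, max_retries, i), call. = FALSE)
    out[[i]] <- data.frame(read = got$read, origin_start = got$s0,
                           origin_end = got$e0, distance = got$dist)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# internal: one mutation attempt
mutate_window <- function(text, tlen, read_length, errors, distance,
                          alphabet) {
  if (distance == "hamming") {
    s0 <- sample.int(tlen - read_length + 1L, 1L) - 1L
    w <- strsplit(substr(text, s0 + 1L, s0 + read_length), "")[[1L]]
    r <- w
    if (errors > 0L) {
      pos <- sample.int(read_length, errors)
      for (p in pos)
        r[p] <- sample(setdiff(alphabet, r[p]), 1L)
    }
    return(list(read = paste(r, collapse = ""), s0 = s0,
                e0 = s0 + read_length,
                dist = sum(r != w)))
  }
  # edit: draw the operations first so the window length can compensate
  ops <- if (errors > 0L)
    sample(c("sub", "ins", "del"), errors, replace = TRUE) else character()
  wlen <- read_length + sum(ops == "del") - sum(ops == "ins")
  if (wlen < 1L || wlen > tlen) return(list(dist = -1L))
  s0 <- sample.int(tlen - wlen + 1L, 1L) - 1L
  w <- strsplit(substr(text, s0 + 1L, s0 + wlen), "")[[1L]]
  r <- w
  for (op in ops) {
    if (op == "sub") {
      p <- sample.int(length(r), 1L)
      r[p] <- sample(setdiff(alphabet, r[p]), 1L)
    } else if (op == "ins") {
      p <- sample.int(length(r) + 1L, 1L)
      r <- append(r, sample(alphabet, 1L), after = p - 1L)
    } else {
      if (length(r) < 2L) return(list(dist = -1L))
      p <- sample.int(length(r), 1L)
      r <- r[-p]
    }
  }
  if (length(r) != read_length) return(list(dist = -1L))
  read <- paste(r, collapse = "")
  list(read = read, s0 = s0, e0 = s0 + wlen,
       dist = edit_distance(read, paste(w, collapse = ""),
                            alphabet = alphabet))
}
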