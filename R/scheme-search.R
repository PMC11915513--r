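#' Execute a search scheme on a bidirectional FM-index
#'
#' Runs every search of the scheme on one query: the search seeds at its
#' first part and extends character by character in part order, branching
#' over match/substitution for Hamming distance and additionally over
#' insertion/deletion for edit distance. A branch is pruned as soon as its
#' accumulated error count exceeds the inflated upper bound at its query
#' position, or its interval becomes empty; cumulative lower bounds are
#' checked at every part boundary. Completed states are located to text
#' positions.
#'
#' For edit distance one text window can be reached through several
#' alignments (and, for a redundant scheme, through several searches). By
#' default the union over searches is deduplicated per window, keeping the
#' minimal error count, and windows whose edge character is an insertion in
#' some optimal alignment (one-character trim lowers the distance) are
#' removed; this canonical form is shared with [brute_force_search()].
#' With \code{raw = TRUE} hits are reported per search without
#' deduplication.
#'
#' @param index an [fm_index()].
#' @param query character scalar or integer code vector.
#' @param scheme a [search_scheme()].
#' @param partition part sizes; defaults to
#'   \code{uniform_partition(|query|, scheme$p)}.
#' @param distance \code{"hamming"} or \code{"edit"}.
#' @param k maximum errors; defaults to \code{scheme$k}.
#' @param raw report per-search hits without deduplication or
#'   canonicalization.
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open text coordinates), \code{distance} and \code{search}
#'   (0-based index of the reporting search; \code{NA} after
#'   deduplication when several searches reported a window).
#' @export
scheme_search <- function(index, query, scheme, partition = NULL,
                          distance = c("hamming", "edit"),
                          k = scheme$k, raw = FALSE) {
  distance <- match.arg(distance)
  q <- pattern_code(index, query)
  if (is.null(partition))
    partition <- uniform_partition(length(q), scheme$p)
  if (sum(partition) != length(q))
    stop("partition does not sum to the query length", call. = FALSE)
  if (length(partition) != scheme$p)
    stop("partition length does not match the scheme's number of parts",
         call. = FALSE)
  hits <- vector("list", length(scheme$searches))
  for (i in seq_along(scheme$searches))
    hits[[i]] <- run_one_search(index, q, scheme$searches[[i]], partition,
                                distance, i - 1L)
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      distance = integer(), search = integer())
  if (raw) {
    out <- unique(out)
    return(out[order(out$start, out$end, out$search), , drop = FALSE])
  }
  if (nrow(out)) {
    # keep minimal distance per (start, end), then canonicalize edges
    out <- out[order(out$start, out$end, out$distance), , drop = FALSE]
    key <- paste(out$start, out$end)
    nsearch <- vapply(split(out$search, key), function(s)
      length(unique(s)), 0L)
    out <- out[!duplicated(key), , drop = FALSE]
    out$search[nsearch[paste(out$start, out$end)] > 1L] <- NA_integer_
    if (distance == "edit")
      out <- canonical_edit_filter(index$text, q, out)
  }
  rownames(out) <- NULL
  out
}

# internal: DFS execution of one search; returns a data.frame of raw hits
run_one_search <- function(index, q, s, partition, distance, search_id) {
  p <- s$p
  ord <- s$order + 1L
  sizes <- partition[ord]
  edit <- distance == "edit"
  sigma <- index$sigma
  # direction of each step: right if the part extends the searched range on
  # the right, left otherwise (the seed part is laid out left to right)
  dirR <- logical(p)
  dirR[1L] <- TRUE
  if (p > 1L)
    for (t in 2:p) dirR[t] <- ord[t] > ord[1L]
  # query characters consumed at each step, in consumption order
  starts <- cumsum(c(0L, partition))       # 0-based part offsets
  qchars <- vector("list", p)
  for (t in seq_len(p)) {
    rng <- (starts[ord[t]] + 1L):(starts[ord[t]] + sizes[t])
    qchars[[t]] <- if (dirR[t]) q[rng] else rev(q[rng])
  }
  posbase <- cumsum(c(0L, sizes))
  hi <- inflate_bounds(s, partition, distance)$hi
  lower <- s$lower
  upper <- s$upper
  fwdtab <- index$fwd
  revtab <- index$rev
  acc_start <- integer(0); acc_end <- integer(0); acc_d <- integer(0)
  sa <- index$fwd$sa
  n <- index$n

  ext <- function(iv, b, right) {
    # iv: c(lo, hi, rlo, rhi)
    if (right) {
      e <- extend_core(revtab, iv[3L], iv[4L], b)
      c(iv[1L] + e[3L], iv[1L] + e[3L] + (e[2L] - e[1L]), e[1L], e[2L])
    } else {
      e <- extend_core(fwdtab, iv[1L], iv[2L], b)
      c(e[1L], e[2L], iv[3L] + e[3L], iv[3L] + e[3L] + (e[2L] - e[1L]))
    }
  }
  report <- function(iv, len, err) {
    if (len < 1L) return(invisible())   # degenerate: whole query deleted
    pos <- sa[(iv[1L] + 1L):iv[2L]]
    pos <- pos[pos + len <= n]
    if (length(pos)) {
      acc_start <<- c(acc_start, pos)
      acc_end <<- c(acc_end, pos + len)
      acc_d <<- c(acc_d, rep.int(err, length(pos)))
    }
  }

  step <- function(iv, len, t, j, err) {
    pos <- posbase[t] + j
    cq <- qchars[[t]][j]
    bound <- hi[pos]
    if (edit && err + 1L <= bound) {
      # insertion: consume a text character, keep the query position
      for (b in seq_len(sigma)) {
        iv2 <- ext(iv, b, dirR[t])
        if (iv2[2L] > iv2[1L]) step(iv2, len + 1L, t, j, err + 1L)
      }
      # deletion: skip the query character, no text character
      advance(iv, len, t, j, err + 1L)
    }
    for (b in seq_len(sigma)) {
      e2 <- err + (b != cq)
      if (e2 <= bound) {
        iv2 <- ext(iv, b, dirR[t])
        if (iv2[2L] > iv2[1L]) advance(iv2, len + 1L, t, j, e2)
      }
    }
  }
  advance <- function(iv, len, t, j, err) {
    if (j < sizes[t]) step(iv, len, t, j + 1L, err)
    else end_part(iv, len, t, err)
  }
  end_part <- function(iv, len, t, err) {
    if (edit && err + 1L <= upper[t]) {
      # trailing insertions attributed to the finished part, before its
      # boundary check
      for (b in seq_len(sigma)) {
        iv2 <- ext(iv, b, dirR[t])
        if (iv2[2L] > iv2[1L]) end_part(iv2, len + 1L, t, err + 1L)
      }
    }
    if (err >= lower[t]) {
      if (t == p) report(iv, len, err)
      else step(iv, len, t + 1L, 1L, err)
    }
  }

  m <- n + 1L
  step(c(0L, m, 0L, m), 0L, 1L, 1L, 0L)
  if (!length(acc_start))
    return(NULL)
  data.frame(start = acc_start, end = acc_end, distance = acc_d,
             search = search_id)
}

#' Brute-force approximate search oracle
#'
#' Finds all approximate occurrences of a query by direct comparison, for
#' verifying [scheme_search()]. For Hamming distance the query is slid over
#' the text and mismatches counted. For edit distance a semi-global dynamic
#' program locates all end positions reachable within \code{k} errors, then
#' per-window dynamic programs recover every (start, end) pair with
#' \code{dist_edit(text[start:end], query) <= k}; by default the same
#' canonical edge filter as [scheme_search()] is applied.
#'
#' @param text character scalar or integer code vector (1..sigma).
#' @param query character scalar or integer code vector.
#' @param k maximum distance.
#' @param distance \code{"hamming"} or \code{"edit"}.
#' @param alphabet alphabet used to decode character input.
#' @param canonical apply the edge-insertion filter (edit distance only).
#' @return data.frame with columns \code{start}, \code{end}, \code{distance}
#'   (0-based half-open coordinates).
#' @export
brute_force_search <- function(text, query, k,
                               distance = c("hamming", "edit"),
                               alphabet = c("A", "C", "G", "T"),
                               canonical = TRUE) {
  distance <- match.arg(distance)
  tt <- decode_seq(text, alphabet)
  q <- decode_seq(query, alphabet)
  n <- length(tt); m <- length(q)
  if (distance == "hamming") {
    if (m > n)
      return(data.frame(start = integer(), end = integer(),
                        distance = integer()))
    d <- vapply(0:(n - m), function(s0)
      sum(tt[(s0 + 1L):(s0 + m)] != q), 0L)
    keep <- which(d <= k) - 1L
    out <- data.frame(start = keep, end = keep + m,
                      distance = d[keep + 1L])
    return(out)
  }
  # edit distance: row-vectorized semi-global DP, free start in the text.
  # D[i, j] = min edit distance of q[1..i] vs some text substring ending at
  # j; horizontal moves are resolved with a cummin trick.
  prev <- rep(0, n)                     # D[0, j] = 0 for every text prefix
  D0 <- 0                               # D[i, 0]: query vs empty substring
  for (i in seq_len(m)) {
    sub <- c(D0, prev[-n]) + (tt != q[i])
    e <- pmin(sub, prev + 1)
    D0 <- i
    prev <- pmin(e, seq_len(n) + cummin(c(D0, e - seq_len(n)))[-1L])
  }
  ends <- which(prev <= k)              # 1-based last-character positions
  res_s <- integer(0); res_e <- integer(0); res_d <- integer(0)
  for (e in ends) {
    a <- max(0L, e - m - k)             # 0-based leftmost candidate start
    W <- tt[(a + 1L):e]
    g <- edit_dist_prefixes(rev(q), rev(W))   # g[j+1] = dist(T[e-j:e], Q)
    for (j in seq_along(W)) {
      if (g[j + 1L] <= k) {
        res_s <- c(res_s, e - j); res_e <- c(res_e, e)
        res_d <- c(res_d, g[j + 1L])
      }
    }
  }
  out <- unique(data.frame(start = res_s, end = res_e, distance = res_d))
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (canonical && nrow(out))
    out <- canonical_edit_filter(tt, q, out)
  rownames(out) <- NULL
  out
}

#' Edit distance between two sequences
#'
#' Plain Levenshtein distance by dynamic programming.
#'
#' @param a,b character scalars or integer code vectors.
#' @param alphabet alphabet used to decode character input.
#' @return integer distance.
#' @export
edit_distance <- function(a, b, alphabet = c("A", "C", "G", "T")) {
  x <- decode_seq(a, alphabet)
  y <- decode_seq(b, alphabet)
  utils::tail(edit_dist_prefixes(x, y), 1L)
}

# internal: last DP row; result[j+1] = dist(x, y[1..j])
edit_dist_prefixes <- function(x, y) {
  ny <- length(y)
  prev <- 0:ny
  for (i in seq_along(x)) {
    cur <- numeric(ny + 1L)
    cur[1L] <- i
    if (ny > 0L) {
      sub <- prev[-(ny + 1L)] + (y != x[i])
      e <- pmin(sub, prev[-1L] + 1)
      cur[-1L] <- pmin(e, seq_len(ny) +
                         cummin(c(cur[1L], e - seq_len(ny)))[-1L])
    }
    prev <- cur
  }
  as.integer(prev)
}

# internal: shared canonical form for edit occurrences. A window (s, e, d)
# is dropped when trimming its first or last character yields edit distance
# d - 1, i.e. when that character is an insertion in some optimal
# alignment. True distances are computed by DP, so the same windows are
# removed from scheme output and from the oracle.
canonical_edit_filter <- function(tt, q, occs) {
  if (!nrow(occs)) return(occs)
  keep <- logical(nrow(occs))
  for (i in seq_len(nrow(occs))) {
    s0 <- occs$start[i]; e0 <- occs$end[i]; d0 <- occs$distance[i]
    trimL <- if (e0 - s0 >= 1L)
      utils::tail(edit_dist_prefixes(q, win(tt, s0 + 1L, e0)), 1L)
      else d0 + 2L
    trimR <- if (e0 - s0 >= 1L)
      utils::tail(edit_dist_prefixes(q, win(tt, s0, e0 - 1L)), 1L)
      else d0 + 2L
    keep[i] <- trimL != d0 - 1L && trimR != d0 - 1L
  }
  occs[keep, , drop = FALSE]
}

# internal: 0-based half-open window of an integer-coded text
win <- function(tt, s0, e0) {
  if (e0 <= s0) integer(0) else tt[(s0 + 1L):e0]
}

# internal: character scalar -> integer codes
decode_seq <- function(x, alphabet) {
  if (is.character(x)) {
    chars <- strsplit(x, "")[[1L]]
    code <- match(chars, alphabet)
    if (anyNA(code))
      stop("sequence contains characters outside the alphabet",
           call. = FALSE)
    code
  } else as.integer(x)
}
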