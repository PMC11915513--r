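# Independent oracles used across the suite. These deliberately re-derive
# results by the most literal method available (per-character walks,
# exhaustive trie enumeration, naive scans, per-window DP) so they share no
# code path with the implementation they check.

DNA <- c("A", "C", "G", "T")

# coverage oracle: lay the search out character by character (each part one
# "character" per error unit is irrelevant here -- we walk the parts in
# search order and check the bounds only at part boundaries)
oracle_covers <- function(search, config) {
  acc <- 0L
  for (t in seq_along(search$order)) {
    acc <- acc + config[search$order[t] + 1L]
    if (acc < search$lower[t] || acc > search$upper[t]) return(FALSE)
  }
  TRUE
}

# exhaustive backtracking-trie node count: DFS over all branch decisions,
# counting every visited (in-window) node. The root (level 0) is not
# counted; it spawns one match child and b error children, as does every
# further node.
oracle_trie_count <- function(lo, hi, b) {
  n <- length(lo)
  visit <- function(l, d) {
    if (l > n) return(0L)
    if (d < lo[l] || d > hi[l]) return(0L)
    total <- 1L
    total <- total + visit(l + 1L, d)        # match branch
    for (i in seq_len(b))
      total <- total + visit(l + 1L, d + 1L) # error branches
    total
  }
  visit(1L, 0L) + sum(vapply(seq_len(b), function(i)
    visit(1L, 1L), 0L))
}

# same, but memoised on (l, d) since the count below a state only depends
# on the state; used to keep sigma=2 sweeps fast while remaining a literal
# trie walk in structure
oracle_trie_count_fast <- function(lo, hi, b) {
  n <- length(lo)
  memo <- new.env(parent = emptyenv())
  visit <- function(l, d) {
    if (l > n) return(0)
    if (d < lo[l] || d > hi[l]) return(0)
    key <- paste(l, d)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    total <- 1 + visit(l + 1L, d) + b * visit(l + 1L, d + 1L)
    memo[[key]] <- total
    total
  }
  visit(1L, 0L) + b * visit(1L, 1L)
}

# naive sliding-window Hamming scan
oracle_hamming_scan <- function(tt, q, k) {
  n <- length(tt); m <- length(q)
  out <- NULL
  if (m <= n)
    for (s0 in 0:(n - m)) {
      d <- sum(tt[(s0 + 1L):(s0 + m)] != q)
      if (d <= k)
        out <- rbind(out, data.frame(start = s0, end = s0 + m,
                                     distance = d))
    }
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      distance = integer())
  out
}

# full-DP-per-window edit oracle (third, independent implementation)
oracle_edit_windows <- function(tt, q, k) {
  n <- length(tt); m <- length(q)
  dp_dist <- function(a, b) {
    na <- length(a); nb <- length(b)
    D <- matrix(0L, na + 1L, nb + 1L)
    D[, 1L] <- 0:na
    D[1L, ] <- 0:nb
    for (i in seq_len(na))
      for (j in seq_len(nb))
        D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                                 D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
    D[na + 1L, nb + 1L]
  }
  out <- NULL
  for (s0 in 0:(n - 1L)) {
    for (e0 in (s0 + 1L):n) {
      if (e0 - s0 < m - k || e0 - s0 > m + k) next
      d <- dp_dist(tt[(s0 + 1L):e0], q)
      if (d <= k)
        out <- rbind(out, data.frame(start = s0, end = e0, distance = d))
    }
  }
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      distance = integer())
  out[order(out$start, out$end), , drop = FALSE]
}

# configuration matrix -> set of strings, for set comparisons
config_strings <- function(m) {
  if (nrow(m) == 0L) return(character())
  sort(apply(m, 1L, paste, collapse = ","))
}

# the generator family exercised in sweeps; heuristic at both preferred
# part counts
generator_schemes <- function(k) {
  if (k == 0L)
    return(list(backtracking = scheme_backtracking(0L),
                heuristic = scheme_heuristic(0L, 2L)))
  out <- list(backtracking = scheme_backtracking(k),
              pigeonhole = scheme_pigeonhole(k),
              pigeonhole_opt = scheme_pigeonhole_opt(k),
              suffix_filter = scheme_suffix_filter(k),
              zero_one_star = scheme_zero_one_star(k),
              zero_one_star_opt = scheme_zero_one_star_opt(k),
              heuristic_p1 = scheme_heuristic(k, k + 1L),
              heuristic_p2 = scheme_heuristic(k, k + 2L))
  out
}

hits_key <- function(h) paste(h$start, h$end, h$distance, sep = ":")
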