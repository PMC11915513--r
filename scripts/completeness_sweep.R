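#!/usr/bin/env Rscript
# Long-running completeness check of the heuristic construction at
# p = k + 2 for large k, by chunked exhaustive enumeration of all error
# configurations with sum <= k. Not part of the test suite: the k = 15 case
# enumerates C(32, 17) = 565 722 720 configurations and takes on the order
# of an hour on one CPU.
#
#   Rscript scripts/completeness_sweep.R [--kmax <int>]

suppressPackageStartupMessages(library(searchschemes))

args <- commandArgs(trailingOnly = TRUE)
i <- match("--kmax", args)
kmax <- if (is.na(i)) 15L else as.integer(args[i + 1L])

# enumerate configurations with sum <= k over p parts in chunks, streaming
# a callback; lexicographic recursion over the first part's count
check_complete_chunked <- function(scheme, k, chunk = 1e6L) {
  p <- scheme$p
  pre <- lapply(scheme$searches, function(s) {
    list(ord = s$order + 1L, lo = s$lower, hi = s$upper)
  })
  uncovered <- NULL
  # iterative odometer over configurations, emitted in blocks
  cfg <- integer(p)
  done <- FALSE
  nxt <- function() {
    # advance cfg to the next vector with sum <= k, lexicographic
    j <- p
    repeat {
      cfg[j] <<- cfg[j] + 1L
      if (sum(cfg) <= k) return(TRUE)
      cfg[j] <<- 0L
      j <- j - 1L
      if (j == 0L) return(FALSE)
    }
  }
  repeat {
    block <- matrix(0L, nrow = chunk, ncol = p)
    nrows <- 0L
    repeat {
      nrows <- nrows + 1L
      block[nrows, ] <- cfg
      if (!nxt()) { done <- TRUE; break }
      if (nrows == chunk) break
    }
    block <- block[seq_len(nrows), , drop = FALSE]
    ncover <- integer(nrows)
    for (s in pre) {
      cum <- block[, s$ord, drop = FALSE]
      for (j in 2:p) cum[, j] <- cum[, j] + cum[, j - 1L]
      bad <- rep(FALSE, nrows)
      for (j in 1:p)
        bad <- bad | cum[, j] < s$lo[j] | cum[, j] > s$hi[j]
      ncover <- ncover + !bad
    }
    if (any(ncover == 0L)) {
      uncovered <- block[which(ncover == 0L)[1L], ]
      break
    }
    if (done) break
  }
  uncovered
}

for (k in 1:kmax) {
  t0 <- proc.time()[3]
  sch <- scheme_heuristic(k, k + 2L)
  valid <- all(vapply(sch$searches, function(s)
    length(validate_search(s)) == 0L, NA))
  witness <- check_complete_chunked(sch, k)
  cat(sprintf("k = %2d  p = %2d  valid: %s  complete: %s  (%.1f s)\n",
              k, k + 2L, valid, is.null(witness),
              proc.time()[3] - t0))
  if (!is.null(witness))
    cat("  uncovered configuration:", paste(witness, collapse = ","), "\n")
}
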