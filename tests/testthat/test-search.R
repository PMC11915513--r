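# Bidirectional FM-index, scheme execution and the brute-force oracle.

test_that("exact search finds all and only the true positions", {
  idx <- fm_index("GATTACA")
  expect_equal(fm_locate(idx, exact_search(idx, "TAC")), 3)
  expect_equal(fm_locate(idx, exact_search(idx, "A")), c(1, 4, 6))
  expect_equal(fm_size(exact_search(idx, "GGG")), 0)
  # empty pattern: interval of size |text| + 1 (sentinel included)
  expect_equal(fm_size(fm_root(idx)), 8)
  expect_error(fm_index("GATTXCA"), "outside the alphabet")
  expect_error(exact_search(idx, "XY"), "outside the alphabet")
})

test_that("exact search equals a naive scan on random texts", {
  set.seed(42)
  for (r in 1:60) {
    n <- sample(5:500, 1)
    txt <- sample(1:4, n, replace = TRUE)
    idx <- fm_index(txt, sigma = 4)
    m <- sample(1:6, 1)
    pat <- sample(1:4, m, replace = TRUE)
    hits <- fm_locate(idx, exact_search(idx, pat))
    naive <- which(vapply(seq_len(max(0, n - m + 1)), function(s)
      all(txt[s:(s + m - 1)] == pat), NA)) - 1L
    expect_equal(as.integer(hits), as.integer(naive))
  }
})

test_that("left and right extension stay synchronized", {
  idx <- fm_index("GATTACA")
  iv <- fm_root(idx)
  iv <- extend_right(idx, iv, "T")
  iv <- extend_right(idx, iv, "T")
  expect_equal(fm_locate(idx, iv), 2)    # "TT" at position 2
  # build ATTA inside-out
  iv <- fm_root(idx)
  iv <- extend_right(idx, iv, "T")
  iv <- extend_left(idx, iv, "T")
  iv <- extend_left(idx, iv, "A")
  iv <- extend_right(idx, iv, "A")       # "ATTA"
  expect_equal(fm_locate(idx, iv), 1)
  # absent character empties the interval; empty is absorbing
  iv <- extend_right(idx, fm_root(idx), "G")
  iv2 <- extend_right(idx, iv, "G")
  expect_equal(fm_size(iv2), 0)
  expect_equal(fm_size(extend_left(idx, iv2, "A")), 0)
  # size is monotone under extension
  set.seed(9)
  txt <- paste(sample(DNA, 300, replace = TRUE), collapse = "")
  idx2 <- fm_index(txt)
  iv <- fm_root(idx2)
  for (c in sample(DNA, 8, replace = TRUE)) {
    iv2 <- if (runif(1) < 0.5) extend_left(idx2, iv, c)
           else extend_right(idx2, iv, c)
    expect_lte(fm_size(iv2), fm_size(iv))
    iv <- iv2
  }
})

test_that("brute force agrees with an independent per-window DP", {
  set.seed(7)
  for (r in 1:25) {
    n <- sample(30:120, 1)
    tt <- sample(1:4, n, replace = TRUE)
    m <- sample(4:10, 1)
    q <- sample(1:4, m, replace = TRUE)
    k <- sample(0:2, 1)
    bf <- brute_force_search(tt, q, k, "edit", canonical = FALSE)
    want <- oracle_edit_windows(tt, q, k)
    expect_equal(hits_key(bf), hits_key(want))
    bh <- brute_force_search(tt, q, k, "hamming")
    expect_equal(hits_key(bh), hits_key(oracle_hamming_scan(tt, q, k)))
  }
})

test_that("deleting a character yields a distance-1 edit occurrence", {
  txt <- "ACGTACGGTGCA"
  expect_equal(edit_distance("ACGTA", "ACGA"), 1)
  bf <- brute_force_search(txt, "CGTACGG", 0)
  expect_equal(bf$start, 1)
  # drop one character from the exact query: still found at distance 1
  bf1 <- brute_force_search(txt, "CGTCGG", 1, "edit")
  expect_true(any(bf1$start == 1 & bf1$distance == 1))
})

test_that("scheme execution equals the oracle on a small dense instance", {
  set.seed(13)
  txt <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  idx <- fm_index(txt, alphabet = c("A", "C"))
  for (k in 0:2) {
    for (r in 1:3) {
      s0 <- sample(0:(400 - 16), 1)
      q <- substr(txt, s0 + 1, s0 + 12)
      for (dist in c("hamming", "edit")) {
        bf <- brute_force_search(txt, q, k, dist, alphabet = c("A", "C"))
        for (sch in generator_schemes(k)) {
          if (sch$p > 6) next
          got <- scheme_search(idx, q, sch, distance = dist, k = k)
          expect_equal(hits_key(got), hits_key(bf),
                       label = sprintf("%s %s k=%d", sch$name, dist, k))
        }
      }
    }
  }
})

test_that("Hamming multiplicity: non-redundant once, redundant more", {
  set.seed(21)
  txt <- paste(sample(DNA, 2000, replace = TRUE), collapse = "")
  idx <- fm_index(txt)
  reads <- simulate_reads(txt, 5, 30, 2, "hamming", seed = 5)
  po <- scheme_pigeonhole_opt(2)        # complete and non-redundant
  ph <- scheme_pigeonhole(2)            # complete but redundant
  seen_multi <- FALSE
  for (i in seq_len(nrow(reads))) {
    raw <- scheme_search(idx, reads$read[i], po, distance = "hamming",
                         raw = TRUE)
    counts <- table(paste(raw$start, raw$end))
    expect_true(all(counts == 1))
    raw2 <- scheme_search(idx, reads$read[i], ph, distance = "hamming",
                          raw = TRUE)
    if (any(table(paste(raw2$start, raw2$end)) >= 2)) seen_multi <- TRUE
  }
  # an exact occurrence (0 errors) is covered by every pigeonhole search
  exact <- substr(txt, 101, 130)
  raw3 <- scheme_search(idx, exact, ph, distance = "hamming", raw = TRUE)
  expect_gte(max(table(paste(raw3$start, raw3$end))), 2)
})

test_that("edit hits are deduplicated; raw mode keeps per-search hits", {
  set.seed(31)
  txt <- paste(sample(DNA, 1500, replace = TRUE), collapse = "")
  idx <- fm_index(txt)
  rd <- simulate_reads(txt, 1, 40, 2, "edit", seed = 6)
  sch <- scheme_pigeonhole(2)
  ded <- scheme_search(idx, rd$read[1], sch, distance = "edit")
  expect_false(any(duplicated(ded[c("start", "end")])))
  raw <- scheme_search(idx, rd$read[1], sch, distance = "edit", raw = TRUE)
  expect_gte(nrow(raw), nrow(ded))
  expect_true(all(c("start", "end", "distance", "search") %in% names(raw)))
})
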