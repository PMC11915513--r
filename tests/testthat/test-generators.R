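# Scheme constructors for the filtration strategies and the heuristic.

sig <- function(sch) {
  vapply(sch$searches, function(s)
    paste(paste(s$order, collapse = ""), paste(s$lower, collapse = ""),
          paste(s$upper, collapse = "")), "")
}

test_that("uniform_partition splits with remainder on the left", {
  expect_equal(uniform_partition(50, 4), c(13, 13, 12, 12))
  expect_equal(uniform_partition(8, 3), c(3, 3, 2))
  expect_equal(uniform_partition(50, 1), 50)
  expect_equal(uniform_partition(7, 7), rep(1, 7))
  expect_error(uniform_partition(3, 4), "p must")
  for (p in 1:10) {
    sz <- uniform_partition(53, p)
    expect_equal(sum(sz), 53)
    expect_lte(max(sz) - min(sz), 1)
  }
})

test_that("backtracking scheme is a single unconstrained search", {
  expect_equal(sig(scheme_backtracking(0)), "0 0 0")
  expect_equal(sig(scheme_backtracking(2)), "0 0 2")
})

test_that("pigeonhole schemes reproduce the worked k = 2 forms", {
  expect_setequal(sig(scheme_pigeonhole(2)),
                  c("012 000 022", "102 000 022", "210 000 022"))
  expect_setequal(sig(scheme_pigeonhole_opt(2)),
                  c("012 000 022", "102 011 022", "210 012 012"))
  expect_setequal(sig(scheme_pigeonhole(1)),
                  c("01 00 01", "10 00 01"))
})

test_that("optimized pigeonhole: non-redundant at k = 2, redundant above", {
  expect_true(check_scheme(scheme_pigeonhole_opt(2))$nonredundant)
  r3 <- check_scheme(scheme_pigeonhole_opt(3))
  expect_true(r3$complete)
  expect_false(r3$nonredundant)
})

test_that("suffix filter staircase and redundancy", {
  sf <- scheme_suffix_filter(2)
  expect_setequal(sig(sf),
                  c("012 000 012", "120 001 012", "210 011 022"))
  expect_false(check_scheme(sf)$nonredundant)
})

test_that("01*0 seeds: triangular family and merged variant", {
  z <- scheme_zero_one_star(2)
  expect_length(z$searches, 6L)          # (k+1)(k+2)/2
  expect_true("1230 0111 0112" %in% sig(z))   # anchor a = 1, j = 1
  expect_length(scheme_zero_one_star(1)$searches, 3L)
  expect_equal(scheme_zero_one_star(1)$p, 3L)

  zo <- scheme_zero_one_star_opt(2)
  expect_setequal(sig(zo),
                  c("0123 0000 0122", "1230 0000 0122", "2310 0000 0022"))
  # merging with min/max widens: every configuration covered by a source
  # search is covered by its merged search
  for (k in 1:3) {
    full <- scheme_zero_one_star(k)
    merged <- scheme_zero_one_star_opt(k)
    expect_lt(length(merged$searches), length(full$searches))
    firsts <- vapply(full$searches, function(s) s$order[1], 0L)
    cfgs <- enumerate_configs(k, full$p, "atmost")
    for (i in seq_along(full$searches)) {
      msearch <- merged$searches[[firsts[i] + 1L]]
      src <- apply(cfgs, 1, function(cf) covers(full$searches[[i]], cf))
      mrg <- apply(cfgs, 1, function(cf) covers(msearch, cf))
      expect_true(all(mrg[src]))
    }
  }
})

test_that("heuristic matrix generation and adjustment", {
  m0 <- heuristic_matrix(3, 5)
  expect_equal(m0, rbind(c(0, 2, 1, 3, 3), c(1, 0, 2, 2, 2),
                         c(2, 1, 0, 1, 1), c(3, 3, 3, 0, 0)),
               ignore_attr = TRUE)
  m1 <- adjust_matrix(m0)
  # column 2 entries of rows 0 and 1 swap; everything else untouched
  expect_equal(m1, rbind(c(0, 2, 2, 3, 3), c(1, 0, 1, 2, 2),
                         c(2, 1, 0, 1, 1), c(3, 3, 3, 0, 0)),
               ignore_attr = TRUE)
  # k = 2 matrix needs no adjustment
  m2 <- heuristic_matrix(2, 4)
  expect_equal(m2, rbind(c(0, 1, 2, 2), c(1, 0, 1, 1), c(2, 2, 0, 0)),
               ignore_attr = TRUE)
  expect_identical(adjust_matrix(m2), m2)
  expect_equal(heuristic_matrix(1, 2), rbind(c(0, 1), c(1, 0)),
               ignore_attr = TRUE)
  # idempotence
  for (k in c(2, 3, 5, 8))
    expect_identical(adjust_matrix(adjust_matrix(heuristic_matrix(k, k + 2))),
                     adjust_matrix(heuristic_matrix(k, k + 2)))
})

test_that("adjust_matrix terminates within budget for large k", {
  for (k in c(16, 32, 64))
    expect_silent(adjust_matrix(heuristic_matrix(k, k + 2)))
})

test_that("heuristic construction reproduces the worked examples", {
  h24 <- scheme_heuristic(2, 4)
  expect_setequal(sig(h24),
                  c("2310 0000 0022", "1230 0011 0112", "0123 0002 0122"))
  h35 <- scheme_heuristic(3, 5)
  expect_equal(sig(h35),
               c("01234 00003 02233", "12340 00022 01223",
                 "23410 00111 01123", "34210 00000 00333"))
  h12 <- scheme_heuristic(1, 2)
  expect_setequal(sig(h12), c("01 01 01", "10 00 01"))
  r <- check_scheme(h12)
  expect_true(r$complete)
  expect_true(r$nonredundant)
  expect_error(scheme_heuristic(3, 3), "larger than k")
})

test_that("search counts follow the constructions", {
  for (k in 1:6) {
    expect_length(scheme_pigeonhole(k)$searches, k + 1L)
    expect_length(scheme_pigeonhole_opt(k)$searches, k + 1L)
    expect_length(scheme_suffix_filter(k)$searches, k + 1L)
    expect_length(scheme_zero_one_star(k)$searches, (k + 1) * (k + 2) / 2)
    expect_length(scheme_zero_one_star_opt(k)$searches, k + 1L)
    expect_length(scheme_heuristic(k, k + 2)$searches, k + 1L)
  }
})

test_that("every generator is valid and complete for k = 1..6", {
  for (k in 1:6) {
    for (nm in names(generator_schemes(k))) {
      r <- check_scheme(generator_schemes(k)[[nm]])
      expect_true(r$valid, label = sprintf("%s k=%d valid", nm, k))
      expect_true(r$complete, label = sprintf("%s k=%d complete", nm, k))
    }
  }
})

test_that("scheme JSON round-trips byte-identically", {
  dir <- system.file("extdata", "schemes", package = "searchschemes")
  files <- list.files(dir, full.names = TRUE)
  expect_gt(length(files), 0L)
  for (f in files) {
    sch <- read_scheme(f)
    tmp <- tempfile(fileext = ".json")
    write_scheme(sch, tmp)
    expect_identical(readLines(tmp), readLines(f), label = basename(f))
  }
  # a freshly generated scheme round-trips through write/read
  sch <- scheme_suffix_filter(3)
  tmp <- tempfile(fileext = ".json")
  write_scheme(sch, tmp)
  expect_true(same_scheme(read_scheme(tmp), sch))
})

test_that("reading a malformed scheme reports the violation", {
  tmp <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"k":1,"name":"bad","p":3,"searches":',
    '[{"L":[0,0,0],"U":[1,1,1],"pi":[0,2,1]}]}'), tmp)
  expect_error(read_scheme(tmp), "connectivity")
  writeLines('{"k":1,"name":"bad"}', tmp)
  expect_error(read_scheme(tmp), "malformed")
})

test_that("build_scheme dispatches by strategy name", {
  expect_true(same_scheme(build_scheme("pigeonhole", 2),
                          scheme_pigeonhole(2)))
  expect_true(same_scheme(build_scheme("heuristic", 2, 4),
                          scheme_heuristic(2, 4)))
  expect_error(build_scheme("heuristic", 2), "requires p")
})
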