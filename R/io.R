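#' Write a search scheme to its canonical JSON form
#'
#' The on-disk format is a single JSON object with sorted keys and integer
#' arrays:
#' \preformatted{{"k": int, "name": str, "p": int,
#'  "searches": [{"L": [int...], "U": [int...], "pi": [int...]}, ...]}}
#' The writer is byte-deterministic (one line, no insignificant
#' whitespace variation, trailing newline), so \code{write(read(x))} is
#' byte-identical to \code{x} for canonical files.
#'
#' @param scheme a [search_scheme()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  arr <- function(v) paste0("[", paste(as.integer(v), collapse = ","), "]")
  one <- function(s)
    sprintf('{"L":%s,"U":%s,"pi":%s}',
            arr(s$lower), arr(s$upper), arr(s$order))
  body <- sprintf(
    '{"k":%d,"name":%s,"p":%d,"searches":[%s]}',
    scheme$k,
    jsonlite::toJSON(scheme$name, auto_unbox = TRUE),
    scheme$p,
    paste(vapply(scheme$searches, one, ""), collapse = ","))
  writeLines(body, path)
  invisible(path)
}

#' Read a search scheme from a JSON file
#'
#' Parses and validates a scheme file in the format written by
#' [write_scheme()]. Invariant violations (broken connectivity,
#' non-monotone bounds, inconsistent part counts) are reported as errors,
#' never silently repaired.
#'
#' @param path file path.
#' @return a [search_scheme()].
#' @export
read_scheme <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("k", "name", "p", "searches")
  if (!all(need %in% names(x)))
    stop("malformed scheme file: missing ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  sl <- x$searches
  searches <- if (is.data.frame(sl)) {
    lapply(seq_len(nrow(sl)), function(i)
      make_search(sl$pi[[i]], sl$L[[i]], sl$U[[i]]))
  } else {
    lapply(sl, function(s) make_search(s$pi, s$L, s$U))
  }
  scheme <- search_scheme(searches, x$k, name = x$name)
  if (scheme$p != x$p)
    stop(sprintf("malformed scheme file: p = %d but searches have %d parts",
                 x$p, scheme$p), call. = FALSE)
  scheme
}

#' @rdname read_scheme
#' @export
load_scheme <- read_scheme

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
    stats::setNames(seqs, sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr])))
  }
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nm[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write occurrence hits as TSV
#'
#' Columns: \code{query_id}, \code{start}, \code{end} (0-based half-open),
#' \code{distance}, \code{search} (0-based search index or NA).
#'
#' @param hits data.frame as returned by [scheme_search()], with an added
#'   \code{query_id} column, or a list of such frames named by query id.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_hits <- function(hits, path) {
  if (is.list(hits) && !is.data.frame(hits)) {
    hits <- do.call(rbind, lapply(names(hits), function(id) {
      h <- hits[[id]]
      if (nrow(h)) cbind(query_id = id, h)
      else cbind(query_id = character(0), h)
    }))
  }
  cols <- c("query_id", "start", "end", "distance",
            intersect("search", names(hits)))
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
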