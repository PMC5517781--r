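#' Normalize source code for size measurement
#'
#' Strips comments (per `dialect`), blank lines, and unnecessary whitespace
#' from source text, the canonical preprocessing before counting lines and
#' characters of code. String literals are protected: comment markers and
#' whitespace inside quotes are kept verbatim. Outside strings, runs of
#' horizontal whitespace are collapsed to a single space (`space = "collapse"`,
#' default) or removed entirely (`space = "remove"`); leading and trailing
#' whitespace is always trimmed and empty lines dropped. The transformation
#' is idempotent.
#'
#' Supported comment dialects:
#' \describe{
#'   \item{`hash`}{`#` to end of line (Python, shell, R).}
#'   \item{`c`}{`//` to end of line and `/* ... */` blocks (C, C++).}
#'   \item{`colon`}{`:` to end of line (NMODL-style model description files).}
#' }
#'
#' @param text Source code: a single string (possibly with newlines) or a
#'   character vector of lines.
#' @param dialect Comment syntax, one of `"hash"`, `"c"`, `"colon"`.
#' @param space `"collapse"` or `"remove"`.
#' @return A single string of normalized source (lines joined by `"\n"`,
#'   empty if nothing but comments/blanks remained).
#' @examples
#' normalize_source("x = 1   # set x\n\ny=2", "hash")  # "x = 1\ny=2"
#' @export
normalize_source <- function(text, dialect = c("hash", "c", "colon"),
                             space = c("collapse", "remove")) {
  dialect <- match.arg(dialect)
  space <- match.arg(space)
  text <- paste(text, collapse = "\n")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nc <- length(chars)
  out <- character(0)
  state <- "code"        # code | dq | sq | block
  block_start_line <- 0L
  line <- 1L
  i <- 1L
  push <- function(ch) out[length(out) + 1L] <<- ch
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "\n") line <- line + 1L
    if (state == "code") {
      nxt <- if (i < nc) chars[i + 1L] else ""
      if (ch == "\"") { state <- "dq"; push(ch) }
      else if (ch == "'") { state <- "sq"; push(ch) }
      else if (dialect == "hash" && ch == "#") {
        while (i <= nc && chars[i] != "\n") i <- i + 1L
        next
      } else if (dialect == "colon" && ch == ":") {
        while (i <= nc && chars[i] != "\n") i <- i + 1L
        next
      } else if (dialect == "c" && ch == "/" && nxt == "/") {
        while (i <= nc && chars[i] != "\n") i <- i + 1L
        next
      } else if (dialect == "c" && ch == "/" && nxt == "*") {
        state <- "block"; block_start_line <- line; i <- i + 2L
        next
      } else push(ch)
    } else if (state == "block") {
      if (ch == "*" && i < nc && chars[i + 1L] == "/") {
        state <- "code"; i <- i + 2L
        next
      }
      if (ch == "\n") push(ch)   # keep line structure across block comments
    } else {                     # inside a string literal
      if (ch == "\\" && i < nc) {
        push(ch); push(chars[i + 1L]); i <- i + 2L
        next
      }
      push(ch)
      if ((state == "dq" && ch == "\"") || (state == "sq" && ch == "'"))
        state <- "code"
    }
    i <- i + 1L
  }
  if (state == "block")
    stop(sprintf("unterminated block comment starting at line %d",
                 block_start_line))
  stripped <- paste(out, collapse = "")
  lines <- strsplit(stripped, "\n", fixed = TRUE)[[1]]
  lines <- .squeeze_ws(lines, mode = space)
  lines <- lines[nzchar(lines)]
  paste(lines, collapse = "\n")
}

# Collapse/remove horizontal whitespace outside string literals, trim ends.
.squeeze_ws <- function(lines, mode) {
  vapply(lines, function(l) {
    chars <- strsplit(l, "", fixed = TRUE)[[1]]
    res <- character(0)
    state <- "code"; prev_ws <- FALSE
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (state == "code") {
        if (ch %in% c(" ", "\t")) {
          if (mode == "collapse" && !prev_ws && length(res) > 0)
            res[length(res) + 1L] <- " "
          prev_ws <- TRUE
        } else {
          prev_ws <- FALSE
          res[length(res) + 1L] <- ch
          if (ch == "\"") state <- "dq" else if (ch == "'") state <- "sq"
        }
      } else {
        res[length(res) + 1L] <- ch
        if (ch == "\\" && j < length(chars)) {
          res[length(res) + 1L] <- chars[j + 1L]; j <- j + 2L; next
        }
        if ((state == "dq" && ch == "\"") || (state == "sq" && ch == "'"))
          state <- "code"
        prev_ws <- FALSE
      }
      j <- j + 1L
    }
    sub("[ \t]+$", "", paste(res, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Count lines and characters of code
#'
#' For text already passed through [normalize_source()]: `loc` is the number
#' of non-empty lines and `noc` the total number of characters excluding line
#' terminators (so the counts are identical for LF and CRLF input). These are
#' the code-size measures used to compare how much a user must type to
#' implement a simulator module from scratch.
#'
#' @param text Normalized source (single string or vector of lines).
#' @return A list of class `"code_metrics"` with integer fields `loc`, `noc`.
#' @examples
#' count_loc_noc("x = 1\ny=2")  # loc 2, noc 8
#' @export
count_loc_noc <- function(text) {
  text <- paste(text, collapse = "\n")
  lines <- strsplit(gsub("\r\n", "\n", text, fixed = TRUE), "\n",
                    fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  structure(list(loc = length(lines), noc = sum(nchar(lines, type = "chars"))),
            class = "code_metrics")
}

#' Code-size metrics for source files
#'
#' Convenience wrapper: normalizes each file with [normalize_source()] and
#' counts lines/characters with [count_loc_noc()].
#'
#' @param paths Character vector of file paths.
#' @param dialect Comment dialect (see [normalize_source()]).
#' @param space Whitespace mode (see [normalize_source()]).
#' @return A data frame with columns `file`, `loc`, `noc`.
#' @export
code_metrics_files <- function(paths, dialect = "hash", space = "collapse") {
  res <- lapply(paths, function(p) {
    m <- count_loc_noc(normalize_source(readLines(p, warn = FALSE), dialect,
                                        space))
    data.frame(file = p, loc = m$loc, noc = m$noc)
  })
  do.call(rbind, res)
}
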