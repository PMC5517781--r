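#' Construct an edge list
#'
#' Connectivity is stored as a plain data frame of directed edges
#' `(pre, post, weight, delay)` with 0-based, population-local node ids and
#' declared population sizes carried as attributes. Weights are in mV (delta
#' synapses) or nS (conductance synapses); delays in ms.
#'
#' @param pre,post Integer vectors of 0-based node ids.
#' @param weight,delay Numeric vectors (recycled).
#' @param n_pre,n_post Declared population sizes.
#' @param validate Check invariants (ranges, no duplicate pairs)?
#' @return A data frame of class `"edge_list"` with attributes `n_pre`,
#'   `n_post`.
#' @export
edge_list <- function(pre = integer(), post = integer(),
                      weight = numeric(), delay = numeric(),
                      n_pre, n_post, validate = TRUE) {
  df <- data.frame(pre = as.integer(pre), post = as.integer(post),
                   weight = rep_len(as.numeric(weight), length(pre)),
                   delay = rep_len(as.numeric(delay), length(pre)))
  attr(df, "n_pre") <- as.integer(n_pre)
  attr(df, "n_post") <- as.integer(n_post)
  class(df) <- c("edge_list", "data.frame")
  if (validate) validate_edge_list(df)
  df
}

#' Validate edge-list invariants
#'
#' Checks id ranges against the declared sizes and rejects duplicate
#' `(pre, post)` pairs (multapses are not supported).
#'
#' @param x An [edge_list()].
#' @return `x`, invisibly, or an error.
#' @export
validate_edge_list <- function(x) {
  n_pre <- attr(x, "n_pre"); n_post <- attr(x, "n_post")
  if (nrow(x) > 0) {
    if (any(x$pre < 0L | x$pre >= n_pre))
      stop("presynaptic ids out of range [0, n_pre)")
    if (any(x$post < 0L | x$post >= n_post))
      stop("postsynaptic ids out of range [0, n_post)")
    if (anyDuplicated(x$pre * as.double(n_post) + x$post))
      stop("duplicate (pre, post) pairs are not supported")
  }
  invisible(x)
}

#' Bernoulli (Erdos-Renyi) random connectivity
#'
#' Every ordered pair `(i, j)` — excluding `i == j` when `same_population` —
#' is included independently with probability `p`. Pairs are drawn in a fixed
#' row-major order over presynaptic ids (the diagonal is drawn and discarded
#' in the within-population case), so a given `(n_pre, n_post, p, seed)`
#' always reproduces the same edge list.
#'
#' @param n_pre,n_post Population sizes.
#' @param p Connection probability in \[0, 1\].
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @param same_population If `TRUE`, `pre` and `post` index the same
#'   population and self-edges are excluded.
#' @param weight,delay Constant synaptic weight and delay stamped on every
#'   edge.
#' @return An [edge_list()].
#' @examples
#' g <- connect_bernoulli(100, 100, 0.05, seed = 1, same_population = TRUE)
#' @export
connect_bernoulli <- function(n_pre, n_post, p, seed = NULL,
                              same_population = FALSE,
                              weight = 0, delay = 1) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must lie in [0, 1]")
  idx <- .with_seed(seed, which(stats::runif(n_pre * n_post) < p))
  pre <- (idx - 1L) %/% n_post
  post <- (idx - 1L) %% n_post
  if (same_population) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  edge_list(pre, post, weight, delay, n_pre = n_pre, n_post = n_post,
            validate = FALSE)
}

#' Fixed-out-degree random connectivity
#'
#' Every presynaptic neuron is connected to exactly `k` distinct targets drawn
#' uniformly without replacement from the same population, excluding itself.
#' Sources are processed in id order, so the result is reproducible from the
#' seed.
#'
#' @param n Population size.
#' @param k Out-degree (0 <= k < n).
#' @param seed Optional integer seed.
#' @param weight,delay Constant synaptic weight and delay.
#' @return An [edge_list()] with `n * k` edges.
#' @examples
#' g <- connect_fixed_outdegree(400, 40, seed = 1)
#' @export
connect_fixed_outdegree <- function(n, k, seed = NULL, weight = 0, delay = 1) {
  if (k >= n) stop("`k` must be smaller than `n`")
  if (k < 0) stop("`k` must be non-negative")
  post <- .with_seed(seed, {
    ids <- 0:(n - 1L)
    unlist(lapply(ids, function(i) sample(ids[ids != i], k)), use.names = FALSE)
  })
  pre <- rep(0:(n - 1L), each = k)
  edge_list(pre, post, weight, delay, n_pre = n, n_post = n, validate = FALSE)
}

#' Write an edge list to a TSV file
#'
#' Plain-text format: two header lines `#n_pre=<int>` and `#n_post=<int>`
#' followed by one tab-separated row `pre post weight delay` per edge.
#' Weights and delays are written with 17 significant digits so that
#' [read_edges()] reproduces the doubles exactly.
#'
#' @param x An [edge_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("#n_pre=%d", attr(x, "n_pre")),
               sprintf("#n_post=%d", attr(x, "n_post"))), con)
  if (nrow(x) > 0)
    writeLines(sprintf("%d\t%d\t%s\t%s", x$pre, x$post,
                       .fmt_double(x$weight), .fmt_double(x$delay)), con)
  invisible(path)
}

#' Read an edge list from a TSV file
#'
#' Inverse of [write_edges()]. Malformed rows (wrong column count or
#' non-numeric fields) raise an error naming the offending line.
#'
#' @param path File produced by [write_edges()].
#' @return An [edge_list()].
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get_hdr <- function(key) {
    m <- grep(sprintf("^#%s=", key), lines, value = TRUE)
    if (length(m) != 1L) stop(sprintf("missing '#%s=' header", key))
    as.integer(sub(sprintf("^#%s=", key), "", m))
  }
  n_pre <- get_hdr("n_pre"); n_post <- get_hdr("n_post")
  body <- which(!hdr & nzchar(lines))
  if (length(body) == 0)
    return(edge_list(n_pre = n_pre, n_post = n_post))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop(sprintf("line %d: expected 4 tab-separated fields, found %d",
                 body[bad[1]], lengths(fields)[bad[1]]))
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 4L, byrow = TRUE)
  if (anyNA(mat)) {
    bad_row <- which(apply(is.na(mat), 1L, any))[1]
    stop(sprintf("line %d: non-numeric field", body[bad_row]))
  }
  edge_list(mat[, 1], mat[, 2], mat[, 3], mat[, 4],
            n_pre = n_pre, n_post = n_post)
}

#' Out-degree / in-degree tallies
#'
#' @param x An [edge_list()].
#' @return A list with integer vectors `out` (length `n_pre`) and `in_`
#'   (length `n_post`), indexed by 0-based id + 1.
#' @export
degree_counts <- function(x) {
  list(out = tabulate(x$pre + 1L, nbins = attr(x, "n_pre")),
       in_ = tabulate(x$post + 1L, nbins = attr(x, "n_post")))
}
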