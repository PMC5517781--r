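# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the global stream is used (and advanced).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Shortest decimal representation that re-reads to the identical double.
.fmt_double <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

.stop_undefined <- function(msg) {
  stop(structure(class = c("spikenet_undefined_result", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
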