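`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG temporarily seeded; the caller's RNG stream is
# restored afterwards so generators are reproducible without clobbering the
# session. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# maximal runs of TRUE in a logical vector, as a data.frame of 1-based
# inclusive [start, end]; empty data.frame when there is no TRUE run
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values) & r$values
  data.frame(start = starts[keep], end = ends[keep])
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
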