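# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG stream derived from (seed, stream),
# restoring the caller's RNG state afterwards. Streams keep the generators
# independent of each other: adding draws to one never shifts another.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  # derived seed stays well below 2^31
  set.seed((as.integer(seed) %% 599999L) * 3571L + as.integer(stream))
  force(expr)
}

# 0-based half-open [start, end) -> 1-based closed IRanges
.ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# IRanges -> 0-based half-open data.frame columns
.from_ir <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
}
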