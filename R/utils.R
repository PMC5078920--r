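# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All user-facing randomness goes through this so
# that a seed argument fully determines the output without clobbering the
# session RNG.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical key for a splice junction.  Coordinates are the package-internal
# 0-based half-open intron interval; conversion to/from the 1-based inclusive
# SJ.out.tab dialect happens only in the I/O layer.
junction_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

# Canonical key for an editing site (1-based position, annotated strand).
site_key <- function(chrom, pos, strand) {
  sprintf("%s:%d:%s", chrom, as.integer(pos), strand)
}

# Total length of the union of a set of 0-based half-open intervals.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  total <- 0L
  cur_s <- starts[1L]
  cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]
      cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform integer draws on [a, b]; safe when a == b (unlike sample(x, ...))
sample_int_range <- function(a, b, n) {
  vals <- seq.int(a, b)
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}
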