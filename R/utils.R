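#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rlnorm rmultinom sd pt var aggregate dhyper fisher.test t.test pf setNames runif
#' @importFrom utils head tail write.table read.table
NULL

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
# All generator randomness flows through this so nothing leaks into (or from)
# the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed derivation: sub-seed = (seed * 101 + offset)
# mod (2^31 - 1).  Offsets are fixed per artifact (clones = 1, noise = 2,
# densitometry = 3, qpcr = 4, background = 5+).
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 101 + offset) %% 2147483647)
}

# Normalize a nucleotide string: uppercase, RNA U -> DNA T.
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

# substring by 0-based half-open interval
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# Merge 0-based half-open intervals that overlap or abut.  Zero-width
# intervals (insertion points) participate: a point at the edge of an
# interval merges with it.  Returns a matrix with columns start, end.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- start[i]
      me <- end[i]
    }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  out
}
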