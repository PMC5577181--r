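# Shared fixtures and independent oracles for the test suite.

# The engineered locus is deterministic; build it once per test run.
the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- suppressWarnings(rbfox2_reference())
    m
  }
})

# Independent translation oracle: Biostrings' translator (the package's own
# find_orf uses a codon-table lookup, a different code path).
oracle_translate <- function(nt) {
  n <- 3L * (nchar(nt) %/% 3L)
  if (n == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)), if.fuzzy.codon = "X"))
  st <- regexpr("*", aa, fixed = TRUE)
  if (st > 0L) substr(aa, 1L, st - 1L) else aa
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# exact test: sum the probabilities of all tables with the same margins
# whose probability does not exceed the observed table's.
oracle_fisher_p <- function(k_a, n_a, k_b, n_b) {
  k <- k_a + k_b
  x <- max(0L, k - n_b):min(k, n_a)
  p <- dhyper(x, n_a, n_b, k)
  p_obs <- dhyper(k_a, n_a, n_b, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Brute-force motif finder: plain substring search inside an explicit
# window, for comparison with scan_motifs.
oracle_motifs <- function(premrna, lo, hi) {
  win <- substr(premrna, lo + 1L, hi)
  occ <- gregexpr("GCATG", win, fixed = TRUE)[[1]]
  if (occ[1] < 0L) integer(0) else lo + as.integer(occ) - 1L
}

# A small random multi-exon model with GT..AG introns (no coding
# constraints), deterministic per seed.  Used for motif-scan and alignment
# property tests.
random_model <- function(seed, n_exons = 4L, exon_len = c(40L, 90L),
                        intron_len = c(30L, 120L)) {
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pieces <- character(0)
  exons <- data.frame(exon_id = sprintf("X%02d", seq_len(n_exons)),
                      start = NA_integer_, end = NA_integer_)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    el <- sample(exon_len[1]:exon_len[2], 1L)
    exons$start[i] <- pos
    pieces <- c(pieces, rand_seq(el))
    pos <- pos + el
    exons$end[i] <- pos
    if (i < n_exons) {
      il <- sample(intron_len[1]:intron_len[2], 1L)
      pieces <- c(pieces, paste0("GT", rand_seq(il - 4L), "AG"))
      pos <- pos + il
    }
  }
  suppressWarnings(ref_model(model_id = sprintf("rand%04d", seed),
                             premrna_seq = paste(pieces, collapse = ""),
                             exons = exons))
}

# All eleven catalogued brain signatures as one noise-free clone each.
planted_brain_clones <- function(model) {
  sigs <- names(signature_specs("brain"))
  tibble::tibble(
    clone_id = sprintf("pl_%02d", seq_along(sigs)),
    group = rep(c("SCN", "COR"), length.out = length(sigs)),
    signature_true = sigs,
    seq = vapply(sigs, function(s) apply_signature(model, s), "",
                 USE.NAMES = FALSE))
}

# spliced-transcript coordinate of a pre-mRNA position (test-local copy so
# tests do not depend on package internals)
premrna_to_tx_test <- function(m, pos) {
  w <- m$exons$end - m$exons$start
  txs <- c(0L, cumsum(w))
  i <- which(pos >= m$exons$start & pos < m$exons$end)
  txs[i] + (pos - m$exons$start[i])
}

# local re-implementations of the documented sub-stream seed derivation
derive_seed_test <- function(seed, offset) {
  as.integer((as.double(seed) * 101 + offset) %% 2147483647)
}
with_seed_test <- function(seed, code) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
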