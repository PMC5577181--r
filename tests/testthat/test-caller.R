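test_that("a clone identical to the reference yields no events", {
  m <- the_model()
  r <- splice_align(splice(m), m)
  expect_identical(nrow(r$events), 0L)
  expect_equal(r$identity, 100)
  expect_false(r$unalignable)
})

test_that("the -12-40 clone decomposes into truncation plus exon skip", {
  m <- the_model()
  r <- splice_align(apply_signature(m, "-12-40"), m)
  ev <- r$events
  expect_identical(ev$kind, c("alt_acceptor_truncation", "exon_skip"))
  expect_identical(ev$delta_nt, c(-12L, -40L))
  expect_identical(ev$anchor_exons, c("E09", "E10"))
  expect_identical(ev$junction_check[1], "confirmed")
  # truncation abuts the exon-9 acceptor; skip spans exon 10 exactly
  expect_identical(ev$tx_start[1], 745L)
  expect_identical(c(ev$tx_start[2], ev$tx_end[2]), c(865L, 905L))
})

test_that("caller agrees with the exon-subset brute-force oracle", {
  # toy 3-exon model; every proper subset of internal exons removed
  for (seed in c(101, 202, 303)) {
    m <- random_model(seed, n_exons = 4L, exon_len = c(50L, 80L))
    tx_parts <- mapply(function(s, e) substr(splice(m), s + 1, e),
                       cumsum(c(0L, head(m$exons$end - m$exons$start, -1))),
                       cumsum(m$exons$end - m$exons$start))
    for (drop in list(2L, 3L, c(2L, 3L))) {
      clone <- paste(tx_parts[-drop], collapse = "")
      r <- splice_align(clone, m, length_ratio = c(0.3, 1.5))
      skips <- r$events[r$events$kind == "exon_skip", ]
      expect_identical(sort(skips$anchor_exons), m$exons$exon_id[sort(drop)],
                       info = sprintf("seed %d drop %s", seed,
                                      paste(drop, collapse = ",")))
      expect_identical(sum(r$events$delta_nt),
                       -sum((m$exons$end - m$exons$start)[drop]))
      expect_identical(r$reconstruction, clone)
    }
  }
})

test_that("signature naming is canonical and registry-driven", {
  expect_identical(call_signature(tibble::tibble()), "non-variant")
  ev <- tibble::tibble(kind = c("alt_acceptor_truncation", "exon_skip"),
                       anchor_exons = c("E09", "E10"),
                       delta_nt = c(-12L, -40L),
                       tx_start = c(745L, 865L), tx_end = c(757L, 905L),
                       inserted_seq = "", junction_check = "confirmed")
  expect_identical(call_signature(ev), "-12-40")
  # 5'->3' order is imposed regardless of row order
  expect_identical(call_signature(ev[2:1, ]), "-12-40")

  # two -3 variations at distinct loci get letter suffixes by position
  e3 <- function(start) tibble::tibble(
    kind = "alt_acceptor_truncation", anchor_exons = "E",
    delta_nt = -3L, tx_start = start, tx_end = start + 3L,
    inserted_seq = "", junction_check = "confirmed")
  reg <- locus_registry(list(e3(207L), e3(370L)))
  expect_identical(call_signature(e3(207L), reg), "-3a")
  expect_identical(call_signature(e3(370L), reg), "-3b")
  # registry assignment does not depend on observation order
  reg2 <- locus_registry(list(e3(370L), e3(207L)))
  expect_identical(reg, reg2)
  # a magnitude seen at a single locus needs no suffix
  reg1 <- locus_registry(list(e3(207L)))
  expect_identical(call_signature(e3(207L), reg1), "-3")
})

test_that("all planted signatures round-trip through the caller", {
  m <- the_model()
  clones <- planted_brain_clones(m)
  calls <- call_clones(m, clones)
  expect_identical(calls$signature, clones$signature_true)
  expect_false(any(calls$unalignable))
  # conservation: reference segments + insertions rebuild each clone
  ref <- splice(m)
  for (i in seq_len(nrow(calls))) {
    expect_identical(reconstruct_clone(ref, calls$events[[i]]),
                     clones$seq[i])
  }
  summ <- summarize_population(calls)
  expect_identical(summ$n_isoforms, 11L)
  expect_identical(summ$n_loci, 6L)
})

test_that("the PC12-style exon substitution is re-expressed canonically", {
  m <- the_model()
  cl <- apply_signature(m, "-2-40+43")
  r <- splice_align(cl, m)
  expect_identical(sort(r$events$kind),
                   sort(c("micro_deletion", "exon_skip",
                          "alt_exon_inclusion")))
  expect_identical(call_signature(r$events), "-2-40+43")
  expect_identical(r$reconstruction, cl)
})

test_that("alternative-exon insertions are confirmed against the pre-mRNA", {
  m <- the_model()
  r <- splice_align(apply_signature(m, "+32"), m)
  ev <- r$events
  expect_identical(ev$kind, "alt_exon_inclusion")
  expect_identical(ev$delta_nt, 32L)
  expect_identical(ev$junction_check, "confirmed")
  # a made-up insertion at the same junction is left unconfirmed
  tx <- splice(m)
  fake <- paste0(substr(tx, 1, 865), "GATTCCGGATCATCAGGATTGCCGGATCATCA",
                 substr(tx, 866, nchar(tx)))
  r2 <- splice_align(fake, m)
  ins <- r2$events[r2$events$delta_nt > 0, ]
  expect_identical(ins$junction_check, "not_confirmed")
})

test_that("degenerate clones are flagged unalignable and logged", {
  m <- the_model()
  # far too short: outside the length-ratio bounds
  expect_message(r <- splice_align(strrep("ACGT", 20), m), "length ratio")
  expect_true(r$unalignable)
  # right length but unrelated sequence: identity below threshold
  junk <- paste(rep(c("A", "C", "G", "T"), length.out = 1175), collapse = "")
  expect_message(r2 <- splice_align(junk, m), "identity")
  expect_true(r2$unalignable)
  # unalignable clones drop out of population tables
  clones <- tibble::tibble(clone_id = c("a", "b"), group = "G",
                           seq = c(splice(m), junk))
  calls <- suppressMessages(call_clones(m, clones))
  summ <- summarize_population(calls)
  expect_identical(sum(unlist(summ$counts[, -1])), 1L)
})

test_that("calling tolerates substitution noise", {
  m <- the_model()
  cfg <- sim_config(seed = 17, per_base_error_rate = 0.001,
                    n_clones_per_group = c(SCN = 25L, COR = 25L))
  clones <- generate_clones(m, cfg)
  calls <- call_clones(m, clones)
  agree <- mean(calls$signature == clones$signature_true)
  expect_gte(agree, 0.95)
})
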