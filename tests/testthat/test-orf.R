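test_that("find_orf translates from a start to the first in-frame stop", {
  r <- find_orf("ATGTAA", 0L)
  expect_identical(r$protein, "M")
  expect_identical(r$orf_nt_len, 3L)
  expect_identical(r$stop_offset, 3L)
  expect_false(r$run_through)

  # run-through: no stop before the end
  r2 <- find_orf("ATGAAACCC", 0L)
  expect_true(r2$run_through)
  expect_identical(r2$protein, "MKP")

  # invariants: orf_nt_len = 3 x protein length; tetrapeptide is a suffix
  m <- the_model()
  orf <- find_orf(splice(m), 12L)
  expect_identical(orf$orf_nt_len, 3L * nchar(orf$protein))
  expect_identical(orf$terminal_tetrapeptide,
                   substr(orf$protein, nchar(orf$protein) - 3,
                          nchar(orf$protein)))

  # errors
  expect_error(find_orf("ATG", 10L), "beyond")
  expect_error(find_orf("CCCTAA", 0L), "ATG")
  expect_identical(find_orf("CCCTAA", 0L, force = TRUE)$protein, "P")
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(404)
  for (i in 1:200) {
    n <- 3L * sample(5:60, 1)
    nt <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = ""))
    r <- find_orf(nt, 0L)
    expect_identical(r$protein, oracle_translate(nt))
  }
})

test_that("frame flags follow cumulative delta mod 3", {
  m <- the_model()
  # single -12: in frame, no shift
  fs <- frame_and_stop(signature_events(m, "-12"), m)
  expect_identical(fs$frame, 0L)
  expect_true(is.na(fs$frame_shift_from))
  expect_identical(fs$stop_used, "reference")

  # -12-40 shifts at the exon-10 skip and uses the alternative stop
  fs2 <- frame_and_stop(signature_events(m, "-12-40"), m)
  expect_identical(fs2$frame, 2L)
  expect_identical(fs2$frame_shift_from, 865L)
  expect_identical(fs2$stop_used, "alternative")
  expect_identical(fs2$terminal_tetrapeptide, "TEVT")

  # modular-arithmetic oracle: micro-deletions of 1..3 nt in a toy exon
  tx <- splice(m)
  for (d in 1:3) {
    ev <- tibble::tibble(kind = "micro_deletion", anchor_exons = "E09",
                         tx_start = 800L, tx_end = 800L + d,
                         delta_nt = -d, inserted_seq = "",
                         junction_check = "not_confirmed")
    fs <- frame_and_stop(ev, m)
    expect_identical(fs$frame, ((-d) %% 3L + 3L) %% 3L)
    expect_identical(is.na(fs$frame_shift_from), d %% 3L == 0L)
  }
})

test_that("nmd_check applies the strict 55-nt junction rule", {
  # stop downstream of the last junction: never NMD
  expect_false(nmd_check(900L, c(100L, 800L))$nmd)
  expect_lt(nmd_check(900L, c(100L, 800L))$distance, 0L)
  # boundary: distance 55 -> FALSE (borderline), 56 -> TRUE
  expect_false(nmd_check(100L, 158L)$nmd)       # 158 - 103 = 55
  expect_true(nmd_check(100L, 158L)$borderline)
  expect_true(nmd_check(100L, 159L)$nmd)        # 56
  # monotone in distance
  d <- vapply(150:170, function(j) nmd_check(100L, j)$nmd, NA)
  expect_identical(d, sort(d))

  # the -93+73 isoform carries a PTC far upstream of the last junction
  m <- the_model()
  r <- orf_report(m, "-93+73")
  expect_true(r$nmd)
  expect_gt(r$nmd_distance, 55L)
  expect_identical(r$stop_used, "premature")
  # all other catalogued isoforms escape NMD
  for (sig in setdiff(names(signature_specs("brain")), "-93+73")) {
    expect_false(orf_report(m, sig)$nmd, info = sig)
  }
})

test_that("domain impact localizes isoform changes", {
  m <- the_model()
  expect_identical(orf_report(m, "non-variant")$domain_impact, "")
  expect_identical(orf_report(m, "-12-40")$domain_impact, "CTD")
  expect_identical(orf_report(m, "-93")$domain_impact, "RRM")
  expect_identical(orf_report(m, "-39")$domain_impact, "CTD")
  expect_identical(orf_report(m, "-93+73")$domain_impact, "RRM;CTD")
  expect_identical(orf_report(m, "-3a-12")$domain_impact, "NTD;CTD")
})

test_that("the -12 deletion reproduces the SLPLV arithmetic", {
  m <- the_model()
  nv <- find_orf(splice(m), 12L)$protein
  v <- orf_report(m, "-12")$protein
  # 5 reference residues lost, 1 novel residue gained
  expect_identical(nchar(nv) - nchar(v), 4L)
  expect_identical(substr(nv, 245, 249), "SLPLV")
  expect_false(grepl("SLPLV", v, fixed = TRUE))
  expect_identical(substr(v, 1, 244), substr(nv, 1, 244))
  expect_identical(substr(v, 246, nchar(v)), substr(nv, 250, nchar(nv)))
})

test_that("scan_nls finds motifs with bounded mismatches", {
  m <- the_model()
  nv <- find_orf(splice(m), 12L)$protein
  hits <- scan_nls(nv, m$nls_patterns)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$aa_position, 122L)
  expect_identical(hits$mismatches, 0L)

  # empty protein: no hits
  expect_identical(nrow(scan_nls("", m$nls_patterns)), 0L)

  # sliding-window Hamming oracle with one substitution
  pat <- "KRLHV"
  prot <- "AAAKRLHVAAAKRLQVAAA"
  h0 <- scan_nls(prot, pat, max_mismatches = 0L)
  expect_identical(h0$aa_position, 4L)
  h1 <- scan_nls(prot, pat, max_mismatches = 1L)
  expect_identical(h1$aa_position, c(4L, 12L))
  expect_identical(h1$mismatches, c(0L, 1L))
  # frameshifted isoforms keep the conserved NLS
  expect_identical(orf_report(m, "-12-40")$n_nls_hits, 1L)
})

test_that("composition_stats counts residues and overlapping dipeptides", {
  z <- composition_stats("")
  expect_true(all(z$residues == 0L))
  q <- composition_stats("QPQPQ", dipeptides = c("QP", "PQ"))
  expect_identical(unname(q$dipeptides["QP"]), 2L)
  expect_identical(unname(q$dipeptides["PQ"]), 2L)
  expect_identical(unname(q$residues["Q"]), 3L)

  # per-domain restriction via the domain table
  m <- the_model()
  nv <- find_orf(splice(m), 12L)$protein
  whole <- composition_stats(nv)
  ctd <- composition_stats(nv, region = "CTD", domains = m$domains)
  ntd <- composition_stats(nv, region = "NTD", domains = m$domains)
  rrm <- composition_stats(nv, region = "RRM", domains = m$domains)
  expect_identical(unname(whole$residues["A"]),
                   unname(ctd$residues["A"] + ntd$residues["A"] +
                            rrm$residues["A"]))
})

test_that("pairwise identity is computed over alignment columns", {
  a <- strrep("MKTAYIAKQR", 10)
  expect_equal(pairwise_identity(a, a), 100)
  b <- paste0(substr(a, 1, 50), "W", substr(a, 52, 100))
  expect_equal(pairwise_identity(a, b), 99)
  expect_error(pairwise_identity("", a), "non-empty")
})
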