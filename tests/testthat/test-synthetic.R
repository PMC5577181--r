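test_that("engineered locus encodes the documented protein architecture", {
  m <- the_model()
  tx <- splice(m)
  orf <- find_orf(tx, m$alt_starts[["MEKK"]])
  expect_identical(orf$orf_nt_len, 1143L)
  expect_identical(nchar(orf$protein), 381L)
  expect_identical(substr(orf$protein, 1, 4), "MEKK")
  expect_identical(orf$terminal_tetrapeptide, "FAPY")
  # dual stops in distinct frames with a 7-nt gap between them
  ref_stop <- premrna_to_tx_test(m, m$stop_pair[["reference"]])
  alt_stop <- premrna_to_tx_test(m, m$stop_pair[["alternative"]])
  expect_identical(alt_stop - (ref_stop + 3L), 7L)
  expect_false((alt_stop - ref_stop) %% 3L == 0L)
  expect_identical(substr(tx, ref_stop + 1, ref_stop + 3), "TGA")
  expect_identical(substr(tx, alt_stop + 1, alt_stop + 3), "TAA")
  # the MAEG alternative start is in frame with MEKK
  expect_identical(substr(tx, 1, 3), "ATG")
})

test_that("frameshifted isoforms use the alternative stop and TEVT", {
  m <- the_model()
  # -12-40: net -52 (+1 frameshift); alternative stop, terminus TEVT
  r <- orf_report(m, "-12-40")
  expect_identical(r$stop_used, "alternative")
  expect_identical(r$terminal_tetrapeptide, "TEVT")
  expect_identical(r$frame, 2L)
  nv <- orf_report(m, "non-variant")
  expect_identical(nv$stop_used, "reference")
  expect_identical(nv$terminal_tetrapeptide, "FAPY")
  # the two stops are 7 nt apart on the shared 3' sequence
  expect_identical((r$stop_offset + 52L) - (nv$stop_offset + 3L), 7L)
})

test_that("generate_clones plants signatures exactly and reproducibly", {
  m <- the_model()
  # error rate 0, a single signature: clones are identical transcripts
  cfg1 <- sim_config(seed = 11, n_clones_per_group = c(G = 5L),
                     group_freqs = list(G = c("non-variant" = 1)))
  cl1 <- generate_clones(m, cfg1)
  expect_identical(nrow(cl1), 5L)
  expect_identical(unique(cl1$seq), splice(m))

  # -12-40 clones are 52 nt shorter than the reference transcript
  cfg2 <- sim_config(seed = 11, n_clones_per_group = c(G = 3L),
                     group_freqs = list(G = c("-12-40" = 1)))
  expect_identical(unique(nchar(generate_clones(m, cfg2)$seq)),
                   nchar(splice(m)) - 52L)

  # per-group clone counts always equal the configured n
  cfg3 <- sim_config(seed = 5)
  cl3 <- generate_clones(m, cfg3)
  expect_identical(as.integer(table(cl3$group)[c("SCN", "COR")]),
                   c(22L, 22L))

  # empirical signature tallies equal the seeded multinomial draw
  counts <- table(cl3$signature_true[cl3$group == "SCN"])
  freqs <- cfg3$group_freqs$SCN
  draw <- with_seed_test(derive_seed_test(5L, 1L),
                         as.vector(rmultinom(1, 22, freqs)))
  expect_identical(as.integer(counts[names(freqs)[draw > 0]]),
                   draw[draw > 0])

  # same seed -> byte-identical output; different seed -> different draw
  cl3b <- generate_clones(m, sim_config(seed = 5))
  expect_identical(cl3, cl3b)
})

test_that("per-base noise changes only isolated bases", {
  m <- the_model()
  cfg <- sim_config(seed = 3, n_clones_per_group = c(G = 10L),
                    group_freqs = list(G = c("non-variant" = 1)),
                    per_base_error_rate = 0.001)
  cl <- generate_clones(m, cfg)
  ref <- splice(m)
  nmut <- vapply(cl$seq, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(ref, "")[[1]])
  }, 0L, USE.NAMES = FALSE)
  expect_identical(unique(nchar(cl$seq)), nchar(ref))
  expect_true(all(nmut >= 0) && mean(nmut) < 5)
  expect_true(any(nmut > 0))
})

test_that("densitometry generator recovers configured inclusion", {
  # sem = 0: every sample sits exactly on the mean
  cfg0 <- sim_config(seed = 2, densitometry = list(
    G = list(mean_pct = 40, sem_pct = 0, n = 3L)))
  d0 <- generate_densitometry(cfg0)
  psi <- 100 * d0$included_intensity /
    (d0$included_intensity + d0$excluded_intensity)
  expect_equal(psi, rep(40, 3), tolerance = 1e-12)

  # law of large numbers: large n converges on the configured mean
  cfg <- sim_config(seed = 2)
  d <- generate_densitometry(cfg, n_samples = 2000)
  pi <- percent_inclusion(d)
  scn <- pi$groups$mean_pct[pi$groups$group == "SCN"]
  cor <- pi$groups$mean_pct[pi$groups$group == "COR"]
  expect_equal(scn, 7.0, tolerance = 0.05)
  expect_equal(cor, 1.7, tolerance = 0.15)
  # implied per-sample SD is sem * sqrt(n)
  scn_sd <- pi$groups$sd_pct[pi$groups$group == "SCN"]
  expect_equal(scn_sd, 0.4 * sqrt(3), tolerance = 0.05)
})

test_that("qPCR generator and ddct reproduce configured folds", {
  # sd = 0 and equal means: every fold is exactly 1
  cfg0 <- sim_config(seed = 9, qpcr = list(
    calibrator = "A",
    groups = list(A = list(mean_dct = 5, sd = 0, n = 4L),
                  B = list(mean_dct = 5, sd = 0, n = 4L))))
  q0 <- ddct(generate_qpcr(cfg0), calibrator_group = "A")
  expect_equal(q0$samples$fold, rep(1, 8), tolerance = 1e-12)

  # one cycle lower dCt doubles the fold
  cfg1 <- sim_config(seed = 9, qpcr = list(
    calibrator = "A",
    groups = list(A = list(mean_dct = 5, sd = 0, n = 4L),
                  B = list(mean_dct = 4, sd = 0, n = 4L))))
  q1 <- ddct(generate_qpcr(cfg1), calibrator_group = "A")
  expect_equal(q1$groups$mean_fold[q1$groups$group == "B"], 2,
               tolerance = 1e-12)

  # seeded run reproducible
  expect_identical(generate_qpcr(sim_config(seed = 4)),
                   generate_qpcr(sim_config(seed = 4)))
})

test_that("write_simulation emits a complete, reproducible data set", {
  dir <- withr::local_tempdir()
  write_simulation(sim_config(seed = 21), file.path(dir, "a"))
  write_simulation(sim_config(seed = 21), file.path(dir, "b"))
  files <- c("model/reference.fasta", "model/exons.tsv", "model/domains.tsv",
             "model/model_config.yaml", "model/exons.gff3", "clones.fasta",
             "groups.tsv", "truth.tsv", "densitometry.tsv", "qpcr.tsv")
  for (f in files) {
    expect_true(file.exists(file.path(dir, "a", f)), info = f)
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)), info = f)
  }
})

test_that("trivial single-exon model has a whole-exon ORF", {
  cfg <- sim_config(seed = 1)
  cfg$n_exons <- 1L
  m <- build_reference(cfg)
  expect_identical(nrow(m$exons), 1L)
  orf <- find_orf(splice(m), 0L)
  expect_false(orf$run_through)
  expect_identical(orf$orf_nt_len + 3L, nchar(splice(m)))
})
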