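# Synthetic Rbfox2-like locus and data generators.
#
# The default reference emulates the cloned rat brain Rbfox2 cDNA: a 13-exon
# transcript whose MEKK-start ORF of 1143 nt encodes a 381-aa protein with
# NTD / RRM / CTD domains, a conserved 31-aa NLS, and a dual stop-codon
# architecture at the 3' end (a reference-frame stop and an alternative-frame
# stop separated by 7 nt of sequence) so that +1-frameshifted isoforms keep a
# similarly sized ORF terminating in TEVT instead of FAPY.  Six variation
# loci host the event menu that produces the eleven catalogued isoform
# signatures; intronic (T)GCATG motifs are planted at known offsets; all
# other sequence is engineered to be free of the motif.
#
# The coding sequence is specified codon-by-codon because two reading frames
# carry constraints at once: the zero-frame protein must contain 33 alanines
# (16 retained in the -12-40 variant prefix) and end FAPY, while the
# +1-frame reading of the same nucleotides downstream of exon 10 must be
# stop-free until the alternative stop, contain no alanine, and gain 5
# glutamines, 11 prolines and five QP dimers relative to the non-variant -
# the residue arithmetic reported for the -12-40 CTD.

# ---- engineered protein (non-variant, 381 aa) -------------------------------

nonvariant_protein_segments <- c(
  "MEKK",                                            # 1-4
  "SDNGEWMVLKHTGSRPDFINEYSTLKMRGDHWESVFIRNTDKLGS",   # 5-49   NTD filler
  "A",                                               # 50
  "TSMERVLDNKHGWFYVSIDTREMLGNEKSFHVDWTRSLN",         # 51-89  (66 = V, -3a)
  "A",                                               # 90
  "GDSKFWETPLHMVNRYSGIDEKMHWTS",                     # 91-117
  "RTVE",                                            # 118-121 RRM start (-3b)
  "KSTPKRLHVSNIPFRFRDPDLRQMFGQFGKI",                 # 122-152 NLS
  "DSWN",                                            # 153-156
  "TGEMVSRHLYDKSAWENFITGDMARHKVSEE",                 # 157-187 -93 interval
  "FDR",                                             # 188-190 RRM end
  "GEHSMTWKDLVNRFGESYITDMHKWSVLERNGDFTSKIHAMGVTESDWKRFHLN", # 191-244
  "SLPLV",                                           # 245-249 lost by -12
  "GAHMAWDEATKFAEGGVAMRAVSAWKALHANTAFA",             # 250-284 Ala-rich CTD
  "VYQDNSALTWHKAF",                                  # 285-298 exon-10 region
  "SGMDTTTTHWKESGVDNRFWHESMGKDVTEWAHADNKGVTSE",      # 299-340
  "ATATAATAAAAAAAAY",                                # 341-356 Ala/Thr run
  "DSTTTTGHWKESMVDRFWHSN",                           # 357-377
  "FAPY")                                            # 378-381

nonvariant_protein <- paste(nonvariant_protein_segments, collapse = "")

# Default codons, chosen so that in the dual-frame region (aa 285-381) the
# +1-frame reading can never hit a stop codon or an unplanned Ala/Gln/Pro:
# codons end in safe dinucleotides (CT, TT, GG, AC, AT, AA, GT, GA).
default_codons <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAC", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAC")

# Position-specific codon overrides (1-based residue -> codon).  These plant
# the cryptic splice-site dinucleotides used by the alternative acceptors /
# donors (GT at the -3a donor, AG just 5' of the -12/-39/-93/-3b acceptors),
# the AG..GT context of the -2 micro-deletion, and the +1-frame Gln/Pro
# choreography of the alanine run.
codon_overrides <- c(
  "66"  = "GTG",  # -3a: removed exon-2 trinucleotide starts GT
  "120" = "GTA",  # -3b: exon4[2:3] == AG
  "187" = "GAG",  # -93: exon5[92:93] == AG
  "245" = "AGT",  # SLPLV; exon 9 starts at the 2nd base of this codon
  "248" = "CTA",  # -12: exon9[11:12] == AG
  "254" = "GCC",  # avoid GCA+TGG creating a spurious GCATG
  "258" = "GCA",  # -39: exon9[38:39] == AG (with 257 = GAA)
  "264" = "GGA",  # -2 micro-deletion context: AG before ...
  "265" = "GGT",  # ... the removed GT ...
  "303" = "ACC", "304" = "ACC", "305" = "ACC", "306" = "ACC", # +1-frame Pro
  "327" = "ACA",  # +1-frame Gln (with 328 = GAA)
  "341" = "GCA", "342" = "ACC", "343" = "GCA", "344" = "ACC",
  "345" = "GCA", "346" = "GCC", "347" = "ACA", "348" = "GCC",
  "349" = "GCA", "350" = "GCC",               # +1-frame QPQPQPQPQP
  "359" = "ACC", "360" = "ACC", "361" = "ACC", "362" = "ACC") # +1-frame Pro

# 5' UTR doubles as the MAEG alternative start (in frame with MEKK).
utr5_seq <- "ATGGCAGAAGGT"

# 3' tail: reference stop TGA, 7 nt gap, then the alternative-frame stop TAA.
# The +1 frame reads ...ACT|GAA|GTG|ACA|TAA = (T)EVT-stop across this tail.
tail_seq <- "TGAAGTGACATAACTTCCTC"

# Alternative (normally intronic) exons.  ALT6A carries an in-frame TAA at
# codon 8 so the -93+73 isoform acquires a premature termination codon.
alt32_seq <- "CCCATCACGATTGGCTTCACGATCCTGGTCAC"
alt43_seq <- "CCGATCATTGGACTTGACCATCGGATTCCTGATCGGTACCTCA"
alt73_seq <- paste0("GGTCATCGTTGGATTCGGTTC", "TAA",
                    "GATCATCCGATTGGTTCGAAGGTCCATTGGATCGTTCCGGTACGATCCA")

# Spliced-transcript exon boundaries (0-based starts; total 1175 nt).
exon_tx_starts <- c(0L, 60L, 210L, 370L, 480L, 600L, 648L, 696L, 745L,
                    865L, 905L, 1025L, 1115L)
exon_tx_ends <- c(exon_tx_starts[-1L], 1175L)

intron_lengths <- c(110L, 130L, 160L, 160L, 100L, 250L, 95L, 140L, 305L,
                    120L, 115L, 105L)

rbfox2_domains <- data.frame(
  domain_label = c("NTD", "RRM", "CTD"),
  aa_start = c(1L, 118L, 191L),
  aa_end = c(117L, 190L, 381L))

rbfox2_nls <- "KSTPKRLHVSNIPFRFRDPDLRQMFGQFGKI"

# ---- sequence assembly ------------------------------------------------------

cds_from_protein <- function(protein, overrides = codon_overrides) {
  aa <- strsplit(protein, "")[[1]]
  codons <- default_codons[aa]
  if (length(overrides)) {
    idx <- as.integer(names(overrides))
    codons[idx] <- overrides
  }
  paste(codons, collapse = "")
}

# GCATG-free pseudo-random background, deterministic given seed.
bg_seq <- function(n, seed) {
  if (n <= 0L) return("")
  x <- with_seed(seed, sample(c("A", "C", "G", "T"), n, replace = TRUE,
                              prob = c(0.3, 0.2, 0.2, 0.3)))
  s <- paste(x, collapse = "")
  repeat {
    hit <- regexpr("GCATG", s, fixed = TRUE)
    if (hit < 0L) break
    substr(s, hit + 2L, hit + 2L) <- "T"
  }
  s
}

# An intron segment: GT ... AG with optional motif plants at fixed 0-based
# offsets within the segment.
intron_part <- function(len, seed, plants = NULL) {
  assert_that(len >= 4L, "intron part too short")
  s <- paste0("GT", bg_seq(len - 4L, seed), "AG")
  if (!is.null(plants)) {
    for (i in seq_len(nrow(plants))) {
      at <- plants$at[i]
      motif <- plants$motif[i]
      substr(s, at + 1L, at + nchar(motif)) <- motif
      if (!plants$u_ext[i] && at >= 1L &&
          substr(s, at, at) == "T") {
        substr(s, at, at) <- "C"   # keep a plain GCATG plain
      }
    }
  }
  s
}

#' The engineered 13-exon Rbfox2-like reference model
#'
#' Deterministic by construction (the background sequence derives from fixed
#' internal seeds, not from the simulation seed).  See the package vignette
#' for the design of the locus.
#'
#' @return A `ref_model` with 13 exons, a 1175-nt spliced transcript, MEKK
#'   and MAEG alternative starts, dual stops, domain map, NLS pattern and
#'   three alternative exons.
#' @export
rbfox2_reference <- function() {
  cds <- cds_from_protein(nonvariant_protein)
  tx <- paste0(utr5_seq, cds, tail_seq)
  exon_seqs <- mapply(function(s, e) substr0(tx, s, e),
                      exon_tx_starts, exon_tx_ends)

  # intron 4: TGCATG 120 nt upstream of exon 5
  i4 <- intron_part(intron_lengths[4], seed = 9004L,
                    plants = data.frame(at = intron_lengths[4] - 120L - 5L,
                                        motif = "TGCATG", u_ext = TRUE))
  # intron 5: plain GCATG 30 nt downstream of exon 5
  i5 <- intron_part(intron_lengths[5], seed = 9005L,
                    plants = data.frame(at = 29L, motif = "GCATG",
                                        u_ext = FALSE))
  # intron 6: [part1] ALT6A [part2]
  i6_p1 <- intron_part(60L, seed = 9006L)
  i6_p2 <- intron_part(250L - 60L - nchar(alt73_seq), seed = 9106L)
  i6 <- paste0(i6_p1, alt73_seq, i6_p2)
  # intron 9: [part1] ALT10A [mid + TGCATG 60 nt downstream of ALT10A]
  #           ALT10B [part3 + TGCATG 80 nt upstream of exon 10]
  i9_p1 <- intron_part(50L, seed = 9009L)
  i9_mid <- intron_part(80L, seed = 9109L,
                        plants = data.frame(at = 58L, motif = "TGCATG",
                                            u_ext = TRUE))
  i9_p3 <- intron_part(100L, seed = 9209L,
                       plants = data.frame(at = 100L - 80L - 5L,
                                           motif = "TGCATG", u_ext = TRUE))
  i9 <- paste0(i9_p1, alt32_seq, i9_mid, alt43_seq, i9_p3)
  introns <- list(
    intron_part(intron_lengths[1], seed = 9001L),
    intron_part(intron_lengths[2], seed = 9002L),
    intron_part(intron_lengths[3], seed = 9003L),
    i4, i5, i6,
    intron_part(intron_lengths[7], seed = 9007L),
    intron_part(intron_lengths[8], seed = 9008L),
    i9,
    intron_part(intron_lengths[10], seed = 9010L),
    intron_part(intron_lengths[11], seed = 9011L),
    intron_part(intron_lengths[12], seed = 9012L))

  pieces <- character(0)
  exon_tab <- data.frame(exon_id = sprintf("E%02d", 1:13),
                         start = NA_integer_, end = NA_integer_)
  pos <- 0L
  for (i in 1:13) {
    exon_tab$start[i] <- pos
    pieces <- c(pieces, exon_seqs[i])
    pos <- pos + nchar(exon_seqs[i])
    exon_tab$end[i] <- pos
    if (i < 13L) {
      pieces <- c(pieces, introns[[i]])
      pos <- pos + nchar(introns[[i]])
    }
  }
  premrna <- paste(pieces, collapse = "")

  # alternative exon coordinates on the pre-mRNA
  i6_start <- exon_tab$end[6]
  i9_start <- exon_tab$end[9]
  alt_exons <- data.frame(
    exon_id = c("ALT6A", "ALT10A", "ALT10B"),
    start = c(i6_start + 60L,
              i9_start + 50L,
              i9_start + 50L + nchar(alt32_seq) + 80L),
    end = c(i6_start + 60L + nchar(alt73_seq),
            i9_start + 50L + nchar(alt32_seq),
            i9_start + 50L + nchar(alt32_seq) + 80L + nchar(alt43_seq)))

  e13_start <- exon_tab$start[13]
  stop_pair <- c(reference = e13_start + (1155L - 1115L),
                 alternative = e13_start + (1165L - 1115L))

  suppressWarnings(
    ref_model(model_id = "rbfox2_synth",
              premrna_seq = premrna,
              exons = exon_tab,
              alt_starts = c(MEKK = 12L, MAEG = 0L),
              stop_pair = stop_pair,
              stop_spacing = 7L,
              domains = rbfox2_domains,
              nls_patterns = rbfox2_nls,
              alt_exons = alt_exons))
}

# ---- event menu and signatures ---------------------------------------------

#' Splice-event menu of the synthetic locus
#'
#' Returns the catalogue of elementary splice variations (spliced-transcript
#' coordinates) from which isoform signatures are composed: alternative
#' acceptor/donor truncations (-3a, -3b, -12, -39, -93), the exon 10 skip
#' (-40), a -2 micro-deletion, and alternative-exon inclusions (+32, +43,
#' +73).
#'
#' @param model The engineered reference from [rbfox2_reference()].
#' @return Named list of event specs (`type`, `tx_start`, `len`, `seq`).
#' @export
event_menu <- function(model) {
  txs <- tx_exon_starts(model)
  del <- function(start, len, kind, anchors)
    list(type = "del", tx_start = start, len = len, seq = "",
         kind = kind, anchors = anchors)
  ins <- function(pos, seq, anchors)
    list(type = "ins", tx_start = pos, len = nchar(seq), seq = seq,
         kind = "alt_exon_inclusion", anchors = anchors)
  list(
    # last 3 nt of exon 2
    "m3a" = del(txs[3] - 3L, 3L, "alt_donor_truncation", c("E02", "E03")),
    # first 3 nt of exon 4
    "m3b" = del(txs[4], 3L, "alt_acceptor_truncation", "E04"),
    # first 93 nt of exon 5
    "m93" = del(txs[5], 93L, "alt_acceptor_truncation", "E05"),
    # ALT6A after exon 6
    "p73" = ins(txs[7], alt73_seq, c("E06", "E07")),
    # first 12 nt of exon 9
    "m12" = del(txs[9], 12L, "alt_acceptor_truncation", "E09"),
    # first 39 nt of exon 9
    "m39" = del(txs[9], 39L, "alt_acceptor_truncation", "E09"),
    # micro-deletion inside exon 9
    "m2"  = del(txs[9] + 60L, 2L, "micro_deletion", "E09"),
    # ALT10A between exons 9 and 10
    "p32" = ins(txs[10], alt32_seq, c("E09", "E10")),
    # exon 10 skip
    "m40" = del(txs[10], 40L, "exon_skip", "E10"),
    # ALT10B replacing exon 10
    "p43" = ins(txs[10], alt43_seq, c("E09", "E10")))
}

#' Ground-truth splice events for a signature
#'
#' Expresses a signature from the menu as the standard events table used by
#' the caller and the ORF module (reference spliced-transcript coordinates,
#' 0-based half-open; insertions have `tx_start == tx_end`).
#'
#' @param model Reference model.
#' @param signature Signature name or vector of event ids.
#' @return Tibble (kind, anchor_exons, delta_nt, tx_start, tx_end,
#'   inserted_seq, junction_check).
#' @export
signature_events <- function(model, signature) {
  menu <- event_menu(model)
  if (length(signature) == 1L &&
      signature %in% names(signature_specs("all"))) {
    ids <- signature_specs("all")[[signature]]
  } else {
    ids <- signature
  }
  assert_that(all(ids %in% names(menu)), "unknown event id")
  if (length(ids) == 0L) {
    return(tibble::tibble(kind = character(0), anchor_exons = character(0),
                          delta_nt = integer(0), tx_start = integer(0),
                          tx_end = integer(0), inserted_seq = character(0),
                          junction_check = character(0)))
  }
  rows <- lapply(menu[ids], function(e) {
    tibble::tibble(
      kind = e$kind,
      anchor_exons = paste(e$anchors, collapse = ";"),
      delta_nt = if (e$type == "del") -e$len else e$len,
      tx_start = e$tx_start,
      tx_end = if (e$type == "del") e$tx_start + e$len else e$tx_start,
      inserted_seq = e$seq,
      junction_check = "confirmed")
  })
  ev <- dplyr::bind_rows(rows)
  ev[order(ev$tx_start), , drop = FALSE]
}

# Apply a standard events table to the reference spliced transcript.
apply_events <- function(model, events) {
  tx <- splice(model)
  if (NROW(events) == 0L) return(tx)
  ord <- order(events$tx_start,
               events$delta_nt < 0,  # at equal position, deletion first
               decreasing = TRUE)
  for (i in ord) {
    if (events$delta_nt[i] < 0) {
      tx <- paste0(substr0(tx, 0L, events$tx_start[i]),
                   substr0(tx, events$tx_end[i], nchar(tx)))
    } else {
      tx <- paste0(substr0(tx, 0L, events$tx_start[i]),
                   events$inserted_seq[i],
                   substr0(tx, events$tx_start[i], nchar(tx)))
    }
  }
  tx
}

#' Isoform signature definitions
#'
#' The eleven brain signatures (non-variant, +32, -12+32,
#' -3a-12, -12-40, -39, -93, -93+73, -93-12, -93-12-40, -3b-12-40) plus the
#' PC12-style extras (-12, -3b-12, -2-40+43).
#'
#' @param which `"brain"` (11 signatures), `"pc12"` (extras) or `"all"`.
#' @return Named list: signature name -> character vector of menu event ids.
#' @export
signature_specs <- function(which = c("brain", "pc12", "all")) {
  which <- match.arg(which)
  brain <- list(
    "non-variant" = character(0),
    "+32"         = "p32",
    "-12+32"      = c("m12", "p32"),
    "-3a-12"      = c("m3a", "m12"),
    "-12-40"      = c("m12", "m40"),
    "-39"         = "m39",
    "-93"         = "m93",
    "-93+73"      = c("m93", "p73"),
    "-93-12"      = c("m93", "m12"),
    "-93-12-40"   = c("m93", "m12", "m40"),
    "-3b-12-40"   = c("m3b", "m12", "m40"))
  pc12 <- list(
    "-12"         = "m12",
    "-3b-12"      = c("m3b", "m12"),
    "-2-40+43"    = c("m2", "m40", "p43"))
  switch(which, brain = brain, pc12 = pc12, all = c(brain, pc12))
}

#' Apply an isoform signature to the reference transcript
#'
#' @param model The engineered reference.
#' @param signature A signature name known to [signature_specs()], or a
#'   character vector of [event_menu()] ids.
#' @return The variant spliced cDNA sequence (character scalar).
#' @export
apply_signature <- function(model, signature) {
  apply_events(model, signature_events(model, signature))
}

# ---- simulation configuration ----------------------------------------------

#' Simulation configuration for the synthetic locus
#'
#' Defaults encode the study conditions: 22 clones per brain region, the
#' -12-40 signature at 12/22 (SCN) versus 4/22 (cortex), exon-7 inclusion
#' densitometry at 7.0 +/- 0.4 % (SCN) versus 1.7 +/- 0.4 % (cortex) with
#' n = 3 samples per group, and an Egr1-style qPCR experiment with fold
#' changes 0.92 (non-variant construct) and 1.12 (-12-40 construct) against
#' the empty-vector calibrator with n = 4 transfections per group.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_clones_per_group Named integer vector of clones per group.
#' @param group_freqs Named list: group -> named numeric vector of signature
#'   probabilities (must sum to 1 per group).
#' @param per_base_error_rate Per-base substitution probability applied to
#'   clone sequences (default 0; sequenced plasmid clones are treated as
#'   error-free consensus sequences).
#' @param densitometry Named list: group -> list(mean_pct, sem_pct, n); `n`
#'   is the cohort size the SEM refers to, so the per-sample SD is
#'   `sem_pct * sqrt(n)`.
#' @param qpcr Named list: group -> list(mean_dct, sd, n); `calibrator`
#'   names the calibrator group.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_clones_per_group = c(SCN = 22L, COR = 22L),
                       group_freqs = NULL,
                       per_base_error_rate = 0,
                       densitometry = list(
                         SCN = list(mean_pct = 7.0, sem_pct = 0.4, n = 3L),
                         COR = list(mean_pct = 1.7, sem_pct = 0.4, n = 3L)),
                       qpcr = list(
                         calibrator = "pc3.1",
                         groups = list(
                           "pc3.1"  = list(mean_dct = 6.0, sd = 0.2, n = 4L),
                           "RBF2"   = list(mean_dct = 6.0 - log2(0.92),
                                           sd = 0.2, n = 4L),
                           "-12-40" = list(mean_dct = 6.0 - log2(1.12),
                                           sd = 0.2, n = 4L)))) {
  assert_that(!missing(seed), "seed is mandatory")
  if (is.null(group_freqs)) {
    group_freqs <- list(
      SCN = c("non-variant" = 4, "+32" = 1, "-12+32" = 1, "-3a-12" = 2,
              "-12-40" = 12, "-39" = 1, "-93" = 1) / 22,
      COR = c("non-variant" = 5, "+32" = 2, "-12-40" = 4, "-93" = 5,
              "-93+73" = 1, "-93-12" = 2, "-93-12-40" = 1,
              "-3b-12-40" = 2) / 22)
  }
  for (g in names(group_freqs)) {
    assert_that(abs(sum(group_freqs[[g]]) - 1) < 1e-9,
                sprintf("group '%s' frequencies must sum to 1", g))
  }
  for (d in densitometry) {
    assert_that(d$mean_pct > 0 && d$mean_pct < 100,
                "densitometry mean must be inside (0, 100)")
  }
  structure(list(seed = as.integer(seed),
                 n_exons = 13L,
                 n_clones_per_group = n_clones_per_group,
                 group_freqs = group_freqs,
                 per_base_error_rate = per_base_error_rate,
                 densitometry = densitometry,
                 qpcr = qpcr),
            class = "sim_config")
}

#' Build the reference model for a simulation configuration
#'
#' With the default `n_exons = 13` this is the engineered locus of
#' [rbfox2_reference()]; `n_exons = 1` yields a trivial single-exon model
#' whose ORF is the whole exon.
#'
#' @param config A `sim_config` (or a list with `n_exons`).
#' @return A `ref_model`.
#' @export
build_reference <- function(config) {
  n_exons <- config$n_exons %||% 13L
  if (n_exons == 13L) {
    return(rbfox2_reference())
  }
  if (n_exons == 1L) {
    cds <- paste0("ATG", "GAAAAGAAATCTGGTCACTTCGATCATTGG", "TGA")
    return(ref_model(model_id = "trivial_synth",
                     premrna_seq = cds,
                     exons = data.frame(exon_id = "E01", start = 0L,
                                        end = nchar(cds)),
                     alt_starts = c(MEKK = 0L)))
  }
  stop("build_reference supports n_exons = 13 (engineered locus) or 1",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate clone populations with planted isoform signatures
#'
#' Per group, clone counts are a seeded multinomial draw from the configured
#' signature frequencies; each clone is the spliced reference with its
#' signature's events applied exactly, plus optional per-base substitution
#' noise.  The true signature is recorded for recovery scoring.
#'
#' @param model Reference model.
#' @param config A [sim_config()].
#' @return Tibble (clone_id, group, signature_true, seq).
#' @export
generate_clones <- function(model, config) {
  menu <- event_menu(model)
  out <- list()
  with_seed(derive_seed(config$seed, 1L), {
    for (g in names(config$n_clones_per_group)) {
      n <- config$n_clones_per_group[[g]]
      freqs <- config$group_freqs[[g]]
      assert_that(!is.null(freqs), sprintf("no frequencies for group %s", g))
      specs <- signature_specs("all")
      assert_that(all(names(freqs) %in% names(specs)),
                  "group frequencies name unknown signatures")
      counts <- as.vector(rmultinom(1L, n, freqs))
      sigs <- rep(names(freqs), counts)
      seqs <- vapply(sigs, function(s) apply_signature(model, s), "",
                     USE.NAMES = FALSE)
      out[[g]] <- tibble::tibble(
        clone_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g, signature_true = sigs, seq = seqs)
    }
  })
  clones <- dplyr::bind_rows(out)
  if (config$per_base_error_rate > 0) {
    clones$seq <- add_base_noise(clones$seq, config$per_base_error_rate,
                                 derive_seed(config$seed, 2L))
  }
  clones
}

# Seeded per-base substitution noise (always to a different base).
add_base_noise <- function(seqs, rate, seed) {
  with_seed(seed, {
    vapply(seqs, function(s) {
      n <- nchar(s)
      hit <- which(runif(n) < rate)
      if (!length(hit)) return(s)
      ch <- strsplit(s, "")[[1]]
      for (i in hit) {
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
}

#' Generate a two-band densitometry (exon inclusion) table
#'
#' Per-sample percent inclusion is drawn from a normal distribution centred
#' on the configured group mean with SD `sem_pct * sqrt(n)` (the per-sample
#' SD implied by the reported SEM and cohort size), truncated by clamping to
#' `[0, 100]`; total band intensity is log-normal.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples per group (defaults to each group's
#'   configured `n`).
#' @return Tibble (sample_id, group, included_intensity,
#'   excluded_intensity).
#' @export
generate_densitometry <- function(config, n_samples = NULL) {
  with_seed(derive_seed(config$seed, 3L), {
    out <- lapply(names(config$densitometry), function(g) {
      d <- config$densitometry[[g]]
      ns <- if (is.null(n_samples)) d$n else n_samples
      sdv <- d$sem_pct * sqrt(d$n)
      psi <- pmin(100, pmax(0, rnorm(ns, d$mean_pct, sdv)))
      total <- rlnorm(ns, log(2e4), 0.25)
      tibble::tibble(sample_id = sprintf("%s_s%04d", g, seq_len(ns)),
                     group = g,
                     included_intensity = total * psi / 100,
                     excluded_intensity = total * (100 - psi) / 100)
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a qPCR Ct table
#'
#' Per sample, a reference-gene Ct is drawn near 16 cycles and the target Ct
#' is `reference + dCt` with `dCt ~ N(mean_dct, sd)` for its group.
#'
#' @param config A [sim_config()].
#' @return Tibble (sample_id, group, gene, ct) with gene in
#'   `c("target", "reference")`.
#' @export
generate_qpcr <- function(config) {
  with_seed(derive_seed(config$seed, 4L), {
    out <- lapply(names(config$qpcr$groups), function(g) {
      q <- config$qpcr$groups[[g]]
      ct_ref <- rnorm(q$n, 16, 0.15)
      dct <- rnorm(q$n, q$mean_dct, q$sd)
      ids <- sprintf("%s_r%d", g, seq_len(q$n))
      tibble::tibble(sample_id = rep(ids, 2L),
                     group = g,
                     gene = rep(c("target", "reference"), each = q$n),
                     ct = c(ct_ref + dct, ct_ref))
    })
    dplyr::bind_rows(out)
  })
}

#' Write a complete simulated data set to a directory
#'
#' Writes the reference model (FASTA + tables + YAML config + GFF3 exons),
#' per-group clone FASTA and group map, the clone truth table, and the
#' densitometry and qPCR TSVs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_reference(config)
  write_reference(model, file.path(dir, "model"))
  export_exons_gff3(model, file.path(dir, "model", "exons.gff3"))
  clones <- generate_clones(model, config)
  write_clones(clones, file.path(dir, "clones.fasta"),
               file.path(dir, "groups.tsv"))
  write.table(clones[, c("clone_id", "group", "signature_true")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(generate_densitometry(config),
              file.path(dir, "densitometry.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(generate_qpcr(config), file.path(dir, "qpcr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
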