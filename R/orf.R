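# Open reading frame consequences: translation, frame/stop usage, NMD
# candidacy, domain impact, NLS scanning and residue composition.

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Translate an in-frame nucleotide string codon-by-codon (standard code),
# returning the aa string including any '*'.
translate_codons <- function(nt) {
  n <- 3L * (nchar(nt) %/% 3L)
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- codon_table()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate an isoform transcript from a start offset
#'
#' Standard nuclear genetic code, from the start codon to the first in-frame
#' stop.  If no stop occurs before the end of the transcript the ORF is
#' reported as run-through with the partial protein.
#'
#' @param transcript Spliced (isoform) transcript, character scalar.
#' @param start_offset 0-based offset of the `A` of the start `ATG`.
#' @param force Allow a non-ATG start.
#' @return List with `protein`, `orf_nt_len` (excludes the stop codon),
#'   `stop_offset` (0-based offset of the stop codon, `NA` if run-through),
#'   `terminal_tetrapeptide`, `run_through`.
#' @export
find_orf <- function(transcript, start_offset, force = FALSE) {
  transcript <- normalize_dna(transcript)
  assert_that(start_offset >= 0 && start_offset < nchar(transcript),
              "start offset beyond transcript end")
  if (!force) {
    assert_that(substr0(transcript, start_offset, start_offset + 3L) == "ATG",
                "start offset does not point at ATG (use force = TRUE)")
  }
  aa <- translate_codons(substring(transcript, start_offset + 1L))
  st <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (st > 0L) {
    protein <- substr(aa, 1L, st - 1L)
    stop_offset <- start_offset + 3L * (st - 1L)
    run_through <- FALSE
  } else {
    protein <- aa
    stop_offset <- NA_integer_
    run_through <- TRUE
  }
  np <- nchar(protein)
  list(protein = protein,
       orf_nt_len = 3L * np,
       stop_offset = stop_offset,
       terminal_tetrapeptide = substr(protein, max(1L, np - 3L), np),
       run_through = run_through)
}

# Map a reference spliced-transcript coordinate through an events table to
# the variant transcript coordinate (positions inside deletions map to the
# deletion point).
map_ref_to_variant <- function(pos, events) {
  if (NROW(events) == 0L) return(pos)
  shift <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$delta_nt[i] < 0) {
      if (events$tx_end[i] <= pos) {
        shift <- shift + events$delta_nt[i]
      } else if (events$tx_start[i] < pos) {
        shift <- shift - (pos - events$tx_start[i])
      }
    } else if (events$tx_start[i] <= pos) {
      shift <- shift + events$delta_nt[i]
    }
  }
  pos + shift
}

#' Exon-exon junction offsets of a variant transcript
#'
#' Maps the reference junctions through the called events (skipped-exon
#' junctions collapse; included alternative exons contribute two new
#' junctions) and returns sorted unique 0-based offsets on the variant
#' transcript.
#'
#' @param model Reference model.
#' @param events Standard events table (may be empty).
#' @return Integer vector of junction offsets.
#' @export
variant_junctions <- function(model, events) {
  txs <- tx_exon_starts(model)
  ref_j <- txs[-c(1L, length(txs))]
  vj <- vapply(ref_j, map_ref_to_variant, 0L, events = events)
  if (NROW(events)) {
    for (i in seq_len(nrow(events))) {
      if (events$delta_nt[i] > 0) {
        s <- map_ref_to_variant(events$tx_start[i], events)
        # the insertion maps after upstream events; its own length is added
        # by map_ref_to_variant, so its variant span is [s - len, s]
        vj <- c(vj, s - events$delta_nt[i], s)
      }
    }
  }
  len <- nchar(splice(model)) + sum(events$delta_nt %||% 0L)
  vj <- sort(unique(vj))
  vj[vj > 0L & vj < len]
}

#' Frame and stop-codon usage implied by called events
#'
#' The cumulative signed event length upstream of each position sets the
#' local reading frame (`delta mod 3`); the first event after which the
#' cumulative delta is not a multiple of 3 marks the frameshift point.  The
#' variant transcript is translated to find which of the model's paired stop
#' codons (or an earlier premature stop) terminates the ORF.
#'
#' @param events Standard events table.
#' @param model Reference model (with `stop_pair`).
#' @param start_label Which alternative start to translate from.
#' @return List with `frame_shift_from` (reference transcript offset of the
#'   first frame-shifting event, `NA` if none), `frame` (net delta mod 3),
#'   `stop_used` (`"reference"`, `"alternative"`, `"premature"` or
#'   `"run_through"`), `stop_offset` (variant transcript), and
#'   `terminal_tetrapeptide`.
#' @export
frame_and_stop <- function(events, model, start_label = "MEKK") {
  start_ref <- model$alt_starts[[start_label]]
  assert_that(!is.null(start_ref), "unknown start label")
  ev <- if (NROW(events)) events[order(events$tx_start), , drop = FALSE]
        else events
  cum <- 0L
  frame_shift_from <- NA_integer_
  if (NROW(ev)) {
    for (i in seq_len(nrow(ev))) {
      cum <- cum + ev$delta_nt[i]
      if (is.na(frame_shift_from) && cum %% 3L != 0L) {
        frame_shift_from <- ev$tx_start[i]
      }
    }
  }
  vtx <- apply_events(model, ev)
  vstart <- map_ref_to_variant(start_ref, ev)
  orf <- find_orf(vtx, vstart)
  stop_used <- "run_through"
  if (!orf$run_through) {
    stop_used <- "premature"
    if (!is.null(model$stop_pair)) {
      ref_stop <- premrna_to_tx(model, unname(model$stop_pair["reference"]))
      alt_stop <- premrna_to_tx(model, unname(model$stop_pair["alternative"]))
      if (orf$stop_offset == map_ref_to_variant(ref_stop, ev)) {
        stop_used <- "reference"
      } else if (orf$stop_offset == map_ref_to_variant(alt_stop, ev)) {
        stop_used <- "alternative"
      }
    }
  }
  list(frame_shift_from = frame_shift_from,
       frame = ((cum %% 3L) + 3L) %% 3L,
       stop_used = stop_used,
       stop_offset = orf$stop_offset,
       terminal_tetrapeptide = orf$terminal_tetrapeptide)
}

#' Nonsense-mediated decay check (50-55 nt junction rule)
#'
#' A stop codon more than `threshold_nt` upstream of the last exon-exon
#' junction flags the transcript for NMD (strict inequality); distances in
#' `(50, threshold_nt]` are labelled borderline.
#'
#' @param stop_offset 0-based offset of the stop codon on the (variant)
#'   transcript.
#' @param junction_offsets Junction offsets of the same transcript.
#' @param threshold_nt NMD distance threshold (default 55).
#' @return List with `nmd` (logical), `distance` (last junction minus stop
#'   codon end; negative when the stop is in the last exon) and
#'   `borderline`.
#' @export
nmd_check <- function(stop_offset, junction_offsets, threshold_nt = 55L) {
  if (is.na(stop_offset) || length(junction_offsets) == 0L) {
    return(list(nmd = FALSE, distance = NA_integer_, borderline = FALSE))
  }
  distance <- max(junction_offsets) - (stop_offset + 3L)
  list(nmd = distance > threshold_nt,
       distance = distance,
       borderline = distance > 50L && distance <= threshold_nt)
}

# Global protein alignment (Needleman-Wunsch) returning the two gapped
# strings.
align_proteins <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Protein domains impacted by an isoform's changes
#'
#' The variant protein is globally aligned to the non-variant protein; every
#' substituted or deleted non-variant residue, and the anchor residue of
#' every insertion, marks a changed position.  A domain is impacted when any
#' changed position falls in its interval.  Post-frameshift tails surface as
#' long mismatch/deletion stretches and are captured by the same rule.
#'
#' @param variant_protein Variant protein (aa string).
#' @param model Reference model carrying `domains`.
#' @param nonvariant_protein The non-variant protein; defaults to the
#'   MEKK-start translation of the model itself.
#' @return Character vector of impacted domain labels (possibly empty).
#' @export
domain_impact <- function(variant_protein, model,
                          nonvariant_protein = NULL) {
  if (is.null(nonvariant_protein)) {
    nonvariant_protein <- find_orf(splice(model),
                                   model$alt_starts[["MEKK"]])$protein
  }
  if (identical(variant_protein, nonvariant_protein)) return(character(0))
  if (!nzchar(variant_protein)) {
    changed <- seq_len(nchar(nonvariant_protein))
  } else {
    g <- align_proteins(variant_protein, nonvariant_protein)
    va <- strsplit(g$a, "")[[1]]
    nv <- strsplit(g$b, "")[[1]]
    refpos <- cumsum(nv != "-")
    changed <- integer(0)
    for (i in seq_along(va)) {
      if (nv[i] == "-") {
        # insertion relative to non-variant: anchor at the preceding residue
        changed <- c(changed, max(refpos[i], 1L))
      } else if (va[i] == "-" || va[i] != nv[i]) {
        changed <- c(changed, refpos[i])
      }
    }
    changed <- unique(changed)
  }
  dom <- model$domains
  hit <- vapply(seq_len(nrow(dom)), function(i) {
    any(changed >= dom$aa_start[i] & changed <= dom$aa_end[i])
  }, NA)
  dom$domain_label[hit]
}

#' Scan a protein for NLS motifs
#'
#' Sliding-window match of each amino-acid pattern allowing up to
#' `max_mismatches` substitutions.
#'
#' @param protein Protein string.
#' @param nls_patterns Character vector of aa motifs.
#' @param max_mismatches Maximum substitutions per hit (default 0).
#' @return Tibble (pattern, aa_position, mismatches), positions 1-based.
#' @export
scan_nls <- function(protein, nls_patterns, max_mismatches = 0L) {
  out <- list()
  pv <- strsplit(protein, "")[[1]]
  for (pat in nls_patterns) {
    k <- nchar(pat)
    if (k == 0L || k > length(pv)) next
    pc <- strsplit(pat, "")[[1]]
    for (i in seq_len(length(pv) - k + 1L)) {
      mm <- sum(pv[i:(i + k - 1L)] != pc)
      if (mm <= max_mismatches) {
        out[[length(out) + 1L]] <- tibble::tibble(
          pattern = pat, aa_position = i, mismatches = mm)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(pattern = character(0), aa_position = integer(0),
                      mismatches = integer(0))
}

#' Residue and dipeptide composition
#'
#' @param protein Protein string.
#' @param region Optional `c(aa_start, aa_end)` (1-based inclusive) or a
#'   domain label resolvable against `domains`.
#' @param dipeptides Character vector of dipeptides to count (overlapping
#'   occurrences counted).
#' @param domains Optional domain table used to resolve a region label.
#' @return List with `residues` (named counts over the 20 amino acids) and
#'   `dipeptides` (named counts).
#' @export
composition_stats <- function(protein, region = NULL,
                              dipeptides = character(0), domains = NULL) {
  if (is.character(region) && length(region) == 1L && !is.null(domains)) {
    i <- match(region, domains$domain_label)
    assert_that(!is.na(i), "unknown domain label")
    region <- c(domains$aa_start[i], domains$aa_end[i])
  }
  if (!is.null(region)) {
    protein <- substr(protein, region[1], min(region[2], nchar(protein)))
  }
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(protein, "")[[1]]
  residues <- setNames(vapply(aas, function(a) sum(ch == a), 0L), aas)
  dp <- setNames(integer(length(dipeptides)), dipeptides)
  if (length(ch) >= 2L) {
    pairs <- paste0(ch[-length(ch)], ch[-1])
    for (d in dipeptides) dp[d] <- sum(pairs == d)
  }
  list(residues = residues, dipeptides = dp)
}

#' Percent identity of two proteins
#'
#' Global alignment; identity = matching columns / alignment columns x 100.
#'
#' @param protein_a,protein_b Non-empty aa strings.
#' @return Numeric percent identity.
#' @export
pairwise_identity <- function(protein_a, protein_b) {
  assert_that(nzchar(protein_a) && nzchar(protein_b),
              "sequences must be non-empty")
  g <- align_proteins(protein_a, protein_b)
  a <- strsplit(g$a, "")[[1]]
  b <- strsplit(g$b, "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Full ORF report for one isoform
#'
#' Runs translation, frame/stop analysis, the NMD junction rule, domain
#' impact, NLS scanning and composition for an events table (or a named
#' signature of the synthetic locus).
#'
#' @param model Reference model.
#' @param events Standard events table, or a signature name.
#' @param start_label Alternative start to use (default `"MEKK"`).
#' @param nmd_threshold NMD distance threshold in nt.
#' @return One-row tibble with the OrfReport fields.
#' @export
orf_report <- function(model, events, start_label = "MEKK",
                       nmd_threshold = 55L) {
  if (is.character(events)) {
    signature <- events
    events <- signature_events(model, events)
  } else {
    signature <- NA_character_
  }
  vtx <- apply_events(model, events)
  vstart <- map_ref_to_variant(model$alt_starts[[start_label]], events)
  orf <- find_orf(vtx, vstart)
  fs <- frame_and_stop(events, model, start_label)
  nm <- nmd_check(orf$stop_offset, variant_junctions(model, events),
                  nmd_threshold)
  di <- domain_impact(orf$protein, model)
  nls <- scan_nls(orf$protein, model$nls_patterns)
  tibble::tibble(
    signature = signature,
    start_label = start_label,
    orf_nt_len = orf$orf_nt_len,
    protein = orf$protein,
    frame_shift_from = fs$frame_shift_from,
    frame = fs$frame,
    stop_used = fs$stop_used,
    stop_offset = orf$stop_offset,
    terminal_tetrapeptide = orf$terminal_tetrapeptide,
    run_through = orf$run_through,
    nmd = nm$nmd,
    nmd_distance = nm$distance,
    nmd_borderline = nm$borderline,
    domain_impact = paste(di, collapse = ";"),
    n_nls_hits = nrow(nls))
}
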