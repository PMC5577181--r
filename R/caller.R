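# Splice-aware isoform calling: clone-versus-reference alignment, event
# normalization and classification, signature naming, population summaries.

default_scoring <- list(match = 1, mismatch = -2, gap_open = 5, gap_ext = 1)

# Global affine-gap alignment of clone vs spliced reference; returns the two
# gapped rows.
align_clone <- function(clone_seq, ref_seq, scoring = default_scoring) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(clone_seq), Biostrings::DNAString(ref_seq),
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    type = "global")
  list(clone = as.character(Biostrings::alignedPattern(aln)),
       ref = as.character(Biostrings::alignedSubject(aln)))
}

# Extract raw gaps from a pair of gapped rows.  Returns deletions (ref
# intervals absent from the clone) and insertions (clone segments absent
# from the reference, located at a reference position), plus match stats.
gaps_from_alignment <- function(g) {
  cl <- strsplit(g$clone, "")[[1]]
  rf <- strsplit(g$ref, "")[[1]]
  n <- length(cl)
  refpos <- cumsum(rf != "-")     # 1-based ref coordinate at each column
  dels <- list()
  inss <- list()
  i <- 1L
  while (i <= n) {
    if (cl[i] == "-") {
      j <- i
      while (j < n && cl[j + 1L] == "-") j <- j + 1L
      dels[[length(dels) + 1L]] <- c(start = refpos[i] - 1L, end = refpos[j])
      i <- j + 1L
    } else if (rf[i] == "-") {
      j <- i
      while (j < n && rf[j + 1L] == "-") j <- j + 1L
      inss[[length(inss) + 1L]] <- list(
        pos = refpos[i],          # 0-based ref position the insert precedes
        seq = paste(cl[i:j], collapse = ""))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  aligned <- cl != "-" & rf != "-"
  list(deletions = dels, insertions = inss,
       n_match = sum(aligned & cl == rf),
       n_mismatch = sum(aligned & cl != rf),
       n_columns = n)
}

# Content-preserving placements of a deletion [d0, d1): shift left while the
# base before the gap equals the last base inside it, right likewise.
deletion_placements <- function(ref, d0, d1) {
  lo <- d0
  while (lo > 0L && substr(ref, lo, lo) == substr(ref, lo + (d1 - d0), lo + (d1 - d0))) {
    lo <- lo - 1L
  }
  hi <- d0
  while (hi + (d1 - d0) < nchar(ref) &&
         substr(ref, hi + 1L, hi + 1L) == substr(ref, hi + (d1 - d0) + 1L, hi + (d1 - d0) + 1L)) {
    hi <- hi + 1L
  }
  lo:hi
}

# Content-preserving placements of an insertion of string s before ref pos p
# (rotating the inserted string accordingly).  Returns candidate positions.
insertion_placements <- function(ref, p, s) {
  len <- nchar(s)
  lo <- p
  s_lo <- s
  while (lo > 0L && substr(ref, lo, lo) == substr(s_lo, len, len)) {
    s_lo <- paste0(substr(ref, lo, lo), substr(s_lo, 1L, len - 1L))
    lo <- lo - 1L
  }
  hi <- p
  s_hi <- s
  while (hi < nchar(ref) &&
         substr(ref, hi + 1L, hi + 1L) == substr(s_hi, 1L, 1L)) {
    s_hi <- paste0(substr(s_hi, 2L, len), substr(ref, hi + 1L, hi + 1L))
    hi <- hi + 1L
  }
  list(range = lo:hi, at = function(q) {
    # rotate s so it is expressed at position q
    if (q == p) return(s)
    if (q < p) {
      k <- p - q
      paste0(substr(ref, q + 1L, p), substr(s, 1L, len - k))
    } else {
      k <- q - p
      paste0(substr(s, k + 1L, len), substr(ref, p + 1L, q))
    }
  })
}

# Pick the placement of a deletion: prefer one aligning with an annotated
# exon boundary (5' start, then 3' end) within the content-preserving range
# extended by at most snap_k, else the leftmost placement.
place_deletion <- function(ref, d0, d1, boundaries, snap_k = 3L) {
  len <- d1 - d0
  cand <- deletion_placements(ref, d0, d1)
  starts_ok <- cand[cand %in% boundaries$starts]
  ends_ok <- cand[(cand + len) %in% boundaries$ends]
  both <- intersect(starts_ok, ends_ok)
  pick <- if (length(both)) min(both)
          else if (length(starts_ok)) min(starts_ok)
          else if (length(ends_ok)) min(ends_ok)
          else min(cand)
  c(pick, pick + len)
}

place_insertion <- function(ref, p, s, boundaries) {
  pl <- insertion_placements(ref, p, s)
  at_junction <- pl$range[pl$range %in% boundaries$junctions]
  pick <- if (length(at_junction)) min(at_junction) else min(pl$range)
  list(pos = pick, seq = pl$at(pick))
}

exon_boundaries <- function(model) {
  txs <- tx_exon_starts(model)
  list(starts = txs[-length(txs)],
       ends = txs[-1L],
       junctions = txs[-c(1L, length(txs))])
}

# Classify a placed deletion into splice events, splitting at internal exon
# boundaries where the deletion spans them.
classify_deletion <- function(model, d0, d1) {
  ex <- model$exons
  txs <- tx_exon_starts(model)
  inner <- txs[txs > d0 & txs < d1]
  cuts <- c(d0, inner, d1)
  out <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    s <- cuts[i]
    e <- cuts[i + 1L]
    xi <- findInterval(s, txs)
    es <- txs[xi]
    ee <- txs[xi + 1L]
    eid <- ex$exon_id[xi]
    if (s == es && e == ee) {
      kind <- "exon_skip"
      anchors <- eid
      jc <- "not_applicable"
    } else if (s == es) {
      kind <- "alt_acceptor_truncation"
      anchors <- eid
      p <- tx_to_premrna(model, e)
      jc <- if (substr0(model$premrna_seq, p - 2L, p) == "AG")
        "confirmed" else "not_confirmed"
    } else if (e == ee) {
      kind <- "alt_donor_truncation"
      anchors <- c(eid, if (xi < nrow(ex)) ex$exon_id[xi + 1L])
      p <- tx_to_premrna(model, s)
      jc <- if (substr0(model$premrna_seq, p, p + 2L) == "GT")
        "confirmed" else "not_confirmed"
    } else {
      kind <- "micro_deletion"
      anchors <- eid
      pa <- tx_to_premrna(model, s)
      pb <- tx_to_premrna(model, e)
      jc <- if (substr0(model$premrna_seq, pa - 2L, pa) == "AG" &&
                substr0(model$premrna_seq, pb, pb + 2L) == "GT")
        "confirmed" else "not_confirmed"
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      kind = kind, anchor_exons = paste(anchors, collapse = ";"),
      delta_nt = -(e - s), tx_start = s, tx_end = e,
      inserted_seq = "", junction_check = jc)
  }
  dplyr::bind_rows(out)
}

classify_insertion <- function(model, pos, s) {
  txs <- tx_exon_starts(model)
  ex <- model$exons
  jc <- "not_confirmed"
  anchors <- ex$exon_id[min(findInterval(pos, txs), nrow(ex))]
  ji <- match(pos, txs[-c(1L, length(txs))])
  if (!is.na(ji)) {
    # insertion at the junction between exon ji and ji+1: search the intron
    anchors <- c(ex$exon_id[ji], ex$exon_id[ji + 1L])
    istart <- ex$end[ji]
    iend <- ex$start[ji + 1L]
    intron <- substr0(model$premrna_seq, istart, iend)
    hit <- regexpr(s, intron, fixed = TRUE)
    if (hit > 0L) {
      q <- istart + as.integer(hit) - 1L   # 0-based pre-mRNA start of insert
      before <- substr0(model$premrna_seq, q - 2L, q)
      after <- substr0(model$premrna_seq, q + nchar(s), q + nchar(s) + 2L)
      if (before == "AG" && after == "GT") jc <- "confirmed"
    }
  }
  tibble::tibble(kind = "alt_exon_inclusion",
                 anchor_exons = paste(anchors, collapse = ";"),
                 delta_nt = nchar(s), tx_start = pos, tx_end = pos,
                 inserted_seq = s, junction_check = jc)
}

#' Align a clone against the reference and call splice events
#'
#' Global affine-gap alignment of the clone against the spliced reference;
#' each gap is normalized (content-preserving placements are enumerated and
#' the one aligning with an annotated exon boundary is preferred, else the
#' leftmost), adjacent gaps are merged, and gaps are classified into splice
#' events with pre-mRNA GT..AG checks for novel junctions.
#'
#' @param clone_seq Clone cDNA sequence.
#' @param model Reference model.
#' @param min_identity Percent identity below which the clone is flagged
#'   unalignable (default 80).
#' @param length_ratio Admissible clone/reference length ratio bounds.
#' @param scoring List (match, mismatch, gap_open, gap_ext).
#' @param snap_k Exon-boundary snap window in nt (default 3).
#' @return List with `events` (standard events table), `identity`,
#'   `n_substitutions`, `unalignable`, and `reconstruction` (clone sequence
#'   rebuilt from reference segments plus inserted sequences; equals the
#'   clone byte-for-byte for substitution-free clones).
#' @export
splice_align <- function(clone_seq, model, min_identity = 80,
                         length_ratio = c(0.5, 1.5),
                         scoring = default_scoring, snap_k = 3L) {
  clone_seq <- normalize_dna(clone_seq)
  ref <- splice(model)
  empty <- tibble::tibble(kind = character(0), anchor_exons = character(0),
                          delta_nt = integer(0), tx_start = integer(0),
                          tx_end = integer(0), inserted_seq = character(0),
                          junction_check = character(0))
  ratio <- nchar(clone_seq) / nchar(ref)
  if (ratio < length_ratio[1] || ratio > length_ratio[2]) {
    message("clone length ratio ", round(ratio, 2), " outside bounds; ",
            "flagged unalignable")
    return(list(events = empty, identity = NA_real_,
                n_substitutions = NA_integer_, unalignable = TRUE,
                reconstruction = NA_character_))
  }
  g <- align_clone(clone_seq, ref, scoring)
  raw <- gaps_from_alignment(g)
  # substitution-level identity over aligned (non-gap) columns: splice-size
  # indels are legitimate, so gaps do not count against a clone
  identity <- 100 * raw$n_match / (raw$n_match + raw$n_mismatch)
  if (identity < min_identity) {
    message("clone identity ", round(identity, 1), "% below threshold; ",
            "flagged unalignable")
    return(list(events = empty, identity = identity,
                n_substitutions = raw$n_mismatch, unalignable = TRUE,
                reconstruction = NA_character_))
  }
  bnd <- exon_boundaries(model)

  placed_dels <- lapply(raw$deletions, function(d) {
    place_deletion(ref, d[["start"]], d[["end"]], bnd, snap_k)
  })
  # merge deletions that become adjacent after normalization
  if (length(placed_dels) > 1L) {
    placed_dels <- placed_dels[order(vapply(placed_dels, `[`, 0, 1L))]
    merged <- list(placed_dels[[1L]])
    for (d in placed_dels[-1L]) {
      last <- merged[[length(merged)]]
      if (d[1L] == last[2L]) {
        merged[[length(merged)]] <- c(last[1L], d[2L])
      } else {
        merged[[length(merged) + 1L]] <- d
      }
    }
    placed_dels <- merged
  }
  placed_inss <- lapply(raw$insertions, function(i) {
    place_insertion(ref, i$pos, i$seq, bnd)
  })

  events <- dplyr::bind_rows(
    lapply(placed_dels, function(d) classify_deletion(model, d[1L], d[2L])),
    lapply(placed_inss, function(i) classify_insertion(model, i$pos, i$seq)))
  if (NROW(events)) {
    events <- events[order(events$tx_start, events$delta_nt), , drop = FALSE]
    events <- refine_substitutions(model, events, g)
  } else {
    events <- empty
  }

  # conservation contract: reference-retained segments plus insertions
  recon <- reconstruct_clone(ref, events)
  list(events = events, identity = identity,
       n_substitutions = raw$n_mismatch, unalignable = FALSE,
       reconstruction = recon)
}

# Clone subsequence aligned to the reference window (ref_a, ref_b]
# (0-based half-open window [ref_a, ref_b)), including inserted columns.
clone_segment <- function(g, ref_a, ref_b) {
  cl <- strsplit(g$clone, "")[[1]]
  rf <- strsplit(g$ref, "")[[1]]
  refpos <- cumsum(rf != "-")
  keep <- (refpos > ref_a | (refpos == ref_a & rf == "-")) & refpos <= ref_b
  paste(cl[keep][cl[keep] != "-"], collapse = "")
}

# Annotation-guided refinement: a mutually-exclusive-exon substitution
# (annotated exon replaced by an annotated alternative exon from a flanking
# intron) defeats plain global alignment, which stitches the two exons
# together with small gaps.  When untidy events overlap an exon whose
# flanking intron holds an alternative exon, and the clone's aligned segment
# across that exon equals the alternative exon sequence exactly, the events
# are re-expressed canonically as exon_skip + alt_exon_inclusion.
refine_substitutions <- function(model, events, g) {
  if (is.null(model$alt_exons) || NROW(events) == 0L) return(events)
  if (!any(events$junction_check == "not_confirmed")) return(events)
  ex <- model$exons
  txs <- tx_exon_starts(model)
  for (ai in seq_len(nrow(model$alt_exons))) {
    alt <- model$alt_exons[ai, ]
    alt_seq <- substr0(model$premrna_seq, alt$start, alt$end)
    # exons whose flanking intron hosts this alternative exon
    for (ei in seq_len(nrow(ex))) {
      upstream_intron <- ei > 1L && alt$end <= ex$start[ei] &&
        alt$start >= ex$end[ei - 1L]
      downstream_intron <- ei < nrow(ex) && alt$start >= ex$end[ei] &&
        alt$end <= ex$start[ei + 1L]
      if (!upstream_intron && !downstream_intron) next
      es <- txs[ei]
      ee <- txs[ei + 1L]
      touches <- events$tx_start < ee + 3L & events$tx_end > es - 3L
      if (!any(touches & events$junction_check == "not_confirmed")) next
      if (clone_segment(g, es, ee) == alt_seq) {
        p <- if (upstream_intron) es else ee
        repl <- dplyr::bind_rows(
          tibble::tibble(kind = "exon_skip",
                         anchor_exons = ex$exon_id[ei],
                         delta_nt = -(ee - es), tx_start = es, tx_end = ee,
                         inserted_seq = "",
                         junction_check = "not_applicable"),
          tibble::tibble(kind = "alt_exon_inclusion",
                         anchor_exons = paste(ex$exon_id[pmax(ei - 1L, 1L)],
                                              ex$exon_id[ei], sep = ";"),
                         delta_nt = nchar(alt_seq), tx_start = p, tx_end = p,
                         inserted_seq = alt_seq,
                         junction_check = "confirmed"))
        events <- dplyr::bind_rows(events[!touches, , drop = FALSE], repl)
        events <- events[order(events$tx_start, events$delta_nt), ,
                         drop = FALSE]
      }
    }
  }
  events
}

#' Rebuild a clone from reference segments and called events
#'
#' @param ref Spliced reference transcript.
#' @param events Standard events table.
#' @return Character scalar; for substitution-free clones this equals the
#'   clone sequence byte-for-byte.
#' @export
reconstruct_clone <- function(ref, events) {
  if (NROW(events) == 0L) return(ref)
  ev <- events[order(events$tx_start, events$delta_nt), , drop = FALSE]
  out <- character(0)
  cur <- 0L
  for (i in seq_len(nrow(ev))) {
    out <- c(out, substr0(ref, cur, ev$tx_start[i]))
    if (ev$delta_nt[i] > 0) {
      out <- c(out, ev$inserted_seq[i])
      cur <- max(cur, ev$tx_start[i])
    } else {
      cur <- ev$tx_end[i]
    }
  }
  out <- c(out, substr0(ref, cur, nchar(ref)))
  paste(out, collapse = "")
}

#' Locus suffix registry for signature naming
#'
#' When two distinct loci host events of the same signed length (the two -3
#' variations), letter suffixes are assigned in order of reference position
#' ("a" most 5').
#'
#' @param events_list List of standard events tables (one per clone), or a
#'   single combined table.
#' @return Named character vector: `"<delta>@<tx_start>"` -> suffix.
#' @export
locus_registry <- function(events_list) {
  ev <- if (is.data.frame(events_list)) events_list
        else dplyr::bind_rows(events_list)
  if (NROW(ev) == 0L) return(character(0))
  key <- unique(ev[, c("delta_nt", "tx_start")])
  key <- key[order(key$delta_nt, key$tx_start), , drop = FALSE]
  out <- character(0)
  for (d in unique(key$delta_nt)) {
    loci <- sort(key$tx_start[key$delta_nt == d])
    suff <- if (length(loci) > 1L) letters[seq_along(loci)] else ""
    out[paste0(d, "@", loci)] <- suff
  }
  out
}

#' Canonical signature name for a set of called events
#'
#' Signed event lengths concatenated 5' to 3' (e.g. `-12-40`, `+32`), with
#' locus letter suffixes from the registry where one magnitude occurs at
#' several loci; an empty event set is the non-variant.
#'
#' @param events Standard events table.
#' @param registry Output of [locus_registry()] (optional).
#' @return Character scalar signature name.
#' @export
call_signature <- function(events, registry = NULL) {
  if (NROW(events) == 0L) return("non-variant")
  ev <- events[order(events$tx_start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(ev)), function(i) {
    suff <- ""
    if (!is.null(registry)) {
      k <- paste0(ev$delta_nt[i], "@", ev$tx_start[i])
      if (k %in% names(registry)) suff <- registry[[k]]
    }
    sprintf("%+d%s", ev$delta_nt[i], suff)
  }, "")
  paste(parts, collapse = "")
}

#' Call isoform signatures for a clone population
#'
#' Aligns every clone, builds the population-wide locus registry, and names
#' each clone's signature.  Unalignable clones are retained with signature
#' `NA` and flagged.
#'
#' @param model Reference model.
#' @param clones Tibble (clone_id, group, seq), e.g. from [read_clones()]
#'   or [generate_clones()].
#' @param ... Passed to [splice_align()].
#' @return Tibble (clone_id, group, signature, n_events, identity,
#'   n_substitutions, unalignable, events (list-column), events_str).
#' @export
call_clones <- function(model, clones, ...) {
  res <- lapply(clones$seq, splice_align, model = model, ...)
  registry <- locus_registry(lapply(res, `[[`, "events"))
  sigs <- vapply(res, function(r) {
    if (r$unalignable) NA_character_ else call_signature(r$events, registry)
  }, "")
  ev_str <- vapply(res, function(r) {
    if (NROW(r$events) == 0L) return("")
    paste(sprintf("%s:%s:%d", r$events$kind, r$events$anchor_exons,
                  r$events$delta_nt), collapse = ";")
  }, "")
  tibble::tibble(
    clone_id = clones$clone_id,
    group = clones$group,
    signature = sigs,
    n_events = vapply(res, function(r) NROW(r$events), 0L),
    identity = vapply(res, `[[`, 0, "identity"),
    n_substitutions = vapply(res, function(r)
      as.integer(r$n_substitutions), 0L),
    unalignable = vapply(res, `[[`, NA, "unalignable"),
    events = lapply(res, `[[`, "events"),
    events_str = ev_str)
}

#' Summarize an isoform population
#'
#' Per-group signature counts, the number of distinct isoform signatures,
#' and the number of distinct variation loci (maximal reference-transcript
#' intervals hosting at least one event across the population; insertions
#' are zero-width points, and intervals that overlap or abut merge).
#'
#' @param calls Output of [call_clones()] (unalignable clones are excluded
#'   from the tables).
#' @return List with `counts` (tibble signature x group), `n_isoforms`,
#'   `n_loci`, and `loci` (matrix of merged intervals).
#' @export
summarize_population <- function(calls) {
  ok <- calls[!calls$unalignable, , drop = FALSE]
  tab <- table(signature = ok$signature, group = ok$group)
  counts <- tibble::tibble(signature = rownames(tab))
  for (g in colnames(tab)) counts[[g]] <- as.integer(tab[, g])
  allev <- dplyr::bind_rows(ok$events)
  if (NROW(allev)) {
    s <- allev$tx_start
    e <- ifelse(allev$delta_nt < 0, allev$tx_end, allev$tx_start)
    loci <- merge_intervals(s, e)
  } else {
    loci <- merge_intervals(numeric(0), numeric(0))
  }
  list(counts = counts,
       n_isoforms = dplyr::n_distinct(ok$signature),
       n_loci = nrow(loci),
       loci = loci)
}
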