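# Reference transcript model: construction, validation and on-disk formats.
#
# Coordinate conventions: nucleotide coordinates are 0-based half-open on the
# pre-mRNA (or spliced transcript where stated); protein coordinates are
# 1-based inclusive residue numbers of the non-variant protein.

#' Construct a reference transcript model
#'
#' A reference model bundles a pre-mRNA sequence with its exon structure,
#' alternative translation starts, the dual stop-codon architecture at the 3'
#' end of the coding sequence, a protein domain map, and nuclear localization
#' signal (NLS) patterns.  All downstream stages (isoform calling, ORF
#' analysis, motif scanning) consume this object.
#'
#' @param model_id Character scalar identifying the model.
#' @param premrna_seq Pre-mRNA sequence, sense strand 5'->3' (DNA; `U` is
#'   normalized to `T`).  `N` is not allowed in the reference.
#' @param exons Data frame with columns `exon_id`, `start`, `end`
#'   (0-based half-open pre-mRNA coordinates), sorted and non-overlapping.
#' @param alt_starts Named integer vector of spliced-transcript offsets of
#'   the `A` of each alternative `ATG` (e.g. `c(MEKK = 12, MAEG = 0)`).
#' @param stop_pair Named integer vector of length two giving the pre-mRNA
#'   offsets of the two in-text stop codons in distinct reading frames
#'   (`reference` and `alternative`).
#' @param stop_spacing Number of nucleotides between the end of the reference
#'   stop codon and the start of the alternative stop codon (default 7).
#' @param domains Data frame with columns `domain_label` (one of `NTD`,
#'   `RRM`, `CTD`), `aa_start`, `aa_end` (1-based inclusive protein
#'   coordinates of the non-variant protein).
#' @param nls_patterns Character vector of amino-acid NLS motifs.
#' @param alt_exons Optional data frame (`exon_id`, `start`, `end`) of
#'   alternative (normally intronic) exons in pre-mRNA coordinates; used by
#'   the motif scanner and to confirm alternative-exon inclusions.
#'
#' @return An object of class `ref_model`.
#' @export
ref_model <- function(model_id, premrna_seq, exons,
                      alt_starts = integer(0),
                      stop_pair = NULL, stop_spacing = 7L,
                      domains = NULL, nls_patterns = character(0),
                      alt_exons = NULL) {
  premrna_seq <- normalize_dna(premrna_seq)
  assert_that(!grepl("[^ACGT]", premrna_seq),
              "reference pre-mRNA may only contain A/C/G/T")
  exons <- as.data.frame(exons)
  assert_that(all(c("exon_id", "start", "end") %in% names(exons)),
              "exon table must have columns exon_id, start, end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  n <- nchar(premrna_seq)
  assert_that(all(exons$start >= 0) && all(exons$end <= n) &&
                all(exons$end > exons$start),
              "exons out of range of the pre-mRNA")
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L) {
    assert_that(all(exons$start[-1L] >= exons$end[-nrow(exons)]),
                "exons overlap")
  }
  m <- structure(
    list(model_id = model_id,
         premrna_seq = premrna_seq,
         exons = exons,
         alt_starts = alt_starts,
         stop_pair = stop_pair,
         stop_spacing = as.integer(stop_spacing),
         domains = domains,
         nls_patterns = nls_patterns,
         alt_exons = alt_exons),
    class = "ref_model")
  tx <- splice(m)
  for (lbl in names(alt_starts)) {
    off <- alt_starts[[lbl]]
    assert_that(substr0(tx, off, off + 3L) == "ATG",
                sprintf("alt_start '%s' does not point at ATG", lbl))
  }
  # internal introns should be GT..AG; a violation is a warning only, so
  # deliberately broken fixtures can still be loaded
  bad <- character(0)
  if (nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      istart <- exons$end[i]
      iend <- exons$start[i + 1L]
      if (iend - istart >= 4L) {
        don <- substr0(premrna_seq, istart, istart + 2L)
        acc <- substr0(premrna_seq, iend - 2L, iend)
        if (don != "GT" || acc != "AG") {
          bad <- c(bad, sprintf("intron %d (%s..%s)", i, don, acc))
        }
      }
    }
  }
  if (length(bad)) {
    warning("non-canonical splice sites: ", paste(bad, collapse = ", "),
            call. = FALSE)
  }
  m
}

#' @export
print.ref_model <- function(x, ...) {
  cat(sprintf("<ref_model> %s: %d nt pre-mRNA, %d exons, %d nt spliced\n",
              x$model_id, nchar(x$premrna_seq), nrow(x$exons),
              nchar(splice(x))))
  if (length(x$alt_starts)) {
    cat("  alt starts:",
        paste(sprintf("%s@%d", names(x$alt_starts), x$alt_starts),
              collapse = ", "), "\n")
  }
  if (!is.null(x$domains)) {
    cat("  domains:",
        paste(sprintf("%s[%d-%d]", x$domains$domain_label,
                      x$domains$aa_start, x$domains$aa_end),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spliced transcript of a reference model
#'
#' Concatenates the exon subsequences of the pre-mRNA in order.  A pure
#' function of the model.
#'
#' @param model A `ref_model`.
#' @return Character scalar, the spliced (mature) transcript.
#' @export
splice <- function(model) {
  paste(mapply(function(s, e) substr0(model$premrna_seq, s, e),
               model$exons$start, model$exons$end),
        collapse = "")
}

# Cumulative exon starts of the spliced transcript (0-based); the junction
# offsets are the internal boundaries.
tx_exon_starts <- function(model) {
  w <- model$exons$end - model$exons$start
  c(0L, cumsum(w))
}

# Map a pre-mRNA coordinate inside an exon to a spliced-transcript coordinate.
premrna_to_tx <- function(model, pos) {
  ex <- model$exons
  txs <- tx_exon_starts(model)
  i <- which(pos >= ex$start & pos < ex$end)
  assert_that(length(i) == 1L, "position is not exonic")
  txs[i] + (pos - ex$start[i])
}

# Map a spliced-transcript coordinate back to the pre-mRNA.
tx_to_premrna <- function(model, pos) {
  ex <- model$exons
  txs <- tx_exon_starts(model)
  i <- findInterval(pos, txs, rightmost.closed = FALSE)
  i <- min(max(i, 1L), nrow(ex))
  ex$start[i] + (pos - txs[i])
}

#' Load a reference model from disk
#'
#' Reads the FASTA pre-mRNA, the exon table, the domain table and a YAML
#' config holding the transcript-local fields (alternative starts, stop
#' pair, NLS patterns, alternative exons), validating all invariants.
#'
#' @param fasta_path FASTA file with a single pre-mRNA record.
#' @param exon_table_path TSV with columns `model_id`, `exon_id`, `start`,
#'   `end`.
#' @param domain_table_path TSV with columns `domain_label`, `aa_start`,
#'   `aa_end`, or `NULL`.
#' @param config_path YAML file with keys `alt_starts`, `stop_pair`,
#'   `stop_spacing`, `nls_patterns`, `alt_exons`, or `NULL`.
#' @return A validated `ref_model`.
#' @export
load_reference <- function(fasta_path, exon_table_path,
                           domain_table_path = NULL, config_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  assert_that(length(seqs) == 1L, "reference FASTA must hold one record")
  exons <- read.table(exon_table_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  model_id <- if ("model_id" %in% names(exons)) exons$model_id[1] else
    sub("\\s.*", "", names(seqs)[1])
  domains <- NULL
  if (!is.null(domain_table_path)) {
    domains <- read.table(domain_table_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  }
  alt_starts <- integer(0)
  stop_pair <- NULL
  stop_spacing <- 7L
  nls_patterns <- character(0)
  alt_exons <- NULL
  if (!is.null(config_path)) {
    cfg <- yaml::read_yaml(config_path)
    if (!is.null(cfg$alt_starts)) alt_starts <- unlist(cfg$alt_starts)
    if (!is.null(cfg$stop_pair)) stop_pair <- unlist(cfg$stop_pair)
    if (!is.null(cfg$stop_spacing)) stop_spacing <- cfg$stop_spacing
    if (!is.null(cfg$nls_patterns)) nls_patterns <- unlist(cfg$nls_patterns)
    if (!is.null(cfg$alt_exons)) {
      alt_exons <- do.call(rbind, lapply(cfg$alt_exons, as.data.frame))
    }
  }
  ref_model(model_id = model_id,
            premrna_seq = as.character(seqs[[1]]),
            exons = exons[, c("exon_id", "start", "end")],
            alt_starts = alt_starts,
            stop_pair = stop_pair,
            stop_spacing = stop_spacing,
            domains = domains,
            nls_patterns = nls_patterns,
            alt_exons = alt_exons)
}

#' Write a reference model to disk
#'
#' Inverse of [load_reference()]; `load -> write -> load` round-trips all
#' tables bit-identically.
#'
#' @param model A `ref_model`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fasta")
  seq <- Biostrings::DNAStringSet(model$premrna_seq)
  names(seq) <- model$model_id
  Biostrings::writeXStringSet(seq, fa, width = 70L)
  ex <- file.path(dir, "exons.tsv")
  etab <- cbind(model_id = model$model_id, model$exons)
  write.table(etab, ex, sep = "\t", quote = FALSE, row.names = FALSE)
  dm <- NULL
  if (!is.null(model$domains)) {
    dm <- file.path(dir, "domains.tsv")
    write.table(model$domains, dm, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  cfgp <- file.path(dir, "model_config.yaml")
  cfg <- list(alt_starts = as.list(model$alt_starts),
              stop_pair = as.list(model$stop_pair),
              stop_spacing = model$stop_spacing,
              nls_patterns = as.list(model$nls_patterns))
  if (!is.null(model$alt_exons)) {
    cfg$alt_exons <- lapply(seq_len(nrow(model$alt_exons)), function(i) {
      as.list(model$alt_exons[i, c("exon_id", "start", "end")])
    })
  }
  yaml::write_yaml(cfg, cfgp)
  invisible(c(fasta = fa, exons = ex, domains = dm, config = cfgp))
}

#' Export the exon structure as GFF3
#'
#' Exon records only, type `exon`, converted to the 1-based inclusive
#' coordinates GFF3 requires.
#'
#' @param model A `ref_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
export_exons_gff3 <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(model$exons))) {
    writeLines(paste(model$model_id, "rbfoxiso", "exon",
                     model$exons$start[i] + 1L, model$exons$end[i],
                     ".", "+", ".",
                     sprintf("ID=%s", model$exons$exon_id[i]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read cloned cDNA sequences with group assignments
#'
#' @param fasta_path FASTA of spliced cDNA clones (sense strand).
#' @param group_map Either a named character vector mapping clone id ->
#'   group, or a data frame with columns `clone_id`, `group`.
#' @return A tibble with columns `clone_id`, `group`, `seq` (U normalized to
#'   T; alphabet restricted to A/C/G/T/N).
#' @export
read_clones <- function(fasta_path, group_map) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) {
    return(tibble::tibble(clone_id = character(0), group = character(0),
                          seq = character(0)))
  }
  ids <- sub("\\s.*", "", names(seqs))
  assert_that(!anyDuplicated(ids), "duplicate clone ids in FASTA")
  if (is.data.frame(group_map)) {
    group_map <- setNames(group_map$group, group_map$clone_id)
  }
  assert_that(all(ids %in% names(group_map)),
              "clone id(s) missing from the group map")
  sq <- vapply(as.character(seqs), normalize_dna, "", USE.NAMES = FALSE)
  assert_that(!any(grepl("[^ACGTN]", sq)),
              "clone sequences restricted to A/C/G/T/N")
  assert_that(all(nzchar(sq)), "empty clone sequence")
  tibble::tibble(clone_id = ids,
                 group = unname(group_map[ids]),
                 seq = sq)
}

#' Write clone records as FASTA plus a group table
#'
#' @param clones Tibble as returned by [read_clones()] or
#'   [generate_clones()].
#' @param fasta_path Output FASTA path.
#' @param groups_path Optional TSV path for (clone_id, group).
#' @return Invisibly, `fasta_path`.
#' @export
write_clones <- function(clones, fasta_path, groups_path = NULL) {
  seqs <- Biostrings::DNAStringSet(clones$seq)
  names(seqs) <- clones$clone_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  if (!is.null(groups_path)) {
    write.table(clones[, c("clone_id", "group")], groups_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
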