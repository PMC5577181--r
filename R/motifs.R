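# Intronic (U)GCAUG RBFOX-binding motif scanning with position-dependent
# splicing-effect prediction.

# Intronic windows flanking a feature (annotated or alternative exon), on
# the pre-mRNA, truncated at neighbouring features and capped at window_nt.
feature_windows <- function(model, feature) {
  feats <- model$exons[, c("exon_id", "start", "end")]
  if (!is.null(model$alt_exons)) {
    feats <- rbind(feats, model$alt_exons[, c("exon_id", "start", "end")])
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  i <- match(feature, feats$exon_id)
  assert_that(!is.na(i), sprintf("unknown exon id '%s'", feature))
  n <- nchar(model$premrna_seq)
  up_limit <- if (i > 1L) max(feats$end[seq_len(i - 1L)]) else 0L
  dn_limit <- if (i < nrow(feats)) min(feats$start[(i + 1L):nrow(feats)]) else n
  list(upstream = c(max(up_limit, feats$start[i] - 500000L), feats$start[i]),
       downstream = c(feats$end[i], dn_limit),
       start = feats$start[i], end = feats$end[i])
}

#' Scan intronic windows around exons for (U)GCAUG motifs
#'
#' Every occurrence of the DNA core `GCATG` in the upstream and downstream
#' intronic windows of each listed exon (annotated or alternative) is
#' reported with its distance from the nearest splice site (1 = adjacent),
#' an `extended_u` flag when the core is preceded by `T` (the `UGCAUG`
#' hexamer), and the predicted position-dependent splicing effect.  Windows
#' are truncated at neighbouring exons.  Sense strand only.
#'
#' @param model Reference model.
#' @param exon_ids Exon (or alternative exon) ids to scan around.
#' @param window_nt Maximum window size in nt (default 500; must be >= 6).
#' @return Tibble (exon_id, side, premrna_start, premrna_end, distance,
#'   core, extended_u, predicted_effect); 0-based half-open pre-mRNA
#'   coordinates of the core.
#' @export
scan_motifs <- function(model, exon_ids, window_nt = 500L) {
  assert_that(window_nt >= 6L, "window must be at least 6 nt")
  out <- list()
  for (eid in exon_ids) {
    w <- feature_windows(model, eid)
    for (side in c("upstream_intron", "downstream_intron")) {
      if (side == "upstream_intron") {
        lo <- max(w$upstream[1], w$start - window_nt)
        hi <- w$upstream[2]
      } else {
        lo <- w$downstream[1]
        hi <- min(w$downstream[2], w$end + window_nt)
      }
      if (hi - lo < 5L) {
        message("exon ", eid, ": no ", side, " window; skipped")
        next
      }
      win <- substr0(model$premrna_seq, lo, hi)
      occ <- gregexpr("GCATG", win, fixed = TRUE)[[1]]
      if (occ[1] < 0L) next
      for (o in as.integer(occ)) {
        s <- lo + o - 1L                     # 0-based core start
        e <- s + 5L
        dist <- if (side == "upstream_intron") w$start - e + 1L
                else s - w$end + 1L
        ext <- s >= 1L &&
          substr0(model$premrna_seq, s - 1L, s) == "T"
        out[[length(out) + 1L]] <- tibble::tibble(
          exon_id = eid, side = side,
          premrna_start = s, premrna_end = e,
          distance = dist, core = "GCATG", extended_u = ext,
          predicted_effect = predict_effect(side))
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(exon_id = character(0), side = character(0),
                      premrna_start = integer(0), premrna_end = integer(0),
                      distance = integer(0), core = character(0),
                      extended_u = logical(0),
                      predicted_effect = character(0))
}

#' Position-dependent splicing effect of an RBFOX motif
#'
#' Downstream intronic binding predicts exon inclusion, upstream intronic
#' binding predicts exon skipping.
#'
#' @param side `"upstream_intron"` or `"downstream_intron"` (or a tibble
#'   row from [scan_motifs()]).
#' @return `"inclusion_enhancing"` or `"skip_enhancing"`.
#' @export
predict_effect <- function(side) {
  if (is.data.frame(side)) side <- side$side
  vapply(side, function(s) {
    switch(s,
           downstream_intron = "inclusion_enhancing",
           upstream_intron = "skip_enhancing",
           stop("side must be upstream_intron or downstream_intron"))
  }, "", USE.NAMES = FALSE)
}
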