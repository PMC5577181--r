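# Group comparisons: signature frequencies, exact count tests, percent
# exon inclusion, t / Levene tests, and delta-delta-Ct qPCR quantitation.

#' Per-group signature frequencies and fold ratios
#'
#' @param counts Tibble with a `signature` column and one integer count
#'   column per group (as produced by [summarize_population()]`$counts`).
#' @param group_a,group_b Groups to compare (defaults: first two count
#'   columns).  Fold = freq_a / freq_b (`Inf` flagged when freq_b is 0).
#' @return Tibble (signature, n_<groups>, freq_<groups>, share_pct_<groups>,
#'   fold).
#' @export
frequency_table <- function(counts, group_a = NULL, group_b = NULL) {
  groups <- setdiff(names(counts), "signature")
  assert_that(length(groups) >= 1L, "no group count columns")
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b) && length(groups) >= 2L) group_b <- groups[2]
  out <- tibble::tibble(signature = counts$signature)
  for (g in groups) {
    n <- counts[[g]]
    total <- sum(n)
    assert_that(total > 0, sprintf("group '%s' has zero total", g))
    out[[paste0("n_", g)]] <- n
    out[[paste0("freq_", g)]] <- n / total
    out[[paste0("share_pct_", g)]] <- 100 * n / total
  }
  if (!is.null(group_b)) {
    fa <- out[[paste0("freq_", group_a)]]
    fb <- out[[paste0("freq_", group_b)]]
    out$fold <- ifelse(fb == 0, Inf, fa / fb)
  }
  out
}

#' Fisher exact comparison of two proportions
#'
#' Two-tailed p by summing hypergeometric tables with probability less than
#' or equal to the observed table; conditional MLE odds ratio.
#'
#' @param k_a,n_a Successes and total in group A.
#' @param k_b,n_b Successes and total in group B.
#' @return List with `p_value`, `odds_ratio`.
#' @export
compare_counts <- function(k_a, n_a, k_b, n_b) {
  assert_that(k_a <= n_a && k_b <= n_b, "k must not exceed n")
  ft <- fisher.test(matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2))
  list(p_value = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Percent spliced-in from a two-band intensity table
#'
#' PSI% = included / (included + excluded) x 100 per sample; rows with zero
#' total intensity are excluded with a warning.
#'
#' @param inclusion_table Tibble (sample_id, group, included_intensity,
#'   excluded_intensity).
#' @return List with `samples` (input plus `psi_pct`) and `groups` (per
#'   group: n, mean_pct, sd_pct, sem_pct).
#' @export
percent_inclusion <- function(inclusion_table) {
  tot <- inclusion_table$included_intensity +
    inclusion_table$excluded_intensity
  bad <- tot <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-total row(s) excluded", call. = FALSE)
    inclusion_table <- inclusion_table[!bad, , drop = FALSE]
    tot <- tot[!bad]
  }
  samples <- inclusion_table
  samples$psi_pct <- 100 * samples$included_intensity / tot
  groups <- dplyr::summarise(
    dplyr::group_by(samples, group),
    n = dplyr::n(),
    mean_pct = mean(psi_pct),
    sd_pct = sd(psi_pct),
    sem_pct = sd(psi_pct) / sqrt(dplyr::n()),
    .groups = "drop")
  list(samples = samples, groups = groups)
}

# Pooled-variance two-sample t statistic (classical independent Student's t).
student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df))
}

# Levene's test on absolute deviations (classical mean-centred variant by
# default; median-centred by flag).
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  cf <- if (center == "mean") mean else stats::median
  zx <- abs(x - cf(x))
  zy <- abs(y - cf(y))
  z <- c(zx, zy)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  n <- length(z); k <- 2L
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  num <- sum(ng * (zg - zbar)^2) / (k - 1)
  den <- sum((z - zg[g])^2) / (n - k)
  f <- num / den
  list(statistic = f, df1 = k - 1L, df2 = n - k,
       p_value = pf(f, k - 1L, n - k, lower.tail = FALSE))
}

#' Compare percent inclusion between two groups
#'
#' Independent two-sample t test (pooled variance by default, Welch by
#' flag) plus Levene's test for equality of variance on the per-sample PSI
#' values.
#'
#' @param inclusion Output of [percent_inclusion()], or a samples tibble
#'   with `group` and `psi_pct`.
#' @param group_a,group_b Groups to compare (defaults: first two groups).
#' @param welch Use Welch's unequal-variance t test.
#' @param levene_center `"mean"` (classical Levene) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `t_statistic`, `t_df`, `p_value`, `levene_statistic`,
#'   `levene_p`, and the per-group mean +/- SEM.
#' @export
compare_inclusion <- function(inclusion, group_a = NULL, group_b = NULL,
                              welch = FALSE, levene_center = "mean") {
  samples <- if (is.list(inclusion) && !is.data.frame(inclusion))
    inclusion$samples else inclusion
  groups <- unique(samples$group)
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- groups[2]
  x <- samples$psi_pct[samples$group == group_a]
  y <- samples$psi_pct[samples$group == group_b]
  assert_that(length(x) >= 2L && length(y) >= 2L,
              "need at least 2 samples per group")
  if (welch) {
    tt <- t.test(x, y, var.equal = FALSE)
    tres <- list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    tres <- student_t(x, y)
  }
  lv <- levene_test(x, y, center = levene_center)
  list(group_a = group_a, group_b = group_b,
       mean_a = mean(x), sem_a = sd(x) / sqrt(length(x)),
       mean_b = mean(y), sem_b = sd(y) / sqrt(length(y)),
       t_statistic = tres$statistic, t_df = tres$df,
       p_value = tres$p_value,
       levene_statistic = lv$statistic, levene_p = lv$p_value)
}

#' Relative qPCR quantitation by the 2^-ddCt method
#'
#' Per sample, dCt = Ct_target - Ct_reference; ddCt is taken against the
#' calibrator group's mean dCt; fold = 2^-ddCt.  Samples missing a
#' reference Ct are dropped with a message.
#'
#' @param ct_table Tibble (sample_id, group, gene, ct) with gene values
#'   `"target"` and `"reference"` (or as named below).
#' @param reference_gene Gene level used for normalization.
#' @param calibrator_group Group whose mean dCt anchors ddCt = 0.
#' @param target_gene Gene level of the target.
#' @return List with `samples` (sample_id, group, dct, ddct, fold) and
#'   `groups` (per group: n, mean_fold, sem_fold, mean_ddct).
#' @export
ddct <- function(ct_table, reference_gene = "reference",
                 calibrator_group, target_gene = "target") {
  tg <- ct_table[ct_table$gene == target_gene, ]
  rf <- ct_table[ct_table$gene == reference_gene, ]
  m <- match(tg$sample_id, rf$sample_id)
  drop <- is.na(m)
  if (any(drop)) {
    message(sum(drop), " sample(s) without reference Ct dropped")
    tg <- tg[!drop, , drop = FALSE]
    m <- m[!drop]
  }
  samples <- tibble::tibble(
    sample_id = tg$sample_id,
    group = tg$group,
    dct = tg$ct - rf$ct[m])
  assert_that(calibrator_group %in% samples$group,
              "calibrator group absent from Ct table")
  cal <- mean(samples$dct[samples$group == calibrator_group])
  samples$ddct <- samples$dct - cal
  samples$fold <- 2^(-samples$ddct)
  groups <- dplyr::summarise(
    dplyr::group_by(samples, group),
    n = dplyr::n(),
    mean_fold = mean(fold),
    sem_fold = sd(fold) / sqrt(dplyr::n()),
    mean_ddct = mean(ddct),
    .groups = "drop")
  list(samples = samples, groups = groups)
}
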