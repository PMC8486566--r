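# Tissue-stage marker selection: per-region rank-sum tests across the
# Normal/AA/CRC groups, Benjamini-Hochberg correction per contrast family,
# effect-size and trend filters, plus the AA-vs-CRC augmentation set.

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided Wilcoxon rank-sum p-value: exact enumeration when the pooled
#' size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. A paired signed-rank
#' mode is available for matched designs.
#'
#' @param a,b Numeric samples (each of length >= 2; equal lengths required
#'   when `paired`).
#' @param paired Use the paired signed-rank form.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired test requires equal group sizes", call. = FALSE)
    }
    return(suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)$p.value))
  }
  no_ties <- !anyDuplicated(c(a, b))
  exact <- no_ties && (length(a) + length(b)) <= 12L
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment returning q-values in input order. Wraps
#' [stats::p.adjust()] after validating the input.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed and propagated).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- p[!is.na(p)]
  if (any(ok < 0 | ok > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' AUROC by rank statistics
#'
#' Area under the ROC curve as the scaled Mann-Whitney statistic: the
#' proportion of (positive, negative) pairs in which the positive scores
#' higher, ties counted half.
#'
#' @param values Numeric scores.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUROC in `[0, 1]`.
#' @export
marker_auroc <- function(values, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(values)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Tissue-stage marker selection
#'
#' Computes the per-region differential-methylation ledger over the tissue
#' cohort and applies the selection cascade: a region enters the core set
#' when (i) CRC vs Normal is significant after BH adjustment
#' (`q < q_threshold`) with `|delta| > min_delta`, (ii) AA vs Normal
#' likewise, and (iii) the CRC and AA changes share a sign. Regions whose
#' AA-vs-CRC contrast is BH-significant form the augmentation set;
#' `selected = selected_core | selected_aa_vs_crc`. Deltas are group-mean
#' (or median) differences on the raw PCM scale; BH is applied per
#' contrast family over the regions tested in that contrast.
#'
#' @param pcm Regions x samples PCM matrix (raw scale), or a `cfmeth_pcm`.
#' @param manifest Sample manifest; only `cohort == "tissue"` rows are
#'   used, and groups Normal, AA and CRC must each have >= 2 samples.
#' @param q_threshold BH-adjusted significance threshold.
#' @param min_delta Minimum absolute group-mean PCM difference.
#' @param delta_stat Group summary for deltas, `"mean"` or `"median"`.
#' @return A data frame (one row per region) with p/q-values for the three
#'   contrasts, `auroc_crc_vs_normal`, `delta_crc`, `delta_aa`,
#'   `same_trend`, `selected_core`, `selected_aa_vs_crc`, `selected` and
#'   `reason` for unselectable regions.
#' @export
select_tissue_markers <- function(pcm, manifest, q_threshold = 0.05,
                                  min_delta = 0.2,
                                  delta_stat = c("mean", "median")) {
  delta_stat <- match.arg(delta_stat)
  if (inherits(pcm, "cfmeth_pcm")) pcm <- pcm$pcm
  meta <- manifest[manifest$cohort == "tissue", , drop = FALSE]
  groups <- list(Normal = NULL, AA = NULL, CRC = NULL)
  for (g in names(groups)) {
    ids <- intersect(meta$sample_id[meta$group == g], colnames(pcm))
    if (length(ids) < 2L) {
      stop("tissue group ", g, " needs at least 2 samples in the matrix",
           call. = FALSE)
    }
    groups[[g]] <- ids
  }
  summ <- if (delta_stat == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) median(x, na.rm = TRUE)
  }
  n_reg <- nrow(pcm)
  res <- data.frame(region_id = rownames(pcm),
                    p_crc_vs_normal = NA_real_, p_aa_vs_normal = NA_real_,
                    p_aa_vs_crc = NA_real_, q_crc_vs_normal = NA_real_,
                    q_aa_vs_normal = NA_real_, q_aa_vs_crc = NA_real_,
                    auroc_crc_vs_normal = NA_real_,
                    delta_crc = NA_real_, delta_aa = NA_real_,
                    same_trend = NA, reason = NA_character_,
                    stringsAsFactors = FALSE)
  xn <- pcm[, groups$Normal, drop = FALSE]
  xa <- pcm[, groups$AA, drop = FALSE]
  xc <- pcm[, groups$CRC, drop = FALSE]
  for (i in seq_len(n_reg)) {
    vn <- xn[i, ][!is.na(xn[i, ])]
    va <- xa[i, ][!is.na(xa[i, ])]
    vc <- xc[i, ][!is.na(xc[i, ])]
    if (length(vn) < 2L || length(va) < 2L || length(vc) < 2L) {
      res$reason[i] <- "insufficient_data"
      next
    }
    res$p_crc_vs_normal[i] <- rank_sum_test(vc, vn)
    res$p_aa_vs_normal[i] <- rank_sum_test(va, vn)
    res$p_aa_vs_crc[i] <- rank_sum_test(va, vc)
    res$auroc_crc_vs_normal[i] <- marker_auroc(
      c(vc, vn), c(rep(TRUE, length(vc)), rep(FALSE, length(vn))))
    res$delta_crc[i] <- summ(vc) - summ(vn)
    res$delta_aa[i] <- summ(va) - summ(vn)
  }
  res$q_crc_vs_normal <- bh_adjust(res$p_crc_vs_normal)
  res$q_aa_vs_normal <- bh_adjust(res$p_aa_vs_normal)
  res$q_aa_vs_crc <- bh_adjust(res$p_aa_vs_crc)
  res$same_trend <- !is.na(res$delta_crc) & !is.na(res$delta_aa) &
    res$delta_crc != 0 & res$delta_aa != 0 &
    sign(res$delta_crc) == sign(res$delta_aa)
  res$selected_core <- !is.na(res$q_crc_vs_normal) &
    res$q_crc_vs_normal < q_threshold &
    !is.na(res$q_aa_vs_normal) & res$q_aa_vs_normal < q_threshold &
    abs(res$delta_crc) > min_delta & abs(res$delta_aa) > min_delta &
    res$same_trend
  res$selected_core[is.na(res$selected_core)] <- FALSE
  res$selected_aa_vs_crc <- !is.na(res$q_aa_vs_crc) &
    res$q_aa_vs_crc < q_threshold
  res$selected <- res$selected_core | res$selected_aa_vs_crc
  attr(res, "thresholds") <- list(q = q_threshold, min_delta = min_delta,
                                  delta_stat = delta_stat)
  res
}

#' Trend concordance between CRC and AA methylation changes
#'
#' Per region, the log2 ratio of the group-mean PCM to the Normal
#' group-mean PCM is computed for CRC and for AA; the Pearson correlation
#' of the two ratio vectors summarises how concordant the adenoma and
#' carcinoma methylation changes are.
#'
#' @inheritParams select_tissue_markers
#' @param pseudocount Added to numerator and denominator means before the
#'   ratio.
#' @param region_ids Optional subset of regions (e.g. planted markers).
#' @return A list with `correlation` and `ratios` (data frame of per-region
#'   `log2fc_crc`, `log2fc_aa`).
#' @export
fold_change_correlation <- function(pcm, manifest, pseudocount = 1e-3,
                                    region_ids = NULL) {
  if (inherits(pcm, "cfmeth_pcm")) pcm <- pcm$pcm
  if (!is.null(region_ids)) {
    pcm <- pcm[intersect(region_ids, rownames(pcm)), , drop = FALSE]
  }
  if (nrow(pcm) == 0L) stop("no regions to correlate", call. = FALSE)
  meta <- manifest[manifest$cohort == "tissue", , drop = FALSE]
  mean_of <- function(g) {
    ids <- intersect(meta$sample_id[meta$group == g], colnames(pcm))
    if (length(ids) == 0L) stop("tissue group ", g, " absent", call. = FALSE)
    rowMeans(pcm[, ids, drop = FALSE], na.rm = TRUE)
  }
  mn <- mean_of("Normal"); ma <- mean_of("AA"); mc <- mean_of("CRC")
  ratios <- data.frame(region_id = rownames(pcm),
                       log2fc_crc = log2((mc + pseudocount) / (mn + pseudocount)),
                       log2fc_aa = log2((ma + pseudocount) / (mn + pseudocount)),
                       stringsAsFactors = FALSE)
  list(correlation = cor(ratios$log2fc_aa, ratios$log2fc_crc,
                         use = "complete.obs"),
       ratios = ratios)
}
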