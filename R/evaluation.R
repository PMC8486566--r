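# Diagnostic evaluation: AUC with DeLong confidence intervals, threshold
# metrics, subgroup reports against the pooled plasma Normal negatives,
# scalar tumor-marker comparison, QC-cascade bookkeeping, cohort summary
# tables and group-mean tests.

#' Round half up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' clinical tables), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # tiny epsilon guards against binary representation of exact .5 ties
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# DeLong components: placement values of positives among negatives and
# vice versa, via midranks.
delong_se <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  if (m > 1L) s10 <- var(v10) else s10 <- 0
  if (n > 1L) s01 <- var(v01) else s01 <- 0
  sqrt(s10 / m + s01 / n)
}

#' AUC with a DeLong 95% confidence interval
#'
#' Point estimate by concordant-pair counting with half-credit for ties
#' (the scaled Mann-Whitney statistic, identical to [marker_auroc()]);
#' standard error by the DeLong placement-value variance; the normal CI is
#' truncated to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels, `TRUE` = positive.
#' @param conf Confidence level.
#' @return A list with `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
auc_with_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  auc <- marker_auroc(scores, labels)
  se <- delong_se(scores, labels)
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
       se = se, n_pos = sum(labels), n_neg = sum(!labels))
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Scores at or above the threshold are called positive.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, `TRUE` = positive.
#' @param threshold Decision threshold.
#' @return A list with `sensitivity`, `specificity`, `accuracy` and the
#'   contingency counts `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  labels <- as.logical(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  fp <- sum(call_pos & !labels); tn <- sum(!call_pos & !labels)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

eval_row <- function(label, scores_pos, scores_neg, threshold) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    return(data.frame(cohort = label, n_pos = length(scores_pos),
                      n_neg = length(scores_neg), auc = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      accuracy = NA_real_, stringsAsFactors = FALSE))
  }
  s <- c(scores_pos, scores_neg)
  l <- c(rep(TRUE, length(scores_pos)), rep(FALSE, length(scores_neg)))
  a <- auc_with_ci(s, l)
  m <- if (is.na(threshold)) {
    list(sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_)
  } else {
    threshold_metrics(s, l, threshold)
  }
  data.frame(cohort = label, n_pos = a$n_pos, n_neg = a$n_neg, auc = a$auc,
             ci_low = a$ci_low, ci_high = a$ci_high,
             sensitivity = m$sensitivity, specificity = m$specificity,
             accuracy = m$accuracy, stringsAsFactors = FALSE)
}

#' Subgroup diagnostic report
#'
#' Scores every plasma sample under the model and reports, per subgroup,
#' AUC with DeLong CI and threshold metrics at the model's operating
#' threshold. For the adenoma/stage panels the negatives are all plasma
#' Normal samples; when a split is supplied, arm-specific training and
#' validation rows (arm CRC vs arm Normal) are reported as well. Empty
#' subgroups yield rows with missing metrics rather than errors.
#'
#' @param model A `cfmeth_model` with its threshold set.
#' @param X Samples x features matrix (log2-PCM) covering all plasma
#'   samples.
#' @param manifest Sample manifest.
#' @param split Optional [stratified_split()] assignment.
#' @return A list with `report` (one row per subgroup) and `scores`
#'   (per-sample data frame with group, stage, arm and risk score).
#' @export
subgroup_report <- function(model, X, manifest, split = NULL) {
  meta <- manifest[manifest$cohort == "plasma", , drop = FALSE]
  ids <- intersect(meta$sample_id, rownames(X))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  sc <- risk_score(model, X[ids, , drop = FALSE])
  arm <- if (!is.null(split)) {
    split$arm[match(ids, split$sample_id)]
  } else rep(NA_character_, length(ids))
  scores_df <- data.frame(sample_id = ids, group = meta$group,
                          stage = meta$stage, arm = arm, score = sc,
                          stringsAsFactors = FALSE)
  neg_all <- sc[meta$group == "Normal"]
  thr <- model$threshold
  rows <- list()
  if (!is.null(split)) {
    for (a in c("training", "validation")) {
      rows[[a]] <- eval_row(a, sc[meta$group == "CRC" & arm == a & !is.na(arm)],
                            sc[meta$group == "Normal" & arm == a & !is.na(arm)],
                            thr)
    }
  }
  sub_defs <- list(
    NAA = meta$group == "NAA",
    AA = meta$group == "AA",
    adenoma = meta$group %in% c("NAA", "AA"),
    `stage I` = meta$group == "CRC" & meta$stage == "I",
    `stage II` = meta$group == "CRC" & meta$stage == "II",
    `stage III` = meta$group == "CRC" & meta$stage == "III",
    `stage IV` = meta$group == "CRC" & meta$stage == "IV",
    CRC = meta$group == "CRC",
    `CRC+AA` = meta$group %in% c("CRC", "AA"))
  for (nm in names(sub_defs)) {
    sel <- sub_defs[[nm]] & !is.na(sub_defs[[nm]])
    rows[[nm]] <- eval_row(nm, sc[sel], neg_all, thr)
  }
  list(report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       scores = scores_df)
}

#' Evaluate a scalar biomarker as a diagnostic score
#'
#' Treats a numeric biomarker (e.g. a serum tumor-marker concentration) as
#' the risk score and reports AUC with CI; with `direction = "less"`
#' smaller values indicate disease. Missing values are excluded (counts
#' reported reflect the non-missing samples). A fixed clinical cutoff may
#' be supplied for threshold metrics.
#'
#' @param values Numeric biomarker values.
#' @param labels Binary labels, `TRUE` = disease.
#' @param direction `"greater"` (default) or `"less"`.
#' @param threshold Optional decision cutoff on the original scale.
#' @param label Row label.
#' @return A one-row data frame in the [subgroup_report()] layout.
#' @export
scalar_biomarker_eval <- function(values, labels,
                                  direction = c("greater", "less"),
                                  threshold = NA_real_, label = "scalar") {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(values) == 0L) stop("all values missing", call. = FALSE)
  if (direction == "less") {
    values <- -values
    if (!is.na(threshold)) threshold <- -threshold
  }
  eval_row(label, values[labels], values[!labels], threshold)
}

#' QC exclusion cascade
#'
#' Applies the three QC exclusions in order (DNA extraction, library
#' yield, sequencing) per cohort and tabulates samples entering, excluded
#' and surviving at each stage; a sample failing an early stage is not
#' counted again later. Count conservation
#' (`collected = survivors + sum(excluded)`) is asserted on every run.
#'
#' @param manifest Sample manifest with QC flags.
#' @return A data frame with columns `cohort`, `stage`, `entering`,
#'   `excluded`, `surviving`; per-group survivor counts are attached as
#'   `attr(, "survivors_by_group")`.
#' @export
qc_cascade <- function(manifest) {
  validate_manifest(manifest, "qc_cascade input")
  stages <- c(extraction = "qc_extraction", library = "qc_library",
              sequencing = "qc_sequencing")
  out <- list(); surv <- list()
  for (co in unique(manifest$cohort)) {
    m <- manifest[manifest$cohort == co, , drop = FALSE]
    entering <- nrow(m)
    collected <- entering
    excl_total <- 0L
    for (st in names(stages)) {
      fails <- m[[stages[[st]]]] == "fail"
      excluded <- sum(fails)
      out[[paste(co, st)]] <- data.frame(
        cohort = co, stage = st, entering = entering, excluded = excluded,
        surviving = entering - excluded, stringsAsFactors = FALSE)
      m <- m[!fails, , drop = FALSE]
      entering <- nrow(m)
      excl_total <- excl_total + excluded
    }
    stopifnot(collected == nrow(m) + excl_total)
    surv[[co]] <- table(factor(m$group, levels = GROUP_LEVELS))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "survivors_by_group") <- surv
  res
}

#' Cohort characteristics table
#'
#' Per-group sample counts, sex counts with percentages, age mean and
#' range, and (within CRC) stage counts with percentages. Percentages are
#' rounded half-up to 2 decimals, matching printed clinical tables.
#'
#' @param manifest Sample manifest (plasma rows are summarised by
#'   default).
#' @param cohort Which cohort to summarise.
#' @return A list with data frames `groups` and `stages`.
#' @export
cohort_table <- function(manifest, cohort = "plasma") {
  m <- manifest[manifest$cohort == cohort, , drop = FALSE]
  groups <- intersect(GROUP_LEVELS, unique(m$group))
  g <- do.call(rbind, lapply(groups, function(gr) {
    s <- m[m$group == gr, , drop = FALSE]
    data.frame(group = gr, n = nrow(s),
               male_n = sum(s$sex == "M"),
               male_pct = round_half_up(100 * sum(s$sex == "M") / nrow(s)),
               female_n = sum(s$sex == "F"),
               female_pct = round_half_up(100 * sum(s$sex == "F") / nrow(s)),
               age_mean = round_half_up(mean(s$age)),
               age_min = min(s$age), age_max = max(s$age),
               stringsAsFactors = FALSE)
  }))
  crc <- m[m$group == "CRC", , drop = FALSE]
  stages <- if (nrow(crc)) {
    do.call(rbind, lapply(STAGE_LEVELS, function(st) {
      n <- sum(crc$stage == st)
      data.frame(stage = st, n = n,
                 pct = round_half_up(100 * n / nrow(crc)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(stage = character(), n = integer(), pct = numeric())
  }
  list(groups = g, stages = stages)
}

#' Welch two-sample t test with group summaries
#'
#' Welch's unequal-variance t test with Satterthwaite degrees of freedom,
#' reporting group means and SDs. Two degenerate inputs with zero variance
#' and equal means return `p = 1` rather than an error.
#'
#' @param a,b Numeric samples (>= 2 non-missing values each).
#' @return A list with `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`.
#' @export
group_mean_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  base <- list(mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b))
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(c(list(t = 0, df = NA_real_, p = 1), base))
    }
    return(c(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p = 0),
             base))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  c(list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value), base)
}
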