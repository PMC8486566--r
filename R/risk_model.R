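# Plasma risk modeling: refinement of tissue markers in plasma, stratified
# train/validation split, L1-penalised logistic selection with
# cross-validated lambda, the final unpenalised logistic fit, risk scoring
# on the probability scale and Youden thresholding.

#' Refine tissue markers in plasma
#'
#' Keeps the tissue markers whose PCM differs between plasma CRC and
#' plasma Normal samples at unadjusted rank-sum `p < alpha` (refinement is
#' a pre-screen feeding the penalised model, hence no multiplicity
#' correction). Input order is preserved.
#'
#' @param pcm Plasma PCM matrix (regions x samples) or `cfmeth_pcm`.
#' @param manifest Sample manifest.
#' @param tissue_markers Character vector of candidate region ids.
#' @param alpha Unadjusted significance threshold.
#' @return Character vector, subset of `tissue_markers`.
#' @export
refine_markers_plasma <- function(pcm, manifest, tissue_markers,
                                  alpha = 0.05) {
  if (inherits(pcm, "cfmeth_pcm")) pcm <- pcm$pcm
  if (length(tissue_markers) == 0L) {
    stop("tissue_markers must be non-empty", call. = FALSE)
  }
  markers <- tissue_markers[tissue_markers %in% rownames(pcm)]
  if (length(markers) == 0L) {
    stop("no tissue marker appears in the plasma matrix", call. = FALSE)
  }
  meta <- manifest[manifest$cohort == "plasma", , drop = FALSE]
  crc <- intersect(meta$sample_id[meta$group == "CRC"], colnames(pcm))
  nrm <- intersect(meta$sample_id[meta$group == "Normal"], colnames(pcm))
  if (length(crc) < 2L || length(nrm) < 2L) {
    stop("plasma CRC and Normal groups must each have >= 2 samples",
         call. = FALSE)
  }
  keep <- vapply(markers, function(r) {
    p <- rank_sum_test(pcm[r, crc], pcm[r, nrm])
    !is.na(p) && p < alpha
  }, logical(1L))
  markers[keep]
}

#' Stratified training/validation split
#'
#' Assigns plasma Normal and CRC samples to training and validation arms
#' within strata of sex x age decade x (Normal | TNM stage). Samples are
#' shuffled within each stratum and dealt alternately; the arm that starts
#' each stratum is the currently smaller one, so arm sizes differ by at
#' most one both per stratum and overall. NAA and AA samples are never
#' assigned: the model is trained on CRC vs Normal and adenoma samples are
#' scored only at evaluation time.
#'
#' @param manifest Sample manifest with age, sex and stage populated for
#'   plasma Normal/CRC samples.
#' @param ratio Training fraction (default 1:1; per-stratum allocation is
#'   by largest remainder for other ratios).
#' @param seed RNG seed for the within-stratum shuffles.
#' @return A data frame `sample_id`, `arm` (training/validation) with the
#'   stratum definition in `attr(, "strata")`.
#' @export
stratified_split <- function(manifest, ratio = 0.5, seed = 1L) {
  meta <- manifest[manifest$cohort == "plasma" &
                     manifest$group %in% c("Normal", "CRC"), , drop = FALSE]
  if (any(is.na(meta$age)) || any(is.na(meta$sex))) {
    stop("age and sex must be present for all split candidates",
         call. = FALSE)
  }
  stopifnot(ratio > 0, ratio < 1)
  stratum <- paste(meta$sex, floor(meta$age / 10),
                   ifelse(meta$group == "Normal", "Normal",
                          as.character(meta$stage)), sep = "/")
  set.seed(seed)
  arm <- character(nrow(meta))
  n_train <- 0L; n_valid <- 0L
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    idx <- idx[sample.int(length(idx))]
    if (abs(ratio - 0.5) < 1e-9) {
      first <- if (n_train <= n_valid) "training" else "validation"
      other <- if (first == "training") "validation" else "training"
      a <- rep(c(first, other), length.out = length(idx))
    } else {
      k <- round(length(idx) * ratio)
      a <- rep(c("training", "validation"), c(k, length(idx) - k))
    }
    arm[idx] <- a
    n_train <- n_train + sum(a == "training")
    n_valid <- n_valid + sum(a == "validation")
  }
  out <- data.frame(sample_id = meta$sample_id, arm = arm,
                    stringsAsFactors = FALSE)
  attr(out, "strata") <- stratum
  out
}

# Stratified fold ids for cross-validation: labels balanced across folds.
stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' LASSO variable selection with cross-validated lambda
#'
#' L1-penalised logistic regression over a descending log-spaced lambda
#' path (glmnet, features standardised internally); lambda is chosen to
#' minimise the 10-fold cross-validated binomial deviance (folds
#' stratified by label), and the features with nonzero coefficients at
#' that lambda are returned. Constant columns are dropped with a warning.
#'
#' @param X Numeric matrix, samples x features (column names are feature
#'   ids); no missing values.
#' @param y Binary labels (0/1 or logical).
#' @param nfolds Number of cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @param nlambda Length of the lambda path.
#' @return A list with `selected` (character), `lambda_min`, `coefficients`
#'   (at `lambda_min`, named, penalised scale) and the `cv_fit`.
#' @export
lasso_select <- function(X, y, nfolds = 10L, seed = 1L, nlambda = 100L) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  const <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped")
    X <- X[, !const, drop = FALSE]
  }
  set.seed(seed)
  foldid <- stratified_folds(y, nfolds)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          nlambda = nlambda, standardize = TRUE)
  beta <- coef(cv, s = "lambda.min")[-1L, 1L]
  list(selected = names(beta)[beta != 0], lambda_min = cv$lambda.min,
       coefficients = beta[beta != 0], cv_fit = cv)
}

#' Fit the logistic risk model
#'
#' Unpenalised logistic regression of the binary label on the selected
#' marker features. Features are median-imputed (values remembered for
#' scoring) and standardised to training mean/SD before the fit, so the
#' stored coefficients act on standardised features. If the fit is
#' separated, a vanishing ridge penalty (1e-6) stabilises it, with a
#' warning.
#'
#' @param X Samples x features matrix (training arm, log2-PCM scale).
#' @param y Binary labels.
#' @param marker_ids Columns of `X` to use.
#' @return An object of class `cfmeth_model`: `marker_ids`,
#'   `coefficients`, `intercept`, `center`, `scale`, `impute`, and
#'   `threshold` (`NA` until set from [youden_threshold()]).
#' @export
fit_risk_model <- function(X, y, marker_ids) {
  missing_ids <- setdiff(marker_ids, colnames(X))
  if (length(missing_ids)) {
    stop("markers absent from X: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(as.logical(y))
  Xm <- X[, marker_ids, drop = FALSE]
  impute <- apply(Xm, 2L, median, na.rm = TRUE)
  for (j in seq_along(marker_ids)) {
    Xm[is.na(Xm[, j]), j] <- impute[j]
  }
  center <- colMeans(Xm)
  scl <- apply(Xm, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(Xm, center = center, scale = scl)
  fit <- suppressWarnings(glm(y ~ Xs, family = binomial()))
  separated <- any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || !fit$converged
  if (separated) {
    warning("separation detected; refitting with a 1e-6 ridge stabiliser")
    Xr <- Xs
    if (ncol(Xr) == 1L) Xr <- cbind(Xr, `.pad` = 0)  # glmnet needs >= 2 cols
    rfit <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
    beta <- as.numeric(coef(rfit))[seq_len(ncol(Xs) + 1L)]
  } else {
    beta <- as.numeric(coef(fit))
  }
  structure(list(marker_ids = marker_ids,
                 coefficients = setNames(beta[-1L], marker_ids),
                 intercept = beta[1L],
                 center = center, scale = scl, impute = impute,
                 threshold = NA_real_),
            class = "cfmeth_model")
}

#' Risk score of samples under a fitted model
#'
#' The risk score is the logistic probability
#' `plogis(intercept + sum(coef * standardized feature))`, a value in
#' (0, 1); missing features are filled with the imputation values stored
#' at fit time.
#'
#' @param model A `cfmeth_model`.
#' @param X Samples x features matrix containing the model's markers.
#' @return Named numeric vector of scores.
#' @export
risk_score <- function(model, X) {
  stopifnot(inherits(model, "cfmeth_model"))
  Xm <- X[, model$marker_ids, drop = FALSE]
  for (j in seq_along(model$marker_ids)) {
    Xm[is.na(Xm[, j]), j] <- model$impute[j]
  }
  Xs <- sweep(sweep(Xm, 2L, model$center), 2L, model$scale, "/")
  eta <- model$intercept + drop(Xs %*% model$coefficients)
  setNames(stats::plogis(eta), rownames(X))
}

#' @export
print.cfmeth_model <- function(x, ...) {
  cat(sprintf("cfmeth risk model: %d markers, threshold %s\n",
              length(x$marker_ids),
              ifelse(is.na(x$threshold), "unset",
                     sprintf("%.3f", x$threshold))))
  invisible(x)
}

#' Youden-index threshold
#'
#' Evaluates `J(t) = sensitivity(t) + specificity(t) - 1` (scores at or
#' above `t` called positive) at the midpoints between consecutive sorted
#' unique scores, plus outer candidates below and above all scores, and
#' returns the maximiser; ties break toward the smaller threshold
#' (favouring sensitivity).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, `TRUE` = positive.
#' @return A list with `threshold`, `J` and a `degenerate` flag (all
#'   scores identical).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    return(list(threshold = u, J = 0, degenerate = TRUE))
  }
  cand <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  J <- vapply(cand, function(t) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    sens + spec - 1
  }, numeric(1L))
  best <- which.max(J)  # which.max takes the first (smallest) maximiser
  list(threshold = cand[best], J = J[best], degenerate = FALSE)
}

#' Age independence of selected markers
#'
#' Spearman correlation of each marker feature with age among plasma
#' Normal samples; markers with `|rho| >= rho_threshold` are flagged
#' (report only, nothing is removed). Constant markers have undefined
#' correlation and are reported missing, not flagged.
#'
#' @param X Samples x features matrix (rownames are sample ids).
#' @param manifest Sample manifest with ages.
#' @param marker_ids Markers to check.
#' @param rho_threshold Flagging threshold on `|rho|`.
#' @return Data frame `marker_id`, `rho`, `n`, `flagged`.
#' @export
check_age_independence <- function(X, manifest, marker_ids,
                                   rho_threshold = 0.3) {
  meta <- manifest[manifest$cohort == "plasma" & manifest$group == "Normal", ,
                   drop = FALSE]
  ids <- intersect(meta$sample_id, rownames(X))
  if (length(ids) < 3L) {
    stop("need at least 3 plasma Normal samples with features", call. = FALSE)
  }
  age <- meta$age[match(ids, meta$sample_id)]
  if (anyNA(age)) stop("ages must be present for all scored samples",
                       call. = FALSE)
  rho <- vapply(marker_ids, function(m) {
    v <- X[ids, m]
    if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) return(NA_real_)
    suppressWarnings(cor(v, age, method = "spearman",
                         use = "complete.obs"))
  }, numeric(1L))
  data.frame(marker_id = marker_ids, rho = rho,
             n = length(ids),
             flagged = !is.na(rho) & abs(rho) >= rho_threshold,
             stringsAsFactors = FALSE)
}

#' Train the full plasma risk model
#'
#' Orchestrates the plasma modeling stage: refine tissue markers in plasma
#' ([refine_markers_plasma()]), split Normal/CRC samples into training and
#' validation arms ([stratified_split()]), run LASSO selection on the
#' training arm's log2-PCM features ([lasso_select()]), fit the final
#' logistic model ([fit_risk_model()]) and set its operating threshold by
#' the Youden index on training-arm scores.
#'
#' @param plasma_pcm A `cfmeth_pcm` for the plasma cohort.
#' @param manifest Sample manifest.
#' @param tissue_markers Character vector of tissue-selected region ids.
#' @param alpha Plasma refinement threshold (unadjusted p).
#' @param ratio Training fraction for the split.
#' @param nfolds Cross-validation folds for lambda selection.
#' @param split_seed,cv_seed Seeds for the split and fold assignment.
#' @return A list with the fitted `model`, `split`, `refined_markers`,
#'   `selected_markers`, `lambda_min`, `training_scores` and
#'   `age_independence`.
#' @export
train_risk_model <- function(plasma_pcm, manifest, tissue_markers,
                             alpha = 0.05, ratio = 0.5, nfolds = 10L,
                             split_seed = 1L, cv_seed = 1L) {
  stopifnot(inherits(plasma_pcm, "cfmeth_pcm"))
  refined <- refine_markers_plasma(plasma_pcm, manifest, tissue_markers,
                                   alpha = alpha)
  if (length(refined) < 2L) {
    stop("fewer than 2 markers survive plasma refinement", call. = FALSE)
  }
  split <- stratified_split(manifest, ratio = ratio, seed = split_seed)
  feats <- t(plasma_pcm$log2pcm[refined, , drop = FALSE])
  train_ids <- split$sample_id[split$arm == "training"]
  Xtr <- feats[train_ids, , drop = FALSE]
  # median-impute per marker before LASSO (values re-derived at final fit)
  for (j in seq_len(ncol(Xtr))) {
    if (anyNA(Xtr[, j])) {
      Xtr[is.na(Xtr[, j]), j] <- median(Xtr[, j], na.rm = TRUE)
    }
  }
  y <- as.integer(manifest$group[match(train_ids, manifest$sample_id)] == "CRC")
  las <- lasso_select(Xtr, y, nfolds = nfolds, seed = cv_seed)
  if (length(las$selected) == 0L) {
    stop("LASSO selected no markers at lambda.min", call. = FALSE)
  }
  model <- fit_risk_model(feats[train_ids, , drop = FALSE], y, las$selected)
  tr_scores <- risk_score(model, feats[train_ids, , drop = FALSE])
  yj <- youden_threshold(tr_scores, y == 1L)
  model$threshold <- yj$threshold
  age_rep <- check_age_independence(feats, manifest, las$selected)
  list(model = model, split = split, refined_markers = refined,
       selected_markers = las$selected, lambda_min = las$lambda_min,
       training_scores = tr_scores, youden_J = yj$J,
       age_independence = age_rep)
}

#' Serialise / restore a risk model as JSON
#'
#' The JSON stores marker ids, coefficients, intercept, threshold,
#' standardisation and imputation values -- everything needed for
#' bit-reproducible scoring.
#'
#' @param model A `cfmeth_model`.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "cfmeth_model"))
  # 17 significant digits: lossless for IEEE doubles
  jsonlite::write_json(unclass(model), path, digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "center", "scale", "impute")) {
    obj[[f]] <- setNames(as.numeric(obj[[f]]), obj$marker_ids)
  }
  obj$threshold <- if (is.null(obj$threshold)) NA_real_
                   else as.numeric(obj$threshold)
  structure(obj, class = "cfmeth_model")
}
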