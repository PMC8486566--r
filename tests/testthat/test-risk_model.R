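test_that("plasma refinement keeps concordant markers and respects alpha", {
  coh <- generate_cohort(small_config(seed = 19L))
  planted <- coh$truth$marker_region_ids
  kept <- refine_markers_plasma(coh$plasma_pcm, coh$manifest, planted)
  expect_gte(mean(planted %in% kept), 0.8)
  # alpha = 1 is the identity
  expect_identical(refine_markers_plasma(coh$plasma_pcm, coh$manifest,
                                         planted, alpha = 1), planted)
  expect_error(refine_markers_plasma(coh$plasma_pcm, coh$manifest,
                                     character(0)), "non-empty")
  expect_error(refine_markers_plasma(coh$plasma_pcm, coh$manifest,
                                     "not_a_region"), "no tissue marker")
})

test_that("the stratified split balances arms globally and per stratum", {
  coh <- generate_cohort(synthetic_config(seed = 17L))
  sp <- stratified_split(coh$manifest, seed = 4L)
  expect_equal(nrow(sp), 381L)  # plasma Normal + CRC only
  expect_lte(abs(diff(table(sp$arm))), 1L)
  tb <- table(attr(sp, "strata"), sp$arm)
  expect_lte(max(abs(tb[, 1] - tb[, 2])), 1L)
  # NAA/AA are never assigned
  grp <- coh$manifest$group[match(sp$sample_id, coh$manifest$sample_id)]
  expect_true(all(grp %in% c("Normal", "CRC")))
  # determinism / seed sensitivity
  expect_identical(sp, stratified_split(coh$manifest, seed = 4L))
  expect_false(identical(sp$arm, stratified_split(coh$manifest,
                                                  seed = 5L)$arm))
  # arm balance on demographics
  m <- coh$manifest[match(sp$sample_id, coh$manifest$sample_id), ]
  sexes <- tapply(m$sex == "M", sp$arm, mean)
  ages <- tapply(m$age, sp$arm, mean)
  expect_lt(abs(diff(sexes)), 0.10)
  expect_lt(abs(diff(ages)), 3)
})

test_that("per-stratum imbalance stays within one on random manifests", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    grp <- sample(c("Normal", "CRC"), n, TRUE)
    man <- data.frame(
      sample_id = sprintf("s%03d", 1:n), cohort = "plasma", group = grp,
      stage = ifelse(grp == "CRC", sample(c("I", "II", "III", "IV"), n, TRUE),
                     NA_character_),
      age = sample(20:85, n, TRUE), sex = sample(c("M", "F"), n, TRUE),
      stringsAsFactors = FALSE)
    sp <- stratified_split(man, seed = i)
    tb <- table(attr(sp, "strata"), factor(sp$arm, c("training", "validation")))
    expect_lte(max(abs(tb[, 1] - tb[, 2])), 1L)
    expect_lte(abs(diff(table(factor(sp$arm, c("training", "validation"))))),
               1L)
  }
})

test_that("LASSO selection finds planted support and respects lambda_max", {
  set.seed(14)
  n <- 150; p <- 60
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 1:4] %*% c(1.5, 1.5, -1.5, 1.5)))
  sel <- lasso_select(X, y, seed = 2L)
  expect_gte(sum(paste0("f", 1:4) %in% sel$selected), 3L)
  # at lambda_max the penalised fit keeps no features
  expect_equal(sum(coef(sel$cv_fit$glmnet.fit,
                        s = max(sel$cv_fit$lambda))[-1] != 0), 0L)
  # constant columns are dropped with a warning
  X2 <- cbind(X, const = 1)
  expect_warning(lasso_select(X2, y, seed = 2L), "constant")
  expect_error(lasso_select(X, rep(1, n)), "both classes")
})

test_that("the logistic fit recovers coefficients and scores monotonically", {
  set.seed(6)
  n <- 1200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(1, -0.8, 0.5)
  y <- rbinom(n, 1, plogis(0.3 + X %*% beta))
  m <- fit_risk_model(X, y, c("a", "b", "c"))
  # coefficients act on standardised features; undo the scaling to compare
  expect_lt(max(abs(m$coefficients / m$scale - beta)), 0.2)
  # probability scale and monotonicity in a positive-coefficient feature
  grid <- cbind(a = seq(-2, 2, length.out = 9), b = 0, c = 0)
  s <- risk_score(m, grid)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) > 0))
  # zero model scores 0.5 everywhere
  m0 <- m; m0$coefficients[] <- 0; m0$intercept <- 0
  expect_equal(unname(risk_score(m0, grid)), rep(0.5, 9))
  # missing features fall back to the stored imputation values
  gx <- grid; gx[3, "a"] <- NA
  expect_equal(unname(risk_score(m, gx)[3]),
               unname(risk_score(m, cbind(a = m$impute["a"], b = 0, c = 0))))
})

test_that("separated fits fall back to the ridge stabiliser", {
  X <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "a"))
  y <- rep(0:1, each = 20)
  expect_warning(m <- fit_risk_model(X, y, "a"), "separation")
  s <- risk_score(m, X)
  expect_true(all(s[y == 1] > 0.5) && all(s[y == 0] < 0.5))
})

test_that("youden_threshold maximises J with midpoint thresholds", {
  res <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$J, 1)
  deg <- youden_threshold(rep(0.4, 6), rep(c(TRUE, FALSE), 3))
  expect_true(deg$degenerate)
  expect_equal(deg$J, 0)
  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    s <- round(runif(n), 2)  # ties on purpose
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    res <- youden_threshold(s, l)
    expect_equal(res$J, exhaustive_max_J(s, l), tolerance = 1e-12)
  }
})

test_that("age-independence screening flags only age-driven markers", {
  coh <- generate_cohort(small_config(seed = 29L))
  feats <- t(coh$plasma_pcm$log2pcm)
  ids <- rownames(feats)
  age <- coh$manifest$age[match(ids, coh$manifest$sample_id)]
  feats <- cbind(feats, age_driven = age / 100, flat = 0.5)
  rep_ <- check_age_independence(feats, coh$manifest,
                                 c("r0001", "age_driven", "flat"))
  expect_true(rep_$flagged[rep_$marker_id == "age_driven"])
  expect_gt(abs(rep_$rho[rep_$marker_id == "age_driven"]), 0.99)
  expect_true(is.na(rep_$rho[rep_$marker_id == "flat"]))
  expect_false(rep_$flagged[rep_$marker_id == "flat"])
})

test_that("a trained model round-trips through JSON with identical scores", {
  coh <- generate_cohort(small_config(seed = 37L))
  mk <- select_tissue_markers(coh$tissue_pcm, coh$manifest)
  tr <- train_risk_model(coh$plasma_pcm, coh$manifest,
                         mk$region_id[mk$selected], nfolds = 5L)
  expect_s3_class(tr$model, "cfmeth_model")
  expect_true(tr$model$threshold > 0 && tr$model$threshold < 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(tr$model, f)
  back <- read_model_json(f)
  feats <- t(coh$plasma_pcm$log2pcm)
  expect_equal(risk_score(tr$model, feats), risk_score(back, feats),
               tolerance = 1e-15)
})
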