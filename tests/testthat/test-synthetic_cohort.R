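test_that("generation is deterministic given the seed", {
  cfg <- small_config(seed = 21L)
  a <- generate_regions(cfg); b <- generate_regions(cfg)
  expect_identical(a, b)
  ca <- generate_cohort(cfg); cb <- generate_cohort(cfg)
  expect_identical(ca$tissue_pcm$pcm, cb$tissue_pcm$pcm)
  expect_identical(ca$manifest, cb$manifest)
  expect_false(identical(ca$plasma_pcm$pcm,
                         generate_cohort(small_config(seed = 22L))$plasma_pcm$pcm))
})

test_that("planted truth obeys its construction invariants", {
  rt <- generate_regions(small_config())
  tb <- rt$truth$table
  mk <- tb$is_crc_marker
  expect_equal(sum(mk), 12L)
  expect_true(all(tb$theta_tumor[mk] - tb$theta_normal[mk] >= 0.25 - 1e-12))
  expect_true(all(tb$theta_aa[mk] > tb$theta_normal[mk]))
  plain <- !mk & !tb$is_aa_crc_marker
  expect_true(all(tb$theta_tumor[plain] == tb$theta_normal[plain]))
  expect_true(all(tb$theta_aa[plain] == tb$theta_normal[plain]))
  # AA-vs-CRC regions differ in AA only
  aac <- tb$is_aa_crc_marker
  expect_true(all(tb$theta_tumor[aac] == tb$theta_normal[aac]))
  expect_true(all(tb$theta_aa[aac] > tb$theta_normal[aac]))

  # null model: no planted markers, all states identical
  rt0 <- generate_regions(small_config(n_crc_markers = 0L,
                                       n_aa_crc_markers = 0L))
  tb0 <- rt0$truth$table
  expect_identical(tb0$theta_tumor, tb0$theta_normal)
  expect_error(synthetic_config(n_regions = 10L, n_crc_markers = 20L),
               "more planted markers")
})

test_that("sample fractions follow the mixture model limits", {
  cfg0 <- small_config(sample_noise_sd = 0)
  rt <- generate_regions(cfg0)
  tb <- rt$truth$table
  set.seed(1)
  # healthy plasma: f = 0, noiseless -> clamped theta_normal exactly
  fr <- simulate_sample_fractions(rt$truth, "plasma", "Normal", config = cfg0)
  expect_equal(fr$tumor_fraction, 0)
  expect_equal(unname(fr$fractions), pmin(pmax(tb$theta_normal, 0.01), 0.99))
  # pure lesion limit: tissue AA is undiluted
  fr <- simulate_sample_fractions(rt$truth, "tissue", "AA", config = cfg0)
  expect_equal(unname(fr$fractions), pmin(pmax(tb$theta_aa, 0.01), 0.99))
  # tissue CRC interpolates with the drawn purity
  fr <- simulate_sample_fractions(rt$truth, "tissue", "CRC", config = cfg0)
  pi_ <- fr$tumor_fraction
  expect_true(pi_ >= 0.3 && pi_ <= 0.9)
  expect_equal(unname(fr$fractions),
               pmin(pmax((1 - pi_) * tb$theta_normal + pi_ * tb$theta_tumor,
                         0.01), 0.99))
})

test_that("stage-II plasma marker shift matches the closed-form mean", {
  cfg <- small_config()
  rt <- generate_regions(cfg)
  tb <- rt$truth$table
  r <- which(tb$is_crc_marker)[1]
  delta <- tb$theta_tumor[r] - tb$theta_normal[r]
  set.seed(99)
  n <- 500
  shifts <- replicate(n, {
    simulate_sample_fractions(rt$truth, "plasma", "CRC", "II",
                              cfg)$fractions[r] - tb$theta_normal[r]
  })
  expected <- mean(c(0.04, 0.10)) * delta   # E[f] * delta
  mc_se <- sd(shifts) / sqrt(n)
  expect_lt(abs(mean(shifts) - expected), 3 * mc_se)
})

test_that("read-level and count-level samplers match the enumeration law", {
  # fixed read length k = 6 so the expectation is a single closed form
  cfg <- small_config(cpgs_per_read = c(6L, 6L), sample_noise_sd = 0)
  region <- data.frame(chrom = "chrS1", start = 0L, end = 400L,
                       region_id = "r1", stringsAsFactors = FALSE)
  p <- 0.3
  q <- p * comethylation_prob(6, 1 - cfg$epsilon) +
    (1 - p) * comethylation_prob(6, cfg$epsilon)

  set.seed(42)
  reads <- simulate_epireads(c(r1 = p), region, "s1", depth = 2000,
                             config = cfg)
  obs <- region_pcm(reads, region)
  se <- sqrt(q * (1 - q) / obs$n_eligible)
  expect_lt(abs(obs$pcm - q), 3 * se)

  cnt <- simulate_region_counts(rep(p, 500), depth = 400, config = cfg)
  pcm_counts <- sum(cnt$n_comethylated) / sum(cnt$n_eligible)
  se <- sqrt(q * (1 - q) / sum(cnt$n_eligible))
  expect_lt(abs(pcm_counts - q), 3 * se)

  # noiseless limits: a pure methylated (unmethylated) epiallele pool
  cfg0 <- small_config(epsilon = 0, cpgs_per_read = c(6L, 6L))
  expect_equal(region_pcm(simulate_epireads(c(r1 = 1), region, "s1", 200,
                                            cfg0))$pcm, 1)
  expect_equal(region_pcm(simulate_epireads(c(r1 = 0), region, "s1", 200,
                                            cfg0))$pcm, 0)
})

test_that("cfDNA yields have the configured group means", {
  cfg <- small_config()
  set.seed(12)
  n <- 10000
  draws <- simulate_cfdna_yield("Normal", n, cfg)
  expect_lt(abs(mean(draws) - 3.94), 3 * sd(draws) / sqrt(n))
  crc <- simulate_cfdna_yield("CRC", n, cfg)
  expect_gt(mean(crc), mean(draws))
  set.seed(5); a <- simulate_cfdna_yield("AA", 3, cfg)
  set.seed(5); b <- simulate_cfdna_yield("AA", 3, cfg)
  expect_identical(a, b)
})

test_that("planted AA and CRC effects are concordant across markers", {
  rt <- generate_regions(synthetic_config(seed = 3L))
  tb <- rt$truth$table[rt$truth$table$is_crc_marker, ]
  d_crc <- tb$theta_tumor - tb$theta_normal
  d_aa <- tb$theta_aa - tb$theta_normal
  # analytic correlation of (a*delta, delta) with a ~ U(0.6, 1),
  # delta ~ U(0.25, 0.6) is ~0.85; assert concordance around that value
  expect_gt(cor(d_aa, d_crc), 0.8)
  expect_gt(coef(lm(d_aa ~ d_crc))[2], 0)
  expect_true(all(d_aa > 0 & d_crc > 0))
})

test_that("the default cohort matches the emulated study composition", {
  cfg <- synthetic_config()
  plan_groups <- c(cfg$plasma_n, CRC = sum(cfg$plasma_crc_stage_n))
  expect_equal(unname(plan_groups[c("Normal", "NAA", "AA", "CRC")]),
               c(133L, 40L, 68L, 248L))
  expect_equal(sum(plan_groups), 489L)
  expect_equal(unname(cfg$tissue_n), c(91L, 26L, 70L))
})
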