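test_that("the window rule matches hand-enumerated examples", {
  expect_true(is_comethylated(c("M", "M", "M")))
  expect_false(is_comethylated(rep("U", 6)))
  # windows (M,U,M,U,U)=2, (U,M,U,U,M)=2, (M,U,U,M,U)=2, all < 3
  expect_false(is_comethylated("MUMUUMU"))
  # first window (M,M,U,U,M) has 3 M
  expect_true(is_comethylated("MMUUMU"))
  # N is never methylated
  expect_false(is_comethylated(c("M", "M", "N")))
  expect_true(is_comethylated(c("M", "M", "N", "M")))
  expect_error(is_comethylated(c("M", "M")), "at least 3")
  expect_error(is_comethylated(c("M", "M", "X")), "\\{M, U, N\\}")
  # short-read policy switch
  expect_false(is_comethylated("MMM", short_read = "exclude"))
})

test_that("is_comethylated agrees with brute-force window enumeration", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(3:12, 1)
    s <- random_call_string(k, p_m = runif(1), p_n = 0.1)
    calls <- strsplit(s, "")[[1]]
    expect_identical(is_comethylated(calls),
                     brute_force_comethylated(calls),
                     info = s)
  }
})

test_that("comethylation_prob matches closed forms and simulation", {
  # k < window: single window, P(Bin(k, p) >= 3)
  expect_equal(comethylation_prob(3, 0.7), 0.7^3)
  expect_equal(comethylation_prob(4, 0.4), 1 - pbinom(2, 4, 0.4))
  # k == window
  expect_equal(comethylation_prob(5, 0.6), 1 - pbinom(2, 5, 0.6))
  expect_equal(comethylation_prob(8, 0), 0)
  expect_equal(comethylation_prob(8, 1), 1)
  # k > window: Monte-Carlo cross-check
  set.seed(5)
  n <- 20000
  hits <- mean(replicate(n, {
    brute_force_comethylated(c("U", "M")[rbinom(7, 1, 0.35) + 1])
  }))
  q <- comethylation_prob(7, 0.35)
  expect_lt(abs(hits - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("region_pcm applies the eligibility rule and handles degeneracy", {
  # 10 eligible reads, 4 co-methylated
  reads <- make_epireads(c(rep("MMM", 4), rep("UUM", 6)))
  res <- region_pcm(reads)
  expect_equal(res$n_eligible, 10L)
  expect_equal(res$pcm, 0.4)

  # reads with only 2 CpGs are excluded from both numerator and denominator
  reads <- make_epireads(c("MM", "MM", "MMM", "MMMM", "MMMMM"))
  res <- region_pcm(reads)
  expect_equal(res$n_eligible, 3L)
  expect_equal(res$pcm, 1.0)

  # fewer than 3 non-N calls makes a read ineligible
  res <- region_pcm(make_epireads(c("MNN", "MMNN", "MMM")))
  expect_equal(res$n_eligible, 1L)

  expect_true(is.na(region_pcm(make_epireads(c("MM", "UU")))$pcm))
  expect_error(region_pcm(make_epireads(c("MMM", "MMM"),
                                        sample_id = c("s1", "s2"))),
               "single")
})

test_that("region_pcm restricts calls to in-region CpGs", {
  reads <- make_epireads("MMMUU", start = 95L)  # positions 98..110
  region <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                       region_id = "r1")
  # position 98 falls outside; restricted calls are MMUU -> not co-methylated
  res <- region_pcm(reads, region)
  expect_equal(res$n_eligible, 1L)
  expect_equal(res$n_comethylated, 0L)
})

test_that("log2 transform evaluates directly and propagates NA", {
  expect_equal(log2_transform(1.0, 1e-3), log2(1.001))
  expect_equal(log2_transform(0.0, 1e-3), log2(0.001))
  expect_equal(log2_transform(0.0, 1e-3), -9.9658, tolerance = 1e-4)
  expect_true(is.na(log2_transform(NA_real_, 1e-3)))
  expect_error(log2_transform(0.5, 0), "positive")
  expect_error(log2_transform(1.3, 1e-3), "\\[0, 1\\]")
  # approaches log2(pcm) as the pseudocount vanishes
  expect_equal(log2_transform(0.25, 1e-9), -2, tolerance = 1e-7)
})

test_that("build_pcm_matrix equals cellwise region_pcm and ignores order", {
  regions <- data.frame(chrom = "chr1", start = c(100L, 500L),
                        end = c(300L, 800L), region_id = c("rA", "rB"),
                        stringsAsFactors = FALSE)
  reads <- rbind(
    make_epireads(c("MMM", "UUU", "MMMM"), "s1", "rA"),
    make_epireads(c("UMU", "UUMU"), "s1", "rB", start = 500L),
    make_epireads(c("MMMMM", "MMUUU"), "s2", "rA"),
    make_epireads("MM", "s2", "rB", start = 500L))
  samples <- c("s1", "s2")
  pm <- build_pcm_matrix(reads, regions, samples)
  for (s in samples) for (r in regions$region_id) {
    sub <- reads[reads$sample_id == s & reads$region_id == r, , drop = FALSE]
    cell <- region_pcm(sub, regions[regions$region_id == r, ])
    expect_equal(unname(pm$pcm[r, s]), cell$pcm)
    expect_equal(unname(pm$n_eligible[r, s]), cell$n_eligible)
  }
  expect_true(is.na(pm$pcm["rB", "s2"]))  # only a 2-CpG read there
  expect_equal(pm$log2pcm, log2_transform(pm$pcm, 1e-3))

  perm <- reads[sample(nrow(reads)), , drop = FALSE]
  expect_equal(build_pcm_matrix(perm, regions, samples)$pcm, pm$pcm)

  empty <- reads[0, , drop = FALSE]
  expect_true(all(is.na(build_pcm_matrix(empty, regions, samples)$pcm)))
  bad <- make_epireads("MMM", "s1", "rZ")
  expect_error(build_pcm_matrix(bad, regions, samples), "rZ")
})

test_that("pcm stays in [0,1] and responds monotonically to reads", {
  set.seed(8)
  for (i in 1:25) {
    calls <- vapply(1:20, function(j) random_call_string(sample(3:8, 1)), "")
    base <- region_pcm(make_epireads(calls))
    expect_gte(base$pcm, 0); expect_lte(base$pcm, 1)
    up <- region_pcm(make_epireads(c(calls, "MMMMM")))
    down <- region_pcm(make_epireads(c(calls, "UUUUU")))
    expect_gte(up$pcm, base$pcm - 1e-12)
    expect_lte(down$pcm, base$pcm + 1e-12)
  }
})
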