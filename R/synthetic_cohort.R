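# Synthetic two-cohort generator. The generative model is a two-epiallele
# mixture: every region r has a methylated-epiallele fraction per biological
# state (theta_normal, theta_aa, theta_tumor); a sample's per-region
# fraction is a purity/tumor-fraction weighted mixture of states plus
# sample-level noise; each sequenced read draws an epiallele and emits CpG
# calls with symmetric per-CpG error epsilon. Under this model a read of k
# CpGs is co-methylated with probability
#   q(p, k) = p * qM(k) + (1 - p) * qU(k),
# where qM/qU are exact window-rule probabilities (comethylation_prob) at
# per-CpG methylation 1-epsilon and epsilon. Because reads are i.i.d. given
# the fraction, the per-cell co-methylated count is exactly Binomial with
# success probability mean_k q(p, k); generate_cohort samples counts
# directly from that law, while simulate_epireads materialises individual
# reads for small-scale cross-checks.

#' Configuration of the synthetic cohort generator
#'
#' Returns a validated configuration list. Defaults emulate the design of a
#' two-cohort colorectal-cancer methylation study: a tissue discovery
#' cohort (91 Normal, 26 advanced adenoma, 70 CRC) and a plasma cohort
#' (133 Normal, 40 NAA, 68 AA, 248 CRC split 66/86/62/34 across stages
#' I-IV), 2000 panel regions of which 300 are planted CRC/AA
#' hypermethylated markers and 50 differ between AA and CRC, read depths of
#' 300 (tissue) and 1000 (plasma) eligible reads per region, per-CpG call
#' error 0.02, and stage-dependent plasma tumor fractions.
#'
#' @param n_regions Number of panel regions.
#' @param n_crc_markers Planted CRC/AA-hypermethylated marker regions.
#' @param n_aa_crc_markers Regions methylated differently in AA than CRC.
#' @param tissue_n Named sizes for tissue groups Normal/AA/CRC.
#' @param plasma_n Named sizes for plasma groups Normal/NAA/AA.
#' @param plasma_crc_stage_n Named sizes for plasma CRC stages I-IV.
#' @param depth_tissue,depth_plasma Mean eligible reads per region (Poisson).
#' @param cpgs_per_read Integer range (min, max) of CpGs per read.
#' @param epsilon Per-CpG call error probability.
#' @param delta_range Range of the planted marker effect
#'   (theta_tumor - theta_normal).
#' @param aa_attenuation_range AA effect as a fraction of the CRC effect.
#' @param tumor_purity_range Tumor purity range for tissue CRC samples.
#' @param tumor_fraction Named list of `c(lo, hi)` tumor-fraction ranges
#'   for plasma groups `Normal`, `NAA`, `AA` and stages `I`-`IV`.
#' @param sample_noise_sd SD of per-sample Gaussian noise on fractions.
#' @param cfdna_yield_means Mean plasma cfDNA yield (ng per mL plasma) per
#'   group; Normal/AA/CRC defaults follow the motivating study's reported
#'   means, the NAA value sits near the Normal one (the two groups did not
#'   differ).
#' @param cfdna_yield_cv Coefficient of variation of the lognormal yield.
#' @param window,min_meth,min_cpgs Co-methylation rule parameters.
#' @param pseudocount Pseudocount for log2 PCM.
#' @param seed RNG seed driving all generator randomness.
#' @return A list of class `cfmeth_config`.
#' @export
synthetic_config <- function(n_regions = 2000L,
                             n_crc_markers = 300L,
                             n_aa_crc_markers = 50L,
                             tissue_n = c(Normal = 91L, AA = 26L, CRC = 70L),
                             plasma_n = c(Normal = 133L, NAA = 40L, AA = 68L),
                             plasma_crc_stage_n = c(I = 66L, II = 86L,
                                                    III = 62L, IV = 34L),
                             depth_tissue = 300,
                             depth_plasma = 1000,
                             cpgs_per_read = c(3L, 10L),
                             epsilon = 0.02,
                             delta_range = c(0.25, 0.60),
                             aa_attenuation_range = c(0.6, 1.0),
                             tumor_purity_range = c(0.3, 0.9),
                             tumor_fraction = list(
                               Normal = c(0, 0),
                               NAA = c(0.005, 0.02),
                               AA = c(0.01, 0.03),
                               I = c(0.02, 0.06),
                               II = c(0.04, 0.10),
                               III = c(0.06, 0.15),
                               IV = c(0.10, 0.25)),
                             sample_noise_sd = 0.02,
                             cfdna_yield_means = c(Normal = 3.94, NAA = 4.20,
                                                   AA = 6.08, CRC = 6.43),
                             cfdna_yield_cv = 0.5,
                             window = 5L, min_meth = 3L, min_cpgs = 3L,
                             pseudocount = 1e-3,
                             seed = 17L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_crc_markers = as.integer(n_crc_markers),
              n_aa_crc_markers = as.integer(n_aa_crc_markers),
              tissue_n = tissue_n, plasma_n = plasma_n,
              plasma_crc_stage_n = plasma_crc_stage_n,
              depth_tissue = depth_tissue, depth_plasma = depth_plasma,
              cpgs_per_read = as.integer(cpgs_per_read), epsilon = epsilon,
              delta_range = delta_range,
              aa_attenuation_range = aa_attenuation_range,
              tumor_purity_range = tumor_purity_range,
              tumor_fraction = tumor_fraction,
              sample_noise_sd = sample_noise_sd,
              cfdna_yield_means = cfdna_yield_means,
              cfdna_yield_cv = cfdna_yield_cv,
              window = as.integer(window), min_meth = as.integer(min_meth),
              min_cpgs = as.integer(min_cpgs), pseudocount = pseudocount,
              seed = as.integer(seed))
  if (cfg$n_crc_markers + cfg$n_aa_crc_markers > cfg$n_regions) {
    stop("more planted markers than regions", call. = FALSE)
  }
  if (!all(c("Normal", "AA", "CRC") %in% names(cfg$tissue_n)) ||
      !all(c("Normal", "NAA", "AA") %in% names(cfg$plasma_n)) ||
      !all(c("I", "II", "III", "IV") %in% names(cfg$plasma_crc_stage_n))) {
    stop("group size vectors must be fully named", call. = FALSE)
  }
  if (any(c(cfg$tissue_n, cfg$plasma_n, cfg$plasma_crc_stage_n) < 2L)) {
    stop("every group must have size >= 2", call. = FALSE)
  }
  if (cfg$epsilon < 0 || cfg$epsilon >= 0.5) {
    stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  }
  fr <- unlist(cfg$tumor_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("tumor fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$delta_range[1] <= 0 || cfg$delta_range[2] > 0.9 ||
      diff(cfg$delta_range) < 0) {
    stop("delta_range must be increasing within (0, 0.9]", call. = FALSE)
  }
  if (cfg$cpgs_per_read[1] < cfg$min_cpgs) {
    stop("cpgs_per_read minimum must be >= min_cpgs", call. = FALSE)
  }
  if (diff(cfg$cpgs_per_read) < 0) {
    stop("cpgs_per_read must be an increasing range", call. = FALSE)
  }
  class(cfg) <- "cfmeth_config"
  cfg
}

# Mean co-methylation probabilities over the read-length distribution,
# cached per (epsilon, window, min_meth, k-range).
comet_prob_table <- function(config) {
  ks <- seq(config$cpgs_per_read[1], config$cpgs_per_read[2])
  qm <- vapply(ks, comethylation_prob, numeric(1L), p_m = 1 - config$epsilon,
               window = config$window, min_meth = config$min_meth)
  qu <- vapply(ks, comethylation_prob, numeric(1L), p_m = config$epsilon,
               window = config$window, min_meth = config$min_meth)
  list(k = ks, q_meth = qm, q_unmeth = qu,
       q_meth_mean = mean(qm), q_unmeth_mean = mean(qu))
}

generate_regions_rng <- function(config) {
  n <- config$n_regions
  len <- sample(120:360, n, replace = TRUE)
  gap <- 500L
  start <- cumsum(c(1000L, head(len, -1L) + gap))
  regions <- data.frame(chrom = "chrS1", start = start, end = start + len,
                        region_id = sprintf("r%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
  planted <- sample(n, config$n_crc_markers + config$n_aa_crc_markers)
  crc_idx <- planted[seq_len(config$n_crc_markers)]
  aa_crc_idx <- planted[-seq_len(config$n_crc_markers)]

  theta_normal <- runif(n, 0.05, 0.95)
  theta_tumor <- theta_normal
  theta_aa <- theta_normal
  delta <- rep(NA_real_, n)
  attenuation <- rep(NA_real_, n)

  theta_normal[crc_idx] <- runif(length(crc_idx), 0.05, 0.20)
  delta[crc_idx] <- runif(length(crc_idx), config$delta_range[1],
                          config$delta_range[2])
  attenuation[crc_idx] <- runif(length(crc_idx),
                                config$aa_attenuation_range[1],
                                config$aa_attenuation_range[2])
  theta_tumor[crc_idx] <- pmin(theta_normal[crc_idx] + delta[crc_idx], 0.95)
  theta_aa[crc_idx] <- pmin(theta_normal[crc_idx] +
                              attenuation[crc_idx] * delta[crc_idx], 0.95)

  # AA-vs-CRC markers: adenoma-specific hypermethylation absent from tumor.
  theta_normal[aa_crc_idx] <- runif(length(aa_crc_idx), 0.05, 0.20)
  theta_tumor[aa_crc_idx] <- theta_normal[aa_crc_idx]
  delta[aa_crc_idx] <- runif(length(aa_crc_idx), config$delta_range[1],
                             config$delta_range[2])
  theta_aa[aa_crc_idx] <- pmin(theta_normal[aa_crc_idx] + delta[aa_crc_idx],
                               0.95)

  truth_table <- data.frame(
    region_id = regions$region_id,
    theta_normal = theta_normal, theta_aa = theta_aa,
    theta_tumor = theta_tumor, delta = delta, attenuation = attenuation,
    is_crc_marker = seq_len(n) %in% crc_idx,
    is_aa_crc_marker = seq_len(n) %in% aa_crc_idx,
    stringsAsFactors = FALSE)
  truth <- structure(list(table = truth_table,
                          marker_region_ids = regions$region_id[sort(crc_idx)],
                          aa_crc_region_ids = regions$region_id[sort(aa_crc_idx)]),
                     class = "cfmeth_truth")
  list(regions = regions, truth = truth)
}

#' Generate synthetic panel regions and planted truth
#'
#' Draws `n_regions` non-overlapping regions on a synthetic chromosome and
#' the per-region epiallele fractions of each biological state. Planted
#' CRC markers are hypermethylated in tumor (background
#' `theta_normal ~ U(0.05, 0.20)`, effect `delta ~ U(delta_range)`) with a
#' concordant, attenuated AA effect; AA-vs-CRC marker regions are
#' hypermethylated in adenoma only; all remaining regions share one
#' `theta ~ U(0.05, 0.95)` across states.
#'
#' @param config A [synthetic_config()].
#' @return A list with `regions` (data frame) and `truth` (planted marker
#'   ids and per-state fractions). Deterministic given `config$seed`.
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "cfmeth_config"))
  set.seed(config$seed)
  generate_regions_rng(config)
}

#' Per-region epiallele fractions for one sample
#'
#' Mixes biological-state fractions according to the sample's tumor purity
#' (tissue) or circulating-tumor-DNA fraction (plasma), adds sample-level
#' Gaussian noise and clamps to `[0.01, 0.99]`. Tissue CRC samples draw a
#' purity from `tumor_purity_range`; tissue AA lesions are taken as pure;
#' plasma samples draw a tumor fraction from the group- or stage-specific
#' range, diluting the lesion signal into a Normal background. Uses the
#' current RNG state (callers seed).
#'
#' @param truth Truth object from [generate_regions()].
#' @param cohort `"tissue"` or `"plasma"`.
#' @param group Group label (Normal/NAA/AA/CRC; NAA plasma only).
#' @param stage TNM stage for CRC samples.
#' @param config A [synthetic_config()].
#' @return A list with `fractions` (named per-region vector) and
#'   `tumor_fraction` (the purity or ctDNA fraction drawn).
#' @export
simulate_sample_fractions <- function(truth, cohort, group, stage = NA,
                                      config) {
  tb <- truth$table
  if (cohort == "tissue") {
    if (group == "Normal") {
      f <- 0; p <- tb$theta_normal
    } else if (group == "AA") {
      f <- 1; p <- tb$theta_aa
    } else if (group == "CRC") {
      f <- runif(1, config$tumor_purity_range[1], config$tumor_purity_range[2])
      p <- (1 - f) * tb$theta_normal + f * tb$theta_tumor
    } else stop("tissue cohort has no group ", group, call. = FALSE)
  } else if (cohort == "plasma") {
    key <- if (group == "CRC") as.character(stage) else group
    rng <- config$tumor_fraction[[key]]
    if (is.null(rng)) stop("no tumor-fraction range for ", key, call. = FALSE)
    f <- runif(1, rng[1], rng[2])
    lesion <- switch(group, Normal = tb$theta_normal,
                     NAA = tb$theta_aa, AA = tb$theta_aa,
                     CRC = tb$theta_tumor)
    p <- (1 - f) * tb$theta_normal + f * lesion
  } else stop("cohort must be tissue or plasma", call. = FALSE)
  p <- p + rnorm(length(p), 0, config$sample_noise_sd)
  p <- pmin(pmax(p, 0.01), 0.99)
  names(p) <- tb$region_id
  list(fractions = p, tumor_fraction = f)
}

#' Draw per-region eligible and co-methylated read counts
#'
#' Exact count-level sampler of the read model: the eligible read count of
#' a region is Poisson(`depth`) and, reads being i.i.d. given the
#' methylated-epiallele fraction, the co-methylated count is Binomial with
#' success probability `p * mean_k qM(k) + (1 - p) * mean_k qU(k)` (window
#' probabilities from [comethylation_prob()], averaged over the read-length
#' distribution). Distributionally identical to materialising reads with
#' [simulate_epireads()] and scoring them with [region_pcm()], at a
#' fraction of the cost. Uses the current RNG state.
#'
#' @param fractions Named per-region fraction vector.
#' @param depth Mean eligible reads per region.
#' @param config A [synthetic_config()].
#' @param probs Optional precomputed [comethylation_prob()] table.
#' @return A list with integer vectors `n_eligible`, `n_comethylated`.
#' @export
simulate_region_counts <- function(fractions, depth, config, probs = NULL) {
  if (is.null(probs)) probs <- comet_prob_table(config)
  n <- rpois(length(fractions), depth)
  q <- fractions * probs$q_meth_mean + (1 - fractions) * probs$q_unmeth_mean
  comet <- rbinom(length(fractions), n, q)
  list(n_eligible = n, n_comethylated = comet)
}

#' Materialise epireads for one sample
#'
#' Read-level path of the generative model: per region, Poisson(`depth`)
#' reads; per read, a CpG count drawn uniformly from `cpgs_per_read`
#' (resampled if the region is shorter than twice the count), an epiallele
#' drawn Bernoulli(fraction), and per-CpG calls flipped with probability
#' `epsilon`; distinct CpG positions placed uniformly in the region.
#' Intended for small configurations; [generate_cohort()] uses the exact
#' count sampler instead. Uses the current RNG state.
#'
#' @inheritParams simulate_region_counts
#' @param regions Region data frame.
#' @param sample_id Sample id stamped on every read.
#' @return An epiread data frame (see [read_epireads()]).
#' @export
simulate_epireads <- function(fractions, regions, sample_id, depth, config) {
  stopifnot(identical(names(fractions), regions$region_id))
  kmin <- config$cpgs_per_read[1]; kmax <- config$cpgs_per_read[2]
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    n <- rpois(1L, depth)
    if (n == 0L) next
    len <- regions$end[i] - regions$start[i]
    kcap <- min(kmax, len %/% 2L)
    kvals <- seq(kmin, max(kmin, kcap))
    k <- kvals[sample.int(length(kvals), n, replace = TRUE)]
    z <- rbinom(n, 1L, fractions[i])
    pm <- ifelse(z == 1L, 1 - config$epsilon, config$epsilon)
    positions <- lapply(k, function(kk) {
      sort(sample(seq(regions$start[i], regions$end[i] - 1L), kk))
    })
    calls <- vapply(seq_len(n), function(j) {
      paste(ifelse(rbinom(k[j], 1L, pm[j]) == 1L, "M", "U"), collapse = "")
    }, character(1L))
    df <- data.frame(sample_id = rep(sample_id, n),
                     region_id = rep(regions$region_id[i], n),
                     chrom = rep(regions$chrom[i], n),
                     stringsAsFactors = FALSE)
    df$positions <- positions
    df$calls <- calls
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    e <- data.frame(sample_id = character(), region_id = character(),
                    chrom = character(), stringsAsFactors = FALSE)
    e$positions <- list(); e$calls <- character()
    return(e)
  }
  do.call(rbind, out)
}

#' Simulate a plasma cfDNA yield
#'
#' Lognormal draw with the group-specific mean from the configuration and
#' coefficient of variation `cfdna_yield_cv`. Uses the current RNG state.
#'
#' @param group Group label.
#' @param n Number of draws.
#' @param config A [synthetic_config()].
#' @return Numeric vector of yields (ng per mL plasma).
#' @export
simulate_cfdna_yield <- function(group, n = 1L, config) {
  m <- config$cfdna_yield_means[[group]]
  if (is.null(m)) stop("no cfDNA yield mean for group ", group, call. = FALSE)
  sdlog <- sqrt(log1p(config$cfdna_yield_cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Synthetic serum tumor-marker analogs (lognormal, weakly elevated with
# disease). Parameters are arbitrary beyond targeting moderate
# discrimination (CEA analog AUC vs Normal ~ 0.75, CA19-9 analog ~ 0.6),
# so the scalar-biomarker comparison machinery has something to chew on.
simulate_serum_markers <- function(group, n) {
  cea_off <- c(Normal = 0, NAA = 0.15, AA = 0.30, CRC = 0.83)[[group]]
  ca_off <- c(Normal = 0, NAA = 0.05, AA = 0.10, CRC = 0.32)[[group]]
  list(cea = rlnorm(n, log(1.8) + cea_off, 0.8),
       ca199 = rlnorm(n, log(8) + ca_off, 1.0))
}

# Deterministic-looking demographics matched to the cohort composition the
# generator emulates (plasma controls younger than patients, ~60% male).
sample_demographics <- function(group, n, cohort) {
  par <- switch(group,
    Normal = if (cohort == "plasma") c(44, 13, 18, 78, 0.5714)
             else c(60, 13, 24, 89, 0.58),
    NAA = c(56, 12, 38, 86, 0.6250),
    AA = c(59, 13, 23, 86, if (cohort == "plasma") 0.6324 else 0.58),
    CRC = c(60, 13, 24, 89, if (cohort == "plasma") 0.5766 else 0.58))
  age <- round(pmin(pmax(rnorm(n, par[1], par[2]), par[3]), par[4]))
  sex <- ifelse(runif(n) < par[5], "M", "F")
  list(age = age, sex = sex)
}

#' Generate a full synthetic study (regions, cohorts, manifest, truth)
#'
#' Runs the whole generative model under `config$seed`: regions and truth,
#' tissue and plasma sample manifests with demographics, QC flags (all
#' pass), cfDNA yields and serum tumor-marker analogs, and PCM matrices
#' drawn from the exact count-level read model. With
#' `emit_epireads = TRUE` individual reads are materialised instead and
#' the PCM matrices are computed from them via [build_pcm_matrix()] (only
#' sensible for small configurations).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `regions.bed`,
#'   `manifest.tsv`, `tissue_pcm.tsv`, `plasma_pcm.tsv`, `truth.json` (and
#'   epiread TSVs when materialised).
#' @param emit_epireads Materialise read-level data.
#' @return A list with `regions`, `truth`, `manifest`, `tissue_pcm`,
#'   `plasma_pcm` (both `cfmeth_pcm`), and `files` (paths written).
#' @export
generate_cohort <- function(config, out_dir = NULL, emit_epireads = FALSE) {
  stopifnot(inherits(config, "cfmeth_config"))
  set.seed(config$seed)
  rt <- generate_regions_rng(config)
  regions <- rt$regions; truth <- rt$truth
  probs <- comet_prob_table(config)

  plan <- rbind(
    data.frame(cohort = "tissue",
               group = rep(c("Normal", "AA", "CRC"),
                           config$tissue_n[c("Normal", "AA", "CRC")]),
               stage = NA_character_, stringsAsFactors = FALSE),
    data.frame(cohort = "plasma",
               group = rep(c("Normal", "NAA", "AA"),
                           config$plasma_n[c("Normal", "NAA", "AA")]),
               stage = NA_character_, stringsAsFactors = FALSE),
    data.frame(cohort = "plasma", group = "CRC",
               stage = rep(c("I", "II", "III", "IV"),
                           config$plasma_crc_stage_n[c("I", "II", "III", "IV")]),
               stringsAsFactors = FALSE))
  # tissue CRC stages: plasma stage mix scaled to the tissue CRC count
  n_tis_crc <- sum(plan$cohort == "tissue" & plan$group == "CRC")
  prop <- config$plasma_crc_stage_n / sum(config$plasma_crc_stage_n)
  tis_stages <- rep(c("I", "II", "III", "IV"),
                    diff(round(cumsum(c(0, prop)) * n_tis_crc)))
  plan$stage[plan$cohort == "tissue" & plan$group == "CRC"] <- tis_stages
  plan$sample_id <- ifelse(plan$cohort == "tissue",
                           sprintf("T%04d", cumsum(plan$cohort == "tissue")),
                           sprintf("P%04d", cumsum(plan$cohort == "plasma")))

  n_samp <- nrow(plan)
  dims <- list(regions$region_id, plan$sample_id)
  n_elig <- matrix(0L, config$n_regions, n_samp, dimnames = dims)
  n_comet <- matrix(0L, config$n_regions, n_samp, dimnames = dims)
  tumor_fraction <- numeric(n_samp)
  epiread_rows <- if (emit_epireads) vector("list", n_samp) else NULL

  for (i in seq_len(n_samp)) {
    fr <- simulate_sample_fractions(truth, plan$cohort[i], plan$group[i],
                                    plan$stage[i], config)
    tumor_fraction[i] <- fr$tumor_fraction
    depth <- if (plan$cohort[i] == "tissue") config$depth_tissue
             else config$depth_plasma
    if (emit_epireads) {
      epiread_rows[[i]] <- simulate_epireads(fr$fractions, regions,
                                             plan$sample_id[i], depth, config)
    } else {
      cnt <- simulate_region_counts(fr$fractions, depth, config, probs)
      n_elig[, i] <- cnt$n_eligible
      n_comet[, i] <- cnt$n_comethylated
    }
  }

  demo <- vector("list", 0L)
  manifest <- plan
  manifest$age <- NA_real_; manifest$sex <- NA_character_
  for (co in c("tissue", "plasma")) {
    for (g in unique(manifest$group[manifest$cohort == co])) {
      sel <- manifest$cohort == co & manifest$group == g
      d <- sample_demographics(g, sum(sel), co)
      manifest$age[sel] <- d$age; manifest$sex[sel] <- d$sex
    }
  }
  manifest$qc_extraction <- "pass"
  manifest$qc_library <- "pass"
  manifest$qc_sequencing <- "pass"
  manifest$cea <- NA_real_; manifest$ca199 <- NA_real_
  manifest$cfdna_ng_per_ml <- NA_real_
  for (g in GROUP_LEVELS) {
    sel <- manifest$cohort == "plasma" & manifest$group == g
    if (!any(sel)) next
    manifest$cfdna_ng_per_ml[sel] <- simulate_cfdna_yield(g, sum(sel), config)
    sm <- simulate_serum_markers(g, sum(sel))
    manifest$cea[sel] <- sm$cea
    manifest$ca199[sel] <- sm$ca199
  }
  manifest <- manifest[, MANIFEST_COLUMNS]
  validate_manifest(manifest, "generated manifest")
  attr(manifest, "tumor_fraction") <-
    setNames(tumor_fraction, manifest$sample_id)

  split_pcm <- function(cohort) {
    ids <- manifest$sample_id[manifest$cohort == cohort]
    if (emit_epireads) {
      reads <- do.call(rbind, epiread_rows[match(ids, plan$sample_id)])
      build_pcm_matrix(reads, regions, ids, min_cpgs = config$min_cpgs,
                       window = config$window, min_meth = config$min_meth,
                       pseudocount = config$pseudocount)
    } else {
      e <- n_elig[, ids, drop = FALSE]; cm <- n_comet[, ids, drop = FALSE]
      pcm <- ifelse(e > 0L, cm / e, NA_real_)
      structure(list(pcm = pcm,
                     log2pcm = log2_transform(pcm, config$pseudocount),
                     n_eligible = e, n_comethylated = cm,
                     pseudocount = config$pseudocount),
                class = "cfmeth_pcm")
    }
  }
  tissue_pcm <- split_pcm("tissue")
  plasma_pcm <- split_pcm("plasma")

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(regions = file.path(out_dir, "regions.bed"),
               manifest = file.path(out_dir, "manifest.tsv"),
               tissue_pcm = file.path(out_dir, "tissue_pcm.tsv"),
               plasma_pcm = file.path(out_dir, "plasma_pcm.tsv"),
               truth = file.path(out_dir, "truth.json"))
    write_regions(regions, files[["regions"]])
    write_manifest(manifest, files[["manifest"]])
    write_pcm_matrix(tissue_pcm$pcm, files[["tissue_pcm"]])
    write_pcm_matrix(plasma_pcm$pcm, files[["plasma_pcm"]])
    jsonlite::write_json(list(marker_region_ids = truth$marker_region_ids,
                              aa_crc_region_ids = truth$aa_crc_region_ids,
                              table = truth$table),
                         files[["truth"]], digits = NA)
    if (emit_epireads) {
      for (co in c("tissue", "plasma")) {
        ids <- manifest$sample_id[manifest$cohort == co]
        reads <- do.call(rbind, epiread_rows[match(ids, plan$sample_id)])
        f <- file.path(out_dir, paste0(co, "_epireads.tsv"))
        write_epireads(reads, f)
        files[[paste0(co, "_epireads")]] <- f
      }
    }
  }
  list(regions = regions, truth = truth, manifest = manifest,
       tissue_pcm = tissue_pcm, plasma_pcm = plasma_pcm, files = files)
}

#' Plant QC failures into a manifest
#'
#' Marks randomly chosen samples (without replacement, at most one failing
#' stage per sample) as failing extraction, library or sequencing QC, for
#' exercising [qc_cascade()].
#'
#' @param manifest Manifest data frame.
#' @param extraction,library,sequencing Number of samples failing each
#'   stage.
#' @param seed RNG seed for the choice of samples.
#' @return The manifest with updated QC flags.
#' @export
plant_qc_failures <- function(manifest, extraction = 0L, library = 0L,
                              sequencing = 0L, seed = 1L) {
  total <- extraction + library + sequencing
  if (total > nrow(manifest)) stop("more failures than samples", call. = FALSE)
  set.seed(seed)
  idx <- sample(nrow(manifest), total)
  manifest$qc_extraction[idx[seq_len(extraction)]] <- "fail"
  manifest$qc_library[idx[extraction + seq_len(library)]] <- "fail"
  manifest$qc_sequencing[idx[extraction + library + seq_len(sequencing)]] <-
    "fail"
  manifest
}

#' Reference sample-flow manifests of the motivating study design
#'
#' Builds, deterministically and without RNG, manifests that reproduce the
#' published sample-flow bookkeeping of the two-cohort colorectal-cancer
#' methylation study this package's pipeline is designed around: 313 tissue
#' samples collected (139 Normal, 30 AA, 144 CRC) of which 2 fail DNA
#' extraction QC, 99 have insufficient library yield and 25 fail sequencing
#' QC, leaving 187 (91/26/70); and 577 plasma samples (169 Normal, 44 NAA,
#' 76 AA, 288 CRC) losing 26/40/22 at the three stages, leaving 489
#' (133/40/68/248, CRC stages 66/86/62/34). Surviving plasma samples carry
#' the published sex split per group. Ages are filled with deterministic
#' within-range sequences (the age *distribution* is not part of the
#' bookkeeping). Intended as input for [qc_cascade()] and [cohort_table()].
#'
#' @param cohort `"tissue"` or `"plasma"`.
#' @return A manifest data frame.
#' @export
study_flow_manifest <- function(cohort = c("tissue", "plasma")) {
  cohort <- match.arg(cohort)
  mk <- function(n, group, stage, sex, age, qc_e, qc_l, qc_s, prefix) {
    data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
               cohort = cohort, group = group, stage = stage, age = age,
               sex = sex, qc_extraction = qc_e, qc_library = qc_l,
               qc_sequencing = qc_s, cea = NA_real_, ca199 = NA_real_,
               cfdna_ng_per_ml = NA_real_, stringsAsFactors = FALSE)
  }
  ages <- function(n, lo, hi) round(seq(lo, hi, length.out = max(n, 2L)))[seq_len(n)]
  sexes <- function(n, n_male) rep(c("M", "F"), c(n_male, n - n_male))
  flags <- function(n, ext, lib, seqq) {
    # failures first, survivors after; one failing stage per sample
    e <- rep(c("fail", "pass"), c(ext, n - ext))
    l <- rep(c("pass", "fail", "pass"), c(ext, lib, n - ext - lib))
    s <- rep(c("pass", "fail", "pass"),
             c(ext + lib, seqq, n - ext - lib - seqq))
    list(e = e, l = l, s = s)
  }
  if (cohort == "tissue") {
    # per-group exclusions (extraction, library, sequencing)
    f_n <- flags(139L, 0L, 40L, 8L)
    f_a <- flags(30L, 0L, 3L, 1L)
    f_c <- flags(144L, 2L, 56L, 16L)
    out <- rbind(
      mk(139L, "Normal", NA_character_, sexes(139L, 81L), ages(139L, 24, 89),
         f_n$e, f_n$l, f_n$s, "TN"),
      mk(30L, "AA", NA_character_, sexes(30L, 18L), ages(30L, 23, 86),
         f_a$e, f_a$l, f_a$s, "TA"),
      mk(144L, "CRC", rep(c("I", "II", "III", "IV"), c(38L, 50L, 36L, 20L)),
         sexes(144L, 84L), ages(144L, 24, 89), f_c$e, f_c$l, f_c$s, "TC"))
  } else {
    # extraction failures per group follow the published post-extraction
    # counts (162/44/74/271); library/sequencing splits complete the
    # per-group totals.
    f_n <- flags(169L, 7L, 20L, 9L)
    f_na <- flags(44L, 0L, 3L, 1L)
    f_a <- flags(76L, 2L, 4L, 2L)
    f_c <- flags(288L, 17L, 13L, 10L)
    sex_excl_n <- sexes(36L, 20L)
    out <- rbind(
      mk(169L, "Normal", NA_character_, c(sex_excl_n, sexes(133L, 76L)),
         ages(169L, 18, 78), f_n$e, f_n$l, f_n$s, "PN"),
      mk(44L, "NAA", NA_character_, c(sexes(4L, 2L), sexes(40L, 25L)),
         ages(44L, 38, 86), f_na$e, f_na$l, f_na$s, "PE"),
      mk(76L, "AA", NA_character_, c(sexes(8L, 5L), sexes(68L, 43L)),
         ages(76L, 23, 86), f_a$e, f_a$l, f_a$s, "PA"),
      mk(288L, "CRC",
         c(rep(c("I", "II", "III", "IV"), each = 10L),
           rep(c("I", "II", "III", "IV"), c(66L, 86L, 62L, 34L))),
         c(sexes(40L, 23L), sexes(248L, 143L)),
         ages(288L, 24, 89), f_c$e, f_c$l, f_c$s, "PC"))
  }
  rownames(out) <- NULL
  validate_manifest(out, "study flow manifest")
  out
}
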