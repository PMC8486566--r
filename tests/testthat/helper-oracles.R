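# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's code paths.

# window rule by explicit enumeration of every window start
brute_force_comethylated <- function(calls, window = 5L, min_meth = 3L) {
  meth <- calls == "M"
  k <- length(meth)
  if (k < window) return(sum(meth) >= min_meth)
  for (s in 1:(k - window + 1L)) {
    if (sum(meth[s:(s + window - 1L)]) >= min_meth) return(TRUE)
  }
  FALSE
}

# AUC by double-loop pair counting
pair_count_auc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# maximum Youden J over all possible thresholds (J only changes at
# observed scores under the >= calling rule)
exhaustive_max_J <- function(scores, labels) {
  cand <- c(sort(unique(scores)), max(scores) + 1)
  max(vapply(cand, function(t) {
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
  }, numeric(1)))
}

# BH step-up written independently (sorted-index formulation)
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  q
}

# small, fast synthetic configuration used throughout the unit tests
small_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(list(
    n_regions = 60L, n_crc_markers = 12L, n_aa_crc_markers = 4L,
    tissue_n = c(Normal = 10L, AA = 6L, CRC = 8L),
    plasma_n = c(Normal = 16L, NAA = 4L, AA = 5L),
    plasma_crc_stage_n = c(I = 5L, II = 5L, III = 4L, IV = 4L),
    depth_tissue = 120, depth_plasma = 400, seed = seed), list(...))
  do.call(synthetic_config, args)
}

# epiread data frame built from parallel vectors of call strings
make_epireads <- function(calls, sample_id = "s1", region_id = "r1",
                          chrom = "chr1", start = 100L) {
  n <- length(calls)
  pos <- lapply(nchar(calls), function(k) start + seq_len(k) * 3L)
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   region_id = rep_len(region_id, n),
                   chrom = rep_len(chrom, n), stringsAsFactors = FALSE)
  df$positions <- pos
  df$calls <- calls
  df
}

random_call_string <- function(k, p_m = 0.5, p_n = 0) {
  paste(sample(c("M", "U", "N"), k, replace = TRUE,
               prob = c(p_m * (1 - p_n), (1 - p_m) * (1 - p_n), p_n)),
        collapse = "")
}
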