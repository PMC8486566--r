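# The PCM statistic. A read is "co-methylated" when some window of five
# consecutive CpG calls contains at least three methylated calls; PCM for a
# (region, sample) cell is the fraction of co-methylated reads among mapped
# reads with at least `min_cpgs` CpGs in the region.

#' Is a read co-methylated?
#'
#' Applies the sliding-window co-methylation rule to one read's ordered CpG
#' calls: the read is co-methylated when some window of `window` (default 5)
#' consecutive calls contains at least `min_meth` (default 3) methylated
#' (`M`) calls. `N` (no call) never counts as methylated. Reads with fewer
#' calls than the window length are judged on their single full-length
#' window when `short_read = "single_window"` (the default: a 3- or 4-CpG
#' read needs `min_meth` methylated CpGs overall), or never co-methylated
#' when `short_read = "exclude"`.
#'
#' @param calls Character vector of single calls (`"M"`, `"U"`, `"N"`) or a
#'   single string such as `"MUM"`. Must have length (or nchar) >= 3;
#'   eligibility filtering is the caller's responsibility.
#' @param window Window length in CpGs.
#' @param min_meth Minimum methylated calls within one window.
#' @param short_read Policy for reads shorter than `window`.
#' @return Logical scalar.
#' @examples
#' is_comethylated(c("M", "M", "M"))        # TRUE
#' is_comethylated("MUMUUMU")               # FALSE: no 5-window has 3 M
#' @export
is_comethylated <- function(calls, window = 5L, min_meth = 3L,
                            short_read = c("single_window", "exclude")) {
  short_read <- match.arg(short_read)
  if (length(calls) == 1L && nchar(calls) > 1L) {
    calls <- strsplit(calls, "", fixed = TRUE)[[1L]]
  }
  if (length(calls) < 3L) {
    stop("a read must carry at least 3 CpG calls", call. = FALSE)
  }
  if (any(!calls %in% c("M", "U", "N"))) {
    stop("calls must be over {M, U, N}", call. = FALSE)
  }
  meth <- as.integer(calls == "M")
  k <- length(meth)
  if (k < window) {
    if (short_read == "exclude") return(FALSE)
    return(sum(meth) >= min_meth)
  }
  cs <- cumsum(c(0L, meth))
  wins <- cs[(window + 1L):(k + 1L)] - cs[1L:(k - window + 1L)]
  any(wins >= min_meth)
}

# Vectorised co-methylation over call strings (used by region_pcm and the
# simulator's read path).
comet_from_strings <- function(calls, window = 5L, min_meth = 3L,
                               short_read = "single_window") {
  vapply(calls, function(s) {
    is_comethylated(s, window = window, min_meth = min_meth,
                    short_read = short_read)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Exact co-methylation probability of a random read
#'
#' Probability that a read of `k` CpGs, whose calls are independently
#' methylated with probability `p_m` each, satisfies the sliding-window
#' co-methylation rule. Computed by exhaustive enumeration of the 2^k call
#' configurations, so it serves as a closed-form reference for
#' simulation-based checks.
#'
#' @param k Number of CpG calls on the read (3 to ~16; enumeration is 2^k).
#' @param p_m Per-CpG methylation probability.
#' @inheritParams is_comethylated
#' @return Numeric scalar in `[0, 1]`.
#' @export
comethylation_prob <- function(k, p_m, window = 5L, min_meth = 3L,
                               short_read = "single_window") {
  stopifnot(k >= 3L, k <= 20L, p_m >= 0, p_m <= 1)
  configs <- as.matrix(expand.grid(rep(list(0:1), k)))
  if (k < window) {
    hit <- rowSums(configs) >= min_meth
    if (short_read == "exclude") hit <- rep(FALSE, nrow(configs))
  } else {
    hit <- apply(configs, 1L, function(v) {
      cs <- cumsum(c(0L, v))
      any(cs[(window + 1L):(k + 1L)] - cs[1L:(k - window + 1L)] >= min_meth)
    })
  }
  m <- rowSums(configs)
  sum(ifelse(hit, 1, 0) * p_m^m * (1 - p_m)^(k - m))
}

#' Log2 transform of PCM values
#'
#' `log2(pcm + pseudocount)`; the pseudocount keeps zero PCM finite.
#' Missing values propagate.
#'
#' @param pcm Numeric vector/matrix of PCM values in `[0, 1]` (or `NA`).
#' @param pseudocount Small positive constant, default `1e-3`.
#' @return Transformed values, same shape as `pcm`.
#' @export
log2_transform <- function(pcm, pseudocount = 1e-3) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("pseudocount must be a positive number", call. = FALSE)
  }
  ok <- pcm[!is.na(pcm)]
  if (any(ok < 0 | ok > 1)) stop("pcm must lie in [0, 1]", call. = FALSE)
  log2(pcm + pseudocount)
}

#' PCM for one (sample, region) cell
#'
#' Restricts each read's calls to the CpGs inside `[start, end)` of the
#' region, drops reads with fewer than `min_cpgs` in-region CpGs or fewer
#' than `min_cpgs` non-N calls, and computes the fraction of the remaining
#' (eligible) reads that are co-methylated.
#'
#' @param epireads Epiread data frame (see [read_epireads()]) for a single
#'   sample and region.
#' @param region One-row region data frame (`chrom`, `start`, `end`,
#'   `region_id`); `NULL` skips position restriction.
#' @param min_cpgs Minimum in-region CpG calls for a read to enter the
#'   denominator.
#' @inheritParams is_comethylated
#' @return A list with `region_id`, `sample_id`, `n_eligible`,
#'   `n_comethylated` and `pcm` (`NA` when no read is eligible).
#' @export
region_pcm <- function(epireads, region = NULL, min_cpgs = 3L, window = 5L,
                       min_meth = 3L, short_read = "single_window") {
  if (nrow(epireads) == 0L) {
    return(list(region_id = NA_character_, sample_id = NA_character_,
                n_eligible = 0L, n_comethylated = 0L, pcm = NA_real_))
  }
  if (length(unique(epireads$sample_id)) > 1L ||
      length(unique(epireads$region_id)) > 1L) {
    stop("region_pcm expects reads from a single (sample, region)",
         call. = FALSE)
  }
  calls <- strsplit(epireads$calls, "", fixed = TRUE)
  if (!is.null(region)) {
    stopifnot(nrow(region) == 1L)
    calls <- mapply(function(pos, cl) {
      cl[pos >= region$start & pos < region$end]
    }, epireads$positions, calls, SIMPLIFY = FALSE)
  }
  n_call <- vapply(calls, function(cl) sum(cl != "N"), integer(1L))
  eligible <- lengths(calls) >= min_cpgs & n_call >= min_cpgs
  n_eligible <- sum(eligible)
  if (n_eligible == 0L) {
    n_comet <- 0L
    pcm <- NA_real_
  } else {
    n_comet <- sum(vapply(calls[eligible], function(cl) {
      is_comethylated(cl, window = window, min_meth = min_meth,
                      short_read = short_read)
    }, logical(1L)))
    pcm <- n_comet / n_eligible
  }
  list(region_id = epireads$region_id[1L],
       sample_id = epireads$sample_id[1L],
       n_eligible = n_eligible, n_comethylated = n_comet, pcm = pcm)
}

#' Build a PCM matrix from an epiread stream
#'
#' Aggregates epireads into a regions x samples PCM matrix. Cells with no
#' eligible reads are `NA`. The result is independent of the input read
#' order.
#'
#' @param epireads Epiread data frame covering any number of samples and
#'   regions.
#' @param regions Region data frame (defines row order and in-region CpG
#'   restriction).
#' @param samples Character vector of sample ids (defines column order).
#' @inheritParams region_pcm
#' @param pseudocount Pseudocount for the log2 companion matrix.
#' @return A list of class `cfmeth_pcm` with matrices `pcm`, `log2pcm`,
#'   `n_eligible`, `n_comethylated` (regions x samples) and the
#'   `pseudocount` used.
#' @export
build_pcm_matrix <- function(epireads, regions, samples, min_cpgs = 3L,
                             window = 5L, min_meth = 3L,
                             short_read = "single_window",
                             pseudocount = 1e-3) {
  region_ids <- regions$region_id
  unknown <- setdiff(unique(epireads$region_id), region_ids)
  if (length(unknown)) {
    stop("epireads reference unknown region_id: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(epireads$sample_id), samples)
  if (length(unknown)) {
    stop("epireads reference unknown sample_id: ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  dims <- list(region_ids, samples)
  pcm <- matrix(NA_real_, length(region_ids), length(samples), dimnames = dims)
  n_elig <- matrix(0L, length(region_ids), length(samples), dimnames = dims)
  n_comet <- matrix(0L, length(region_ids), length(samples), dimnames = dims)
  if (nrow(epireads) > 0L) {
    key <- paste(epireads$sample_id, epireads$region_id, sep = "\r")
    for (cell in split(seq_len(nrow(epireads)), key)) {
      sub <- epireads[cell, , drop = FALSE]
      reg <- regions[regions$region_id == sub$region_id[1L], , drop = FALSE]
      res <- region_pcm(sub, reg, min_cpgs = min_cpgs, window = window,
                        min_meth = min_meth, short_read = short_read)
      pcm[res$region_id, res$sample_id] <- res$pcm
      n_elig[res$region_id, res$sample_id] <- res$n_eligible
      n_comet[res$region_id, res$sample_id] <- res$n_comethylated
    }
  }
  structure(list(pcm = pcm, log2pcm = log2_transform(pcm, pseudocount),
                 n_eligible = n_elig, n_comethylated = n_comet,
                 pseudocount = pseudocount),
            class = "cfmeth_pcm")
}

#' @export
print.cfmeth_pcm <- function(x, ...) {
  cat(sprintf("PCM matrix: %d regions x %d samples (%.1f%% cells missing)\n",
              nrow(x$pcm), ncol(x$pcm), 100 * mean(is.na(x$pcm))))
  invisible(x)
}
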