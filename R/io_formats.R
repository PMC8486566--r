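# File formats: BED4 regions, epiread TSV, sample manifest TSV, PCM matrix
# TSV. All coordinates are 0-based half-open (BED convention); epiread CpG
# positions are 0-based positions of the CpG cytosine. Parsers are strict:
# every invalid line raises an error naming the line number.

MANIFEST_COLUMNS <- c(
  "sample_id", "cohort", "group", "stage", "age", "sex",
  "qc_extraction", "qc_library", "qc_sequencing",
  "cea", "ca199", "cfdna_ng_per_ml"
)

GROUP_LEVELS <- c("Normal", "NAA", "AA", "CRC")
STAGE_LEVELS <- c("I", "II", "III", "IV")

format_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Read a BED4 region file
#'
#' Reads tab-separated BED with at least four columns (chrom, start, end,
#' name). Coordinates are interpreted 0-based half-open; column 4 is the
#' region identifier and must be unique. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom`, `start`, `end`, `region_id`,
#'   in file order.
#' @seealso [write_regions()]
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    format_error(path, idx[which(nf < 4L)[1L]],
                 "expected at least 4 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  region_id <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) format_error(path, idx[bad[1L]], "non-integer coordinate")
  bad <- which(start < 0L)
  if (length(bad)) format_error(path, idx[bad[1L]], "negative start")
  bad <- which(end <= start)
  if (length(bad)) format_error(path, idx[bad[1L]], "end must exceed start")
  dup <- which(duplicated(region_id))
  if (length(dup)) {
    format_error(path, idx[dup[1L]],
                 sprintf("duplicate region_id '%s'", region_id[dup[1L]]))
  }
  data.frame(chrom = chrom, start = start, end = end,
             region_id = region_id, stringsAsFactors = FALSE)
}

#' Write regions as BED4
#'
#' @param regions Data frame with `chrom`, `start`, `end`, `region_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end", "region_id") %in% names(regions)))
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region_id in region set", call. = FALSE)
  }
  if (any(regions$end <= regions$start)) {
    stop("end must exceed start for every region", call. = FALSE)
  }
  write.table(regions[, c("chrom", "start", "end", "region_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an epiread TSV
#'
#' The epiread dialect is one read per line with five tab-separated fields:
#' `sample_id`, `region_id`, `chrom`, comma-separated CpG positions
#' (0-based, strictly increasing), and a call string over `M` (methylated),
#' `U` (unmethylated), `N` (no call) of the same length as the position
#' list.
#'
#' @param path Path to an epiread TSV (no header).
#' @return A data frame with columns `sample_id`, `region_id`, `chrom`,
#'   `positions` (list column of integer vectors) and `calls` (character,
#'   one string per read). An empty file yields a zero-row frame.
#' @seealso [write_epireads()]
#' @export
read_epireads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  empty <- data.frame(sample_id = character(), region_id = character(),
                      chrom = character(), stringsAsFactors = FALSE)
  empty$positions <- list()
  empty$calls <- character()
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    format_error(path, idx[which(nf != 5L)[1L]], "expected 5 fields")
  }
  calls <- vapply(fields, `[[`, "", 5L)
  bad <- which(grepl("[^MUN]", calls) | nchar(calls) == 0L)
  if (length(bad)) {
    format_error(path, idx[bad[1L]], "call string must be over {M,U,N}")
  }
  positions <- lapply(fields, function(f) {
    suppressWarnings(as.integer(strsplit(f[[4L]], ",", fixed = TRUE)[[1L]]))
  })
  bad <- which(vapply(positions, anyNA, logical(1L)))
  if (length(bad)) format_error(path, idx[bad[1L]], "non-integer CpG position")
  bad <- which(lengths(positions) != nchar(calls))
  if (length(bad)) {
    format_error(path, idx[bad[1L]],
                 "number of positions does not match call string length")
  }
  bad <- which(!vapply(positions, function(p) {
    length(p) < 2L || all(diff(p) > 0L)
  }, logical(1L)))
  if (length(bad)) {
    format_error(path, idx[bad[1L]], "CpG positions must be strictly increasing")
  }
  out <- data.frame(sample_id = vapply(fields, `[[`, "", 1L),
                    region_id = vapply(fields, `[[`, "", 2L),
                    chrom = vapply(fields, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  out$positions <- positions
  out$calls <- calls
  out
}

#' Write epireads to TSV
#'
#' @param epireads Data frame as returned by [read_epireads()].
#' @param path Output path.
#' @param append Append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_epireads <- function(epireads, path, append = FALSE) {
  pos <- vapply(epireads$positions, paste, "", collapse = ",")
  lines <- paste(epireads$sample_id, epireads$region_id, epireads$chrom,
                 pos, epireads$calls, sep = "\t")
  if (append) {
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

validate_manifest <- function(manifest, context = "manifest") {
  required <- setdiff(MANIFEST_COLUMNS, c("cea", "ca199", "cfdna_ng_per_ml"))
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop(context, ": missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop(context, ": duplicate sample_id", call. = FALSE)
  }
  bad <- !manifest$cohort %in% c("tissue", "plasma")
  if (any(bad)) {
    stop(context, ": unknown cohort label '",
         manifest$cohort[which(bad)[1L]], "'", call. = FALSE)
  }
  bad <- !manifest$group %in% GROUP_LEVELS
  if (any(bad)) {
    stop(context, ": unknown group label '",
         manifest$group[which(bad)[1L]], "'", call. = FALSE)
  }
  bad <- manifest$cohort == "tissue" & manifest$group == "NAA"
  if (any(bad)) {
    stop(context, ": tissue cohort admits groups Normal/AA/CRC only",
         call. = FALSE)
  }
  crc <- manifest$group == "CRC"
  if (any(crc & is.na(manifest$stage))) {
    stop(context, ": CRC samples must carry a TNM stage", call. = FALSE)
  }
  if (any(!crc & !is.na(manifest$stage))) {
    stop(context, ": stage must be NA for non-CRC samples", call. = FALSE)
  }
  if (any(!is.na(manifest$stage) & !manifest$stage %in% STAGE_LEVELS)) {
    stop(context, ": stage must be one of I/II/III/IV", call. = FALSE)
  }
  if (any(is.na(manifest$age)) || any(manifest$age <= 0)) {
    stop(context, ": age must be a positive number for every sample",
         call. = FALSE)
  }
  if (any(!manifest$sex %in% c("M", "F"))) {
    stop(context, ": sex must be M or F", call. = FALSE)
  }
  for (qc in c("qc_extraction", "qc_library", "qc_sequencing")) {
    if (any(!manifest[[qc]] %in% c("pass", "fail"))) {
      stop(context, ": ", qc, " must be pass or fail", call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Read a sample manifest TSV
#'
#' One row per sample with columns `sample_id`, `cohort` (tissue/plasma),
#' `group` (Normal/NAA/AA/CRC), `stage` (I-IV, NA unless CRC), `age`,
#' `sex` (M/F), QC flags `qc_extraction`, `qc_library`, `qc_sequencing`
#' (pass/fail), and optional numeric columns `cea` (ng/mL), `ca199`
#' (U/mL), `cfdna_ng_per_ml`. Missing optional values are encoded `NA`
#' and stay missing; they are never imputed on read.
#'
#' @param path Path to a tab-separated manifest with a header row.
#' @return A validated data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = "NA", colClasses = "character")
  for (col in c("age", "cea", "ca199", "cfdna_ng_per_ml")) {
    if (col %in% names(m)) m[[col]] <- as.numeric(m[[col]])
  }
  for (col in setdiff(c("cea", "ca199", "cfdna_ng_per_ml"), names(m))) {
    m[[col]] <- NA_real_
  }
  validate_manifest(m, context = path)
  m
}

#' Write a sample manifest TSV
#'
#' @param manifest Manifest data frame (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  cols <- intersect(MANIFEST_COLUMNS, names(manifest))
  write.table(manifest[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read / write a PCM matrix TSV
#'
#' The on-disk layout is one row per region: first column `region_id`,
#' remaining columns one per sample (header row of sample ids). Missing
#' cells (regions with no eligible reads in a sample) are the literal
#' `NA`. Values are written at 6 decimal places, so a write/read round
#' trip reproduces the matrix to 1e-6.
#'
#' @param mat Numeric matrix, regions in rows (rownames are region ids),
#'   samples in columns; values in `[0, 1]` or `NA`.
#' @param path File path.
#' @return `read_pcm_matrix()` returns the numeric matrix;
#'   `write_pcm_matrix()` returns `path` invisibly.
#' @export
write_pcm_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  vals <- mat[!is.na(mat)]
  if (any(vals < 0 | vals > 1)) {
    stop("PCM values must lie in [0, 1]", call. = FALSE)
  }
  df <- data.frame(region_id = rownames(mat),
                   formatC(mat, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(mat)] <- "NA"
  names(df) <- c("region_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_pcm_matrix
#' @export
read_pcm_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1L] != "region_id") {
    stop(path, ": first column must be region_id", call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$region_id
  mat
}
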