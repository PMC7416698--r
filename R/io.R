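# Plain-text interchange formats: B-scans as TSV matrices, cohorts as CSV.

#' Write a B-scan as TSV
#'
#' Layout: a comment line recording the alignment flag, then a header row
#' whose first cell is `depth_um` followed by the lateral positions (deg),
#' then one row per depth (um above BrM, increasing toward the vitreous)
#' with the reflectivity values. If the scan carries ground-truth boundary
#' depths a sidecar `<path>.truth.tsv` is written alongside.
#'
#' @param scan a `bscan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(scan, path) {
  .check_bscan(scan)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fovecast bscan aligned=%s",
                     if (isTRUE(scan$aligned)) "TRUE" else "FALSE"), con)
  writeLines(paste(c("depth_um", format(scan$lateral_deg, digits = 6)),
                   collapse = "\t"), con)
  body <- cbind(scan$depth_um, scan$reflectivity)
  utils::write.table(format(body, digits = 6), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  truth <- attr(scan, "truth")
  if (!is.null(truth)) {
    tdf <- data.frame(lateral_deg = scan$lateral_deg, truth,
                      check.names = FALSE)
    utils::write.table(format(tdf, digits = 6), paste0(path, ".truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a B-scan from TSV
#'
#' Axes reversed on disk are normalised to the canonical orientation (depth
#' and lateral position strictly increasing) with a warning. A sidecar
#' `<path>.truth.tsv`, if present, is restored as the `truth` attribute.
#'
#' @param path TSV file written by [write_bscan()].
#' @return a `bscan`.
#' @export
read_bscan <- function(path) {
  lines <- readLines(path, n = 2)
  aligned <- FALSE
  skip <- 0
  if (startsWith(lines[1], "#")) {
    aligned <- grepl("aligned=TRUE", lines[1], fixed = TRUE)
    skip <- 1
  }
  header <- strsplit(lines[skip + 1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "depth_um")
    stopf("malformed header in %s line %d: expected first cell 'depth_um', got '%s'",
          path, skip + 1, header[1])
  lateral <- as.numeric(header[-1])
  if (anyNA(lateral)) stopf("non-numeric lateral positions in %s", path)
  body <- utils::read.table(path, sep = "\t", skip = skip + 1,
                            header = FALSE)
  if (ncol(body) != length(lateral) + 1)
    stopf("missing depth column or ragged row in %s", path)
  depth <- body[[1]]
  refl <- as.matrix(body[-1])
  dimnames(refl) <- NULL

  if (is.unsorted(depth, strictly = TRUE)) {
    if (is.unsorted(rev(depth), strictly = TRUE))
      stopf("non-monotone depth axis in %s", path)
    warning("depth axis reversed on disk; normalising orientation")
    depth <- rev(depth)
    refl <- refl[rev(seq_len(nrow(refl))), , drop = FALSE]
  }
  if (is.unsorted(lateral, strictly = TRUE)) {
    if (is.unsorted(rev(lateral), strictly = TRUE))
      stopf("non-monotone lateral axis in %s", path)
    warning("lateral axis reversed on disk; normalising orientation")
    lateral <- rev(lateral)
    refl <- refl[, rev(seq_len(ncol(refl))), drop = FALSE]
  }

  truth <- NULL
  tp <- paste0(path, ".truth.tsv")
  if (file.exists(tp)) {
    tdf <- utils::read.table(tp, sep = "\t", header = TRUE)
    truth <- as.matrix(tdf[-1])
  }
  structure(list(reflectivity = refl, depth_um = depth,
                 lateral_deg = lateral, aligned = aligned,
                 foveola = NA_real_),
            class = "bscan", truth = truth)
}

#' Write a cohort table as CSV
#'
#' Non-detectable foveal sensitivity is encoded as the literal string `ND`
#' in the `fs_db` column; ground-truth columns keep their `gt_` prefix.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  out$fs_db <- ifelse(is.na(out$fs_db), "ND", format(out$fs_db, digits = 8))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV written by [write_cohort()].
#' @return a `cohort_table` (`fs_db` is numeric with `NA` = non-detectable).
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "fs_db", "va_decimal")
  if (!all(need %in% names(df)))
    stopf("cohort CSV must have header columns %s", paste(need, collapse = ","))
  df$fs_db <- suppressWarnings(
    ifelse(df$fs_db == "ND", NA_real_, as.numeric(df$fs_db)))
  if (any(df$va_decimal <= 0)) stopf("va_decimal must be > 0")
  structure(df, class = c("cohort_table", "data.frame"))
}
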