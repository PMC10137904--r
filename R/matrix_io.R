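# Abundance-matrix I/O and pre-correction filters.
#
# The on-disk convention is the plain omics TSV: first header field
# "feature_id" followed by sample IDs, first column feature IDs, missing
# values written as "NA" and read from empty cells, "NA" or "NaN".

#' Read a feature-by-sample abundance matrix
#'
#' Parses a TSV (default) or CSV abundance table into a numeric matrix with
#' feature rownames and sample colnames.  Cells that are empty, `"NA"`,
#' `"NaN"` or otherwise non-numeric become `NA`.  Duplicate feature or
#' sample IDs and ragged rows are errors (the latter reported with their
#' line number).
#'
#' @param path Path to the file.  The separator is inferred from the
#'   extension (`.csv` implies comma) unless `sep` is given.
#' @param sep Field separator, `"\t"` or `","`.
#' @return Numeric matrix, features in rows, samples in columns, `NA` for
#'   missing values.
#' @seealso [write_abundance()], [sanitize_nonpositive()]
#' @export
read_abundance <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  # drop trailing blank lines only; an interior blank line is a ragged row
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) < 2L) stop("abundance file needs a header and at least one feature row",
                               call. = FALSE)
  split_row <- function(x) {
    parts <- strsplit(x, sep, fixed = TRUE)[[1L]]
    # strsplit drops a single trailing empty field
    if (endsWith(x, sep)) parts <- c(parts, "")
    parts
  }
  fields <- lapply(lines, split_row)
  header <- fields[[1L]]
  p <- length(header)
  lens <- vapply(fields[-1L], length, integer(1))
  bad <- which(lens != p)
  if (length(bad)) {
    stop("ragged row at line ", bad[1L] + 1L, ": expected ", p, " fields, found ",
         lens[bad[1L]], call. = FALSE)
  }
  sample_ids <- trimws(header[-1L])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "), call. = FALSE)
  }
  feature_ids <- vapply(fields[-1L], function(f) trimws(f[1L]), character(1))
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "), call. = FALSE)
  }
  parse_cell <- function(tok) {
    tok <- trimws(tok)
    if (tok == "" || toupper(tok) %in% c("NA", "NAN")) return(NA_real_)
    suppressWarnings(as.numeric(tok))
  }
  values <- t(vapply(fields[-1L],
                     function(f) vapply(f[-1L], parse_cell, numeric(1)),
                     numeric(p - 1L)))
  if (p == 2L) values <- matrix(values, ncol = 1L)  # vapply drops dims for 1 sample
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Write an abundance matrix
#'
#' Inverse of [read_abundance()]: missing values are written as `"NA"`,
#' numbers with full double precision so a read/write round trip is
#' lossless to at least 12 significant digits.
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(m, path, sep = "\t") {
  assert_abundance(m)
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Requires columns `sample_id` and `batch`; an optional `is_gis` column is
#' parsed from `true/false/1/0` (absent means all `FALSE`).  Any further
#' columns are carried along as traits (diagnosis, sex, age, ...).
#'
#' @param path TSV or CSV file.
#' @param sep Separator; inferred from the extension when `NULL`.
#' @return A data.frame with at least `sample_id`, `batch`, `is_gis`.
#' @export
read_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"", comment.char = "")
  need <- setdiff(c("sample_id", "batch"), names(ann))
  if (length(need)) stop("annotation is missing column(s): ", paste(need, collapse = ", "),
                         call. = FALSE)
  if (is.null(ann$is_gis)) ann$is_gis <- FALSE
  ann$is_gis <- parse_logical(ann$is_gis)
  ann$sample_id <- as.character(ann$sample_id)
  ann$batch <- as.character(ann$batch)
  ann
}

#' Convert non-positive values to missing
#'
#' The polish works on log2 ratios, so zero and negative entries cannot
#' participate; they are converted to `NA` rather than raising an error
#' because real instrument exports routinely contain zeros.
#'
#' @param m Abundance matrix.
#' @return A list with `matrix` (sanitized) and `n_converted`.  A warning
#'   is emitted when any value was converted.
#' @export
sanitize_nonpositive <- function(m) {
  assert_abundance(m)
  bad <- !is.na(m) & m <= 0
  n <- sum(bad)
  if (n > 0L) {
    m[bad] <- NA_real_
    warning(n, " non-positive value(s) converted to missing", call. = FALSE)
  }
  list(matrix = m, n_converted = n)
}

#' Remove features with too much missing data
#'
#' A feature is removed when its missing fraction is greater than or equal
#' to `max_missing_frac` (default 0.5, i.e. removal at exactly 50%).
#' Surviving row order is preserved.
#'
#' @param m Abundance matrix.
#' @param max_missing_frac Removal threshold in (0, 1]; removal is `>=`.
#' @return A list with `matrix` (filtered) and `report` (a
#'   `tampor_filter_report`: removed IDs, per-feature missing fraction,
#'   threshold).
#' @export
filter_rows_by_missingness <- function(m, max_missing_frac = 0.5) {
  assert_abundance(m)
  if (!is.numeric(max_missing_frac) || max_missing_frac <= 0 || max_missing_frac > 1) {
    stop("`max_missing_frac` must be in (0, 1]", call. = FALSE)
  }
  frac <- rowMeans(is.na(m))
  keep <- frac < max_missing_frac
  if (!any(keep)) {
    stop("all features removed at missingness threshold ", max_missing_frac,
         "; review the threshold or the input", call. = FALSE)
  }
  report <- structure(list(removed_feature_ids = rownames(m)[!keep],
                           missing_fraction = stats::setNames(frac, rownames(m)),
                           threshold = max_missing_frac,
                           rule = ">="),
                      class = "tampor_filter_report")
  list(matrix = m[keep, , drop = FALSE], report = report)
}

#' Censor low-signal values and drop noise-dominated features
#'
#' Intended for count-type (transcriptomic) input whose log2 distribution
#' has a noise-dominated left tail: values less than or equal to
#' `noise_threshold` become missing, then features whose combined
#' noise-plus-missing fraction exceeds `max_noise_frac` (strictly) are
#' removed.
#'
#' @param m Abundance matrix.
#' @param noise_threshold Values `<=` this are treated as noise (>= 0).
#' @param max_noise_frac Feature removed when noise+missing fraction `>`
#'   this (default 0.5).
#' @return A list with `matrix` and `report`, as
#'   [filter_rows_by_missingness()].
#' @export
censor_low_signal <- function(m, noise_threshold, max_noise_frac = 0.5) {
  assert_abundance(m)
  if (noise_threshold < 0) stop("`noise_threshold` must be >= 0", call. = FALSE)
  m[!is.na(m) & m <= noise_threshold] <- NA_real_
  frac <- rowMeans(is.na(m))
  keep <- frac <= max_noise_frac
  if (!any(keep)) {
    stop("all features removed by censoring at noise threshold ", noise_threshold,
         "; review the thresholds", call. = FALSE)
  }
  report <- structure(list(removed_feature_ids = rownames(m)[!keep],
                           missing_fraction = stats::setNames(frac, rownames(m)),
                           threshold = max_noise_frac,
                           noise_threshold = noise_threshold,
                           rule = ">"),
                      class = "tampor_filter_report")
  list(matrix = m[keep, , drop = FALSE], report = report)
}

#' @export
print.tampor_filter_report <- function(x, ...) {
  cat("feature filter: removed", length(x$removed_feature_ids), "of",
      length(x$missing_fraction), "features (fraction", x$rule, x$threshold, ")\n")
  invisible(x)
}

#' Transpose a multi-platform matrix into a correction problem
#'
#' For harmonizing measurements of the same samples across platforms
#' (e.g. mass spectrometry, proximity extension, aptamer panels): the
#' feature-by-sample matrix is transposed so original samples become rows
#' and assays become columns; each assay column is annotated with its
#' platform as the batch, and assays of features measured on every
#' platform become the bridging (GIS) set.  Requires complete data and at
#' least two platforms.
#'
#' @param m Abundance matrix whose rows are assays (unique IDs; use
#'   `feature@platform` when a feature is assayed on several platforms).
#' @param platform Character vector of platform labels aligned to the rows
#'   of `m`, or a data.frame with columns `feature_id`, `platform` keyed by
#'   rowname.
#' @param common_features Base feature IDs shared by all platforms (the
#'   bridging set).
#' @param feature Optional base feature ID per row; defaults to the rowname
#'   with any `@platform` suffix stripped.
#' @return A list with `matrix` (transposed: original samples x assays,
#'   columns named `feature@platform`) and `annotation` (assay-level:
#'   `sample_id`, `batch` = platform, `is_gis`, `feature`).
#' @export
transpose_for_multiplatform <- function(m, platform, common_features, feature = NULL) {
  assert_abundance(m)
  if (anyNA(m)) {
    stop("multi-platform transposition requires complete data; impute or drop ",
         sum(is.na(m)), " missing value(s) first", call. = FALSE)
  }
  if (is.data.frame(platform)) {
    if (!all(c("feature_id", "platform") %in% names(platform))) {
      stop("platform map needs columns feature_id and platform", call. = FALSE)
    }
    idx <- match(rownames(m), platform$feature_id)
    if (anyNA(idx)) {
      stop("rows without a platform label: ",
           paste(utils::head(rownames(m)[is.na(idx)], 5), collapse = ", "), call. = FALSE)
    }
    platform <- as.character(platform$platform[idx])
  }
  platform <- as.character(platform)
  if (length(platform) != nrow(m)) {
    stop("`platform` must have one label per matrix row", call. = FALSE)
  }
  platforms <- unique(platform)
  if (length(platforms) < 2L) {
    stop("at least 2 platforms are required for harmonization; got ",
         length(platforms), call. = FALSE)
  }
  if (is.null(feature)) feature <- sub("@[^@]*$", "", rownames(m))
  feature <- as.character(feature)
  for (cf in common_features) {
    counts <- table(factor(platform[feature == cf], levels = platforms))
    if (any(counts == 0L)) {
      stop("common feature '", cf, "' is missing from platform(s): ",
           paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
    }
    if (any(counts > 1L)) {
      stop("common feature '", cf, "' occurs more than once on platform(s): ",
           paste(names(counts)[counts > 1L], collapse = ", "), call. = FALSE)
    }
  }
  assay_id <- paste0(feature, "@", platform)
  if (anyDuplicated(assay_id)) {
    stop("duplicate assay IDs after feature@platform naming: ",
         paste(utils::head(unique(assay_id[duplicated(assay_id)]), 5), collapse = ", "),
         call. = FALSE)
  }
  tm <- t(m)
  colnames(tm) <- assay_id
  annotation <- data.frame(sample_id = assay_id,
                           batch = platform,
                           is_gis = feature %in% common_features,
                           feature = feature,
                           stringsAsFactors = FALSE)
  list(matrix = tm, annotation = annotation)
}
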