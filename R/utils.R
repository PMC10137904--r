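# Internal helpers shared across modules.

# Median over present values; NA when nothing is present.
med <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

# Row-wise medians over a column subset, NA-aware.  The 1- and 2-column
# cases are closed-form (identity / midpoint), which matters because GIS
# denominator sets are typically 1-2 channels per batch.
row_medians <- function(m, cols = seq_len(ncol(m))) {
  sub <- m[, cols, drop = FALSE]
  if (ncol(sub) == 1L) return(sub[, 1L])
  if (ncol(sub) == 2L) {
    a <- sub[, 1L]; b <- sub[, 2L]
    out <- rowMeans(sub, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    return(out)
  }
  apply(sub, 1L, med)
}

col_medians <- function(m) apply(m, 2L, med)

# Frobenius norm over present entries only.
frobenius_norm <- function(m) {
  sqrt(sum(m[!is.na(m)]^2))
}

is_abundance_like <- function(m) {
  is.matrix(m) && is.numeric(m) && !is.null(rownames(m)) && !is.null(colnames(m))
}

assert_abundance <- function(m, arg = "matrix") {
  if (!is_abundance_like(m)) {
    stop("`", arg, "` must be a numeric matrix with feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  invisible(m)
}

# Align an annotation table to the matrix columns; every sample must have
# exactly one annotation row.
align_annotation <- function(m, annotation) {
  if (!is.data.frame(annotation) || !all(c("sample_id", "batch") %in% names(annotation))) {
    stop("`annotation` must be a data.frame with columns sample_id and batch", call. = FALSE)
  }
  if (anyDuplicated(annotation$sample_id)) {
    stop("duplicate sample_id in annotation: ",
         paste(unique(annotation$sample_id[duplicated(annotation$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(colnames(m), annotation$sample_id)
  if (length(missing)) {
    stop("samples without annotation: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  if (is.null(ann$is_gis)) ann$is_gis <- FALSE
  ann$is_gis <- parse_logical(ann$is_gis)
  ann$batch <- as.character(ann$batch)
  ann
}

parse_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes")
  out
}
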