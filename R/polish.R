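# The iterative median polish of ratios: per-row ratio computation in three
# tunable denominator modes, column median centering of log2 ratios, row
# scale restoration, iterated to Frobenius-norm convergence.

MODE_LEVELS <- c("noGIS", "gis_only", "gis_plus_nonGIS")

# Accept both internal names and the user-facing flag spellings.
normalize_mode <- function(mode) {
  key <- tolower(gsub("[^a-z]", "", tolower(mode)))
  out <- switch(key,
                "nogis" = "noGIS",
                "gis" = "gis_only",
                "gisonly" = "gis_only",
                "useallnongis" = "gis_plus_nonGIS",
                "gisplusnongis" = "gis_plus_nonGIS",
                NULL)
  if (is.null(out)) {
    stop("unknown mode '", mode, "'; use one of noGIS, GIS (gis_only), ",
         "useAllNonGIS (gis_plus_nonGIS)", call. = FALSE)
  }
  out
}

#' Configuration for the median polish of ratios
#'
#' @param mode Denominator tuning: `"noGIS"` (medians of all samples per
#'   batch; requires trait-balanced batches), `"gis_only"` (alias `"GIS"`;
#'   intra-batch GIS medians in both ratio terms, the least aggressive
#'   variant) or `"gis_plus_nonGIS"` (alias `"useAllNonGIS"`; GIS medians
#'   as first-term denominators plus a non-GIS/GIS batch factor that
#'   corrects defective GIS channels).
#' @param tolerance Convergence tolerance on the inter-iteration Frobenius
#'   statistic (default `1e-8`).
#' @param max_iterations Iteration cap (default 250).
#' @param convergence `"norm_diff"` (default): absolute difference of
#'   successive Frobenius norms of the working log2 matrix, taken over
#'   present entries.  `"matrix_diff"`: the stricter Frobenius norm of the
#'   element-wise difference between successive log2 matrices.
#' @return A `tampor_config` list.
#' @export
tampor_config <- function(mode = c("gis_plus_nonGIS", "useAllNonGIS", "GIS",
                                   "gis_only", "noGIS"),
                          tolerance = 1e-8,
                          max_iterations = 250L,
                          convergence = c("norm_diff", "matrix_diff")) {
  mode <- normalize_mode(if (length(mode) > 1L) mode[1L] else mode)
  convergence <- match.arg(convergence)
  if (!is.numeric(tolerance) || tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("`max_iterations` must be >= 1", call. = FALSE)
  }
  structure(list(mode = mode, tolerance = tolerance,
                 max_iterations = max_iterations, convergence = convergence),
            class = "tampor_config")
}

#' @export
print.tampor_config <- function(x, ...) {
  cat("tampor config: mode =", x$mode, "| tolerance =", format(x$tolerance),
      "| max iterations =", x$max_iterations, "| convergence =", x$convergence, "\n")
  invisible(x)
}

# Samples (columns) grouped by batch, with the mode's denominator set.
batch_structure <- function(m, annotation, mode) {
  ann <- align_annotation(m, annotation)
  batches <- unique(ann$batch)
  out <- lapply(batches, function(b) {
    in_b <- which(ann$batch == b)
    gis <- in_b[ann$is_gis[in_b]]
    nongis <- in_b[!ann$is_gis[in_b]]
    denom <- if (mode == "noGIS") in_b else gis
    list(batch = b, samples = in_b, gis = gis, nongis = nongis, denom = denom)
  })
  names(out) <- batches
  if (mode != "noGIS") {
    empty <- batches[vapply(out, function(x) length(x$gis) == 0L, logical(1))]
    if (length(empty)) {
      stop("mode '", mode, "' requires >= 1 GIS sample in every batch; missing in: ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  if (mode == "gis_plus_nonGIS") {
    empty <- batches[vapply(out, function(x) length(x$nongis) == 0L, logical(1))]
    if (length(empty)) {
      stop("mode 'gis_plus_nonGIS' requires >= 1 non-GIS sample in every batch; ",
           "missing in: ", paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Per-row denominator medians for one batch
#'
#' The first-term denominator of the ratio step: the median over present
#' values of each row restricted to the batch's denominator samples (GIS
#' channels, or all samples of the batch in noGIS mode).  `NA` where all
#' denominator values of a row are missing.
#'
#' @param m Abundance matrix.
#' @param annotation Sample annotation (`sample_id`, `batch`, `is_gis`).
#' @param batch Batch label.
#' @param denom_set `"gis"` or `"all"`.
#' @return Named numeric vector, one entry per feature.
#' @export
denominator_median <- function(m, annotation, batch, denom_set = c("gis", "all")) {
  assert_abundance(m)
  denom_set <- match.arg(denom_set)
  mode <- if (denom_set == "all") "noGIS" else "gis_only"
  bs <- batch_structure(m, annotation, mode)
  if (!batch %in% names(bs)) stop("unknown batch '", batch, "'", call. = FALSE)
  cols <- bs[[batch]]$denom
  if (length(cols) == 0L) stop("batch '", batch, "' has no denominator samples", call. = FALSE)
  stats::setNames(row_medians(m, cols), rownames(m))
}

#' Per-row, per-batch factors M and their grand medians
#'
#' In `gis_plus_nonGIS` mode, `M[i, k] = median(non-GIS values of row i in
#' batch k) / median(GIS values)`, the second-term batch factor that
#' re-references defective GIS channels to the batch's own samples.  In
#' `noGIS` and `gis_only` modes the numerator and denominator sets
#' coincide, so `M` is identically 1.  `grand[i]` is the median of the
#' defined `M[i, ]`.
#'
#' @inheritParams denominator_median
#' @param mode A mode name accepted by [tampor_config()].
#' @return A list with `M` (feature x batch matrix) and `grand` (vector).
#' @export
batch_factor <- function(m, annotation, mode = "gis_plus_nonGIS") {
  assert_abundance(m)
  mode <- normalize_mode(mode)
  bs <- batch_structure(m, annotation, mode)
  M <- matrix(1, nrow(m), length(bs), dimnames = list(rownames(m), names(bs)))
  if (mode == "gis_plus_nonGIS") {
    for (b in names(bs)) {
      M[, b] <- row_medians(m, bs[[b]]$nongis) / row_medians(m, bs[[b]]$gis)
    }
    M[!is.finite(M)] <- NA_real_
  }
  grand <- apply(M, 1L, med)
  list(M = M, grand = grand)
}

#' One row-wise ratio step
#'
#' Computes `ratio[i, j in k] = value[i, j] / D[i, k] * grand[i] / M[i, k]`
#' where `D` is the batch's denominator-set median ([denominator_median()])
#' and `M`, `grand` come from [batch_factor()].  This drives the median of
#' each batch's denominator set toward a ratio of 1 per row.  Entries whose
#' `D` or `M` is undefined become missing.
#'
#' @inheritParams batch_factor
#' @return Matrix of positive ratios, same shape as `m`.
#' @export
rowwise_ratio_step <- function(m, annotation, mode = "gis_plus_nonGIS") {
  assert_abundance(m)
  mode <- normalize_mode(mode)
  bs <- batch_structure(m, annotation, mode)
  bf <- batch_factor(m, annotation, mode)
  ratio <- m
  for (b in names(bs)) {
    D <- row_medians(m, bs[[b]]$denom)
    scale <- bf$grand / (D * bf$M[, b])
    scale[!is.finite(scale)] <- NA_real_
    ratio[, bs[[b]]$samples] <- m[, bs[[b]]$samples, drop = FALSE] * scale
  }
  ratio
}

#' Center each column of a log2-ratio table at median 0
#'
#' Subtracts each column's median over present values, bringing every
#' sample's central tendency to a log2 ratio of 0 (this is what corrects
#' unequal sample loading).
#'
#' @param log2m Matrix of log2 ratios (missing values allowed).
#' @return Centered matrix.
#' @export
column_center <- function(log2m) {
  cm <- col_medians(log2m)
  if (anyNA(cm)) {
    stop("column(s) with no present values: ",
         paste(colnames(log2m)[is.na(cm)], collapse = ", "), call. = FALSE)
  }
  sweep(log2m, 2L, cm, "-")
}

#' Restore row scale after centering
#'
#' Maps centered log2 ratios back to input units:
#' `value[i, j] = 2^centered[i, j] * saved_median[i]`, where the saved
#' medians are the per-row medians of the filtered input computed once
#' before the first iteration.
#'
#' @param centered_log2 Centered log2 ratio matrix.
#' @param saved_row_medians Per-row medians of the pre-polish input.
#' @return Abundance matrix in input units.
#' @export
restore_row_scale <- function(centered_log2, saved_row_medians) {
  if (length(saved_row_medians) != nrow(centered_log2)) {
    stop("`saved_row_medians` must have one entry per row", call. = FALSE)
  }
  2^centered_log2 * saved_row_medians
}

#' Inter-iteration Frobenius statistic
#'
#' `|  ||cur||_F - ||prev||_F  |`, where the Frobenius norm sums squares
#' over present entries only.  Both matrices must have the same shape and
#' missing pattern.
#'
#' @param prev_log2,cur_log2 Working log2 matrices of successive iterations.
#' @return Nonnegative scalar.
#' @export
frobenius_delta <- function(prev_log2, cur_log2) {
  if (!identical(dim(prev_log2), dim(cur_log2))) {
    stop("matrices differ in shape: ", paste(dim(prev_log2), collapse = "x"),
         " vs ", paste(dim(cur_log2), collapse = "x"), call. = FALSE)
  }
  abs(frobenius_norm(cur_log2) - frobenius_norm(prev_log2))
}

#' Run the iterative median polish of ratios
#'
#' Iterates row-wise ratio calculation, log2 transform, column median
#' centering, antilog and row-scale restoration on the working abundance
#' matrix, recomputing ratios from the current matrix each iteration while
#' reusing the once-saved row medians.  Stops when the inter-iteration
#' Frobenius statistic of the working log2 matrix falls below the
#' tolerance, or at the iteration cap (with a warning: such a run should be
#' treated as preliminary and judged from its convergence trace).
#'
#' Input must be sanitized (all present values positive, see
#' [sanitize_nonpositive()]) and filtered ([filter_rows_by_missingness()]).
#'
#' @param m Abundance matrix (positive values, `NA` for missing).
#' @param annotation Sample annotation with `sample_id`, `batch`, `is_gis`.
#' @param config A [tampor_config()].
#' @param verbose Print one line per iteration.
#' @return A `tampor_result`: `abundance` (corrected matrix, input units,
#'   same IDs and missing pattern apart from entries whose denominators
#'   were undefined), `trace` (data.frame `iteration`, `frobenius_norm`,
#'   `delta`), `converged`, `iterations`, `row_medians` (the restoration
#'   constants), `config`.
#' @export
run_tampor <- function(m, annotation, config = tampor_config(), verbose = FALSE) {
  assert_abundance(m)
  if (!inherits(config, "tampor_config")) stop("`config` must be a tampor_config()", call. = FALSE)
  if (any(!is.na(m) & m <= 0)) {
    stop("matrix contains non-positive values; run sanitize_nonpositive() first",
         call. = FALSE)
  }
  saved <- stats::setNames(row_medians(m), rownames(m))
  if (anyNA(saved)) {
    stop("feature(s) with no present values: ",
         paste(utils::head(rownames(m)[is.na(saved)], 5), collapse = ", "), call. = FALSE)
  }
  bs <- batch_structure(m, annotation, config$mode)  # validates up front
  work <- m
  prev_log2 <- log2(work)
  prev_norm <- frobenius_norm(prev_log2)
  trace <- data.frame(iteration = integer(0), frobenius_norm = numeric(0),
                      delta = numeric(0))
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    ratio <- rowwise_ratio_step(work, annotation, config$mode)
    centered <- column_center(log2(ratio))
    work <- restore_row_scale(centered, saved)
    cur_log2 <- log2(work)
    cur_norm <- frobenius_norm(cur_log2)
    delta <- if (config$convergence == "norm_diff") {
      abs(cur_norm - prev_norm)
    } else {
      d <- cur_log2 - prev_log2
      frobenius_norm(d)
    }
    trace <- rbind(trace, data.frame(iteration = it, frobenius_norm = cur_norm,
                                     delta = delta))
    if (verbose) {
      message(sprintf("iteration %3d | frobenius norm %.8f | delta %.3e",
                      it, cur_norm, delta))
    }
    prev_norm <- cur_norm
    prev_log2 <- cur_log2
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("no convergence within ", config$max_iterations,
            " iterations (last delta ", format(trace$delta[nrow(trace)]),
            "); consider this run preliminary and inspect the trace",
            call. = FALSE)
  }
  structure(list(abundance = work, trace = trace, converged = converged,
                 iterations = nrow(trace), row_medians = saved, config = config),
            class = "tampor_result")
}

#' @export
print.tampor_result <- function(x, ...) {
  cat("median polish of ratios:", nrow(x$abundance), "features x",
      ncol(x$abundance), "samples\n")
  cat("  mode:", x$config$mode, "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  final delta:", format(x$trace$delta[nrow(x$trace)]), "\n")
  invisible(x)
}

#' Naive intra-batch GIS ratio baseline
#'
#' The conventional single-pass correction: each value divided by the mean
#' (or median) of its batch's GIS channels for that feature.  No iteration
#' and no column centering; provided as the benchmarking baseline.
#'
#' @inheritParams run_tampor
#' @param center `"mean"` or `"median"` of the intra-batch GIS values.
#' @return Ratio matrix (dimensionless), same shape as `m`.
#' @export
naive_gis_ratio <- function(m, annotation, center = c("mean", "median")) {
  assert_abundance(m)
  center <- match.arg(center)
  bs <- batch_structure(m, annotation, "gis_only")
  out <- m
  for (b in names(bs)) {
    g <- m[, bs[[b]]$gis, drop = FALSE]
    denom <- if (center == "mean") {
      d <- rowMeans(g, na.rm = TRUE); d[is.nan(d)] <- NA_real_; d
    } else {
      row_medians(m, bs[[b]]$gis)
    }
    denom[!is.na(denom) & denom <= 0] <- NA_real_
    out[, bs[[b]]$samples] <- m[, bs[[b]]$samples, drop = FALSE] / denom
  }
  out
}
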