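# Quality-control and evaluation metrics: mean-SD series, classical MDS,
# per-feature variance partition, robust correlation, replicate-pair and
# all-pair correlation-shift analyses, differential abundance.

#' Per-feature mean and standard deviation of log2 abundance
#'
#' The mean-SD series: per-feature mean and sample SD (n - 1 denominator)
#' over present values, ranked by mean descending.  A successful correction
#' lowers the SD band across all ranks.  Features with fewer than two
#' present values are excluded and reported in the `excluded` attribute.
#'
#' @param log2m Matrix of log2 abundances.
#' @return data.frame `feature_id`, `mean`, `sd`, `n_present`, ordered by
#'   mean descending, with attribute `excluded` (feature IDs with < 2
#'   present values).
#' @export
mean_sd_series <- function(log2m) {
  n <- rowSums(!is.na(log2m))
  ok <- n >= 2L
  mu <- rowMeans(log2m, na.rm = TRUE)
  sdv <- apply(log2m, 1L, stats::sd, na.rm = TRUE)
  out <- data.frame(feature_id = rownames(log2m)[ok], mean = mu[ok], sd = sdv[ok],
                    n_present = n[ok], stringsAsFactors = FALSE)
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(log2m)[!ok]
  out
}

# Squared Euclidean inter-sample distances over pairwise-complete features,
# rescaled by total/shared feature counts so distances stay comparable
# under missingness.
pairwise_distances <- function(log2m) {
  X <- t(log2m)
  present <- !is.na(X)
  shared <- present %*% t(present)
  none <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(none)) {
    stop("sample pair sharing zero features: ", rownames(X)[none[1, 1]], " / ",
         rownames(X)[none[1, 2]], call. = FALSE)
  }
  Xz <- X
  Xz[!present] <- 0
  cross <- Xz %*% t(Xz)
  sq <- (Xz^2) %*% t(present)
  d2 <- sq + t(sq) - 2 * cross
  d2 <- d2 * (ncol(X) / shared)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson scaling of Euclidean inter-sample distances computed over
#' pairwise-complete features (each pair's squared distance rescaled by
#' total features / shared features).  Before correction, samples cluster
#' by batch; afterwards the embedding should collapse to a single focus.
#'
#' @param log2m Matrix of log2 abundances.
#' @param n_dims Embedding dimension (default 2; must be < number of
#'   samples).
#' @return A list with `points` (samples x `n_dims`, centroid at the
#'   origin) and `eig` (eigenvalues of the scaling solution).
#' @export
classical_mds <- function(log2m, n_dims = 2L) {
  n_dims <- as.integer(n_dims)
  if (ncol(log2m) < n_dims + 1L) {
    stop("need at least n_dims + 1 samples (", n_dims + 1L, "); got ", ncol(log2m),
         call. = FALSE)
  }
  d <- pairwise_distances(log2m)
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < n_dims) {  # cmdscale drops dimensions with ~zero eigenvalue
    pts <- cbind(pts, matrix(0, nrow(pts), n_dims - ncol(pts)))
  }
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  list(points = pts, eig = fit$eig)
}

#' Fraction of per-feature variance explained by sample factors
#'
#' Each factor is scored marginally (one at a time): categorical factors by
#' a one-way method-of-moments variance-component fraction
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2)` with the between component
#' truncated at zero, continuous traits by squared Pearson correlation.
#' This is a deliberately simple approximation to mixed-model variance
#' partitioning; see the methods vignette.
#'
#' @param log2m Matrix of log2 abundances.
#' @param annotation Sample annotation; `factors` must name its columns.
#' @param factors Character vector of factor/trait names to score.
#' @return data.frame with `feature_id`, one fraction column per factor,
#'   `residual` (`max(0, 1 - sum)`), and `constant` (flag for zero-variance
#'   features, whose fractions are 0).
#' @export
variance_explained <- function(log2m, annotation, factors) {
  ann <- align_annotation(log2m, annotation)
  missing_f <- setdiff(factors, names(ann))
  if (length(missing_f)) {
    stop("factor(s) not in annotation: ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  nf <- nrow(log2m)
  out <- data.frame(feature_id = rownames(log2m), stringsAsFactors = FALSE)
  constant <- apply(log2m, 1L, function(x) stats::var(x, na.rm = TRUE)) == 0
  constant[is.na(constant)] <- TRUE
  for (f in factors) {
    v <- ann[[f]]
    if (is.numeric(v)) {
      r <- suppressWarnings(stats::cor(t(log2m), v, use = "pairwise.complete.obs"))
      frac <- as.vector(r)^2
      frac[is.na(frac)] <- 0
    } else {
      frac <- vapply(seq_len(nf), function(i) {
        one_way_vc_fraction(log2m[i, ], v)
      }, numeric(1))
    }
    frac[constant] <- 0
    out[[f]] <- frac
  }
  fracs <- as.matrix(out[, factors, drop = FALSE])
  out$residual <- pmax(0, 1 - rowSums(fracs))
  out$constant <- constant
  out
}

# One-way method-of-moments variance-component fraction for one feature.
# Unbalanced-design n0 = (N - sum(n_k^2)/N) / (K - 1).
one_way_vc_fraction <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  g <- droplevels(g)
  nk <- table(g)
  if (length(nk) < 2L || sum(nk >= 2L) < 2L) return(0)
  N <- length(x); K <- length(nk)
  means <- tapply(x, g, mean)
  grand <- mean(x)
  ssb <- sum(nk * (means - grand)^2)
  ssw <- sum((x - means[g])^2)
  msb <- ssb / (K - 1)
  if (N - K <= 0) return(0)
  msw <- ssw / (N - K)
  n0 <- (N - sum(nk^2) / N) / (K - 1)
  sigma_b2 <- max(0, (msb - msw) / n0)
  denom <- sigma_b2 + msw
  if (denom <= 0) return(0)
  sigma_b2 / denom
}

#' Pearson correlation over pairwise-complete values
#'
#' @param x,y Numeric vectors of equal length; at least 3 paired present
#'   values and nonzero dispersion are required, otherwise `NA` with a
#'   warning.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 paired present values; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero dispersion; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Tukey biweight transform used by bicor: deviations from the median,
# weighted by (1 - u^2)^2 inside the |u| < 1 window with u = dev / (9 * MAD),
# raw MAD (no 1.4826 consistency factor).
biweight_deviation <- function(x) {
  mx <- stats::median(x)
  madx <- stats::median(abs(x - mx))
  if (madx == 0) return(NULL)
  u <- (x - mx) / (9 * madx)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  (x - mx) * w
}

#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD with Tukey biweights: values more
#' than 9 MADs from the median get zero weight, so a minority of gross
#' outliers cannot move the estimate the way they move Pearson correlation.
#'
#' @inheritParams pearson_corr
#' @return Correlation in `[-1, 1]`, or `NA` (zero MAD / too few pairs),
#'   with a warning.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 paired present values; bicor undefined", call. = FALSE)
    return(NA_real_)
  }
  ax <- biweight_deviation(x[ok])
  ay <- biweight_deviation(y[ok])
  if (is.null(ax) || is.null(ay)) {
    warning("zero median absolute deviation; bicor undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))
}

# Prepare a matrix for sample-sample correlation analysis: log2 transform
# and per-feature median centering (removes the row profile that would
# otherwise dominate every correlation).
corr_prep <- function(m, log2_transform = TRUE, row_center = TRUE) {
  if (log2_transform) m <- log2(m)
  if (row_center) m <- m - row_medians(m)
  m
}

#' Replicate-pair correlation comparison between two corrections
#'
#' For each technical replicate pair, the Pearson correlation of the two
#' sample columns (over shared features, on log2 row-centered data) is
#' computed in the `before` and `after` matrices; pairs are classified as
#' improved, worsened or unchanged, and a one-tailed Welch t-test asks
#' whether the mean absolute correlation change of the improved pairs
#' exceeds that of the worsened pairs.
#'
#' @param before,after Abundance matrices with the same sample columns
#'   (e.g. naive GIS ratio vs the polished result).
#' @param pairs data.frame with columns `sample_1`, `sample_2`.
#' @param log2_transform,row_center Preprocessing applied to each matrix
#'   before correlating (defaults `TRUE`; see the methods vignette).
#' @return A `replicate_pair_report`: `pairs` (per-pair correlations and
#'   deltas), counts, group means of `|delta|` with standard errors,
#'   one-tailed `p_value` (`NA` with a flag when a group is too small), and
#'   `excluded_pairs`.
#' @export
replicate_pair_analysis <- function(before, after, pairs,
                                    log2_transform = TRUE, row_center = TRUE) {
  assert_abundance(before); assert_abundance(after)
  if (!all(c("sample_1", "sample_2") %in% names(pairs))) {
    stop("`pairs` needs columns sample_1 and sample_2", call. = FALSE)
  }
  bad <- !(pairs$sample_1 %in% colnames(before) & pairs$sample_2 %in% colnames(before) &
           pairs$sample_1 %in% colnames(after) & pairs$sample_2 %in% colnames(after))
  if (any(bad)) {
    stop("pair(s) reference unknown samples: ",
         paste(pairs$sample_1[bad], pairs$sample_2[bad], sep = "/", collapse = ", "),
         call. = FALSE)
  }
  pb <- corr_prep(before, log2_transform, row_center)
  pa <- corr_prep(after, log2_transform, row_center)
  excluded <- character(0)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    s1 <- pairs$sample_1[i]; s2 <- pairs$sample_2[i]
    shared_b <- sum(!is.na(pb[, s1]) & !is.na(pb[, s2]))
    shared_a <- sum(!is.na(pa[, s1]) & !is.na(pa[, s2]))
    if (min(shared_b, shared_a) < 3L) return(NULL)
    rb <- suppressWarnings(pearson_corr(pb[, s1], pb[, s2]))
    ra <- suppressWarnings(pearson_corr(pa[, s1], pa[, s2]))
    data.frame(sample_1 = s1, sample_2 = s2, r_before = rb, r_after = ra,
               delta = ra - rb, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) {
    excluded <- paste(pairs$sample_1[!keep], pairs$sample_2[!keep], sep = "/")
    warning(length(excluded), " pair(s) excluded (< 3 shared features)", call. = FALSE)
  }
  tab <- do.call(rbind, rows[keep])
  improved <- tab$delta > 0
  worsened <- tab$delta < 0
  up <- abs(tab$delta[improved])
  down <- abs(tab$delta[worsened])
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  p <- NA_real_
  flag <- NULL
  if (length(up) >= 2L && length(down) >= 2L &&
      (stats::sd(up) > 0 || stats::sd(down) > 0)) {
    p <- stats::t.test(up, down, alternative = "greater", var.equal = FALSE)$p.value
  } else {
    flag <- "t-test undefined: fewer than 2 improved or 2 worsened pairs, or no spread"
  }
  structure(list(pairs = tab,
                 n_improved = sum(improved),
                 n_worsened = sum(worsened),
                 n_unchanged = sum(tab$delta == 0),
                 mean_abs_delta_improved = if (length(up)) mean(up) else NA_real_,
                 sem_abs_delta_improved = sem(up),
                 mean_abs_delta_worsened = if (length(down)) mean(down) else NA_real_,
                 sem_abs_delta_worsened = sem(down),
                 p_value = p, flag = flag,
                 excluded_pairs = excluded),
            class = "replicate_pair_report")
}

#' @export
print.replicate_pair_report <- function(x, ...) {
  cat("replicate pairs:", nrow(x$pairs), "scored |", x$n_improved, "improved,",
      x$n_worsened, "worsened,", x$n_unchanged, "unchanged\n")
  cat("  mean |delta rho| improved:", format(x$mean_abs_delta_improved, digits = 3),
      "| worsened:", format(x$mean_abs_delta_worsened, digits = 3),
      "| one-tailed p:", format(x$p_value, digits = 3), "\n")
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Correlation shift across all non-replicate sample pairs
#'
#' Scores every unordered sample pair (optionally excluding a set of
#' technical replicate pairs) with Pearson correlation or biweight
#' midcorrelation in the `before` and `after` matrices and summarizes the
#' per-pair deltas.  A correction that tightens the correlation structure
#' shifts the Pearson deltas positive while leaving the robust bicor
#' deltas near zero.
#'
#' @inheritParams replicate_pair_analysis
#' @param method `"pearson"` or `"bicor"`.
#' @param replicate_pairs Optional data.frame (`sample_1`, `sample_2`) of
#'   pairs to exclude.
#' @return A list: `deltas` (data.frame `sample_1`, `sample_2`, `r_before`,
#'   `r_after`, `delta`), `mean_before`, `mean_after`, `mean_delta`,
#'   `n_pairs`.
#' @export
all_pair_correlation_shift <- function(before, after, method = c("pearson", "bicor"),
                                       replicate_pairs = NULL,
                                       log2_transform = TRUE, row_center = TRUE) {
  assert_abundance(before); assert_abundance(after)
  method <- match.arg(method)
  if (!identical(sort(colnames(before)), sort(colnames(after)))) {
    stop("`before` and `after` must contain the same samples", call. = FALSE)
  }
  samples <- colnames(before)
  pb <- corr_prep(before, log2_transform, row_center)
  pa <- corr_prep(after[, samples, drop = FALSE], log2_transform, row_center)
  idx <- utils::combn(length(samples), 2L)
  keep <- rep(TRUE, ncol(idx))
  if (!is.null(replicate_pairs) && nrow(replicate_pairs)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    rep_keys <- key(as.character(replicate_pairs$sample_1),
                    as.character(replicate_pairs$sample_2))
    pair_keys <- key(samples[idx[1, ]], samples[idx[2, ]])
    keep <- !(pair_keys %in% rep_keys)
  }
  idx <- idx[, keep, drop = FALSE]
  if (method == "pearson") {
    cb <- suppressWarnings(stats::cor(pb, use = "pairwise.complete.obs"))
    ca <- suppressWarnings(stats::cor(pa, use = "pairwise.complete.obs"))
    rb <- cb[cbind(idx[1, ], idx[2, ])]
    ra <- ca[cbind(idx[1, ], idx[2, ])]
  } else {
    rb <- numeric(ncol(idx)); ra <- numeric(ncol(idx))
    for (p in seq_len(ncol(idx))) {
      i <- idx[1, p]; j <- idx[2, p]
      rb[p] <- suppressWarnings(bicor(pb[, i], pb[, j]))
      ra[p] <- suppressWarnings(bicor(pa[, i], pa[, j]))
    }
  }
  deltas <- data.frame(sample_1 = samples[idx[1, ]], sample_2 = samples[idx[2, ]],
                       r_before = rb, r_after = ra, delta = ra - rb,
                       stringsAsFactors = FALSE)
  list(deltas = deltas,
       mean_before = mean(rb, na.rm = TRUE),
       mean_after = mean(ra, na.rm = TRUE),
       mean_delta = mean(ra - rb, na.rm = TRUE),
       n_pairs = nrow(deltas),
       method = method)
}

#' Differential abundance between two sample groups
#'
#' Per-feature Welch two-sample t-test on log2 values with
#' Benjamini-Hochberg adjustment across tested features.  The log2 fold
#' change is `mean(group_a) - mean(group_b)`.  Features with fewer than two
#' present values in either group, or zero variance in both, are skipped
#' and counted in the `n_untestable` attribute.
#'
#' @param log2m Matrix of log2 abundances.
#' @param annotation Sample annotation.
#' @param group_col Annotation column holding the grouping trait.
#' @param group_a,group_b Level labels to contrast (`a` minus `b`).
#' @param exclude_gis Drop GIS channels before testing (default `TRUE`).
#' @return data.frame `feature_id`, `log2fc`, `p_value`, `adj_p_value`,
#'   `n_a`, `n_b`, with attribute `n_untestable`.
#' @export
differential_abundance <- function(log2m, annotation, group_col, group_a, group_b,
                                   exclude_gis = TRUE) {
  ann <- align_annotation(log2m, annotation)
  if (!group_col %in% names(ann)) stop("no annotation column '", group_col, "'", call. = FALSE)
  use <- if (exclude_gis) !ann$is_gis else rep(TRUE, nrow(ann))
  ga <- use & !is.na(ann[[group_col]]) & ann[[group_col]] == group_a
  gb <- use & !is.na(ann[[group_col]]) & ann[[group_col]] == group_b
  if (sum(ga) < 2L || sum(gb) < 2L) {
    stop("each group needs >= 2 samples; got ", sum(ga), " and ", sum(gb), call. = FALSE)
  }
  A <- log2m[, ga, drop = FALSE]
  B <- log2m[, gb, drop = FALSE]
  rows <- lapply(seq_len(nrow(log2m)), function(i) {
    xa <- A[i, ][!is.na(A[i, ])]
    xb <- B[i, ][!is.na(B[i, ])]
    if (length(xa) < 2L || length(xb) < 2L) return(NULL)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) return(NULL)  # Welch undefined
    tt <- stats::t.test(xa, xb)
    data.frame(feature_id = rownames(log2m)[i],
               log2fc = mean(xa) - mean(xb),
               p_value = tt$p.value,
               n_a = length(xa), n_b = length(xb),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[keep])
  if (is.null(tab)) stop("no testable features", call. = FALSE)
  tab$adj_p_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab <- tab[, c("feature_id", "log2fc", "p_value", "adj_p_value", "n_a", "n_b")]
  rownames(tab) <- NULL
  attr(tab, "n_untestable") <- sum(!keep)
  tab
}
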