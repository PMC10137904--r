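# Core polish machinery: denominators, batch factors, the ratio step,
# centering, restoration, the convergence statistic, the full loop, and the
# naive baseline.

test_that("denominator medians match conventions and a brute-force oracle", {
  m <- rbind(f1 = c(2, 4, 8), f2 = c(2, 8, 100))
  colnames(m) <- paste0("s", 1:3)
  ann <- data.frame(sample_id = colnames(m), batch = "b1", is_gis = FALSE)
  d <- denominator_median(m, ann, "b1", denom_set = "all")
  expect_equal(unname(d["f1"]), 4)
  expect_equal(unname(d["f2"]), 8)

  # even count: mean of the central pair
  m2 <- rbind(f1 = c(2, 8))
  colnames(m2) <- c("s1", "s2")
  ann2 <- data.frame(sample_id = c("s1", "s2"), batch = "b1", is_gis = FALSE)
  expect_equal(unname(denominator_median(m2, ann2, "b1", "all")["f1"]), 5)

  # random 7-value sets vs sort-and-pick
  set.seed(21)
  for (i in 1:50) {
    x <- matrix(runif(7, 1, 100), 1, 7, dimnames = list("f", paste0("s", 1:7)))
    a <- data.frame(sample_id = colnames(x), batch = "b", is_gis = FALSE)
    expect_equal(unname(denominator_median(x, a, "b", "all")),
                 sort(as.vector(x))[4])
  }

  expect_error(denominator_median(m, ann, "b1", "gis"), "GIS sample in every batch")
})

test_that("batch factors are 1 outside gis_plus_nonGIS and follow the non-GIS/GIS ratio", {
  m <- rbind(f1 = c(6, 10, 4, 5, 5, 5))
  colnames(m) <- paste0("s", 1:6)
  ann <- data.frame(sample_id = colnames(m),
                    batch = c("A", "A", "A", "B", "B", "B"),
                    is_gis = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  bf <- batch_factor(m, ann, "gis_plus_nonGIS")
  expect_equal(unname(bf$M["f1", "A"]), 8 / 4)  # median(6,10)/median(4)
  expect_equal(unname(bf$M["f1", "B"]), 1)
  expect_equal(unname(bf$grand["f1"]), 1.5)

  for (mode in c("gis_only", "noGIS")) {
    bfu <- batch_factor(m, ann, mode)
    expect_true(all(bfu$M == 1))
    expect_true(all(bfu$grand == 1))
  }

  # grand median over three batches {0.5, 1, 2} -> 1; multipliers {2, 1, 0.5}
  m3 <- rbind(f1 = c(1, 2, 1, 4, 1, 8, 4, 1))
  colnames(m3) <- paste0("s", 1:8)
  # construct batches where non-GIS/GIS medians are 0.5, 1, 2
  ann3 <- data.frame(sample_id = colnames(m3),
                     batch = c("A", "A", "B", "B", "C", "C", "C", "C"),
                     is_gis = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  # A: nonGIS 1 / GIS 2 = 0.5; B: 1/4 ... adjust values for {0.5, 1, 2}
  m3 <- rbind(f1 = c(1, 2, 4, 4, 8, 8, 4, 4))
  colnames(m3) <- paste0("s", 1:8)
  bf3 <- batch_factor(m3, ann3, "gis_plus_nonGIS")
  expect_equal(unname(bf3$M["f1", ]), c(0.5, 1, 2))
  expect_equal(unname(bf3$grand["f1"]), 1)
  expect_equal(unname(bf3$grand["f1"] / bf3$M["f1", ]), c(2, 1, 0.5))
})

test_that("the ratio step reproduces hand-computed ratios and drives medians to 1", {
  # one batch, noGIS: {2,4,8} -> {0.5, 1, 2}
  m <- rbind(f1 = c(2, 4, 8))
  colnames(m) <- paste0("s", 1:3)
  ann <- data.frame(sample_id = colnames(m), batch = "b", is_gis = FALSE)
  expect_equal(unname(rowwise_ratio_step(m, ann, "noGIS")["f1", ]), c(0.5, 1, 2))

  # gis_plus_nonGIS toy: batch A GIS median 4, non-GIS median 8; batch B both 5
  # M = {2, 1}, grand = 1.5; value 8 in batch A -> 8/4 * 1.5/2 = 1.5
  m2 <- rbind(f1 = c(8, 8, 4, 5, 5, 5))
  colnames(m2) <- paste0("s", 1:6)
  ann2 <- data.frame(sample_id = colnames(m2),
                     batch = c("A", "A", "A", "B", "B", "B"),
                     is_gis = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  r2 <- rowwise_ratio_step(m2, ann2, "gis_plus_nonGIS")
  expect_equal(unname(r2["f1", "s1"]), 8 / 4 * 1.5 / 2)

  # row-wise centering: the denominator-set median of the ratios is exactly
  # grand/M for every batch (so 1 in the single-denominator-set modes)
  ds <- simulate_dataset(simulation_design(n_features = 40, n_batches = 3,
                                           samples_per_batch = 5,
                                           gis_per_batch = 2, seed = 33))
  r <- rowwise_ratio_step(ds$abundance, ds$annotation, "gis_only")
  for (b in unique(ds$annotation$batch)) {
    gis <- ds$annotation$sample_id[ds$annotation$batch == b & ds$annotation$is_gis]
    expect_equal(unname(apply(r[, gis, drop = FALSE], 1, median)),
                 rep(1, nrow(r)), tolerance = 1e-9)
  }

  # at convergence one further full iteration is a no-op (fixed point)
  fit <- run_tampor(ds$abundance, ds$annotation,
                    tampor_config("useAllNonGIS", tolerance = 1e-11,
                                  max_iterations = 1000))
  W <- fit$abundance
  W2 <- restore_row_scale(
    column_center(log2(rowwise_ratio_step(W, ds$annotation, "gis_plus_nonGIS"))),
    fit$row_medians)
  expect_lt(max(abs(W2 / W - 1), na.rm = TRUE), 1e-9)
})

test_that("column centering zeroes column medians and flags empty columns", {
  l <- cbind(a = c(0, 1, 2), b = c(5, 5, 5))
  rownames(l) <- paste0("f", 1:3)
  cc <- column_center(l)
  expect_equal(unname(cc[, "a"]), c(-1, 0, 1))
  expect_equal(unname(cc[, "b"]), c(0, 0, 0))
  expect_identical(column_center(cc), cc)  # already centered

  set.seed(8)
  lm <- matrix(rnorm(100), 10, 10, dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  lm[sample(100, 20)] <- NA
  cc2 <- column_center(lm)
  for (j in 1:10) {
    expect_equal(median(cc2[, j], na.rm = TRUE), 0, tolerance = 1e-12)
  }
  bad <- lm; bad[, 3] <- NA
  expect_error(column_center(bad), "s3")
})

test_that("row-scale restoration inverts the log-ratio transform", {
  cl <- rbind(f1 = c(-1, 0, 1))
  colnames(cl) <- paste0("s", 1:3)
  expect_equal(unname(restore_row_scale(cl, 8)["f1", ]), c(4, 8, 16))
  expect_equal(unname(restore_row_scale(rbind(f1 = 0), 100)[1, 1]), 100)

  set.seed(14)
  m <- toy_matrix(8, 5, seed = 14)
  med <- apply(m, 1, median)
  expect_equal(restore_row_scale(log2(m / med), med), m, tolerance = 1e-12)
})

test_that("frobenius_delta matches a brute-force sum-of-squares oracle", {
  expect_equal(frobenius_delta(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(frobenius_delta(matrix(c(3, 4), 1), matrix(c(6, 8), 1)), 5)
  expect_error(frobenius_delta(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")

  set.seed(5)
  for (i in 1:50) {
    a <- matrix(rnorm(24), 4, 6); b <- matrix(rnorm(24), 4, 6)
    miss <- matrix(runif(24) < 0.2, 4, 6)
    a[miss] <- NA; b[miss] <- NA
    oracle <- abs(sqrt(sum(b[!miss]^2)) - sqrt(sum(a[!miss]^2)))
    expect_equal(frobenius_delta(a, b), oracle, tolerance = 1e-12)
  }
})

test_that("run_tampor converges, logs a trace, and maps user-facing mode names", {
  ds <- simulate_dataset(simulation_design(n_features = 60, n_batches = 3,
                                           samples_per_batch = 5,
                                           gis_per_batch = 2, seed = 3))
  fit <- run_tampor(ds$abundance, ds$annotation, tampor_config("useAllNonGIS"))
  expect_s3_class(fit, "tampor_result")
  expect_true(fit$converged)
  expect_equal(nrow(fit$trace), fit$iterations)
  expect_true(all(is.finite(fit$trace$delta)))
  expect_lt(fit$trace$delta[fit$iterations], 1e-8)
  expect_identical(dimnames(fit$abundance), dimnames(ds$abundance))

  # user-facing spellings map onto the internal modes
  expect_equal(tampor_config("useAllNonGIS")$mode, "gis_plus_nonGIS")
  expect_equal(tampor_config("GIS")$mode, "gis_only")
  expect_equal(tampor_config("noGIS")$mode, "noGIS")
  expect_error(tampor_config("bogus"), "unknown mode")

  # mode requirements validated up front, naming the offending batch
  ann_nogis <- ds$annotation
  ann_nogis$is_gis[ann_nogis$batch == "B02"] <- FALSE
  expect_error(run_tampor(ds$abundance, ann_nogis, tampor_config("GIS")), "B02")

  # hitting the cap warns and flags the run as preliminary
  expect_warning(
    run_tampor(ds$abundance, ds$annotation,
               tampor_config("useAllNonGIS", max_iterations = 2)),
    "preliminary")
})

test_that("single-batch noGIS agrees with the Tukey median-polish oracle", {
  # odd sample count: the even-median convention differs between linear and
  # log space, so only odd counts make the two paths identical
  set.seed(42)
  m <- matrix(2^rnorm(20 * 11, 8, 2), 20, 11,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:11)))
  ann <- data.frame(sample_id = colnames(m), batch = "b1", is_gis = FALSE)
  fit <- run_tampor(m, ann, tampor_config("noGIS", tolerance = 1e-10,
                                          max_iterations = 1000))
  mp <- stats::medpolish(log2(m), eps = 1e-12, maxiter = 1000, trace.iter = FALSE)
  oracle <- mp$residuals + log2(apply(m, 1, median))
  expect_lt(max(abs(log2(fit$abundance) - oracle)), 1e-6)
})

test_that("naive GIS ratio divides by the intra-batch GIS center", {
  m <- rbind(f1 = c(10, 4, 6))
  colnames(m) <- paste0("s", 1:3)
  ann <- data.frame(sample_id = colnames(m), batch = "b",
                    is_gis = c(FALSE, TRUE, TRUE))
  out <- naive_gis_ratio(m, ann, center = "mean")
  expect_equal(unname(out["f1", "s1"]), 2)  # 10 / mean(4, 6)
  # a GIS sample divided by its own batch's sole GIS value is 1
  m2 <- rbind(f1 = c(10, 4))
  colnames(m2) <- c("s1", "g1")
  ann2 <- data.frame(sample_id = colnames(m2), batch = "b", is_gis = c(FALSE, TRUE))
  expect_equal(unname(naive_gis_ratio(m2, ann2)["f1", "g1"]), 1)

  # with one GIS per batch, the gis_only ratio step equals the naive ratio
  ds <- simulate_dataset(simulation_design(n_features = 30, n_batches = 3,
                                           samples_per_batch = 4,
                                           gis_per_batch = 1, seed = 12))
  step <- rowwise_ratio_step(ds$abundance, ds$annotation, "gis_only")
  naive <- naive_gis_ratio(ds$abundance, ds$annotation, center = "median")
  expect_equal(step, naive, tolerance = 1e-12)

  ann_bad <- ds$annotation
  ann_bad$is_gis[ann_bad$batch == "B01"] <- FALSE
  expect_error(naive_gis_ratio(ds$abundance, ann_bad), "B01")
})

test_that("missing patterns are preserved and undefined denominators logged as missing", {
  ds <- simulate_dataset(simulation_design(n_features = 50, n_batches = 3,
                                           samples_per_batch = 5, gis_per_batch = 2,
                                           missing_frac_random = 0.15, seed = 9))
  m <- ds$abundance
  fit <- suppressWarnings(run_tampor(m, ds$annotation, tampor_config("useAllNonGIS")))
  na_in <- is.na(m)
  na_out <- is.na(fit$abundance)
  # no value invented; extra missingness only from undefined denominators
  expect_true(all(na_out[na_in]))
  extra <- which(na_out & !na_in, arr.ind = TRUE)
  if (nrow(extra) > 0) {
    for (k in seq_len(nrow(extra))) {
      b <- ds$annotation$batch[match(colnames(m)[extra[k, 2]], ds$annotation$sample_id)]
      gis <- ds$annotation$sample_id[ds$annotation$batch == b & ds$annotation$is_gis]
      nong <- ds$annotation$sample_id[ds$annotation$batch == b & !ds$annotation$is_gis]
      expect_true(all(is.na(m[extra[k, 1], gis])) || all(is.na(m[extra[k, 1], nong])))
    }
  }
})
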