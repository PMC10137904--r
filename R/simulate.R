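# Seeded generator of abundance matrices with the variance structure the
# polish assumes: log-normal feature levels spanning orders of magnitude,
# multiplicative per-feature-by-batch effects, per-sample loading factors,
# pooled-average GIS channels (optionally with a sparse "digestion defect"),
# group fold changes on a spiked feature subset, random / batch-wise
# missingness, cross-batch technical replicate pairs, and monotone
# platform-specific transforms of a shared latent proteome.

#' Simulation design
#'
#' All effects are multiplicative (log2-additive), matching the additive-
#' in-log model the ratio polish corrects.  Defaults are the repo's
#' standard-benchmark conditions; see [tampor_standard_benchmark()].
#'
#' @param n_features Number of features (rows).
#' @param n_batches Number of batches.
#' @param samples_per_batch Non-GIS (case) samples per batch.
#' @param gis_per_batch GIS channels per batch (pooled all-sample mixture).
#' @param dynamic_range_orders Base-10 orders of magnitude spanned by the
#'   latent feature medians (log-normal; default 4).
#' @param base_log2_level Center of the latent feature medians on the log2
#'   scale (default 20, i.e. ~1e6 intensity units).
#' @param batch_effect_sd SD of per-feature-by-batch log2 effects.
#' @param loading_sd SD of per-sample log2 loading factors.
#' @param technical_noise_sd SD of per-value log2 noise.
#' @param case_fraction Fraction of donors labeled `case` (vs `control`).
#' @param balance_groups If `TRUE` (default), donor groups are interleaved
#'   systematically so every batch is approximately trait-balanced -- the
#'   cohort design the correction assumes.  `FALSE` assigns groups at
#'   random, which deliberately violates that assumption.
#' @param spike_frac Fraction of features carrying a group effect.
#' @param spike_log2fc Log2 fold change (case minus control) on spiked
#'   features.
#' @param burst_prob Probability that a given feature is episodically
#'   elevated ("bursts") in a given donor.  Bursts are one-sided log2
#'   elevations with feature-specific magnitudes, emulating the
#'   right-skewed episodic expression (inflammation proteins, blood
#'   contamination) that gives real proteome samples a genuinely positive
#'   all-pair correlation baseline.  Technical replicates of a donor share
#'   its bursts.  Default 0 (off).
#' @param burst_log2_scale Mean burst magnitude in log2 units
#'   (feature-specific magnitudes are gamma with shape 2; default 1).
#' @param gis_defect_sd Marginal SD (log2) of the GIS defect, applied per
#'   feature-by-GIS-channel (each GIS replicate is digested separately, so
#'   defects are channel-specific).  The defect is contaminated-normal: a
#'   fraction `gis_defect_frac` of cells receive a shift of SD
#'   `gis_defect_sd / sqrt(gis_defect_frac)`, emulating differential
#'   digestion that ablates a minority of proteins strongly.
#' @param gis_defect_frac Fraction of feature-by-channel cells carrying
#'   the defect (default 0.01).
#' @param missing_frac_random Expected fraction of randomly masked cells.
#' @param missing_batchwise Probability that a feature is entirely missing
#'   in a given batch (whole-block dropout).
#' @param mnar If `TRUE`, random masking is intensity-dependent
#'   (left-tail-biased) instead of uniform; off by default since the polish
#'   assumes missingness without extreme bias.
#' @param replicate_pairs Number of donors measured twice, in two different
#'   batches, with fresh technical noise.
#' @param seed Seed pinned into the design (default 20230412).  The RNG is
#'   fixed to Mersenne-Twister / Inversion so seeds are portable.
#' @return A `tampor_design` list.
#' @export
simulation_design <- function(n_features = 1000L,
                              n_batches = 10L,
                              samples_per_batch = 8L,
                              gis_per_batch = 2L,
                              dynamic_range_orders = 4,
                              base_log2_level = 20,
                              batch_effect_sd = 1.0,
                              loading_sd = 0.5,
                              technical_noise_sd = 0.3,
                              case_fraction = 0.5,
                              balance_groups = TRUE,
                              spike_frac = 0.1,
                              spike_log2fc = 1.0,
                              burst_prob = 0,
                              burst_log2_scale = 1,
                              gis_defect_sd = 0,
                              gis_defect_frac = 0.01,
                              missing_frac_random = 0,
                              missing_batchwise = 0,
                              mnar = FALSE,
                              replicate_pairs = 0L,
                              seed = 20230412L) {
  d <- list(n_features = as.integer(n_features), n_batches = as.integer(n_batches),
            samples_per_batch = as.integer(samples_per_batch),
            gis_per_batch = as.integer(gis_per_batch),
            dynamic_range_orders = dynamic_range_orders,
            base_log2_level = base_log2_level,
            batch_effect_sd = batch_effect_sd, loading_sd = loading_sd,
            technical_noise_sd = technical_noise_sd,
            case_fraction = case_fraction, balance_groups = isTRUE(balance_groups),
            spike_frac = spike_frac,
            spike_log2fc = spike_log2fc,
            burst_prob = burst_prob, burst_log2_scale = burst_log2_scale,
            gis_defect_sd = gis_defect_sd, gis_defect_frac = gis_defect_frac,
            missing_frac_random = missing_frac_random,
            missing_batchwise = missing_batchwise, mnar = isTRUE(mnar),
            replicate_pairs = as.integer(replicate_pairs),
            seed = as.integer(seed),
            rng = list(kind = "Mersenne-Twister", normal_kind = "Inversion"))
  sds <- c(d$batch_effect_sd, d$loading_sd, d$technical_noise_sd, d$gis_defect_sd,
           d$burst_log2_scale)
  if (any(sds < 0)) stop("all effect SDs must be >= 0", call. = FALSE)
  fr <- c(d$case_fraction, d$spike_frac, d$missing_frac_random, d$missing_batchwise,
          d$gis_defect_frac, d$burst_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (d$n_features < 1L || d$n_batches < 1L || d$samples_per_batch < 1L ||
      d$gis_per_batch < 0L) {
    stop("counts must be positive (gis_per_batch may be 0)", call. = FALSE)
  }
  n_slots <- d$n_batches * d$samples_per_batch
  if (d$replicate_pairs > floor(n_slots / 2)) {
    stop("replicate_pairs (", d$replicate_pairs, ") exceeds half the available sample ",
         "slots (", n_slots, ")", call. = FALSE)
  }
  if (d$replicate_pairs > 0L && d$n_batches < 2L) {
    stop("replicate pairs require >= 2 batches", call. = FALSE)
  }
  structure(d, class = "tampor_design")
}

#' The repo's standard benchmark design
#'
#' 1,000 features, 10 batches of 8 case samples + 2 GIS channels (100
#' samples), batch-effect SD 1.0, loading SD 0.5, technical noise 0.3,
#' 10% spiked features at log2 fold change 1, seed 20230412.
#'
#' @param ... Overrides passed to [simulation_design()].
#' @return A `tampor_design`.
#' @export
tampor_standard_benchmark <- function(...) {
  simulation_design(...)
}

#' The replicate-pair benchmark design
#'
#' A scaled twin of a replicated-CSF-style cohort with defective GIS
#' channels: 500 features, 40 small batches of 3 case samples + 3 GIS
#' channels, 60 donors each measured in two batches (120 case columns,
#' every sample replicated), one third cases with exact within-batch
#' balance, a sparse channel-specific GIS digestion defect of marginal SD
#' 0.5 log2, and episodic expression bursts (probability 0.25, mean
#' magnitude 1 log2) giving unrelated samples the positive correlation
#' baseline real CSF proteomes show.  Intended to be corrected with the
#' least-aggressive GIS-only mode and compared against the naive
#' intra-batch GIS-mean ratio.
#'
#' @param ... Overrides passed to [simulation_design()].
#' @return A `tampor_design`.
#' @export
tampor_replicate_benchmark <- function(...) {
  args <- list(n_features = 500L, n_batches = 40L, samples_per_batch = 3L,
               gis_per_batch = 3L, replicate_pairs = 60L, case_fraction = 1 / 3,
               gis_defect_sd = 0.5, burst_prob = 0.25)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_design, args)
}

#' @export
print.tampor_design <- function(x, ...) {
  cat("simulation design:", x$n_features, "features,", x$n_batches, "batches x (",
      x$samples_per_batch, "case +", x$gis_per_batch, "GIS ), seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an abundance dataset with ground truth
#'
#' Deterministic for a fixed seed.  Latent feature medians are drawn
#' log-normal spanning the requested dynamic range; case samples get the
#' spiked group effect; GIS channels are the equal mixture (linear-scale
#' mean) of all case sample columns, subject to the same batch effect plus
#' their own loading, noise, and optional defect; masking is applied last.
#'
#' @param design A [simulation_design()].
#' @param seed Override of the design's seed.
#' @return A list with `abundance` (feature x sample matrix), `annotation`
#'   (`sample_id`, `batch`, `is_gis`, `group`, `donor`), and `truth`
#'   (latent linear matrix, per-feature-by-batch log2 multipliers, log2
#'   loadings, log2 noise, per-GIS-channel defect, spiked feature IDs and
#'   true log2FC, replicate pair map, the design, and the annotation).
#'   Before masking, `abundance = latent * 2^(batch + loading + noise
#'   [+ defect])` exactly.
#' @export
simulate_dataset <- function(design = simulation_design(), seed = design$seed) {
  stopifnot(inherits(design, "tampor_design"))
  old <- RNGkind(design$rng$kind, design$rng$normal_kind)
  on.exit(RNGkind(old[1], old[2]), add = TRUE)
  set.seed(seed)

  nf <- design$n_features; nb <- design$n_batches
  spb <- design$samples_per_batch; gpb <- design$gis_per_batch
  feature_ids <- sprintf("F%04d", seq_len(nf))
  batch_ids <- sprintf("B%02d", seq_len(nb))

  # sample slots, batch-major; replicate donors occupy slot t and t + n/2
  n_slots <- nb * spb
  slot_batch <- rep(seq_len(nb), each = spb)
  donor_of_slot <- integer(n_slots)
  half <- n_slots %/% 2L
  r <- design$replicate_pairs
  if (r > 0L) {
    donor_of_slot[seq_len(r)] <- seq_len(r)
    donor_of_slot[half + seq_len(r)] <- seq_len(r)
  }
  fresh <- which(donor_of_slot == 0L)
  donor_of_slot[fresh] <- r + seq_along(fresh)
  n_donors <- max(donor_of_slot)

  if (design$balance_groups) {
    # systematic interleaving: donor t is a case when floor(t*f) increments,
    # which spreads cases evenly over the batch-major slot order so every
    # batch is approximately balanced
    t_seq <- seq_len(n_donors)
    donor_group <- ifelse(floor(t_seq * design$case_fraction) >
                            floor((t_seq - 1) * design$case_fraction),
                          "case", "control")
  } else {
    n_case_donors <- round(design$case_fraction * n_donors)
    case_donors <- sample(n_donors, n_case_donors)
    donor_group <- ifelse(seq_len(n_donors) %in% case_donors, "case", "control")
  }

  n_spiked <- round(design$spike_frac * nf)
  spike_idx <- sort(sample(nf, n_spiked))
  spike_ids <- feature_ids[spike_idx]

  # latent log2 medians spanning the requested dynamic range
  mu <- stats::rnorm(nf, design$base_log2_level,
                     design$dynamic_range_orders * log2(10) / 4)

  # latent linear columns for case samples (replicates share a donor column)
  latent_log2_slot <- matrix(mu, nf, n_slots)
  spike_effect <- matrix(0, nf, n_slots)
  is_case_slot <- donor_group[donor_of_slot] == "case"
  spike_effect[spike_idx, is_case_slot] <- design$spike_log2fc
  latent_log2_slot <- latent_log2_slot + spike_effect
  if (design$burst_prob > 0) {
    # one-sided episodic elevation: feature i bursts in donor d with
    # probability burst_prob, by a feature-specific log-normal magnitude;
    # replicates of a donor share its bursts (biology, not technique)
    h <- stats::rgamma(nf, shape = 2, rate = 2 / design$burst_log2_scale)
    bursts <- matrix(stats::runif(nf * n_donors) < design$burst_prob, nf, n_donors)
    latent_log2_slot <- latent_log2_slot +
      (bursts * h)[, donor_of_slot, drop = FALSE]
  }
  latent_slot <- 2^latent_log2_slot

  # GIS latent: equal physical mixture of all case sample columns
  gis_latent <- rowMeans(latent_slot)

  # ids and column layout: within each batch, case samples then GIS
  sample_ids <- character(0)
  col_batch <- character(0); col_is_gis <- logical(0); col_donor <- integer(0)
  col_latent <- NULL
  slot_counter <- split(seq_len(n_slots), slot_batch)
  for (b in seq_len(nb)) {
    slots_b <- slot_counter[[b]]
    ids_b <- sprintf("%s.S%d", batch_ids[b], seq_along(slots_b))
    sample_ids <- c(sample_ids, ids_b)
    col_batch <- c(col_batch, rep(batch_ids[b], length(slots_b)))
    col_is_gis <- c(col_is_gis, rep(FALSE, length(slots_b)))
    col_donor <- c(col_donor, donor_of_slot[slots_b])
    col_latent <- cbind(col_latent, latent_slot[, slots_b, drop = FALSE])
    if (gpb > 0L) {
      gis_ids <- sprintf("%s.GIS%d", batch_ids[b], seq_len(gpb))
      sample_ids <- c(sample_ids, gis_ids)
      col_batch <- c(col_batch, rep(batch_ids[b], gpb))
      col_is_gis <- c(col_is_gis, rep(TRUE, gpb))
      col_donor <- c(col_donor, rep(NA_integer_, gpb))
      col_latent <- cbind(col_latent, matrix(gis_latent, nf, gpb))
    }
  }
  ncol_total <- length(sample_ids)
  dimnames(col_latent) <- list(feature_ids, sample_ids)

  batch_log2 <- matrix(stats::rnorm(nf * nb, 0, design$batch_effect_sd), nf, nb,
                       dimnames = list(feature_ids, batch_ids))
  loading_log2 <- stats::setNames(stats::rnorm(ncol_total, 0, design$loading_sd),
                                  sample_ids)
  noise_log2 <- matrix(stats::rnorm(nf * ncol_total, 0, design$technical_noise_sd),
                       nf, ncol_total, dimnames = list(feature_ids, sample_ids))

  n_gis_cols <- sum(col_is_gis)
  defect_log2 <- matrix(0, nf, n_gis_cols,
                        dimnames = list(feature_ids, sample_ids[col_is_gis]))
  if (design$gis_defect_sd > 0 && n_gis_cols > 0) {
    hit <- matrix(stats::runif(nf * n_gis_cols) < design$gis_defect_frac,
                  nf, n_gis_cols)
    mag <- matrix(stats::rnorm(nf * n_gis_cols, 0,
                               design$gis_defect_sd / sqrt(design$gis_defect_frac)),
                  nf, n_gis_cols)
    defect_log2[hit] <- mag[hit]
  }

  batch_idx <- match(col_batch, batch_ids)
  log2_obs <- log2(col_latent) + batch_log2[, batch_idx] +
    matrix(loading_log2, nf, ncol_total, byrow = TRUE) + noise_log2
  log2_obs[, col_is_gis] <- log2_obs[, col_is_gis] + defect_log2
  abundance <- 2^log2_obs

  # masking, applied last
  if (design$missing_batchwise > 0) {
    drop <- matrix(stats::runif(nf * nb) < design$missing_batchwise, nf, nb)
    for (b in seq_len(nb)) abundance[drop[, b], batch_idx == b] <- NA_real_
  }
  if (design$missing_frac_random > 0) {
    if (design$mnar) {
      # left-tail-biased: masking probability decreases linearly with the
      # value's rank within its row, mean probability = missing_frac_random
      rk <- t(apply(abundance, 1L, rank, na.last = "keep"))
      pm <- design$missing_frac_random * 2 * (1 - (rk - 0.5) / ncol_total)
      pm[is.na(pm)] <- 0
      mask <- matrix(stats::runif(nf * ncol_total), nf, ncol_total) < pm
    } else {
      mask <- matrix(stats::runif(nf * ncol_total) < design$missing_frac_random,
                     nf, ncol_total)
    }
    abundance[mask] <- NA_real_
  }

  annotation <- data.frame(sample_id = sample_ids, batch = col_batch,
                           is_gis = col_is_gis,
                           group = ifelse(col_is_gis, NA_character_,
                                          donor_group[col_donor]),
                           donor = ifelse(col_is_gis, NA_character_,
                                          sprintf("D%03d", col_donor)),
                           stringsAsFactors = FALSE)

  replicate_map <- NULL
  if (r > 0L) {
    nongis_ids <- sample_ids[!col_is_gis]
    nongis_donor <- col_donor[!col_is_gis]
    replicate_map <- do.call(rbind, lapply(seq_len(r), function(d) {
      s <- nongis_ids[nongis_donor == d]
      data.frame(donor = sprintf("D%03d", d), sample_1 = s[1], sample_2 = s[2],
                 stringsAsFactors = FALSE)
    }))
  }

  truth <- list(latent = col_latent, batch_log2 = batch_log2,
                loading_log2 = loading_log2, noise_log2 = noise_log2,
                gis_defect_log2 = defect_log2,
                spike_features = spike_ids, spike_log2fc = design$spike_log2fc,
                replicate_map = replicate_map,
                annotation = annotation, design = design, seed = seed)
  list(abundance = abundance, annotation = annotation, truth = truth)
}

#' Simulate a multi-platform dataset sharing one latent proteome
#'
#' Each platform observes a monotone power-law transform of the shared
#' latent sample profiles for its feature panel
#' (`observed = scale * latent^gamma * 2^noise`); a designated feature
#' subset (the bridging set) appears on every platform.  Data are complete
#' (no missingness), and assay rows are named `feature@platform`.
#'
#' @param design A [simulation_design()]; its feature/spike/group fields
#'   define the latent proteome, its `samples_per_batch * n_batches` the
#'   number of individuals.  Batch and loading effects are not applied (the
#'   platform transform is the "batch" here).
#' @param n_platforms Number of platforms (>= 2).
#' @param panel_size Assays per platform (bridging set included).
#' @param n_shared Size of the bridging set (must not exceed `panel_size`
#'   or the latent feature count).
#' @param gamma Power-law exponents per platform (default spread over
#'   0.6-1.4).
#' @param scale_log2_sd SD of the per-platform log2 scale offset.
#' @param noise_sd Per-value log2 noise SD on each platform.
#' @param seed Override of the design's seed.
#' @return A list: `abundance` (assays x samples), `platform_map`
#'   (data.frame `feature_id` = assay ID, `platform`, `base_feature`),
#'   `common_feature_ids`, `truth` (latent matrix, gammas, scales, design).
#' @export
make_multiplatform <- function(design = simulation_design(), n_platforms = 3L,
                               panel_size = 200L, n_shared = 50L,
                               gamma = NULL, scale_log2_sd = 2,
                               noise_sd = 0.2, seed = design$seed) {
  stopifnot(inherits(design, "tampor_design"))
  n_platforms <- as.integer(n_platforms)
  if (n_platforms < 2L) stop("need >= 2 platforms", call. = FALSE)
  if (n_shared > panel_size) {
    stop("bridging set (", n_shared, ") larger than the platform panel (",
         panel_size, ")", call. = FALSE)
  }
  need <- n_shared + n_platforms * (panel_size - n_shared)
  if (need > design$n_features) {
    stop("design has ", design$n_features, " features but the panels need ", need,
         call. = FALSE)
  }
  old <- RNGkind(design$rng$kind, design$rng$normal_kind)
  on.exit(RNGkind(old[1], old[2]), add = TRUE)
  set.seed(seed)

  nf <- design$n_features
  n_samples <- design$n_batches * design$samples_per_batch
  feature_ids <- sprintf("P%04d", seq_len(nf))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  platforms <- sprintf("platform%d", seq_len(n_platforms))
  if (is.null(gamma)) gamma <- seq(0.6, 1.4, length.out = n_platforms)
  if (length(gamma) != n_platforms) stop("need one gamma per platform", call. = FALSE)

  mu <- stats::rnorm(nf, design$base_log2_level,
                     design$dynamic_range_orders * log2(10) / 4)
  n_case <- round(design$case_fraction * n_samples)
  group <- ifelse(seq_len(n_samples) %in% sample(n_samples, n_case), "case", "control")
  spike_idx <- sort(sample(nf, round(design$spike_frac * nf)))
  latent_log2 <- matrix(mu, nf, n_samples, dimnames = list(feature_ids, sample_ids))
  latent_log2[spike_idx, group == "case"] <-
    latent_log2[spike_idx, group == "case"] + design$spike_log2fc
  latent <- 2^latent_log2

  shared_idx <- seq_len(n_shared)
  remaining <- setdiff(seq_len(nf), shared_idx)
  scales <- stats::rnorm(n_platforms, 0, scale_log2_sd)
  blocks <- list(); map <- list()
  offset <- 0L
  for (p in seq_len(n_platforms)) {
    own <- remaining[offset + seq_len(panel_size - n_shared)]
    offset <- offset + (panel_size - n_shared)
    panel <- c(shared_idx, own)
    obs_log2 <- gamma[p] * latent_log2[panel, , drop = FALSE] + scales[p] +
      matrix(stats::rnorm(length(panel) * n_samples, 0, noise_sd),
             length(panel), n_samples)
    assay_ids <- paste0(feature_ids[panel], "@", platforms[p])
    rownames(obs_log2) <- assay_ids
    blocks[[p]] <- 2^obs_log2
    map[[p]] <- data.frame(feature_id = assay_ids, platform = platforms[p],
                           base_feature = feature_ids[panel],
                           stringsAsFactors = FALSE)
  }
  abundance <- do.call(rbind, blocks)
  platform_map <- do.call(rbind, map)
  list(abundance = abundance, platform_map = platform_map,
       common_feature_ids = feature_ids[shared_idx],
       truth = list(latent = latent, gamma = gamma, scale_log2 = scales,
                    group = stats::setNames(group, sample_ids),
                    spike_features = feature_ids[spike_idx], design = design,
                    seed = seed))
}

#' Score a correction against simulation ground truth
#'
#' Reports (a) the per-feature variance fraction explained by batch after
#' correction (median and mean over features, non-GIS samples), (b) the
#' error of estimated spiked log2 fold changes against truth (RMSE and
#' median absolute error), and (c) the per-batch dispersion of
#' corrected/latent log2 ratios (median over features of the SD across
#' batches of per-batch median offsets; 0 means batch structure fully
#' removed).
#'
#' @param corrected Corrected abundance matrix (features may be a subset of
#'   the simulated ones, e.g. after filtering).
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @return A list: `batch_fraction_median`, `batch_fraction_mean`,
#'   `spike_log2fc_rmse`, `spike_log2fc_mae`, `spike_log2fc_estimates`,
#'   `batch_dispersion`.
#' @export
evaluate_recovery <- function(corrected, truth) {
  assert_abundance(corrected)
  ann <- truth$annotation
  if (!all(colnames(corrected) %in% ann$sample_id)) {
    stop("corrected matrix contains samples unknown to the ground truth", call. = FALSE)
  }
  if (!all(rownames(corrected) %in% rownames(truth$latent))) {
    stop("corrected matrix contains features unknown to the ground truth", call. = FALSE)
  }
  ann <- ann[match(colnames(corrected), ann$sample_id), , drop = FALSE]
  nongis <- ann$sample_id[!ann$is_gis]
  log2c <- log2(corrected)

  vp <- variance_explained(log2c[, nongis, drop = FALSE], ann[!ann$is_gis, ], "batch")
  batch_fraction_median <- stats::median(vp$batch)
  batch_fraction_mean <- mean(vp$batch)

  spike_rmse <- NA_real_; spike_mae <- NA_real_; est <- NULL
  groups <- unique(stats::na.omit(ann$group[!ann$is_gis]))
  spikes <- intersect(truth$spike_features, rownames(corrected))
  if (all(c("case", "control") %in% groups) && length(spikes)) {
    case <- ann$sample_id[!ann$is_gis & !is.na(ann$group) & ann$group == "case"]
    ctrl <- ann$sample_id[!ann$is_gis & !is.na(ann$group) & ann$group == "control"]
    est <- rowMeans(log2c[spikes, case, drop = FALSE], na.rm = TRUE) -
      rowMeans(log2c[spikes, ctrl, drop = FALSE], na.rm = TRUE)
    err <- est - truth$spike_log2fc
    spike_rmse <- sqrt(mean(err^2, na.rm = TRUE))
    spike_mae <- stats::median(abs(err), na.rm = TRUE)
  }

  latent <- truth$latent[rownames(corrected), colnames(corrected), drop = FALSE]
  rel <- log2c - log2(latent)
  rel <- rel - row_medians(rel)
  batch_of <- ann$batch
  per_batch <- vapply(unique(batch_of), function(b) {
    row_medians(rel, which(batch_of == b))
  }, numeric(nrow(rel)))
  disp <- apply(per_batch, 1L, stats::sd, na.rm = TRUE)
  batch_dispersion <- stats::median(disp, na.rm = TRUE)

  list(batch_fraction_median = batch_fraction_median,
       batch_fraction_mean = batch_fraction_mean,
       spike_log2fc_rmse = spike_rmse,
       spike_log2fc_mae = spike_mae,
       spike_log2fc_estimates = stats::setNames(est, spikes),
       batch_dispersion = batch_dispersion)
}
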