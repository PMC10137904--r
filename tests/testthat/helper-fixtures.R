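# Shared fixtures and small builders.  Everything is generated in code;
# expensive benchmark runs are memoised so several tests can share them.

toy_matrix <- function(nf = 6, ns = 4, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(2^rnorm(nf * ns, 10, sd), nf, ns,
         dimnames = list(sprintf("f%02d", seq_len(nf)), sprintf("s%02d", seq_len(ns))))
}

toy_annotation <- function(m, batches = 1, gis_per_batch = 0) {
  ns <- ncol(m)
  batch <- rep(sprintf("b%d", seq_len(batches)), length.out = ns)
  batch <- sort(batch)
  is_gis <- logical(ns)
  if (gis_per_batch > 0) {
    for (b in unique(batch)) {
      idx <- which(batch == b)
      is_gis[utils::tail(idx, gis_per_batch)] <- TRUE
    }
  }
  data.frame(sample_id = colnames(m), batch = batch, is_gis = is_gis,
             stringsAsFactors = FALSE)
}

# memoised expensive runs shared across test files
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

standard_benchmark_run <- function() {
  cached("standard_run", {
    ds <- simulate_dataset(tampor_standard_benchmark())
    fit <- run_tampor(ds$abundance, ds$annotation, tampor_config("useAllNonGIS"))
    list(dataset = ds, fit = fit)
  })
}

recovery_benchmark_run <- function() {
  cached("recovery_run", {
    ds <- simulate_dataset(simulation_design(n_batches = 5))  # 20 cases per group
    fit <- run_tampor(ds$abundance, ds$annotation, tampor_config("useAllNonGIS"))
    list(dataset = ds, fit = fit)
  })
}
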