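# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Toy-genome study state: 100-sample panel of 5 M reads (the generator's
# default conditions), trained reference model.
toy_state <- function() {
  memo("toy", function() {
    spec <- synthetic_spec(seed = 11L, reads_per_sample = 5e6)
    panel <- make_panel(spec)
    model <- train_reference_model(panel$samples, panel$genome$gc,
                                   panel$genome$grid)
    list(spec = spec, panel = panel, genome = panel$genome, model = model)
  })
}

# Genome-scale study state for the in-silico accuracy checks: hg19
# chromosome sizes, 100 training samples, 10 CNV-free test samples of
# 11 M reads (so they can be downsampled to 10 M).
hg19_state <- function() {
  memo("hg19", function() {
    spec <- synthetic_spec(genome = hg19_chrom_sizes(), n_samples = 100L,
                           reads_per_sample = 1.1e7, seed = 101L)
    genome <- make_reference_genome(spec)
    panel <- make_panel(spec, genome = genome)
    model <- train_reference_model(panel$samples, genome$gc, genome$grid)
    test_samples <- lapply(1:10, function(s)
      make_case(spec, list(), genome = genome, seed = 2000L + s,
                sample_id = sprintf("test_%02d", s))$sample)
    list(spec = spec, genome = genome, model = model,
         test_samples = test_samples)
  })
}

# A tiny single-chromosome grid for constructed-profile tests.
tiny_grid <- function(n_bins = 200, bin_size = 20000,
                      name = "chr1") {
  build_bin_grid(data.frame(name = name, length = n_bins * bin_size),
                 bin_size = bin_size)
}

# Wrap a numeric vector as a normalized profile on `grid`.
make_profile <- function(values, grid, mask = rep(TRUE, grid$n_bins),
                         m = 100, sample_id = "constructed") {
  v <- values
  v[!mask] <- NA_real_
  structure(list(sample_id = sample_id, values = v, mask = mask,
                 reason = ifelse(mask, NA_character_, "manual"),
                 mean_bin_count = m, grid = grid,
                 fingerprint = grid$fingerprint),
            class = "normalized_profile")
}

# Wrap per-bin values as GC-corrected scaled counts (train input).
make_scaled <- function(values, grid, sample_id = "s",
                        targets = compartment_targets(grid)) {
  structure(list(sample_id = sample_id, values = values,
                 scale_factors = NULL, targets = targets,
                 unusable_compartments = character(0),
                 fingerprint = grid$fingerprint, gc_corrected = TRUE),
            class = "scaled_bin_counts")
}

# Uniform GC track (GC defined everywhere) for constructed grids.
flat_gc <- function(grid, gc = 0.45) {
  structure(list(gc = rep(gc, grid$n_bins),
                 defined_frac = rep(1, grid$n_bins),
                 fingerprint = grid$fingerprint),
            class = "gc_track")
}

# Allowance for the chromosome-mean shift of the generator's smooth
# rank-k artifact on a single sample: the loadings are AR(0.95) series
# (correlation mass (1+phi)/(1-phi) = 39), so a chromosome of n bins
# retains a mean artifact of sd scale * m * sqrt(39 / n) per unit factor.
# The PCA removes this on autosomes but not on chrX/chrY; using the
# truth factors keeps the centering check sharp everywhere else.
artifact_mean_allowance <- function(spec, factors, n_bins, m = 100) {
  3 * spec$artifact_scale * m * sqrt(39 / n_bins) *
    sqrt(sum(factors^2))
}

# Standard error of a mean that is robust to short-range autocorrelation
# (sd of block means over blocks of `block` bins).
block_se <- function(v, block = 25) {
  v <- v[!is.na(v)]
  nb <- floor(length(v) / block)
  if (nb < 2) return(sd(v) / sqrt(length(v)))
  bm <- vapply(seq_len(nb), function(b)
    mean(v[((b - 1) * block + 1):(b * block)]), 0)
  sd(bm) / sqrt(nb)
}

# Independent exhaustive oracle for the first CBS split: maximize the
# standardized arc-vs-complement mean difference over every arc by
# direct enumeration of means.
oracle_max_arc <- function(x) {
  n <- length(x)
  s <- sqrt(mean((x - mean(x))^2))
  best <- list(t = 0, i = NA, j = NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      t <- abs(mean(arc) - mean(rest)) / (s * sqrt(1 / k + 1 / (n - k)))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}
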