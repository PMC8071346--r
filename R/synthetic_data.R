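# Synthetic low-coverage WGS bin counts with the statistical structure
# the pipeline assumes: a GC-dependent multiplicative bias, low-rank
# cross-sample artifacts (shared per-bin loadings times per-sample
# factors), unmappable zero-rate regions, highly variable regions, and
# Poisson counting noise.

#' GRCh37/hg19 chromosome sizes
#'
#' Canonical autosomes plus X and Y; used for genome-scale simulations.
#' @return data.frame with columns `name`, `length`.
#' @export
hg19_chrom_sizes <- function() {
  data.frame(
    name = paste0("chr", c(1:22, "X", "Y")),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560, 59373566),
    stringsAsFactors = FALSE)
}

toy_chrom_sizes <- function() {
  data.frame(name = c("chr1", "chr2", "chr3", "chrX", "chrY"),
             length = c(20e6, 16e6, 12e6, 8e6, 4e6),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic sample panel
#'
#' Defaults describe a ~60 Mb toy genome (3 autosomes + X + Y) at 20 kb
#' bins with 100 samples of 10 M reads each: GC bias peaking near GC
#' 0.45, three low-rank artifact factors, 10% unmappable bins and 3%
#' highly variable bins. Sex chromosomes are simulated at half the
#' autosomal rate (one copy each, male-like).
#'
#' @param genome data.frame (name, length); default the toy genome; use
#'   [hg19_chrom_sizes()] for genome-scale runs.
#' @param bin_size bin width in bp.
#' @param n_samples panel size.
#' @param reads_per_sample expected total read count per sample.
#' @param gc_peak,gc_width,gc_strength GC-bias curve parameters: the
#'   relative rate is `exp(-gc_strength * ((gc - gc_peak)/gc_width)^2)`.
#' @param artifact_rank number of planted artifact factors.
#' @param artifact_scale per-bin loading standard deviation (log scale).
#' @param unmappable_fraction fraction of bins with zero rate, placed in
#'   centromere-like blocks.
#' @param high_variance_fraction fraction of bins with extra per-sample
#'   lognormal noise.
#' @param high_variance_sd log-sd of that extra noise.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @param seed seed fixing the genome layout and all draws.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome = toy_chrom_sizes(),
                           bin_size = 20000L,
                           n_samples = 100L,
                           reads_per_sample = 1e7,
                           gc_peak = 0.45, gc_width = 0.35,
                           gc_strength = 0.5,
                           artifact_rank = 3L,
                           artifact_scale = 0.015,
                           unmappable_fraction = 0.10,
                           high_variance_fraction = 0.03,
                           high_variance_sd = 0.5,
                           overdispersion = 0,
                           seed = 1L) {
  stop_if(unmappable_fraction < 0 || unmappable_fraction > 1 ||
            high_variance_fraction < 0 || high_variance_fraction > 1,
          "fractions must be in [0, 1]")
  stop_if(artifact_rank >= n_samples, "artifact_rank must be < n_samples")
  stop_if(reads_per_sample <= 0, "reads_per_sample must be positive")
  structure(as.list(environment()), class = "synthetic_spec")
}

ar1_smooth <- function(n, phi, seed_offset = 0) {
  # stationary AR(1) series, unit marginal sd
  z <- numeric(n)
  innov_sd <- sqrt(1 - phi^2)
  z[1] <- rnorm(1)
  if (n > 1) for (i in 2:n) z[i] <- phi * z[i - 1] + rnorm(1, sd = innov_sd)
  z
}

#' Generate a synthetic reference genome layout
#'
#' Builds the bin grid, a smooth per-bin GC track in [0.3, 0.7],
#' centromere-like unmappable blocks (zero rate), highly variable bins,
#' and the per-bin loadings of the planted low-rank artifact factors.
#' Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `grid`, `gc` (a `gc_track`), `base_rate`,
#'   `gc_mult`, `loadings`, `unmappable`, `high_variance` and the spec.
#' @export
make_reference_genome <- function(spec) {
  grid <- build_bin_grid(spec$genome, spec$bin_size)
  n <- grid$n_bins
  with_seed(spec$seed, {
    gc <- numeric(n)
    for (cn in grid$chromosomes$name) {
      rows <- which(grid$bins$chrom == cn)
      z <- ar1_smooth(length(rows), phi = 0.98)
      gc[rows] <- 0.5 + 0.4 * (pnorm(z) - 0.5)
    }
    unmappable <- logical(n)
    if (spec$unmappable_fraction > 0) {
      target <- round(spec$unmappable_fraction * n)
      while (sum(unmappable) < target) {
        len <- 1L + rgeom(1, 1 / 5)
        at <- sample.int(n, 1L)
        idx <- at:min(n, at + len - 1L)
        idx <- idx[grid$bins$chrom[idx] == grid$bins$chrom[at]]
        idx <- idx[!unmappable[idx]]
        idx <- idx[seq_len(min(length(idx), target - sum(unmappable)))]
        unmappable[idx] <- TRUE
      }
    }
    hv <- logical(n)
    pool <- which(!unmappable)
    n_hv <- round(spec$high_variance_fraction * n)
    if (n_hv > 0) hv[sample(pool, min(n_hv, length(pool)))] <- TRUE
    loadings <- if (spec$artifact_rank > 0)
      vapply(seq_len(spec$artifact_rank),
             function(k) ar1_smooth(n, phi = 0.95) * spec$artifact_scale,
             numeric(n))
    else matrix(0, n, 0)
  })
  width_frac <- (grid$bins$end - grid$bins$start) / grid$bin_size
  copy <- ifelse(grid$bins$compartment == "autosome", 1, 0.5)
  base_rate <- width_frac * copy * as.numeric(!unmappable)
  gc_mult <- exp(-spec$gc_strength * ((gc - spec$gc_peak) / spec$gc_width)^2)
  gc_track <- structure(list(gc = gc, defined_frac = rep(1, n),
                             fingerprint = grid$fingerprint),
                        class = "gc_track")
  list(grid = grid, gc = gc_track, base_rate = base_rate,
       gc_mult = gc_mult, loadings = loadings, unmappable = unmappable,
       high_variance = hv, spec = spec)
}

simulate_counts <- function(genome, factors, cnv_mult, sample_id) {
  spec <- genome$spec
  lograte <- log(pmax(genome$base_rate * genome$gc_mult, 0))
  if (length(factors) > 0)
    lograte <- lograte + as.numeric(genome$loadings %*% factors)
  if (any(genome$high_variance))
    lograte[genome$high_variance] <- lograte[genome$high_variance] +
      rnorm(sum(genome$high_variance), sd = spec$high_variance_sd)
  rate <- exp(lograte)
  rate[genome$base_rate == 0] <- 0
  lambda <- spec$reads_per_sample * rate / sum(rate) * cnv_mult
  counts <- if (spec$overdispersion > 0)
    rnbinom(length(lambda), mu = lambda, size = 1 / spec$overdispersion)
  else rpois(length(lambda), lambda)
  new_raw_bin_counts(counts, genome$grid, sample_id)
}

#' Generate a CNV-free reference panel
#'
#' Per-bin expected count = base rate x GC bias x
#' exp(loadings x per-sample factors) x mappability, with Poisson (or
#' negative-binomial) noise. Truth (factors, loadings, masks) is
#' returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param genome optional [make_reference_genome()] output (built from
#'   the spec if missing).
#' @param seed seed for the sample draws (default derived from the
#'   spec's seed).
#' @return list with `samples` (list of `raw_bin_counts`), `factors`
#'   (n_samples x rank matrix) and `genome`.
#' @export
make_panel <- function(spec, genome = NULL, seed = spec$seed + 1L) {
  if (is.null(genome)) genome <- make_reference_genome(spec)
  with_seed(seed, {
    factors <- matrix(rnorm(spec$n_samples * spec$artifact_rank),
                      spec$n_samples, spec$artifact_rank)
    samples <- lapply(seq_len(spec$n_samples), function(s)
      simulate_counts(genome, factors[s, ], 1,
                      sample_id = sprintf("panel_%03d", s)))
  })
  list(samples = samples, factors = factors, genome = genome)
}

#' Generate a test sample with planted CNVs
#'
#' Same generative model as [make_panel()], with expected counts
#' multiplied over the CNV regions before the noise draw. With an empty
#' CNV list the sample is exchangeable with a panel sample.
#'
#' @param spec a [synthetic_spec()].
#' @param cnvs list of [simulated_cnv()] (may be empty).
#' @param genome optional prebuilt genome.
#' @param seed seed for this sample's draws.
#' @param sample_id label.
#' @return list with `sample` (a `raw_bin_counts`), `cnvs`, `factors`
#'   and `genome`.
#' @export
make_case <- function(spec, cnvs = list(), genome = NULL,
                      seed = spec$seed + 1000L, sample_id = "case") {
  if (is.null(genome)) genome <- make_reference_genome(spec)
  grid <- genome$grid
  mult <- rep(1, grid$n_bins)
  for (cnv in cnvs) {
    rows <- which(grid$bins$chrom == cnv$chrom &
                    grid$bins$start >= cnv$start_bp &
                    grid$bins$end <= cnv$end_bp)
    stop_if(length(rows) == 0, "CNV outside grid")
    mult[rows] <- cnv$multiplier
  }
  with_seed(seed, {
    factors <- rnorm(spec$artifact_rank)
    sample <- simulate_counts(genome, factors, mult, sample_id)
  })
  list(sample = sample, cnvs = cnvs, factors = factors, genome = genome)
}
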