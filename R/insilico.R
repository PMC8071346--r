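# In-silico accuracy framework: downsample real or synthetic samples,
# inject CNVs by bin multiplication (mapping happens once per sample),
# rerun the caller unchanged, and tabulate detection and coordinate
# accuracy over a (CNV length x read count) grid.

#' Downsample a sample to a target read count
#'
#' Each bin's count is replaced by a binomial draw with success
#' probability `target_reads / total_counted` — distributionally
#' equivalent to thinning the read stream before binning.
#'
#' @param raw a `raw_bin_counts`.
#' @param target_reads target total read count; must not exceed the
#'   sample's `total_counted`.
#' @param seed optional seed for a reproducible draw.
#' @return a `raw_bin_counts` with thinned counts.
#' @export
downsample_counts <- function(raw, target_reads, seed = NULL) {
  stop_if(target_reads > raw$total_counted,
          "target_reads exceeds available reads")
  q <- target_reads / raw$total_counted
  out <- raw
  if (q < 1) {
    out$counts <- with_seed(seed,
                            rbinom(length(raw$counts), raw$counts, q))
    out$total_counted <- sum(out$counts)
  }
  out
}

#' A simulated CNV
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp 0-based half-open, bin-aligned coordinates.
#' @param multiplier copy multiplier: 0.5 single-copy loss, 1.5
#'   single-copy gain.
#' @return list of class `simulated_cnv`.
#' @export
simulated_cnv <- function(chrom, start_bp, end_bp, multiplier) {
  stop_if(end_bp <= start_bp, "empty CNV region")
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 length_bp = end_bp - start_bp, multiplier = multiplier),
            class = "simulated_cnv")
}

eligible_window_starts <- function(grid, mask, n_bins_window) {
  # start indices (global) of windows of n consecutive usable autosomal
  # bins of full width, within one chromosome
  ok <- mask & grid$bins$compartment == "autosome" &
    (grid$bins$end - grid$bins$start) == grid$bin_size
  n <- grid$n_bins
  w <- n_bins_window
  if (w > n) return(integer(0))
  cs <- cumsum(ok)
  first <- seq_len(n - w + 1L)
  all_ok <- (cs[first + w - 1L] - c(0, cs)[first]) == w
  same_chrom <- grid$bins$chrom[first] == grid$bins$chrom[first + w - 1L]
  which(all_ok & same_chrom)
}

#' Sample a random CNV placement avoiding filtered bins
#'
#' Uniform over all bin-aligned autosomal windows of the requested
#' length whose bins are all unfiltered.
#'
#' @param grid a grid.
#' @param mask usable-bin logical vector (e.g. `model$mask`).
#' @param length_bp CNV length; must be a multiple of the bin size.
#' @param multiplier copy multiplier for the returned CNV (default 0.5).
#' @param seed optional seed.
#' @return a [simulated_cnv()].
#' @export
sample_random_region <- function(grid, mask, length_bp, multiplier = 0.5,
                                 seed = NULL) {
  stop_if(length_bp %% grid$bin_size != 0,
          "length_bp must be a multiple of the bin size")
  w <- as.integer(length_bp / grid$bin_size)
  starts <- eligible_window_starts(grid, mask, w)
  stop_if(length(starts) == 0,
          "no eligible placement for the requested length")
  i <- with_seed(seed, starts[sample.int(length(starts), 1L)])
  simulated_cnv(grid$bins$chrom[i], grid$bins$start[i],
                grid$bins$start[i] + length_bp, multiplier)
}

#' Inject a CNV into bin counts by multiplication
#'
#' Counts of the member bins are multiplied by the CNV's multiplier
#' (real-valued result retained; the downstream pipeline is real-valued
#' after scaling); all other bins are untouched.
#'
#' @param raw a `raw_bin_counts`.
#' @param cnv a [simulated_cnv()].
#' @param grid the grid.
#' @param mask optional usable-bin vector; if given, overlap with a
#'   filtered bin is an error.
#' @return a `raw_bin_counts` with modified counts.
#' @export
inject_cnv <- function(raw, cnv, grid, mask = NULL) {
  rows <- which(grid$bins$chrom == cnv$chrom &
                  grid$bins$start >= cnv$start_bp &
                  grid$bins$end <= cnv$end_bp)
  stop_if(length(rows) == 0, "CNV region outside grid")
  stop_if(!is.null(mask) && any(!mask[rows]),
          "CNV region overlaps filtered bins")
  out <- raw
  out$counts[rows] <- out$counts[rows] * cnv$multiplier
  out$total_counted <- sum(out$counts)
  out
}

#' Score one injected CNV against a call set
#'
#' `detected`: some non-green call of matching sign overlaps the truth
#' by at least 1 bp. `exact`: such a call has both boundaries equal to
#' the truth's. `within_one_bin`: both boundaries within one bin width
#' of the truth's. Exact match of coordinates is not required for
#' detection.
#'
#' @param truth a [simulated_cnv()].
#' @param calls classified segments from [call_cnvs()].
#' @param bin_size bin width in bp.
#' @return logical list `detected`, `exact`, `within_one_bin`.
#' @export
score_detection <- function(truth, calls, bin_size) {
  want <- if (truth$multiplier < 1) "deletion" else "duplication"
  hits <- calls[calls$significance != "green" &
                  calls$call_type == want &
                  calls$chrom == truth$chrom &
                  calls$start_bp < truth$end_bp &
                  calls$end_bp > truth$start_bp, , drop = FALSE]
  detected <- nrow(hits) > 0
  exact <- any(hits$start_bp == truth$start_bp &
                 hits$end_bp == truth$end_bp)
  within <- any(abs(hits$start_bp - truth$start_bp) <= bin_size &
                  abs(hits$end_bp - truth$end_bp) <= bin_size)
  list(detected = detected, exact = exact, within_one_bin = within)
}

#' Enumerate an in-silico grid design before running it
#'
#' @param n_samples number of base samples.
#' @param lengths CNV lengths (bp).
#' @param read_counts target read counts.
#' @param n_variants random CNVs per (sample, cell).
#' @return list with the per-cell data.frame `cells` and the total
#'   planned trial count `n_trials`.
#' @export
plan_insilico_grid <- function(n_samples, lengths, read_counts, n_variants) {
  cells <- expand.grid(variation_length = lengths, read_count = read_counts)
  cells$n_trials <- n_samples * n_variants
  list(cells = cells, n_trials = sum(cells$n_trials))
}

#' Run the in-silico detection-accuracy grid
#'
#' For every (CNV length, read count) cell, each base sample is
#' downsampled to the target read count, `n_variants` random single-copy
#' CNVs (alternating loss and gain) are injected one at a time, the
#' sample is normalized and called without changes, and the result is
#' scored against the injected truth. Fractions are aggregated over
#' samples x variants.
#'
#' @param base_samples list of CNV-free `raw_bin_counts`.
#' @param lengths CNV lengths in bp (bin-aligned).
#' @param read_counts target read counts.
#' @param n_variants random CNVs per sample per cell.
#' @param model trained [train_reference_model()] model.
#' @param gc GC track.
#' @param seed master seed; every trial's randomness derives from it.
#' @param params [cbs_params()] for the caller.
#' @return data.frame of accuracy cells: `variation_length`,
#'   `read_count`, `n_trials`, `detected_fraction`,
#'   `exact_match_fraction`, `within_one_bin_fraction`.
#' @export
run_insilico_grid <- function(base_samples, lengths, read_counts,
                              n_variants, model, gc, seed = 1L,
                              params = cbs_params()) {
  stop_if(length(lengths) == 0 || length(read_counts) == 0,
          "lengths and read_counts must be non-empty")
  grid <- model$grid
  plan <- plan_insilico_grid(length(base_samples), lengths, read_counts,
                             n_variants)
  cells <- plan$cells
  cells$detected_fraction <- NA_real_
  cells$exact_match_fraction <- NA_real_
  cells$within_one_bin_fraction <- NA_real_

  # eligible placements depend only on (grid, mask, length): cache them
  starts_by_len <- lapply(lengths, function(len)
    eligible_window_starts(grid, model$mask,
                           as.integer(len / grid$bin_size)))
  names(starts_by_len) <- as.character(lengths)

  with_seed(seed, {
    for (ci in seq_len(nrow(cells))) {
      len <- cells$variation_length[ci]
      rc <- cells$read_count[ci]
      starts <- starts_by_len[[as.character(len)]]
      stop_if(length(starts) == 0,
              "no eligible placement for length ", len)
      det <- ex <- w1 <- 0L
      for (s in seq_along(base_samples)) {
        ds <- downsample_counts(base_samples[[s]], rc)
        for (v in seq_len(n_variants)) {
          mult <- if (v %% 2 == 1) 0.5 else 1.5
          i <- starts[sample.int(length(starts), 1L)]
          cnv <- simulated_cnv(grid$bins$chrom[i], grid$bins$start[i],
                               grid$bins$start[i] + len, mult)
          injected <- inject_cnv(ds, cnv, grid)
          prof <- normalize_sample(injected, gc, model)
          # every cell metric is a property of calls overlapping the
          # injected region, so only its chromosome needs segmenting
          calls <- call_cnvs(prof, params, chromosomes = cnv$chrom)
          sc <- score_detection(cnv, calls, grid$bin_size)
          det <- det + sc$detected
          ex <- ex + sc$exact
          w1 <- w1 + sc$within_one_bin
        }
      }
      n <- cells$n_trials[ci]
      cells$detected_fraction[ci] <- det / n
      cells$exact_match_fraction[ci] <- ex / n
      cells$within_one_bin_fraction[ci] <- w1 / n
    }
  })
  cells
}
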