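#' LOESS GC-bias correction
#'
#' Fits a locally weighted regression of scaled bin count on GC fraction
#' over autosomal bins with defined GC, per sample, and multiplies each
#' bin's count by `median(fitted) / fitted(GC)`. The correction is
#' multiplicative, preserving non-negativity and the Poisson
#' mean-variance relation. The fit uses autosomal bins only (sex
#' chromosomes share the same GC physics but carry copy-number effects)
#' and is applied to all compartments. Bins with undefined GC, or whose
#' fitted value is non-positive, pass through unchanged and are flagged.
#'
#' @param scaled a [scale_compartments()] result.
#' @param gc a [compute_gc_track()] GC track.
#' @param grid the matching grid.
#' @param span LOESS span (default 0.3).
#' @param min_bins minimum number of defined-GC autosomal bins required
#'   to fit (default 1000; relaxed automatically for toy genomes smaller
#'   than that).
#' @param max_fit_bins cap on the number of bins entering the fit; when
#'   more are available a deterministic GC-stratified subsample (every
#'   j-th bin in GC order) is used. The fit is then interpolated to all
#'   bins; with tens of thousands of fit points the curve is already
#'   noise-free, so this only bounds run time.
#' @return a `scaled_bin_counts` with corrected `values` and a logical
#'   `gc_flagged` vector marking uncorrected bins.
#' @export
loess_gc_correct <- function(scaled, gc, grid, span = 0.3, min_bins = 1000,
                             max_fit_bins = 20000) {
  stop_if(!identical(scaled$fingerprint, grid$fingerprint),
          "sample and grid fingerprints differ")
  stop_if(!identical(gc$fingerprint, grid$fingerprint),
          "GC track and grid fingerprints differ")
  auto <- grid$bins$compartment == "autosome"
  defined <- !is.na(gc$gc)
  fit_bins <- auto & defined & !is.na(scaled$values)
  stop_if(sum(fit_bins) < min(min_bins, floor(0.5 * sum(auto))),
          "too few bins with defined GC to fit the GC correction")

  fit_idx <- which(fit_bins)
  if (length(fit_idx) > max_fit_bins) {
    # every j-th usable bin in genome order; GC varies smoothly along the
    # genome, so the subsample covers the GC range like the full set
    fit_idx <- fit_idx[unique(round(seq(1, length(fit_idx),
                                        length.out = max_fit_bins)))]
  }
  lw <- lowess(gc$gc[fit_idx], scaled$values[fit_idx], f = span)
  fitted <- rep(NA_real_, grid$n_bins)
  fitted[defined] <- approx(lw, xout = gc$gc[defined], rule = 2,
                            ties = "ordered")$y
  med <- median(fitted[fit_idx])

  correctable <- defined & !is.na(fitted) & fitted > 0
  values <- scaled$values
  values[correctable] <- values[correctable] * med / fitted[correctable]

  # re-pin compartment sums to their targets: the multiplicative
  # correction drifts each sample's total by a fraction of a percent,
  # and corrected counts must still satisfy the scaled-sum invariant
  if (!is.null(scaled$targets)) {
    comp <- grid$bins$compartment
    for (cp in names(scaled$targets)) {
      rows <- comp == cp
      tot <- sum(values[rows], na.rm = TRUE)
      if (tot > 0) values[rows] <- values[rows] * scaled$targets[[cp]] / tot
    }
  }

  out <- scaled
  out$values <- values
  out$gc_corrected <- TRUE
  out$gc_flagged <- !correctable
  out
}

read_exclusion_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(d) <- c("chrom", "start", "end")
  d
}

bins_in_regions <- function(grid, regions) {
  hit <- logical(grid$n_bins)
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (grid$bins$chrom == regions$chrom[r] &
                    grid$bins$start < regions$end[r] &
                    grid$bins$end > regions$start[r])
  }
  hit
}

#' Train a reference model from a panel of non-aberrated samples
#'
#' Fits the normalization state used by [normalize_sample()]:
#' a principal-component basis over autosomal bins (the leading
#' components of a CNV-free panel capture recurrent cross-sample
#' artifacts), per-bin training means (computed on PCA-denoised values
#' for autosomes, on GC-corrected values for chrX/chrY, which stay
#' outside the PCA), per-bin training standard deviations, and the
#' unusable-bin mask.
#'
#' A bin is filtered when its training mean is below
#' `low_mean_frac` x (compartment median mean) — poorly mappable regions,
#' above `high_mean_frac` x median — repeats or systematic bias, or its
#' training standard deviation exceeds `high_var_frac` x (compartment
#' median sd) — highly variable regions. Bins with undefined GC are
#' filtered too, and an optional exclusion table is merged with reason
#' `"manual"`.
#'
#' @param panel list of samples: either `scaled_bin_counts` already
#'   GC-corrected, or `raw_bin_counts` (then scaling and GC correction
#'   are applied here).
#' @param gc GC track.
#' @param grid the shared grid.
#' @param n_components number of principal components to store
#'   (default 15; truncated with a warning if the panel is smaller).
#' @param loess_span span for GC correction of raw input.
#' @param low_mean_frac,high_mean_frac,high_var_frac filtration
#'   thresholds, as multiples of the compartment median (defaults 0.25,
#'   2.0, 3.0).
#' @param exclusion optional data.frame (chrom, start, end) or BED path
#'   of regions to mask with reason `"manual"`.
#' @param targets per-compartment scaling targets.
#' @param min_training panel size below which a warning is emitted
#'   (default 100).
#' @return object of class `reference_model`.
#' @export
train_reference_model <- function(panel, gc, grid,
                                  n_components = 15L,
                                  loess_span = 0.3,
                                  low_mean_frac = 0.25,
                                  high_mean_frac = 2.0,
                                  high_var_frac = 3.0,
                                  exclusion = NULL,
                                  targets = compartment_targets(grid),
                                  min_training = 100L) {
  stop_if(length(panel) < 2, "panel must contain at least 2 samples")
  if (length(panel) < min_training)
    warning(sprintf(
      "training panel has %d samples; at least %d are recommended",
      length(panel), min_training))

  panel <- lapply(panel, function(s) {
    if (inherits(s, "raw_bin_counts"))
      s <- loess_gc_correct(scale_compartments(s, grid, targets), gc, grid,
                            span = loess_span)
    stop_if(!inherits(s, "scaled_bin_counts"), "panel samples must be counts")
    stop_if(!identical(s$fingerprint, grid$fingerprint),
            "panel sample grid fingerprint mismatch")
    s
  })

  M <- do.call(rbind, lapply(panel, `[[`, "values"))
  ns <- nrow(M)

  filter_reasons <- function(means, sds) {
    reason <- rep(NA_character_, grid$n_bins)
    comp <- grid$bins$compartment
    for (cp in unique(comp)) {
      rows <- comp == cp
      med_mean <- median(means[rows], na.rm = TRUE)
      med_sd <- median(sds[rows], na.rm = TRUE)
      high <- rows & !is.na(means) & means > high_mean_frac * med_mean
      hv <- rows & !is.na(sds) & sds > high_var_frac * med_sd
      low <- rows & (is.na(means) | means < low_mean_frac * med_mean)
      reason[hv & is.na(reason)] <- "high_variance"
      reason[high & is.na(reason)] <- "high_mean"
      reason[low] <- "low_mean"      # low mean takes precedence
    }
    reason[is.na(gc$gc) & is.na(reason)] <- "undefined_gc"
    reason
  }

  # Provisional filter on GC-corrected panel statistics: the PCA must be
  # fitted on usable bins only, or unmappable and highly variable bins
  # dominate the leading components and the projection leaks their noise
  # into clean bins.
  means0 <- colMeans(M, na.rm = TRUE)
  sds0 <- apply(M, 2, sd, na.rm = TRUE)
  pre_ok <- is.na(filter_reasons(means0, sds0))
  pca_idx <- which(grid$bins$compartment == "autosome" & pre_ok)

  k <- min(n_components, ns - 1L)
  if (k < n_components)
    warning(sprintf("panel supports only %d components (requested %d)",
                    k, n_components))
  A <- M[, pca_idx, drop = FALSE]
  A[is.na(A)] <- 0
  centering <- colMeans(A)
  Xc <- sweep(A, 2, centering)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  d <- sqrt(pmax(eg$values[seq_len(k)], 0))
  keep <- d > max(d[1], 1e-12) * 1e-8
  U <- eg$vectors[, seq_len(k), drop = FALSE][, keep, drop = FALSE]
  d <- d[keep]
  basis <- crossprod(Xc, U)
  basis <- sweep(basis, 2, d, "/")     # |pca_idx| x k, orthonormal columns

  # denoised panel: remove the basis reconstruction of each sample's
  # deviation from the panel mean
  resid <- Xc - (Xc %*% basis) %*% t(basis)
  denoA <- sweep(resid, 2, centering, "+")

  means <- means0
  sds <- sds0
  means[pca_idx] <- colMeans(denoA)
  sds[pca_idx] <- apply(denoA, 2, sd)

  reason <- filter_reasons(means, sds)
  if (!is.null(exclusion)) {
    if (is.character(exclusion)) exclusion <- read_exclusion_bed(exclusion)
    reason[bins_in_regions(grid, exclusion) & is.na(reason)] <- "manual"
  }
  mask <- is.na(reason)   # TRUE = usable

  structure(list(format_version = "bincnv-model-1",
                 fingerprint = grid$fingerprint,
                 grid = grid,
                 targets = targets,
                 n_components = ncol(basis),
                 centering = centering,
                 basis = basis,
                 pca_idx = pca_idx,
                 n_autosomal_bins = sum(grid$bins$compartment == "autosome"),
                 means = means,
                 sds = sds,
                 mask = mask,
                 reason = reason,
                 n_training_samples = ns,
                 config = list(loess_span = loess_span,
                               low_mean_frac = low_mean_frac,
                               high_mean_frac = high_mean_frac,
                               high_var_frac = high_var_frac)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(paste0("reference_model: %d training samples, %d components, ",
                     "%d/%d bins usable (%.1f%% filtered)\n"),
              x$n_training_samples, x$n_components, sum(x$mask),
              length(x$mask), 100 * mean(!x$mask)))
  invisible(x)
}

#' Remove reference-panel principal components from a sample
#'
#' The sample's deviation from the panel mean over the PCA-usable
#' autosomal bins is projected onto the stored components and the
#' reconstruction is subtracted; chrX, chrY and filtered bins pass
#' through unchanged (the basis is trained on usable autosomes only).
#'
#' @param sample a GC-corrected `scaled_bin_counts`.
#' @param model a [train_reference_model()] model.
#' @return numeric vector of denoised per-bin values.
#' @export
pca_denoise <- function(sample, model) {
  stop_if(!identical(sample$fingerprint, model$fingerprint),
          "sample and model grid fingerprints differ")
  x <- sample$values
  a <- model$pca_idx
  dev <- x[a] - model$centering
  dev[is.na(dev)] <- 0
  recon <- as.numeric(model$basis %*% crossprod(model$basis, dev))
  x[a] <- x[a] - recon
  x
}

#' Subtract per-bin training means and apply the filter mask
#'
#' @param denoised per-bin values from [pca_denoise()].
#' @param model the reference model.
#' @param sample_id sample label.
#' @return object of class `normalized_profile`: zero-centered `values`
#'   (`NA` at filtered bins), the mask and reasons, and `mean_bin_count`
#'   (the compartment target mean, whose half is the single-copy level).
#' @export
center_profile <- function(denoised, model, sample_id = "sample") {
  values <- denoised - model$means
  values[!model$mask] <- NA_real_
  m <- model$targets[["autosome"]] / model$n_autosomal_bins
  structure(list(sample_id = sample_id, values = values,
                 mask = model$mask, reason = model$reason,
                 mean_bin_count = m,
                 # mean count of usable bins, the scale of the Poisson
                 # mean-variance relation on the profile
                 usable_mean_count = mean(model$means[model$mask]),
                 grid = model$grid,
                 fingerprint = model$fingerprint),
            class = "normalized_profile")
}

#' Full normalization of one sample
#'
#' Composition of [scale_compartments()], [loess_gc_correct()],
#' [pca_denoise()] and [center_profile()], in that order.
#'
#' @param raw a `raw_bin_counts`.
#' @param gc GC track.
#' @param model trained reference model.
#' @return a `normalized_profile`.
#' @export
normalize_sample <- function(raw, gc, model) {
  grid <- model$grid
  scaled <- scale_compartments(raw, grid, model$targets)
  corrected <- loess_gc_correct(scaled, gc, grid,
                                span = model$config$loess_span)
  denoised <- pca_denoise(corrected, model)
  center_profile(denoised, model, sample_id = raw$sample_id)
}

#' Save / load a reference model
#'
#' Single-file serialization with a format-version tag; round-trips
#' losslessly.
#'
#' @param model a `reference_model`.
#' @param path file path.
#' @return `load_reference_model` returns the model.
#' @export
save_reference_model <- function(model, path) {
  stop_if(!inherits(model, "reference_model"), "not a reference_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_reference_model
#' @export
load_reference_model <- function(path) {
  model <- readRDS(path)
  stop_if(!inherits(model, "reference_model") ||
            !identical(model$format_version, "bincnv-model-1"),
          "not a bincnv reference model (or unsupported format version)")
  model
}
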