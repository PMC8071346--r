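#' Parameters for the circular binary segmentation engine
#'
#' @param alpha significance level a candidate split must beat in the
#'   permutation test (default 0.01).
#' @param n_permutations maximum permutations per candidate split
#'   (default 10000; sequential early stopping usually needs far fewer).
#' @param min_seg_bins minimum bins per segment (default 1).
#' @param undo_sd if positive, adjacent segments whose mean difference is
#'   below `undo_sd` x pooled residual sd are merged after segmentation
#'   (default 0 = no undo).
#' @param rng_seed optional seed making segmentation reproducible
#'   independently of the caller's RNG state.
#' @param max_gap_bp filtered gaps longer than this break segments so
#'   calls never bridge e.g. a centromere (default 1e6).
#' @param kshort arcs up to this many bins long (and their complements)
#'   are searched exhaustively; intermediate lengths are covered by the
#'   extreme-partial-sum candidate search. Segments shorter than
#'   `2 * kshort` bins are therefore searched exhaustively.
#' @param n_candidates extreme centered partial sums kept per side in
#'   the candidate search.
#' @param refine_window after segmentation each internal boundary is
#'   re-fitted to the cut within this many bins that minimizes the
#'   two-segment sum of squares (0 disables). Corrects the occasional
#'   off-by-one cut the greedy recursion leaves behind.
#' @return a list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 10000L,
                       min_seg_bins = 1L, undo_sd = 0,
                       rng_seed = NULL, max_gap_bp = 1e6,
                       kshort = 12L, n_candidates = 50L,
                       refine_window = 2L) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stop_if(n_permutations < 100, "n_permutations must be at least 100")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 min_seg_bins = as.integer(min_seg_bins), undo_sd = undo_sd,
                 rng_seed = rng_seed, max_gap_bp = max_gap_bp,
                 kshort = as.integer(kshort),
                 n_candidates = as.integer(n_candidates),
                 refine_window = as.integer(refine_window)),
            class = "cbs_params")
}

refine_bounds <- function(x, bounds, window = 2L, min_seg = 1L,
                          mu0 = NULL) {
  # Move each internal cut to the position within +/- window minimizing
  # the two adjacent segments' Gaussian negative log-likelihood. With
  # `mu0` (the mean count of usable bins on the profile scale) the
  # variance of a segment at level mu is modeled as proportional to
  # mu + mu0 — the Poisson mean-variance relation, under which e.g. a
  # single-copy deletion has half the variance of its flanks and the
  # optimal cut is not the midpoint rule. Without `mu0` the criterion
  # reduces to the residual sum of squares.
  if (length(bounds) < 2 || window < 1) return(bounds)
  for (pass in 1:3) {
    changed <- FALSE
    starts <- c(1L, head(bounds, -1) + 1L)
    c0 <- 1
    if (!is.null(mu0)) {
      means <- vapply(seq_along(bounds),
                      function(i) mean(x[starts[i]:bounds[i]]), 0)
      fit <- rep(means, bounds - starts + 1L)
      c0 <- sum((x - fit)^2) / sum(pmax(fit + mu0, 0.05 * mu0))
      if (!is.finite(c0) || c0 <= 0) c0 <- 1
    }
    seg_nll <- function(vals) {
      m <- mean(vals)
      if (is.null(mu0)) return(sum((vals - m)^2))
      v <- c0 * max(m + mu0, 0.05 * mu0)
      length(vals) * log(v) + sum((vals - m)^2) / v
    }
    for (i in seq_len(length(bounds) - 1L)) {
      lo <- if (i == 1L) 1L else bounds[i - 1L] + 1L
      cut <- bounds[i]
      hi <- bounds[i + 1L]
      cand <- (cut - window):(cut + window)
      cand <- cand[cand >= lo + min_seg - 1L & cand <= hi - min_seg]
      if (length(cand) < 2) next
      nll <- vapply(cand, function(cc)
        seg_nll(x[lo:cc]) + seg_nll(x[(cc + 1L):hi]), 0)
      best <- cand[which.min(nll)]
      if (best != cut) {
        bounds[i] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bounds
}

undo_splits <- function(x, bounds, undo_sd) {
  # bounds: integer vector of segment end positions (cumulative, last = n)
  repeat {
    if (length(bounds) < 2) break
    starts <- c(1L, head(bounds, -1) + 1L)
    means <- vapply(seq_along(bounds),
                    function(i) mean(x[starts[i]:bounds[i]]), 0)
    resid_sd <- sqrt(sum((x - rep(means, diff(c(0L, bounds))))^2) /
                       max(1, length(x) - length(bounds)))
    diffs <- abs(diff(means))
    weakest <- which.min(diffs)
    if (diffs[weakest] >= undo_sd * resid_sd) break
    bounds <- bounds[-weakest]
  }
  bounds
}

segment_one_run <- function(x, params, mu0 = NULL) {
  cps <- cpp_cbs_changepoints(x, alpha = params$alpha,
                              nperm = params$n_permutations,
                              min_width = params$min_seg_bins,
                              kshort = params$kshort,
                              ncand = params$n_candidates)
  bounds <- c(cps, length(x))
  if (params$undo_sd > 0) bounds <- undo_splits(x, bounds, params$undo_sd)
  bounds <- refine_bounds(x, bounds, window = params$refine_window,
                          min_seg = params$min_seg_bins, mu0 = mu0)
  bounds
}

#' Segment a normalized profile with circular binary segmentation
#'
#' Per chromosome, the unfiltered bins are segmented by recursively
#' locating the arc of the circularized series that maximizes the
#' standardized mean-difference statistic between the arc and its
#' complement; a split is accepted when its permutation p-value falls
#' below `alpha`, and recursion continues on the resulting pieces.
#' Runs of unfiltered bins separated by filtered gaps longer than
#' `max_gap_bp` are segmented independently. Segment genomic coordinates
#' span from the first member bin's start to the last member bin's end
#' (bridging short filtered gaps); `length_bp` is the sum of member-bin
#' spans.
#'
#' @param profile a [normalize_sample()] profile.
#' @param params a [cbs_params()] object.
#' @param chromosomes chromosomes to segment (default all in the grid).
#' @return data.frame of segments: `chrom`, `start_bin`, `end_bin`
#'   (0-based half-open global bin-grid indices), `start_bp`, `end_bp`,
#'   `n_bins`, `length_bp`, `mean_level`. Chromosomes with zero
#'   unfiltered bins are skipped.
#' @export
cbs_segment <- function(profile, params = cbs_params(),
                        chromosomes = NULL) {
  stop_if(!inherits(profile, "normalized_profile"), "need a normalized_profile")
  grid <- profile$grid
  chromosomes <- chromosomes %||% grid$chromosomes$name
  stop_if(!all(chromosomes %in% grid$chromosomes$name),
          "unknown chromosome requested")
  # bins are stored in chromosome blocks; locate each block once
  first <- match(grid$chromosomes$name, grid$bins$chrom)
  last <- c(first[-1] - 1L, grid$n_bins)
  names(first) <- names(last) <- grid$chromosomes$name
  usable <- profile$mask & !is.na(profile$values)
  run_cbs <- function() {
    out <- list()
    for (cn in chromosomes) {
      block <- first[[cn]]:last[[cn]]
      rows <- block[usable[block]]
      if (length(rows) == 0) next
      gap <- c(0, grid$bins$start[rows[-1]] -
                 grid$bins$end[rows[-length(rows)]])
      run_id <- cumsum(gap > params$max_gap_bp)
      for (r in unique(run_id)) {
        idx <- rows[run_id == r]
        x <- profile$values[idx]
        bounds <- segment_one_run(x, params,
                                  mu0 = profile$usable_mean_count)
        starts <- c(1L, head(bounds, -1) + 1L)
        for (s in seq_along(bounds)) {
          mem <- idx[starts[s]:bounds[s]]
          out[[length(out) + 1L]] <- data.frame(
            chrom = cn,
            start_bin = mem[1] - 1L,
            end_bin = mem[length(mem)],
            start_bp = grid$bins$start[mem[1]],
            end_bp = grid$bins$end[mem[length(mem)]],
            n_bins = length(mem),
            length_bp = sum(grid$bins$end[mem] - grid$bins$start[mem]),
            mean_level = mean(profile$values[mem]),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  }
  segs <- with_seed(params$rng_seed, run_cbs())
  if (is.null(segs)) segs <- data.frame(
    chrom = character(0), start_bin = integer(0), end_bin = integer(0),
    start_bp = numeric(0), end_bp = numeric(0), n_bins = integer(0),
    length_bp = numeric(0), mean_level = numeric(0))
  segs
}

#' Significance classes, ranked
#' @keywords internal
SIGNIFICANCE_LEVELS <- c("green", "yellow", "orange", "red", "magenta")

#' Classify segments into five significance classes
#'
#' The single-copy level is `L = m/2`, the expected deviation for gain or
#' loss of one chromosome copy at mean scaled bin count `m`. With
#' relative level `r = |mean_level| / L`, the first matching rule wins:
#' magenta if `r >= 0.75` and length >= 200 kb; red if `r >= 0.25` and
#' length >= 200 kb; orange if `r >= 0.25` and length >= 40 kb; yellow if
#' `r >= 0.125` and length >= 40 kb; green otherwise (very short
#' segments or segments around zero). Non-green segments are CNV calls;
#' `call_type` is `"deletion"` or `"duplication"` from the sign of the
#' mean level, `"neutral"` for green segments.
#'
#' @param segments data.frame from [cbs_segment()].
#' @param m mean scaled bin count (profile `mean_bin_count`).
#' @return the data.frame with `relative_level`, `significance` and
#'   `call_type` columns added.
#' @export
classify_segments <- function(segments, m) {
  stop_if(m <= 0, "m must be positive")
  L <- m / 2
  r <- abs(segments$mean_level) / L
  len <- segments$length_bp
  sig <- rep("green", nrow(segments))
  sig[r >= 0.125 & len >= 40000] <- "yellow"
  sig[r >= 0.25 & len >= 40000] <- "orange"
  sig[r >= 0.25 & len >= 200000] <- "red"
  sig[r >= 0.75 & len >= 200000] <- "magenta"
  segments$relative_level <- r
  segments$significance <- factor(sig, levels = SIGNIFICANCE_LEVELS)
  segments$call_type <- ifelse(sig == "green", "neutral",
                               ifelse(segments$mean_level < 0,
                                      "deletion", "duplication"))
  segments
}

#' Segment and classify a profile
#'
#' Runs [cbs_segment()] then [classify_segments()]; non-green rows are
#' the CNV calls.
#'
#' @inheritParams cbs_segment
#' @return classified segment data.frame.
#' @export
call_cnvs <- function(profile, params = cbs_params(), chromosomes = NULL) {
  segs <- cbs_segment(profile, params, chromosomes = chromosomes)
  classify_segments(segs, profile$mean_bin_count)
}

#' Write segment reports
#'
#' Writes a TSV with every segment field (stable column order) and a
#' BED of the non-green calls (0-based half-open; name = call type,
#' score = `round(1000 * min(r, 1))`, strand = ".").
#'
#' @param segments classified segments from [call_cnvs()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bed`.
#' @return invisibly, the two paths.
#' @export
report_calls <- function(segments, prefix) {
  cols <- c("chrom", "start_bin", "end_bin", "start_bp", "end_bp",
            "n_bins", "length_bp", "mean_level", "relative_level",
            "call_type", "significance")
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  d <- segments[, cols, drop = FALSE]
  d$mean_level <- sprintf("%.4f", d$mean_level)
  d$relative_level <- sprintf("%.4f", d$relative_level)
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- segments[segments$significance != "green", , drop = FALSE]
  if (nrow(calls) > 0) {
    bed_df <- data.frame(chrom = calls$chrom,
                         start = format(calls$start_bp, scientific = FALSE,
                                        trim = TRUE),
                         end = format(calls$end_bp, scientific = FALSE,
                                      trim = TRUE),
                         name = calls$call_type,
                         score = round(1000 * pmin(calls$relative_level, 1)),
                         strand = ".")
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}

significance_color <- c(green = "forestgreen", yellow = "gold2",
                        orange = "darkorange", red = "red2",
                        magenta = "magenta3")

#' Plot one chromosome of a profile with its segments
#'
#' Per-bin values as grey points, segment means as horizontal lines
#' colored by significance class, dashed lines at the single-copy levels
#' +/- m/2, and filtered bins as black marks on the zero line.
#'
#' @param profile a normalized profile.
#' @param segments classified segments.
#' @param chromosome chromosome name.
#' @param file optional PNG path; if given the plot is written there.
#' @param width,height device size in pixels when `file` is used.
#' @return invisibly, `file` (or `NULL` when plotting to the current
#'   device).
#' @export
plot_chromosome <- function(profile, segments, chromosome, file = NULL,
                            width = 1200, height = 400) {
  grid <- profile$grid
  stop_if(!chromosome %in% grid$chromosomes$name,
          "unknown chromosome: ", chromosome)
  if (!is.null(file)) {
    png(file, width = width, height = height)
    on.exit(dev.off())
  }
  rows <- which(grid$bins$chrom == chromosome)
  mid <- (grid$bins$start[rows] + grid$bins$end[rows]) / 2
  v <- profile$values[rows]
  m <- profile$mean_bin_count
  ylim <- range(c(v, m / 2, -m / 2), na.rm = TRUE) * 1.05
  plot(mid / 1e6, v, pch = 16, cex = 0.4, col = "grey55",
       xlab = paste(chromosome, "position (Mb)"),
       ylab = "normalized bin count", ylim = ylim,
       main = paste(profile$sample_id, chromosome))
  abline(h = 0, col = "grey80")
  abline(h = c(-m / 2, m / 2), lty = 2, col = "magenta3")
  filt <- rows[!profile$mask[rows]]
  if (length(filt))
    points((grid$bins$start[filt] + grid$bins$end[filt]) / 2e6,
           rep(0, length(filt)), pch = 15, cex = 0.4, col = "black")
  segs <- segments[segments$chrom == chromosome, , drop = FALSE]
  if (nrow(segs))
    segments(segs$start_bp / 1e6, segs$mean_level,
             segs$end_bp / 1e6, segs$mean_level,
             col = significance_color[as.character(segs$significance)],
             lwd = 3)
  invisible(file)
}
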