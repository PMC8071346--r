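# SAM flag bits used for read filtering
FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

new_raw_bin_counts <- function(counts, grid, sample_id,
                               total_discarded_low_mapq = 0L,
                               total_skipped_chrom = 0L) {
  structure(list(sample_id = sample_id,
                 counts = counts,
                 total_counted = sum(counts),
                 total_discarded_low_mapq = total_discarded_low_mapq,
                 total_skipped_chrom = total_skipped_chrom,
                 fingerprint = grid$fingerprint),
            class = "raw_bin_counts")
}

#' Count mapped reads in genome bins
#'
#' Each retained alignment increments exactly one bin, chosen by the
#' 0-based leftmost mapped position (`floor(pos / bin_size)`); reads are
#' binned by their starts. Alignments with mapping quality below
#' `mapq_min`, or flagged unmapped, secondary, supplementary or
#' duplicate, are discarded. For paired-end data each mate passing the
#' filters is counted independently. No other read information is used.
#'
#' @param alignments either the path of a SAM/BAM file (SAM is converted
#'   via `Rsamtools::asBam`), or a data.frame with columns `chrom`,
#'   `pos` (1-based leftmost, as in SAM), `mapq` and `flag`.
#' @param grid a [build_bin_grid()] grid.
#' @param mapq_min minimum mapping quality (default 40).
#' @param sample_id sample label stored in the result.
#' @return object of class `raw_bin_counts`: per-bin integer counts plus
#'   `total_counted`, `total_discarded_low_mapq` and the count of reads
#'   skipped because their chromosome is absent from the grid.
#' @export
bin_reads <- function(alignments, grid, mapq_min = 40L, sample_id = "sample") {
  if (is.character(alignments) && length(alignments) == 1L) {
    stop_if(!requireNamespace("Rsamtools", quietly = TRUE),
            "reading SAM/BAM requires the Rsamtools package")
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    alignments <- data.frame(chrom = as.character(b$rname), pos = b$pos,
                             mapq = b$mapq, flag = b$flag,
                             stringsAsFactors = FALSE)
  }
  stop_if(!all(c("chrom", "pos", "mapq", "flag") %in% names(alignments)),
          "alignments need columns chrom, pos, mapq, flag")
  stop_if(nrow(alignments) == 0, "empty alignment input")

  bad_flag <- bitwAnd(alignments$flag,
                      FLAG_UNMAPPED + FLAG_SECONDARY +
                        FLAG_DUPLICATE + FLAG_SUPPLEMENTARY) != 0L
  bad_flag <- bad_flag | is.na(alignments$pos)
  mapq <- alignments$mapq
  low_mapq <- !bad_flag & (is.na(mapq) | mapq < mapq_min)
  keep <- !bad_flag & !low_mapq

  # SAM pos is 1-based; the grid is 0-based half-open
  idx <- bin_index(grid, alignments$chrom[keep], alignments$pos[keep] - 1L)
  skipped <- sum(is.na(idx))
  counts <- tabulate(idx[!is.na(idx)], nbins = grid$n_bins)
  new_raw_bin_counts(counts, grid, sample_id,
                     total_discarded_low_mapq = sum(low_mapq),
                     total_skipped_chrom = skipped)
}

#' Read / write a per-bin count table
#'
#' TSV with columns chrom, start, end, count, matching the grid row
#' order. This front end lets the pipeline run from count tables without
#' alignment files.
#'
#' @param path TSV path.
#' @param grid a grid the table must match.
#' @param sample_id sample label.
#' @return `read_bin_counts` returns a `raw_bin_counts`.
#' @export
read_bin_counts <- function(path, grid, sample_id = basename(path)) {
  d <- read.table(path, sep = "\t", header = TRUE)
  stop_if(nrow(d) != grid$n_bins, "count table length does not match grid")
  stop_if(!all(c("chrom", "start", "end", "count") %in% names(d)),
          "count table needs columns chrom, start, end, count")
  stop_if(!all(d$start == grid$bins$start) ||
            !all(as.character(d$chrom) == grid$bins$chrom),
          "count table coordinates do not match grid")
  stop_if(any(d$count < 0), "negative counts")
  new_raw_bin_counts(d$count, grid, sample_id)
}

#' @rdname read_bin_counts
#' @param counts a `raw_bin_counts`.
#' @export
write_bin_counts <- function(counts, grid, path) {
  d <- data.frame(chrom = grid$bins$chrom, start = grid$bins$start,
                  end = grid$bins$end, count = counts$counts)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default per-compartment scaling targets
#'
#' The scaled sum of each compartment is fixed so that the mean scaled
#' bin count equals `mean_count` (default 100); levels are then
#' interpretable across samples and the single-copy level is
#' `mean_count / 2`.
#'
#' @param grid a grid.
#' @param mean_count target mean scaled count per bin.
#' @return named numeric vector of per-compartment target sums.
#' @export
compartment_targets <- function(grid, mean_count = 100) {
  n <- table(grid$bins$compartment)
  setNames(as.numeric(n) * mean_count, names(n))
}

#' Scale bin counts to common per-compartment totals
#'
#' Each compartment (autosomes, chrX, chrY) is scaled independently so
#' that its bin-count sum equals the target; relative proportions within
#' a compartment are unchanged. A compartment with zero total and a
#' nonzero target is flagged unusable (values set `NA`) rather than
#' divided by zero.
#'
#' @param counts a `raw_bin_counts`.
#' @param grid the matching grid.
#' @param targets per-compartment target sums (default
#'   [compartment_targets()]).
#' @return object of class `scaled_bin_counts`: `values`,
#'   `scale_factors`, `targets`, `unusable_compartments`.
#' @export
scale_compartments <- function(counts, grid,
                               targets = compartment_targets(grid)) {
  stop_if(!identical(counts$fingerprint, grid$fingerprint),
          "counts and grid fingerprints differ")
  comp <- grid$bins$compartment
  values <- as.numeric(counts$counts)
  factors <- setNames(rep(NA_real_, length(targets)), names(targets))
  unusable <- character(0)
  for (cp in names(targets)) {
    rows <- comp == cp
    tot <- sum(values[rows])
    if (tot == 0 && targets[[cp]] != 0) {
      values[rows] <- NA_real_
      unusable <- c(unusable, cp)
    } else if (tot > 0) {
      factors[cp] <- targets[[cp]] / tot
      values[rows] <- values[rows] * factors[cp]
    }
  }
  structure(list(sample_id = counts$sample_id, values = values,
                 scale_factors = factors, targets = targets,
                 unusable_compartments = unusable,
                 fingerprint = grid$fingerprint),
            class = "scaled_bin_counts")
}
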