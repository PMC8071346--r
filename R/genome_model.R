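#' Compartment of a chromosome name
#'
#' Autosomes (1..22, with or without a `chr` prefix) map to `"autosome"`,
#' X to `"chrX"` and Y to `"chrY"`. Anything else (mitochondrion,
#' unplaced contigs, alt haplotypes) returns `NA` and is excluded from
#' the bin grid unless explicitly whitelisted.
#'
#' @param name character vector of chromosome names.
#' @return character vector: `"autosome"`, `"chrX"`, `"chrY"` or `NA`.
#' @export
chrom_compartment <- function(name) {
  stripped <- sub("^chr", "", name, ignore.case = TRUE)
  out <- rep(NA_character_, length(name))
  out[stripped %in% as.character(1:22)] <- "autosome"
  out[toupper(stripped) == "X"] <- "chrX"
  out[toupper(stripped) == "Y"] <- "chrY"
  out
}

#' Tile a genome into fixed-size bins
#'
#' Every chromosome is tiled with adjacent, non-overlapping bins of
#' `bin_size` bp starting at 0; the last bin of a chromosome is truncated
#' when the length is not a multiple of `bin_size`. Coordinates are
#' 0-based, half-open throughout. Truncated terminal bins are kept (they
#' fall to low-mean filtration if problematic). By default only the
#' canonical autosomes plus X and Y enter the grid; other contigs are
#' dropped unless listed in `keep`.
#'
#' @param chrom_sizes data.frame with columns `name` and `length`, a
#'   named numeric vector, or the path of a two-column TSV.
#' @param bin_size bin width in bp (default 20000).
#' @param keep optional character vector of chromosome names to keep
#'   regardless of [chrom_compartment()]; non-canonical names kept this
#'   way are treated as autosomal.
#' @return an object of class `bin_grid`: list with `chromosomes`
#'   (data.frame `name`, `length`), `bin_size`, `bins` (data.frame
#'   `chrom`, `start`, `end`, `compartment`), `n_bins` and `fingerprint`.
#' @export
build_bin_grid <- function(chrom_sizes, bin_size = 20000L, keep = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (!is.null(names(chrom_sizes)) && is.numeric(chrom_sizes))
    chrom_sizes <- data.frame(name = names(chrom_sizes),
                              length = as.numeric(chrom_sizes))
  stop_if(!all(c("name", "length") %in% names(chrom_sizes)),
          "chrom_sizes needs columns 'name' and 'length'")
  stop_if(bin_size <= 0, "bin_size must be positive")
  stop_if(anyDuplicated(chrom_sizes$name) > 0, "duplicate chromosome names")
  stop_if(any(chrom_sizes$length <= 0), "non-positive chromosome length")

  comp <- chrom_compartment(chrom_sizes$name)
  keep_row <- !is.na(comp) | chrom_sizes$name %in% keep
  comp[is.na(comp)] <- "autosome"
  chrom_sizes <- chrom_sizes[keep_row, , drop = FALSE]
  comp <- comp[keep_row]
  stop_if(nrow(chrom_sizes) == 0, "no usable chromosomes after filtering")

  nb <- ceiling(chrom_sizes$length / bin_size)
  chrom <- rep(chrom_sizes$name, nb)
  local <- unlist(lapply(nb, function(k) seq_len(k) - 1L), use.names = FALSE)
  start <- local * bin_size
  end <- pmin(start + bin_size, rep(chrom_sizes$length, nb))
  bins <- data.frame(chrom = chrom, start = start, end = end,
                     compartment = rep(comp, nb),
                     stringsAsFactors = FALSE)
  fp <- paste0("binsize=", bin_size, ";",
               paste(chrom_sizes$name, chrom_sizes$length,
                     sep = ":", collapse = ","))
  structure(list(chromosomes = data.frame(name = chrom_sizes$name,
                                          length = chrom_sizes$length,
                                          stringsAsFactors = FALSE),
                 bin_size = as.integer(bin_size),
                 bins = bins,
                 n_bins = nrow(bins),
                 fingerprint = fp),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosomes, %d bins of %d bp\n",
              nrow(x$chromosomes), x$n_bins, x$bin_size))
  invisible(x)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (name, length), no header.
#' @return data.frame with columns `name`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("name", "length"),
                  colClasses = c("character", "numeric"))
  d
}

#' Global bin index for genomic positions
#'
#' @param grid a [build_bin_grid()] grid.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of 1-based global bin indices (`NA` for
#'   positions on chromosomes absent from the grid or out of range).
#' @export
bin_index <- function(grid, chrom, pos) {
  first <- match(grid$chromosomes$name, grid$bins$chrom)
  offset <- setNames(first - 1L, grid$chromosomes$name)
  len <- setNames(grid$chromosomes$length, grid$chromosomes$name)
  idx <- offset[chrom] + pos %/% grid$bin_size + 1L
  idx[is.na(idx) | pos < 0 | pos >= len[chrom]] <- NA_integer_
  unname(idx)
}

#' Per-bin GC content from chromosome sequences
#'
#' GC fraction is (G+C)/(A+C+G+T) over the bin span; N and other
#' ambiguity codes are excluded from numerator and denominator. A bin
#' whose defined-base fraction falls below `min_defined` gets `NA` GC and
#' is flagged via the `defined_frac` track.
#'
#' @param sequences a `Biostrings::DNAStringSet`, a named character
#'   vector of sequences, or a FASTA file path. Names must cover every
#'   chromosome in the grid.
#' @param grid a [build_bin_grid()] grid.
#' @param min_defined minimum defined-base fraction for GC to be defined
#'   (default 0.5).
#' @return object of class `gc_track`: list with numeric vectors `gc`
#'   (NA where undefined) and `defined_frac`, plus the grid fingerprint.
#' @export
compute_gc_track <- function(sequences, grid, min_defined = 0.5) {
  if (is.character(sequences) && is.null(names(sequences)) &&
      length(sequences) == 1L && file.exists(sequences)) {
    stop_if(!requireNamespace("Biostrings", quietly = TRUE),
            "reading FASTA requires the Biostrings package")
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  missing <- setdiff(grid$chromosomes$name, names(sequences))
  stop_if(length(missing) > 0,
          "missing chromosome(s) in sequence source: ",
          paste(missing, collapse = ", "))

  gc <- numeric(grid$n_bins)
  def <- numeric(grid$n_bins)
  for (cn in grid$chromosomes$name) {
    rows <- which(grid$bins$chrom == cn)
    st <- grid$bins$start[rows] + 1L   # 1-based for substring/Views
    en <- grid$bins$end[rows]
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      s <- sequences[[cn]]
      if (is.character(s)) s <- Biostrings::DNAString(s)
      v <- Biostrings::Views(s, start = st, end = en)
      lf <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    } else {
      s <- toupper(as.character(sequences[[cn]]))
      lf <- t(vapply(seq_along(st), function(i) {
        b <- strsplit(substr(s, st[i], en[i]), "")[[1]]
        c(A = sum(b == "A"), C = sum(b == "C"),
          G = sum(b == "G"), T = sum(b == "T"))
      }, numeric(4)))
    }
    acgt <- rowSums(lf)
    def[rows] <- acgt / (en - st + 1L)
    gc[rows] <- ifelse(acgt > 0, (lf[, "C"] + lf[, "G"]) / acgt, NA_real_)
  }
  gc[def < min_defined] <- NA_real_
  structure(list(gc = gc, defined_frac = def,
                 fingerprint = grid$fingerprint),
            class = "gc_track")
}

#' Write / read a GC track cache
#'
#' TSV with columns chrom, start, end, gc, defined_fraction.
#' @param gc a `gc_track`.
#' @param grid the matching grid.
#' @param path output/input TSV path.
#' @return `read_gc_track` returns a `gc_track`.
#' @export
write_gc_track <- function(gc, grid, path) {
  d <- data.frame(chrom = grid$bins$chrom, start = grid$bins$start,
                  end = grid$bins$end, gc = gc$gc,
                  defined_fraction = gc$defined_frac)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gc_track
#' @export
read_gc_track <- function(path, grid) {
  d <- read.table(path, sep = "\t", header = TRUE)
  stop_if(nrow(d) != grid$n_bins, "GC track length does not match grid")
  structure(list(gc = d$gc, defined_frac = d$defined_fraction,
                 fingerprint = grid$fingerprint),
            class = "gc_track")
}
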