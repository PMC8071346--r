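# Closed-form binomial power model for read-depth CNV detection.
#
# Sequencing is modeled as drawing n reads uniformly from a mappable
# genome of length lg; the count falling in a CNV region of length lc is
# binomial with p = lc/lg, mean mu = n*p, variance n*p*(1-p). A
# single-copy gain or loss shifts the regional count to n*(p +/- p/2),
# giving Z^2 = n*p / (4*(1-p)) = n*lc / (4*(lg - lc)) for either sign.

check_theory_args <- function(lc, lg, n = 1, z = 1) {
  stop_if(any(lc <= 0) || any(lg <= 0), "lengths must be positive")
  stop_if(any(lc >= lg), "CNV length must be smaller than genome length")
  stop_if(any(n <= 0), "read count must be positive")
  stop_if(any(z <= 0), "Z-score must be positive")
}

#' Detection Z-score for a given read count
#'
#' `Z = sqrt(n * lc / (4 * (lg - lc)))` — the standardized deviation of
#' the regional read count under a single-copy gain or loss (both signs
#' give the same magnitude).
#'
#' @param n number of uniquely mapped reads.
#' @param lc CNV length in bp.
#' @param lg mappable genome length in bp (default 3.1e9, human scale).
#' @return the Z-score (vectorized).
#' @export
zscore_for_reads <- function(n, lc, lg = 3.1e9) {
  check_theory_args(lc, lg, n = n)
  sqrt(n * lc / (4 * (lg - lc)))
}

#' Minimal read count for a target Z-score
#'
#' `n = 4 * Z^2 * (lg - lc) / lc`, the smallest number of uniquely
#' mapped reads at which a single-copy CNV of length `lc` reaches the
#' desired Z-score.
#'
#' @param z target Z-score.
#' @inheritParams zscore_for_reads
#' @return list with `n` (exact real value) and `n_ceiling` (smallest
#'   whole read count).
#' @export
min_reads <- function(z, lc, lg = 3.1e9) {
  check_theory_args(lc, lg, z = z)
  n <- 4 * z^2 * (lg - lc) / lc
  list(n = n, n_ceiling = ceiling(n))
}

#' Minimal detectable CNV length for a read count
#'
#' Algebraic inverse of [min_reads()]:
#' `lc = 4 * Z^2 * lg / (n + 4 * Z^2)`.
#'
#' @inheritParams zscore_for_reads
#' @param z target Z-score.
#' @return CNV length in bp.
#' @export
min_length <- function(z, n, lg = 3.1e9) {
  stop_if(any(z <= 0) || any(n <= 0) || any(lg <= 0),
          "all arguments must be positive")
  4 * z^2 * lg / (n + 4 * z^2)
}

#' Minimal read count over a grid of CNV lengths and Z-scores
#'
#' @param z vector of Z-scores (one curve each).
#' @param lc vector of CNV lengths in bp.
#' @param lg mappable genome length.
#' @return data.frame with columns `z`, `lc`, `n` (exact) and
#'   `n_ceiling`; `n` is decreasing in `lc` within each curve.
#' @export
theory_table <- function(z = c(4, 5, 6, 7, 8, 9, 10),
                         lc = seq(20000, 500000, by = 20000),
                         lg = 3.1e9) {
  g <- expand.grid(lc = lc, z = z)[, c("z", "lc")]
  mr <- min_reads(g$z, g$lc, lg)
  g$n <- mr$n
  g$n_ceiling <- mr$n_ceiling
  g
}
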