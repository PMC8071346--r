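test_that("a constant profile yields exactly one segment at its level", {
  g <- tiny_grid(150)
  prof <- make_profile(rep(7.5, 150), g)
  segs <- cbs_segment(prof, cbs_params(rng_seed = 1))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$mean_level, 7.5)
  expect_equal(segs$n_bins, 150L)
  expect_equal(segs$start_bp, 0)
  expect_equal(segs$end_bp, 150 * 20000)
})

test_that("the chosen first split matches exhaustive arc search (n <= 30)", {
  max_arc <- getFromNamespace("cpp_max_arc", "bincnv")
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    if (rep %% 3 == 0) {             # sometimes plant a real step
      w <- sample(2:4, 1)
      at <- sample(seq_len(n - w), 1)
      x[at:(at + w - 1)] <- x[at:(at + w - 1)] + 5
    }
    got <- max_arc(x)
    want <- oracle_max_arc(x)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(c(got$i, got$j), c(want$i, want$j))
  }
})

test_that("iid noise stays unsplit in at least 95% of replicates", {
  g <- tiny_grid(500)
  n_single <- 0
  for (r in 1:100) {
    set.seed(3000 + r)
    prof <- make_profile(rnorm(500, sd = 8), g)
    segs <- cbs_segment(prof, cbs_params(rng_seed = r))
    n_single <- n_single + (nrow(segs) == 1L)
  }
  expect_gte(n_single, 95)
})

test_that("a planted step is found with exact boundaries", {
  g <- tiny_grid(210)
  hits <- 0
  for (r in 1:50) {
    set.seed(4000 + r)
    x <- rnorm(210, sd = 8)
    x[101:110] <- x[101:110] - 50
    prof <- make_profile(x, g)
    segs <- cbs_segment(prof, cbs_params(rng_seed = r))
    ok <- nrow(segs) == 3 && segs$start_bin[2] == 100 &&
      segs$end_bin[2] == 110
    hits <- hits + ok
  }
  expect_gte(hits, 45)   # >= 90% of replicates
})

test_that("significance classes follow the five-level rule table", {
  seg <- function(level, len) data.frame(
    chrom = "chr1", start_bin = 0L, end_bin = 10L, start_bp = 0,
    end_bp = len, n_bins = 10L, length_bp = len, mean_level = level)
  m <- 100  # single-copy level L = 50
  cls <- function(level, len)
    as.character(classify_segments(seg(level, len), m)$significance)
  expect_equal(cls(-0.80 * 50, 240000), "magenta")
  expect_equal(cls(0.30 * 50, 100000), "orange")
  expect_equal(cls(0.30 * 50, 220000), "red")
  expect_equal(cls(0.10 * 50, 5e6), "green")
  expect_equal(cls(0.13 * 50, 39999), "green")   # fails the length rule
  expect_equal(cls(0.13 * 50, 40000), "yellow")
  # boundary values are inclusive
  expect_equal(cls(0.75 * 50, 200000), "magenta")
  expect_equal(cls(0.25 * 50, 200000), "red")
  expect_equal(cls(0.125 * 50, 40000), "yellow")
  # call type from the sign; green is neutral
  out <- classify_segments(rbind(seg(-40, 240000), seg(40, 240000),
                                 seg(1, 240000)), m)
  expect_equal(out$call_type, c("deletion", "duplication", "neutral"))
})

test_that("classification is monotone in level and length", {
  rank_of <- function(level, len) {
    s <- data.frame(chrom = "c", start_bin = 0L, end_bin = 1L,
                    start_bp = 0, end_bp = len, n_bins = 1L,
                    length_bp = len, mean_level = level)
    match(as.character(classify_segments(s, 100)$significance),
          SIGNIFICANCE_LEVELS)
  }
  set.seed(12)
  for (i in 1:50) {
    level <- runif(1, 0, 60)
    len <- runif(1, 2e4, 3e5)
    r0 <- rank_of(level, len)
    expect_gte(rank_of(level * runif(1, 1, 2), len), r0)
    expect_gte(rank_of(level, len * runif(1, 1, 2)), r0)
  }
})

test_that("segments cover every unfiltered bin exactly once", {
  st <- toy_state()
  case <- make_case(st$spec, list(simulated_cnv("chr1", 2e6, 2.2e6, 1.5)),
                    genome = st$genome, seed = 601)
  prof <- normalize_sample(case$sample, st$genome$gc, st$model)
  segs <- cbs_segment(prof, cbs_params(rng_seed = 2))
  # a segment's members are the unfiltered bins inside its half-open
  # bin range; bridged filtered bins are not members
  usable <- which(prof$mask & !is.na(prof$values))
  members <- unlist(lapply(seq_len(nrow(segs)), function(i)
    intersect((segs$start_bin[i] + 1):segs$end_bin[i], usable)))
  expect_setequal(members, usable)
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(sum(segs$n_bins), length(usable))
})

test_that("filtered gaps longer than max_gap_bp break segments", {
  g <- tiny_grid(200)
  mask <- rep(TRUE, 200)
  mask[50:120] <- FALSE    # 71 bins = 1.42 Mb gap
  prof <- make_profile(rep(2, 200), g, mask = mask)
  segs <- cbs_segment(prof, cbs_params(rng_seed = 1))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$end_bin[1], 49L)
  expect_equal(segs$start_bin[2], 120L)
  # a short gap is bridged
  mask2 <- rep(TRUE, 200)
  mask2[50:60] <- FALSE    # 11 bins = 220 kb
  prof2 <- make_profile(rep(2, 200), g, mask = mask2)
  segs2 <- cbs_segment(prof2, cbs_params(rng_seed = 1))
  expect_equal(nrow(segs2), 1L)
  expect_equal(segs2$n_bins, 189L)
  expect_equal(segs2$length_bp, 189 * 20000)   # member spans, not the gap
})

test_that("reports are byte-stable and BED intervals are half-open", {
  g <- tiny_grid(100)
  segs <- data.frame(
    chrom = "chr1",
    start_bin = c(0L, 10L, 20L), end_bin = c(10L, 20L, 100L),
    start_bp = c(0, 200000, 400000), end_bp = c(200000, 400000, 2000000),
    n_bins = c(10L, 10L, 80L), length_bp = c(200000, 200000, 1600000),
    mean_level = c(-48.0, 51.5, 0.75))
  segs <- classify_segments(segs, 100)
  prefix <- file.path(tempdir(), "calls_golden")
  report_calls(segs, prefix)
  tsv <- readLines(paste0(prefix, ".tsv"))
  bed <- readLines(paste0(prefix, ".bed"))
  expect_equal(tsv, c(
    paste("chrom", "start_bin", "end_bin", "start_bp", "end_bp", "n_bins",
          "length_bp", "mean_level", "relative_level", "call_type",
          "significance", sep = "\t"),
    "chr1\t0\t10\t0\t2e+05\t10\t2e+05\t-48.0000\t0.9600\tdeletion\tmagenta",
    "chr1\t10\t20\t2e+05\t4e+05\t10\t2e+05\t51.5000\t1.0300\tduplication\tmagenta",
    "chr1\t20\t100\t4e+05\t2e+06\t80\t1600000\t0.7500\t0.0150\tneutral\tgreen"))
  expect_equal(bed, c("chr1\t0\t200000\tdeletion\t960\t.",
                      "chr1\t200000\t400000\tduplication\t1000\t."))
  starts <- as.numeric(sapply(strsplit(bed, "\t"), `[`, 2))
  ends <- as.numeric(sapply(strsplit(bed, "\t"), `[`, 3))
  expect_true(all(starts < ends))
  expect_true(all(starts >= 0))

  # an empty call set writes a header-only TSV and an empty BED
  prefix2 <- file.path(tempdir(), "calls_empty")
  report_calls(segs[0, ], prefix2)
  expect_equal(length(readLines(paste0(prefix2, ".tsv"))), 1L)
  expect_equal(length(readLines(paste0(prefix2, ".bed"))), 0L)
})

test_that("chromosome plots render for typical call sets", {
  st <- toy_state()
  variants <- list(list(cnvs = list(), name = "none"),
                   list(cnvs = list(simulated_cnv("chr1", 3e6, 3.2e6, 0.5)),
                        name = "del"),
                   list(cnvs = list(simulated_cnv("chr1", 3e6, 3.4e6, 1.5)),
                        name = "dup"))
  for (v in variants) {
    case <- make_case(st$spec, v$cnvs, genome = st$genome, seed = 611)
    prof <- normalize_sample(case$sample, st$genome$gc, st$model)
    segs <- call_cnvs(prof, cbs_params(rng_seed = 3), chromosomes = "chr1")
    f <- tempfile(fileext = ".png")
    plot_chromosome(prof, segs, "chr1", file = f)
    expect_true(file.exists(f))
    expect_gt(file.info(f)$size, 5000)
  }
  expect_error(plot_chromosome(prof, segs, "chr99"), "unknown chromosome")
})

test_that("segmentation with a fixed rng_seed is reproducible", {
  g <- tiny_grid(300)
  set.seed(99)
  x <- rnorm(300, sd = 8); x[100:120] <- x[100:120] + 30
  prof <- make_profile(x, g)
  s1 <- cbs_segment(prof, cbs_params(rng_seed = 42))
  s2 <- cbs_segment(prof, cbs_params(rng_seed = 42))
  expect_identical(s1, s2)
})
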