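test_that("GC correction is the identity on GC-flat counts and symmetric", {
  g <- tiny_grid(2000)
  set.seed(3)
  gc <- structure(list(gc = runif(2000, 0.3, 0.7),
                       defined_frac = rep(1, 2000),
                       fingerprint = g$fingerprint), class = "gc_track")
  sc <- make_scaled(rep(100, 2000), g)
  out <- loess_gc_correct(sc, gc, g, min_bins = 100)
  expect_equal(out$values, sc$values, tolerance = 1e-8)

  # two bins with identical GC and counts get identical corrections
  gc$gc[2] <- gc$gc[1]
  sc2 <- make_scaled(c(80, 80, runif(1998, 90, 110)), g)
  out2 <- loess_gc_correct(sc2, gc, g, min_bins = 100)
  expect_equal(out2$values[1], out2$values[2])
})

test_that("GC correction removes a planted linear GC trend", {
  g <- tiny_grid(3000)
  set.seed(5)
  gcv <- runif(3000, 0.3, 0.7)
  gc <- structure(list(gc = gcv, defined_frac = rep(1, 3000),
                       fingerprint = g$fingerprint), class = "gc_track")
  counts <- 100 * (0.5 + gcv)
  sc <- make_scaled(counts, g)
  out <- loess_gc_correct(sc, gc, g, min_bins = 100)
  slope_before <- coef(lm(counts ~ gcv))[2]
  slope_after <- coef(lm(out$values ~ gcv))[2]
  expect_lt(abs(slope_after), abs(slope_before) / 10)
  # undefined-GC bins receive no GC-dependent correction, only flagged
  # (tested without compartment targets so no re-pinning rescale applies)
  gc$gc[5] <- NA
  sc_nt <- make_scaled(counts, g, targets = NULL)
  out3 <- loess_gc_correct(sc_nt, gc, g, min_bins = 100)
  expect_equal(out3$values[5], counts[5])
  expect_true(out3$gc_flagged[5])
})

test_that("a panel of identical samples trains a degenerate model", {
  g <- tiny_grid(400)
  gc <- flat_gc(g)
  common <- c(rep(100, 380), rep(0, 20))  # 20 dead bins
  panel <- lapply(1:10, function(i) make_scaled(common, g, sprintf("s%d", i)))
  model <- suppressWarnings(
    train_reference_model(panel, gc, g, n_components = 3))
  expect_equal(model$means[model$mask], common[model$mask])
  # a bin that is zero in every sample is filtered as low_mean
  expect_true(all(model$reason[381:400] == "low_mean"))
  expect_false(any(model$mask[381:400]))
})

test_that("the component basis captures planted rank-3 structure", {
  g <- tiny_grid(2500)
  gc <- flat_gc(g)
  ns <- 100
  set.seed(21)
  loadings <- matrix(rnorm(2500 * 3, sd = 5), 2500, 3)
  factors <- matrix(rnorm(ns * 3), ns, 3)
  art <- factors %*% t(loadings)
  noise <- matrix(rnorm(ns * 2500, sd = 2.5), ns, 2500)
  panel <- lapply(seq_len(ns), function(s)
    make_scaled(100 + art[s, ] + noise[s, ], g, sprintf("s%d", s)))
  model <- train_reference_model(panel, gc, g)
  expect_equal(model$n_components, 15L)
  # basis columns are orthonormal
  gram <- crossprod(model$basis)
  expect_equal(gram, diag(ncol(model$basis)), tolerance = 1e-8)
  # >= 99% of the planted artifact energy lies in the first 3 components
  A <- sweep(art[, model$pca_idx, drop = FALSE], 2,
             colMeans(art[, model$pca_idx, drop = FALSE]))
  captured <- sum((A %*% model$basis[, 1:3])^2) / sum(A^2)
  expect_gte(captured, 0.99)
})

test_that("small panels warn and truncate the component count", {
  g <- tiny_grid(300)
  gc <- flat_gc(g)
  set.seed(2)
  panel <- lapply(1:5, function(i)
    make_scaled(100 + rnorm(300), g, sprintf("s%d", i)))
  expect_warning(
    expect_warning(train_reference_model(panel, gc, g),
                   "components"),
    "recommended")
  model <- suppressWarnings(train_reference_model(panel, gc, g))
  expect_lte(model$n_components, 4L)
})

test_that("denoising projects out stored directions and nothing else", {
  g <- tiny_grid(500)
  gc <- flat_gc(g)
  ns <- 40
  set.seed(31)
  loadings <- matrix(rnorm(500 * 2, sd = 6), 500, 2)
  factors <- matrix(rnorm(ns * 2), ns, 2)
  panel_mat <- 100 + factors %*% t(loadings) +
    matrix(rnorm(ns * 500, sd = 1), ns, 500)
  panel <- lapply(seq_len(ns), function(s)
    make_scaled(panel_mat[s, ], g, sprintf("s%d", s)))
  model <- suppressWarnings(
    train_reference_model(panel, gc, g, n_components = 5))

  # a sample lying in centering + span(basis): residual deviation ~ 0
  idx <- model$pca_idx
  x <- rep(0, g$n_bins)
  x[idx] <- model$centering + as.numeric(model$basis %*% c(3, -2, 1, 0, 0))
  den <- pca_denoise(make_scaled(x, g), model)
  prof <- center_profile(den, model)
  expect_lt(max(abs(prof$values[idx] -
                      (model$centering - model$means[idx]))), 1e-8)

  # a sample orthogonal to the basis passes through unchanged
  set.seed(32)
  y <- rep(0, g$n_bins)
  ortho <- rnorm(length(idx))
  ortho <- ortho - model$basis %*% crossprod(model$basis, ortho)
  y[idx] <- model$centering + as.numeric(ortho)
  den_y <- pca_denoise(make_scaled(y, g), model)
  expect_equal(den_y, y, tolerance = 1e-8)
})

test_that("a planted CNV survives reference-panel denoising", {
  st <- toy_state()
  g <- st$genome
  cnv <- simulated_cnv("chr1", 5e6, 6e6, 1.5)   # 50 bins at +50%
  case <- make_case(st$spec, list(cnv), genome = g, seed = 501)
  scaled <- scale_compartments(case$sample, g$grid, st$model$targets)
  corr <- loess_gc_correct(scaled, g$gc, g$grid)
  rows <- which(g$grid$bins$chrom == "chr1" & g$grid$bins$start >= 5e6 &
                  g$grid$bins$end <= 6e6 & st$model$mask)
  before <- mean(corr$values[rows] - st$model$means[rows])
  den <- pca_denoise(corr, st$model)
  after <- mean(den[rows] - st$model$means[rows])
  expect_lt(abs(after - before) / abs(before), 0.10)
})

test_that("full-chain profiles of training samples center near zero", {
  st <- toy_state()
  g <- st$genome
  for (s in c(1, 25, 70)) {
    prof <- normalize_sample(st$panel$samples[[s]], g$gc, st$model)
    for (cn in g$grid$chromosomes$name) {
      rows <- g$grid$bins$chrom == cn & st$model$mask
      v <- prof$values[rows]
      # block SE because the smooth artifact correlates nearby bins;
      # chrX/chrY additionally keep their (non-PCA-removed) artifact,
      # bounded from the generator truth
      allow <- artifact_mean_allowance(st$spec, st$panel$factors[s, ],
                                       sum(rows))
      expect_lt(abs(mean(v, na.rm = TRUE)),
                3 * block_se(v) + allow + 0.1)
    }
  }
  # filtered bins are flagged NA, never silently zero
  prof <- normalize_sample(st$panel$samples[[1]], g$gc, st$model)
  expect_true(all(is.na(prof$values[!st$model$mask])))
  expect_true(all(is.finite(prof$values[st$model$mask])))
})

test_that("a planted heterozygous deletion sits near -m/2 after the chain", {
  st <- toy_state()
  g <- st$genome
  cnv <- simulated_cnv("chr2", 4e6, 4.4e6, 0.5)   # 20 bins
  case <- make_case(st$spec, list(cnv), genome = g, seed = 502)
  prof <- normalize_sample(case$sample, g$gc, st$model)
  rows <- which(g$grid$bins$chrom == "chr2" & g$grid$bins$start >= 4e6 &
                  g$grid$bins$end <= 4.4e6 & st$model$mask)
  m <- prof$mean_bin_count
  level <- mean(prof$values[rows])
  expect_lt(abs(level - (-m / 2)) / (m / 2), 0.15)
})

test_that("filtration is monotone in each threshold", {
  st <- toy_state()
  g <- st$genome
  panel <- lapply(st$panel$samples[1:30], function(s)
    loess_gc_correct(scale_compartments(s, g$grid), g$gc, g$grid))
  base <- suppressWarnings(
    train_reference_model(panel, g$gc, g$grid, min_training = 30))
  tighter <- list(
    suppressWarnings(train_reference_model(panel, g$gc, g$grid,
                                           low_mean_frac = 0.5,
                                           min_training = 30)),
    suppressWarnings(train_reference_model(panel, g$gc, g$grid,
                                           high_mean_frac = 1.5,
                                           min_training = 30)),
    suppressWarnings(train_reference_model(panel, g$gc, g$grid,
                                           high_var_frac = 2.0,
                                           min_training = 30)))
  for (m2 in tighter) {
    # tightening a threshold never unfilters a bin
    expect_true(all(which(!base$mask) %in% which(!m2$mask)))
    expect_gte(sum(!m2$mask), sum(!base$mask))
  }
})

test_that("an exclusion table masks bins with reason manual", {
  st <- toy_state()
  g <- st$genome
  excl <- data.frame(chrom = "chr1", start = 0, end = 100000)
  panel <- lapply(st$panel$samples[1:20], function(s)
    loess_gc_correct(scale_compartments(s, g$grid), g$gc, g$grid))
  model <- suppressWarnings(
    train_reference_model(panel, g$gc, g$grid, exclusion = excl,
                          min_training = 20))
  first5 <- 1:5
  expect_false(any(model$mask[first5]))
  expect_true(all(model$reason[first5] %in%
                    c("manual", "low_mean", "high_mean", "high_variance")))
  expect_true("manual" %in% model$reason[first5])
})

test_that("model serialization round-trips to bit-identical profiles", {
  st <- toy_state()
  g <- st$genome
  path <- tempfile(fileext = ".rds")
  save_reference_model(st$model, path)
  back <- load_reference_model(path)
  case <- make_case(st$spec, list(), genome = g, seed = 503)
  p1 <- normalize_sample(case$sample, g$gc, st$model)
  p2 <- normalize_sample(case$sample, g$gc, back)
  expect_identical(p1$values, p2$values)
  expect_identical(back$mask, st$model$mask)
  # a foreign RDS is rejected
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_reference_model(other), "format")
})

test_that("grid fingerprint mismatches are caught", {
  st <- toy_state()
  g_other <- tiny_grid(100)
  sc <- make_scaled(rep(100, 100), g_other)
  expect_error(pca_denoise(sc, st$model), "fingerprint")
})
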