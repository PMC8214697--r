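test_that("cv uses the sample standard deviation over unmasked bins", {
  expect_equal(cv(profile_from_counts(c(5, 5, 5, 5))), 0)
  expect_equal(cv(profile_from_counts(c(2, 4, 6, 8))),
               sqrt(20 / 3) / 5, tolerance = 1e-12)
  ## masked bins are excluded entirely
  p <- profile_from_counts(c(2, 4, 6, 8, 1000),
                           masked = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cv(p), sqrt(20 / 3) / 5, tolerance = 1e-12)
  expect_error(cv(profile_from_counts(c(0, 0, 0))), "zero mean")
  expect_error(cv(profile_from_counts(1:4, masked = rep(TRUE, 4))),
               "unmasked")
})

test_that("mapd log2-transforms with +1 pseudocount and pools across runs", {
  expect_equal(mapd(profile_from_counts(rep(9, 10))), 0)
  expect_equal(mapd(profile_from_counts(c(3, 7, 3, 7))), 1.0)
  ## a masked bin splits the profile into runs; d pooled across them
  p <- profile_from_counts(c(3, 7, 99, 3, 7),
                           masked = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(mapd(p), 1.0)
  ## runs never span a chromosome boundary
  p2 <- coverage_profile(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0, 1, 0, 1), end = c(1, 2, 1, 2), count = c(3, 7, 3, 7)))
  expect_equal(mapd(p2), 1.0)
  expect_error(mapd(profile_from_counts(c(1, 2), masked = c(FALSE, TRUE))),
               "run")
})

test_that("mapd with many zero bins underestimates local noise", {
  ## the zero-run artifact: interleaved zero bins drag the pooled median
  ## down relative to the same informative bins alone
  set.seed(42)
  counts <- rpois(50, 40)
  sparse <- as.vector(rbind(counts, 0, 0, 0))
  expect_lte(mapd(profile_from_counts(sparse)),
             mapd(profile_from_counts(counts)) + 1e-12)
})

test_that("lorenz curve sorts ascending and spans (0,0) to (1,1)", {
  lc <- lorenz_curve(profile_from_counts(c(1, 3)))
  expect_equal(lc$frac_bins, c(0, 0.5, 1))
  expect_equal(lc$frac_reads, c(0, 0.25, 1))
  lc2 <- lorenz_curve(profile_from_counts(c(0, 0, 0, 4)))
  expect_equal(lc2$frac_reads[lc2$frac_bins == 0.75], 0)
  expect_equal(lc2$frac_reads[5], 1)
  ## uniform counts lie on the diagonal
  lcu <- lorenz_curve(profile_from_counts(rep(7, 8)))
  expect_equal(lcu$frac_bins, lcu$frac_reads)
  expect_error(lorenz_curve(profile_from_counts(c(0, 0))), "zero total")
})

test_that("lorenz curve is monotone and convex on random profiles", {
  set.seed(7)
  for (i in 1:20) {
    counts <- rnbinom(sample(5:60, 1), mu = 20, size = 1)
    if (sum(counts) == 0) counts[1] <- 1
    lc <- lorenz_curve(profile_from_counts(counts))
    expect_true(all(diff(lc$frac_reads) >= -1e-12))
    slopes <- diff(lc$frac_reads) / diff(lc$frac_bins)
    expect_true(all(diff(slopes) >= -1e-9))
  }
})

test_that("gini matches worked values and the closed form for 1-of-n", {
  expect_equal(gini(profile_from_counts(rep(3, 6))), 0)
  expect_equal(gini(profile_from_counts(c(1, 3))), 0.25)
  expect_equal(gini(profile_from_counts(c(0, 0, 0, 4))), 0.75)
  expect_equal(gini(profile_from_counts(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 5))),
               0.9)
})

test_that("gini agrees with the mean-absolute-difference oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:80, 1)
    counts <- rnbinom(n, mu = 15, size = 0.8)
    if (sum(counts) == 0) counts[1] <- 1
    g <- gini(profile_from_counts(counts))
    expect_equal(g, gini_mad(counts), tolerance = 1 / n)
  }
})

test_that("gini and cv are invariant under uniform rescaling", {
  counts <- c(3, 9, 1, 14, 6)
  for (k in c(2, 10, 0.5)) {
    expect_equal(gini(profile_from_counts(counts * k)),
                 gini(profile_from_counts(counts)))
    expect_equal(cv(profile_from_counts(counts * k)),
                 cv(profile_from_counts(counts)))
  }
})

test_that("breadth counts unmasked bins at or above the depth threshold", {
  expect_equal(breadth(profile_from_counts(c(1, 2, 3))), 1)
  expect_equal(breadth(profile_from_counts(c(0, 0))), 0)
  expect_equal(breadth(profile_from_counts(c(2, 2, 1, 0)), min_depth = 2),
               0.5)
})

test_that("bin_coverage assigns read starts, honours MAPQ and masks", {
  g <- genome(c(chr1 = paste(rep("A", 100), collapse = "")),
              masks = data.frame(chrom = "chr1", start = 80L, end = 90L))
  reads <- data.frame(chrom = "chr1",
                      pos = c(rep(25L, 10), 5L, 85L),
                      mapq = c(rep(60, 10), 39, 60))
  p <- bin_coverage(reads, g, bin_size = 10)
  expect_equal(nrow(p$bins), 10)
  expect_equal(p$bins$count[3], 10)     # ten reads start in bin [20,30)
  expect_equal(p$bins$count[1], 0)      # MAPQ 39 read dropped
  expect_true(p$masked[9])              # bin inside the segdup mask
  expect_equal(sum(p$bins$count), 11)
})

test_that("metric_vs_scale rebins, thins, and respects trivial cases", {
  p <- profile_from_counts(rep(6, 16), bin_size = 10)
  tab <- metric_vs_scale(p, bin_sizes = c(10, 20, 40), metric = cv)
  expect_equal(tab$value, rep(0, 3))
  ## thinning fraction 1.0 leaves the metric unchanged
  p2 <- profile_from_counts(c(4, 9, 2, 14, 7, 7, 3, 1), bin_size = 10)
  t2 <- metric_vs_scale(p2, fractions = 1, metric = gini)
  expect_equal(t2$value, gini(p2))
})

test_that("cv shrinks with bin size for Poisson-like counts", {
  ## Poisson noise scales as 1/sqrt(bin size); mean CV over seeds must
  ## decrease when pooling 10x
  set.seed(3)
  ratio <- replicate(60, {
    p <- profile_from_counts(rpois(200, 8), bin_size = 10)
    tab <- metric_vs_scale(p, bin_sizes = c(10, 100), metric = cv)
    tab$value[tab$bin_size == 100] / tab$value[tab$bin_size == 10]
  })
  expect_lt(mean(ratio), 0.6)  # expected ~ 1/sqrt(10) = 0.32
})

test_that("coverage profiles reject malformed bins", {
  expect_error(coverage_profile(data.frame(
    chrom = "chr1", start = c(0, 5), end = c(10, 15), count = c(1, 1))),
    "overlapping")
  expect_error(coverage_profile(data.frame(
    chrom = "chr1", start = c(10, 0), end = c(20, 10), count = c(1, 1))),
    "sorted")
  expect_error(coverage_profile(data.frame(
    chrom = "chr1", start = 0, end = 10, count = -1)), "negative")
})
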