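test_that("callable filter applies the bulk/cell depth rule with the
          ceiling convention", {
  depth4 <- data.frame(chrom = "chr1", pos = 1:3, bulk = c(20, 14, 20),
                       c1 = c(10, 10, 10), c2 = c(6, 6, 2),
                       c3 = c(5, 5, 2), c4 = c(1, 9, 1))
  cf <- callable_filter(depth4)
  ## site 1: bulk 20, 3 of 4 cells >= 5 (>= ceiling(2)) -> pass
  ## site 2: bulk 14 -> fail;  site 3: only 1 of 4 cells -> fail
  expect_equal(cf$pass, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(cf$sites), 1)
  ## 2 of 5 cells fails the ceiling: ceiling(2.5) = 3
  depth5 <- data.frame(chrom = "chr1", pos = 1, bulk = 30,
                       c1 = 9, c2 = 9, c3 = 1, c4 = 0, c5 = 2)
  expect_false(callable_filter(depth5)$pass)
  ## callable span: dense rows count positions; site-sampled scales
  expect_equal(callable_filter(depth4)$callable_mb, 1 / 1e6)
  expect_equal(callable_filter(depth4, genome_mb = 300)$callable_mb, 100)
  expect_error(callable_filter(depth4[, 1:3]), "cell")
})

test_that("classification separates germline, somatic and false positive
          calls and partitions every variant", {
  bulk <- mk_callset("bulk", pos = c(10, 20), role = "bulk")
  cells <- list(
    mk_callset("c1", pos = c(10, 20, 30, 50)),
    mk_callset("c2", pos = c(10, 20, 30)),
    mk_callset("c3", pos = c(10, 30)),
    mk_callset("c4", pos = c(10, 20, 30, 60)))
  cls <- classify_variants(bulk, cells)
  lab <- with(cls$variants, stats::setNames(label, pos))
  expect_equal(unname(lab[c("10", "20")]), rep("germline", 2))
  expect_equal(unname(lab["30"]), "somatic")       # 4 cells, not in bulk
  expect_equal(unname(lab[c("50", "60")]), rep("false_positive", 2))
  ## partition: one label per variant, counts sum to total
  expect_equal(anyDuplicated(cls$variants[, c("chrom", "pos", "alt")]), 0)
  expect_equal(sum(table(cls$variants$label)), nrow(cls$variants))
  ## carrier counts
  nc <- with(cls$variants, stats::setNames(n_carriers, pos))
  expect_equal(unname(nc[c("10", "30", "50")]), c(4L, 4L, 1L))
})

test_that("callable restriction drops variants at non-callable sites", {
  bulk <- mk_callset("bulk", pos = c(10, 20), role = "bulk")
  cells <- list(mk_callset("c1", pos = c(10, 20, 30)),
                mk_callset("c2", pos = c(10, 30)))
  cls <- classify_variants(bulk, cells,
                           callable = data.frame(chrom = "chr1",
                                                 pos = c(10, 30)))
  expect_equal(sort(cls$variants$pos), c(10, 30))
})

test_that("high-quality flags follow the DP/GQ/AF thresholds exactly", {
  mk <- function(dp, gq, ad_alt) callset("c", data.frame(
    chrom = "chr1", pos = 1, ref = "A", alt = "T", dp = dp, gq = gq,
    ad_ref = dp - ad_alt, ad_alt = ad_alt, gt = "0/1"))
  bulk <- mk_callset("bulk", pos = 99, role = "bulk")
  hq_of <- function(cs) classify_variants(bulk, list(cs, mk_callset(
    "dummy", pos = 98)))$carriers$hq[1]
  expect_true(hq_of(mk(10, 20, 4)))            # VAF 0.4: all at threshold
  expect_false(hq_of(mk(9, 60, 4)))            # DP 9 < 10
  expect_false(hq_of(mk(30, 19, 15)))          # GQ 19 < 20
  expect_false(hq_of(mk(20, 60, 6)))           # VAF 0.30 < 0.35
  expect_true(hq_of(mk(20, 60, 7)))            # VAF 0.35 passes
})

test_that("class summaries report het fractions and per-cell precision", {
  bulk <- mk_callset("bulk", pos = 1:1000, role = "bulk")
  cells <- list(
    mk_callset("c1", pos = c(1:990, 2001:2010)),   # 990 germ + 10 FP
    mk_callset("c2", pos = 1:900))
  smry <- summarize_classes(classify_variants(bulk, cells))
  pc <- smry$per_cell
  expect_equal(pc$precision[pc$cell == "c1"], 0.99)
  expect_equal(pc$precision[pc$cell == "c2"], 1)
  expect_equal(smry$counts[["germline"]], 1000L)
  expect_equal(smry$counts[["false_positive"]], 10L)
  expect_equal(unname(smry$het_fraction["germline"]), 1)
})

test_that("somatic rate divides observed HQ somatics by sensitivity and
          callable span", {
  ## bulk: 10 HQ het germline; founder somatics at 101:200 in both cells
  bulk <- mk_callset("bulk", pos = 1:10, role = "bulk")
  som_pos <- 101:200
  full <- c(1:10, som_pos)
  c1 <- mk_callset("c1", pos = full)
  c2 <- mk_callset("c2", pos = full)
  cls <- classify_variants(bulk, list(c1, c2))
  ## sensitivity 1.0, 100 somatics, 100 Mb callable -> 1.0 per Mb
  r <- estimate_somatic_rate(cls, callable_mb = 100)
  expect_equal(r$rate_per_mb, c(1, 1))
  expect_equal(r$sensitivity, c(1, 1))
  ## dropping 1 of 10 germline and 10 of 100 somatics: 90 / (0.9 * 100)
  c3 <- mk_callset("c3", pos = c(1:9, som_pos[1:90]))
  cls2 <- classify_variants(bulk, list(c3, c2))
  r2 <- estimate_somatic_rate(cls2, callable_mb = 100)
  expect_equal(r2$rate_per_mb[r2$cell == "c3"], 90 / (0.9 * 100))
  ## genome-wide extrapolation at the default genome size
  r3 <- estimate_somatic_rate(cls, callable_mb = 200)
  expect_equal(r3$rate_per_mb, c(0.5, 0.5))
  expect_equal(r3$genome_wide, c(1544, 1544))
})

test_that("private HQ calls can optionally count as somatic", {
  bulk <- mk_callset("bulk", pos = 1:10, role = "bulk")
  c1 <- mk_callset("c1", pos = c(1:10, 50, 60))   # 2 private HQ calls
  c2 <- mk_callset("c2", pos = 1:10)
  cls <- classify_variants(bulk, list(c1, c2))
  r_rec <- estimate_somatic_rate(cls, callable_mb = 10)
  expect_equal(r_rec$n_hq_somatic, c(0, 0))
  r_priv <- estimate_somatic_rate(cls, callable_mb = 10,
                                  include_private = TRUE)
  expect_equal(r_priv$n_hq_somatic[r_priv$cell == "c1"], 2)
})

test_that("classification agrees with the generator's truth at high
          detection and zero FP burden", {
  sim <- simulate_kindred_dataset(n_cells = 4, genome_mb = 20,
                                  germline_density = 200, somatic_rate = 5,
                                  fp_burden = 0, detect_prob = 0.97,
                                  seed = 77L)
  cls <- classify_variants(sim$bulk, sim$cells)
  truth_lab <- with(sim$truth, stats::setNames(class,
                                               variant_key(chrom, pos,
                                                           alt)))
  got <- with(cls$variants, stats::setNames(label,
                                            variant_key(chrom, pos, alt)))
  common <- intersect(names(got), names(truth_lab))
  agree <- mean(got[common] == truth_lab[common])
  expect_gte(agree, 0.99)
})

test_that("corrected rate stays unbiased as detection probability drops", {
  ## lowering detect_prob lowers sensitivity but not the corrected rate
  rates <- sapply(c(0.95, 0.7), function(dp) {
    per_seed <- sapply(1:6, function(s) {
      sim <- simulate_kindred_dataset(n_cells = 4, genome_mb = 40,
                                      germline_density = 400,
                                      somatic_rate = 5, fp_burden = 10,
                                      detect_prob = dp, seed = 1000L + s)
      cls <- classify_variants(sim$bulk, sim$cells)
      attr(estimate_somatic_rate(cls, callable_mb = 40), "mean_rate")
    })
    mean(per_seed)
  })
  ## both within 15% of the planted 5 per Mb, and close to each other
  expect_equal(unname(rates[1]), 5, tolerance = 0.15)
  expect_equal(unname(rates[2]), 5, tolerance = 0.15)
})
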