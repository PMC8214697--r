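test_that("sensitivity is the detected fraction of bulk variants", {
  bulk <- mk_callset("bulk", pos = 1:10, role = "bulk")
  same <- mk_callset("c1", pos = 1:10)
  expect_equal(snv_sensitivity(same, bulk), 1)
  cell <- mk_callset("c2", pos = c(1:9, 101:103))
  expect_equal(snv_sensitivity(cell, bulk), 0.9)
  expect_equal(snv_sensitivity(mk_callset("c3", pos = 50:55), bulk), 0)
  expect_error(snv_sensitivity(cell, mk_callset("b0", pos = integer(),
                                                role = "bulk")), "empty")
  ## genotype mismatch still counts as detected
  hom <- mk_callset("c4", pos = 1:10, gt = "1/1", ad_alt = 20)
  expect_equal(snv_sensitivity(hom, bulk), 1)
})

test_that("sensitivity and missed fraction partition the bulk set", {
  set.seed(2)
  bulk <- mk_callset("bulk", pos = 1:50, role = "bulk")
  for (i in 1:10) {
    cell <- mk_callset("c", pos = sample(1:80, 30))
    miss <- sum(!(1:50 %in% cell$variants$pos)) / 50
    expect_equal(snv_sensitivity(cell, bulk) + miss, 1)
  }
})

test_that("discordant calls are cell-not-bulk with their VAFs", {
  bulk <- mk_callset("bulk", pos = 1:10, role = "bulk")
  expect_equal(discordant_calls(mk_callset("c", pos = 1:10), bulk)$count, 0)
  cell <- mk_callset("c", pos = c(1:10, 20, 21, 22), dp = 20,
                     ad_alt = c(rep(10, 10), 2, 4, 6))
  d <- discordant_calls(cell, bulk)
  expect_equal(d$count, 3)
  expect_equal(sort(d$vaf), c(0.1, 0.2, 0.3))
  expect_equal(d$rate, 3 / 13)
  ## dropout does not create discordance
  expect_equal(discordant_calls(mk_callset("c", pos = 1:4), bulk)$count, 0)
})

test_that("het-site allele metrics flag dropout outside the VAF bounds", {
  bulk <- mk_callset("bulk", pos = c(1, 2, 3), role = "bulk")
  cell <- callset("c", data.frame(
    chrom = "chr1", pos = c(1, 2, 3), ref = "A", alt = "T",
    dp = c(10, 12, 9), gq = 60,
    ad_ref = c(5, 12, 0), ad_alt = c(5, 0, 9), gt = "0/1"))
  m <- het_allele_metrics(cell, bulk, min_depth = 10)
  ## site 3 has depth 9 < 10: not evaluable; (5,5) fine, (12,0) is ADO
  expect_equal(m$n_evaluable, 2)
  expect_equal(m$ado_rate, 0.5)
  ## with depth 10 everywhere: VAFs 0.5, 0.0, 1.0 -> ADO 2/3
  cell2 <- callset("c", data.frame(
    chrom = "chr1", pos = c(1, 2, 3), ref = "A", alt = "T",
    dp = c(10, 12, 10), gq = 60,
    ad_ref = c(5, 12, 0), ad_alt = c(5, 0, 10), gt = "0/1"))
  m2 <- het_allele_metrics(cell2, bulk, min_depth = 10)
  expect_equal(m2$ado_rate, 2 / 3)
  expect_equal(sort(m2$vaf), c(0, 0.5, 1))
  ## uncalled site with coverage counts as ADO when depth supplied
  cell3 <- callset("c", data.frame(chrom = "chr1", pos = 1, ref = "A",
                                   alt = "T", dp = 10, gq = 60,
                                   ad_ref = 5, ad_alt = 5, gt = "0/1"))
  m3 <- het_allele_metrics(cell3, bulk, min_depth = 10,
                           cell_depth = data.frame(chrom = "chr1",
                                                   pos = c(2, 3),
                                                   dp = c(30, 4)))
  expect_equal(m3$n_evaluable, 2)  # site 3 has only 4x: not evaluable
  expect_equal(m3$ado_rate, 0.5)
})

test_that("base-change spectrum collapses purine references by reverse
          complement", {
  g <- genome(c(chr1 = "AACAATGTAA"))
  ## C>T at 0-based pos 2 (context ACA), G>A at pos 6 (context TGT)
  v <- data.frame(chrom = "chr1", pos = c(2, 6), ref = c("C", "G"),
                  alt = c("T", "A"))
  s6 <- base_change_spectrum(v, g)
  expect_equal(s6[["C>T"]], 2)
  expect_equal(sum(s6), 2)
  s96 <- trinucleotide_spectrum(v, g)
  expect_equal(s96[["A[C>T]A"]], 2)
  expect_equal(sum(s96), 2)
})

test_that("96-channel spectrum skips edges and N contexts, conserves
          counts, and ignores variant order", {
  g <- genome(c(chr1 = "ACGTNCGTACGT"))
  v <- data.frame(chrom = "chr1",
                  pos = c(0, 3, 6, 9),   # edge, N-context, ok, ok
                  ref = c("A", "T", "G", "C"),
                  alt = c("T", "G", "A", "T"))
  s <- trinucleotide_spectrum(v, g)
  expect_equal(sum(s), 2)
  expect_equal(attr(s, "n_skipped"), 2)
  s_rev <- trinucleotide_spectrum(v[rev(seq_len(nrow(v))), ], g)
  expect_equal(as.integer(s_rev), as.integer(s))
})

test_that("strand collapse is involution-consistent: the reverse
          complement genome gives identical channels", {
  set.seed(9)
  g <- random_genome(c(chr1 = 3000L), seed = 10)
  seq_chr <- as.character(g$seq[[1]])
  n <- nchar(seq_chr)
  pos <- sample(1:(n - 2), 40)
  ref <- vapply(pos, function(p) substr(seq_chr, p + 1, p + 1),
                character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), character(1))
  v <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_seq <- paste(rev(unname(comp[strsplit(seq_chr, "")[[1]]])),
                  collapse = "")
  g_rc <- genome(c(chr1 = rc_seq))
  v_rc <- data.frame(chrom = "chr1", pos = n - 1 - pos,
                     ref = unname(comp[ref]), alt = unname(comp[alt]))
  expect_equal(as.integer(trinucleotide_spectrum(v_rc, g_rc)),
               as.integer(trinucleotide_spectrum(v, g)))
})

test_that("signature reconstruction solves non-negative least squares", {
  set.seed(21)
  k <- 3
  M <- matrix(rexp(96 * k), 96, k)
  M <- sweep(M, 2, colSums(M), "/")
  colnames(M) <- paste0("S", 1:k)
  ## a pure reference column: exposure 1 on it, cosine 1
  fit <- reconstruct_signature(M[, 2], M)
  expect_equal(unname(fit$exposures), c(0, 1, 0), tolerance = 1e-6)
  expect_equal(fit$cosine, 1, tolerance = 1e-8)
  ## a known mixture is recovered
  mix <- 0.6 * M[, 1] + 0.4 * M[, 3]
  fit2 <- reconstruct_signature(mix, M)
  expect_equal(unname(fit2$exposures[c(1, 3)]), c(0.6, 0.4),
               tolerance = 0.01)
  ## orthogonal spectrum: cosine near zero
  Mo <- rbind(diag(2), matrix(0, 94, 2))
  colnames(Mo) <- c("A", "B")
  s <- c(0, 0, 1, rep(0, 93))
  expect_lt(reconstruct_signature(s, Mo)$cosine, 1e-8)
  expect_error(reconstruct_signature(rep(0, 96), M), "zero")
})

test_that("NNLS matches the simplex grid-search oracle and beats any
          single column", {
  set.seed(31)
  for (i in 1:5) {
    k <- sample(2:3, 1)
    M <- matrix(rexp(96 * k), 96, k)
    M <- sweep(M, 2, colSums(M), "/")
    colnames(M) <- paste0("S", 1:k)
    w <- runif(k); w <- w / sum(w)
    s <- as.numeric(M %*% w) + abs(rnorm(96, sd = 0.001))
    s <- s / sum(s)
    fit <- reconstruct_signature(s, M)
    oracle <- nnls_grid(M, s)
    expect_lte(sum((s - M %*% fit$exposures)^2), oracle$objective + 1e-8)
    ## cosine at least as good as the best single reference column
    single <- max(apply(M, 2, function(col)
      sum(s * col) / sqrt(sum(s^2) * sum(col^2))))
    expect_gte(fit$cosine, single - 1e-8)
  }
})
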