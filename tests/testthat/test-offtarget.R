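proto <- "GACGTTAACCGGATTCACGA"

embed_site <- function(core, at, len = 2000, seed = 1) {
  ## plants `core` (protospacer+PAM, or its reverse complement) at
  ## 0-based `at` in a random background
  g <- random_genome(c(chr1 = len), seed = seed)
  s <- as.character(g$seq[[1]])
  substr(s, at + 1, at + nchar(core)) <- core
  genome(c(chr1 = s))
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

test_that("exact protospacer+NGG embeddings are found with the canonical
          cut 3 bp 5' of the PAM", {
  g <- embed_site(paste0(proto, "AGG"), at = 700)
  s <- enumerate_candidate_sites(g, protospacer_query(proto, 0))
  expect_equal(nrow(s), 1)
  expect_equal(s$strand, "+")
  expect_equal(s$mismatches, 0)
  expect_equal(s$start, 700)
  expect_equal(s$cut, 717)
})

test_that("reverse-complement embeddings map to minus-strand sites with
          forward cut coordinates", {
  core <- paste0(proto, "TGG")
  g <- embed_site(revcomp(core), at = 900, seed = 2)
  s <- enumerate_candidate_sites(g, protospacer_query(proto, 0))
  expect_equal(nrow(s), 1)
  expect_equal(s$strand, "-")
  expect_equal(s$start, 900)
  ## minus-strand cut: 6 bases from the forward window start
  expect_equal(s$cut, 906)
  ## agreement with the brute-force scan
  bf <- brute_force_sites(g, proto, 0)
  expect_equal(s$cut, bf$cut)
  expect_equal(s$strand, bf$strand)
})

test_that("the mismatch budget and the PAM are enforced", {
  mm6 <- proto
  for (i in c(1, 4, 7, 10, 13, 16)) {
    b <- substr(mm6, i, i)
    substr(mm6, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  g6 <- embed_site(paste0(mm6, "AGG"), at = 500, seed = 3)
  expect_equal(nrow(enumerate_candidate_sites(
    g6, protospacer_query(proto, 5))), 0)
  ## NAG PAM is not NGG
  gnag <- embed_site(paste0(proto, "AAG"), at = 500, seed = 4)
  expect_equal(nrow(enumerate_candidate_sites(
    gnag, protospacer_query(proto, 5))), 0)
  ## windows containing N are skipped
  gn <- embed_site(paste0(substr(proto, 1, 10), "N",
                          substr(proto, 12, 20), "AGG"), at = 500,
                   seed = 5)
  expect_equal(nrow(enumerate_candidate_sites(
    gn, protospacer_query(proto, 5))), 0)
  expect_error(protospacer_query("ACGT"), "20")
  expect_error(protospacer_query("NACGTACGTACGTACGTACG"), "ACGT")
})

test_that("enumeration equals the brute-force double-strand scan on random
          genomes and is monotone in the mismatch budget", {
  set.seed(55)
  for (case in 1:12) {
    p <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
    g <- random_genome(c(chr1 = 1500L, chr2 = 800L), seed = 100 + case)
    prev <- -1L
    for (mm in c(3, 5, 6)) {
      got <- enumerate_candidate_sites(g, protospacer_query(p, mm))
      bf <- brute_force_sites(g, p, mm)
      expect_equal(nrow(got), nrow(bf))
      if (nrow(bf)) {
        expect_equal(got$start, bf$start)
        expect_equal(got$strand, bf$strand)
        expect_equal(got$mismatches, bf$mismatches)
        expect_equal(got$cut, bf$cut)
      }
      expect_gte(nrow(got), prev)
      prev <- nrow(got)
    }
  }
})

test_that("indel attribution applies the window, bulk and cross-gRNA
          exclusions and assigns the nearest cut", {
  sites <- list(g1 = data.frame(chrom = "chr1", start = 0, end = 23,
                                strand = "+", mismatches = 0,
                                cut = c(1000, 1100)))
  grna_of <- c(e1 = "g1", e2 = "g1", ctrl = "control")
  mk_indel <- function(sample, pos, alt = "AT", ref = "A")
    mk_callset(sample, pos = pos, ref = ref, alt = alt)
  cells <- list(
    mk_indel("e1", pos = c(1010, 1160, 1045, 1500)),
    mk_indel("e2", pos = 1045),
    mk_indel("ctrl", pos = 1090))
  bulk <- mk_indel("bulk", pos = 1045)
  att <- attribute_indels(cells, sites, bulk = bulk, grna_of = grna_of)
  a <- att$attributed
  ## 1010: 10 bp from cut 1000 -> attributed to 1000
  ## 1160: 60 bp from both cuts -> dropped
  ## 1045: in bulk -> dropped;  1500: far -> dropped
  expect_equal(a$pos, 1010)
  expect_equal(a$site_cut, 1000)
  ## equidistant tie goes to the lower cut coordinate
  cells2 <- list(mk_indel("e1", pos = 1050), mk_indel("e2", pos = 2))
  a2 <- attribute_indels(cells2, sites, grna_of = grna_of)$attributed
  expect_equal(a2$site_cut, 1000)
  ## control-cell hits near sites are presumed false positives
  expect_equal(att$presumed_fp$cell, "ctrl")
  expect_equal(att$presumed_fp$pos, 1090)
  ## an indel shared with a cell of a different gRNA is excluded
  grna_of3 <- c(e1 = "g1", x1 = "g2")
  sites3 <- list(g1 = sites$g1,
                 g2 = data.frame(chrom = "chr1", start = 0, end = 23,
                                 strand = "+", mismatches = 0, cut = 5000))
  cells3 <- list(mk_indel("e1", pos = 1010), mk_indel("x1", pos = 1010))
  a3 <- attribute_indels(cells3, sites3, grna_of = grna_of3)$attributed
  expect_equal(nrow(a3), 0)
  expect_error(attribute_indels(cells, list(g1 = sites$g1[0, ]),
                                grna_of = grna_of), "empty")
})

test_that("non-recurrent single-base insertions are removed, everything
          else kept", {
  att <- data.frame(
    cell = c("e1", "e1", "e2", "e1", "e2"),
    grna = "g1", chrom = "chr1",
    pos = c(10, 20, 20, 30, 40),
    ref = c("A", "A", "A", "ACCT", "A"),
    alt = c("AT", "AG", "AG", "A", "AGG"),
    site_cut = 0, dist = 0)
  f <- recurrence_filter(att)
  ## pos 10: 1-bp insertion in one cell -> removed
  ## pos 20: same 1-bp insertion in two cells -> kept
  ## pos 30: deletion in one cell -> kept; pos 40: 2-bp insertion -> kept
  expect_equal(f$n_removed, 1)
  expect_equal(f$removed$pos, 10)
  expect_equal(sort(f$kept$pos), c(20, 20, 30, 40))
})

test_that("SV attribution needs both breakpoints near cuts and drops
          events shared with other-gRNA or control cells", {
  sites <- list(g1 = data.frame(chrom = "chr1", start = 0, end = 23,
                                strand = "+", mismatches = 0,
                                cut = c(1000, 9000)))
  grna_of <- c(e1 = "g1", e2 = "g1", ctrl = "control")
  pairs <- data.frame(
    cell = c("e1", "e1", "e2", "ctrl"),
    chromA = "chr1", posA = c(1050, 1050, 1100, 1010),
    chromB = "chr1", posB = c(8950, 9500, 9100, 8990))
  r <- attribute_svs(pairs, sites, grna_of)
  ## e1 #1: both ends within 200 of (different) cuts -> kept
  ## e1 #2: one end 500 away -> dropped
  ## e2: kept;  ctrl: near cuts but control -> counted, never attributed
  expect_equal(sort(r$attributed$cell), c("e1", "e2"))
  expect_equal(r$n_control_window_hits, 1)
  expect_equal(unname(r$per_cell["ctrl"]), 0)
  ## an event also present in a control cell is excluded
  pairs2 <- rbind(pairs[1, ],
                  transform(pairs[1, ], cell = "ctrl"))
  r2 <- attribute_svs(pairs2, sites, grna_of)
  expect_equal(nrow(r2$attributed), 0)
  ## malformed pair rejects with its row
  bad <- pairs; bad$posB[2] <- NA
  expect_error(attribute_svs(bad, sites, grna_of), "row 2")
})

test_that("closed loop: planted off-target indels are recovered, background
          insertions removed, control SVs empty", {
  d <- demo_edited_genome(seed = 8)
  sim <- simulate_edited_dataset(d$genome, d$protospacer,
                                 n_edited = 4, n_control = 3,
                                 offtarget_sites = d$offtargets,
                                 sv_pairs = d$sv_pairs,
                                 bg_insertions = 3, seed = 9)
  sites <- list(g1 = sim$sites)
  att <- attribute_indels(sim$cells, sites, bulk = NULL,
                          grna_of = sim$grna_of)
  rec <- recurrence_filter(att$attributed)
  ## every planted edit indel is recovered after the recurrence filter
  planted <- sim$truth[sim$truth$class == "edit_indel", ]
  for (k in seq_len(nrow(planted))) {
    hit <- rec$kept$cell == planted$cell[k] &
      abs(rec$kept$site_cut - planted$cut[k]) <= 2
    expect_true(any(hit))
  }
  ## every attributed-and-kept call is a planted edit (no background
  ## insertion survives: they are non-recurrent 1-bp insertions)
  expect_true(all(nchar(rec$kept$ref) > nchar(rec$kept$alt)))
  ## SVs: none in control cells
  sv <- attribute_svs(sim$sv, sites, sim$grna_of)
  ctrl <- names(sim$grna_of)[sim$grna_of == "control"]
  expect_equal(sum(sv$attributed$cell %in% ctrl), 0)
})
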