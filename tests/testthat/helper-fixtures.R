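## Shared fixtures, built in code at test time.

## Minimal callset from a compact spec: pos vector plus optional fields.
mk_callset <- function(sample, pos, alt = "T", ref = "A", chrom = "chr1",
                       dp = 20, gq = 60, ad_alt = 10, gt = "0/1",
                       role = "cell") {
  n <- length(pos)
  callset(sample,
          data.frame(chrom = rep_len(chrom, n), pos = pos,
                     ref = rep_len(ref, n), alt = rep_len(alt, n),
                     dp = rep_len(dp, n), gq = rep_len(gq, n),
                     ad_ref = rep_len(dp, n) - rep_len(ad_alt, n),
                     ad_alt = rep_len(ad_alt, n), gt = rep_len(gt, n)),
          role = role)
}

## Brute-force Gini via the mean-absolute-difference formula
## sum|c_i - c_j| / (2 n^2 mu): the independent oracle for gini().
gini_mad <- function(counts) {
  n <- length(counts)
  mu <- mean(counts)
  sum(abs(outer(counts, counts, "-"))) / (2 * n^2 * mu)
}

## Brute-force double-strand candidate-site scan: the independent oracle
## for enumerate_candidate_sites(), pure character comparison.
brute_force_sites <- function(genome, protospacer, max_mm = 5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  pvec <- strsplit(protospacer, "")[[1]]
  out <- list()
  for (ch in names(genome$lengths)) {
    s <- as.character(genome$seq[[ch]])
    len <- nchar(s)
    for (w0 in 0:(len - 23L)) {
      win <- substr(s, w0 + 1L, w0 + 23L)
      if (grepl("N", win, fixed = TRUE)) next
      ## forward: protospacer at 1..20, GG at 22..23
      if (substr(win, 22, 23) == "GG") {
        mm <- sum(strsplit(substr(win, 1, 20), "")[[1]] != pvec)
        if (mm <= max_mm)
          out[[length(out) + 1L]] <-
            data.frame(chrom = ch, start = w0, strand = "+", mismatches = mm,
                       cut = w0 + 17L)
      }
      ## reverse: site reads protospacer+PAM on the minus strand
      rwin <- rc(win)
      if (substr(rwin, 22, 23) == "GG") {
        mm <- sum(strsplit(substr(rwin, 1, 20), "")[[1]] != pvec)
        if (mm <= max_mm)
          out[[length(out) + 1L]] <-
            data.frame(chrom = ch, start = w0, strand = "-", mismatches = mm,
                       cut = w0 + 6L)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      cut = integer()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), ]
}

## Grid-search oracle for non-negative least squares on k <= 3 columns:
## exhaustive search over a lattice of non-negative exposures.
nnls_grid <- function(M, s, emax = 1.5, step = 0.02) {
  k <- ncol(M)
  grid <- seq(0, emax, by = step)
  best <- NULL; best_obj <- Inf
  if (k == 1) combos <- matrix(grid, ncol = 1)
  else if (k == 2) combos <- as.matrix(expand.grid(grid, grid))
  else combos <- as.matrix(expand.grid(grid, grid, grid))
  for (i in seq_len(nrow(combos))) {
    e <- combos[i, ]
    obj <- sum((s - M %*% e)^2)
    if (obj < best_obj) { best_obj <- obj; best <- e }
  }
  list(exposures = best, objective = best_obj)
}
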