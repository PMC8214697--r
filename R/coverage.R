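#' Binned coverage profile
#'
#' Ordered, uniform-width, non-overlapping genomic bins with read counts.
#' Bins flagged as masked (assembly gaps, segmental duplications) are
#' excluded from every statistic computed on the profile.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `count`.
#' @param masked optional logical vector flagging bins to exclude.
#' @return Object of class `scwga_coverage` with elements `bins` and
#'   `masked`.
#' @export
coverage_profile <- function(bins, masked = NULL) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "count") %in% names(bins)))
  if (nrow(bins) == 0L) stop("profile needs at least one bin")
  if (any(bins$count < 0)) stop("negative bin counts")
  ## sorted, non-overlapping within chromosome
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins not sorted on ", ch)
    ov <- which(b$start[-1L] < b$end[-nrow(b)])
    if (length(ov))
      stop(sprintf("overlapping bins on %s: [%d,%d) and [%d,%d)", ch,
                   b$start[ov[1]], b$end[ov[1]],
                   b$start[ov[1] + 1L], b$end[ov[1] + 1L]))
  }
  if (is.null(masked)) masked <- rep(FALSE, nrow(bins))
  stopifnot(length(masked) == nrow(bins))
  structure(list(bins = as.data.frame(bins), masked = as.logical(masked)),
            class = "scwga_coverage")
}

#' @export
print.scwga_coverage <- function(x, ...) {
  cat(sprintf("scwga coverage profile: %d bins (%d masked), %s reads\n",
              nrow(x$bins), sum(x$masked),
              format(sum(x$bins$count[!x$masked]), big.mark = ",")))
  invisible(x)
}

## Unmasked counts, in genomic order.
profile_counts <- function(profile) {
  stopifnot(inherits(profile, "scwga_coverage"))
  profile$bins$count[!profile$masked]
}

#' Coverage profile from a bare count vector
#'
#' Convenience constructor: consecutive bins of `bin_size` on one
#' chromosome with the given counts.
#' @param counts numeric vector of bin counts.
#' @param bin_size bin width (default 1).
#' @param chrom chromosome name.
#' @param masked optional logical mask.
#' @return A [coverage_profile()].
#' @export
profile_from_counts <- function(counts, bin_size = 1L, chrom = "chr1",
                                masked = NULL) {
  n <- length(counts)
  coverage_profile(data.frame(chrom = chrom,
                              start = (seq_len(n) - 1L) * bin_size,
                              end = seq_len(n) * bin_size,
                              count = counts), masked = masked)
}

#' Bin read starts into a coverage profile
#'
#' Reads with mapping quality below `mapq_min` are dropped (when a `mapq`
#' column is present). A read is assigned to the bin containing its start.
#' Bins overlapping any masked interval of the genome are flagged and
#' excluded from downstream statistics.
#'
#' @param reads data.frame with `chrom`, `pos` (0-based read start) and
#'   optionally `mapq`.
#' @param genome an [genome()] supplying sequence lengths and masks.
#' @param bin_size bin width in bases.
#' @param mapq_min minimum mapping quality (default 40).
#' @return A [coverage_profile()].
#' @export
bin_coverage <- function(reads, genome, bin_size, mapq_min = 40) {
  stopifnot(bin_size >= 1)
  if (!is.null(reads$mapq)) reads <- reads[reads$mapq >= mapq_min, ,
                                           drop = FALSE]
  bins <- do.call(rbind, lapply(names(genome$lengths), function(ch) {
    len <- genome$lengths[[ch]]
    if (bin_size > len)
      warning("bin_size exceeds length of ", ch, "; using a single bin")
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, len))
  }))
  key <- paste(bins$chrom, bins$start)
  idx <- match(paste(reads$chrom, (reads$pos %/% bin_size) * bin_size), key)
  counts <- tabulate(idx, nbins = nrow(bins))
  masked <- rep(FALSE, nrow(bins))
  m <- genome$masks
  if (nrow(m)) {
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(bins$chrom,
                             IRanges::IRanges(bins$start + 1L, bins$end)),
      GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$start + 1L, m$end)))
    masked[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  bins$count <- counts
  coverage_profile(bins, masked)
}

#' Coefficient of variation of binned coverage
#'
#' `sd(c)/mean(c)` over unmasked bins, with the sample (n - 1) standard
#' deviation.
#'
#' @param profile a [coverage_profile()].
#' @return Non-negative numeric scalar.
#' @examples
#' cv(profile_from_counts(c(2, 4, 6, 8)))  # 0.5164
#' @export
cv <- function(profile) {
  c_ <- profile_counts(profile)
  if (length(c_) < 2L) stop("CV needs at least 2 unmasked bins")
  mu <- mean(c_)
  if (mu <= 0) stop("CV undefined for zero mean coverage")
  stats::sd(c_) / mu
}

#' Median absolute pairwise difference (MAPD) of log2 coverage
#'
#' Bin counts are log2-transformed with a +1 pseudocount,
#' `x_i = log2(c_i + 1)`; absolute differences `|x_(i+1) - x_i|` are formed
#' within each maximal run of consecutive unmasked bins (runs never span a
#' chromosome boundary or a masked bin), pooled across runs, and the pooled
#' median is returned. Small values mean locally smooth coverage.
#'
#' @param profile a [coverage_profile()].
#' @return Non-negative numeric scalar.
#' @examples
#' mapd(profile_from_counts(c(3, 7, 3, 7)))  # 1.0
#' @export
mapd <- function(profile) {
  b <- profile$bins
  run <- cumsum(profile$masked |
                  c(TRUE, b$chrom[-1L] != b$chrom[-nrow(b)]))
  keep <- !profile$masked
  d <- unlist(lapply(split(b$count[keep], run[keep]), function(cc) {
    if (length(cc) < 2L) return(numeric())
    abs(diff(log2(cc + 1)))
  }), use.names = FALSE)
  if (!length(d))
    stop("MAPD needs a run of at least 2 consecutive unmasked bins")
  stats::median(d)
}

#' Lorenz curve of binned coverage
#'
#' Bins are sorted ascending by count; the curve traces cumulative fraction
#' of bins against cumulative fraction of reads. A perfectly uniform
#' profile lies on the diagonal.
#'
#' @param profile a [coverage_profile()].
#' @return data.frame with columns `frac_bins`, `frac_reads`, starting at
#'   (0, 0) and ending at (1, 1); the curve is monotone and convex.
#' @export
lorenz_curve <- function(profile) {
  c_ <- profile_counts(profile)
  tot <- sum(c_)
  if (tot <= 0) stop("Lorenz curve undefined for zero total reads")
  ## stable sort keeps equal counts in input order
  c_ <- sort(c_, method = "radix")
  n <- length(c_)
  data.frame(frac_bins = c(0, seq_len(n) / n),
             frac_reads = c(0, cumsum(c_) / tot))
}

#' Gini index of binned coverage
#'
#' One minus twice the trapezoidal area under the [lorenz_curve()];
#' 0 for perfectly uniform coverage, approaching 1 as reads concentrate in
#' few bins.
#'
#' @param profile a [coverage_profile()].
#' @return Numeric in `[0, 1)`.
#' @examples
#' gini(profile_from_counts(c(1, 3)))  # 0.25
#' @export
gini <- function(profile) {
  lc <- lorenz_curve(profile)
  auc <- sum(diff(lc$frac_bins) *
               (utils::head(lc$frac_reads, -1) + lc$frac_reads[-1]) / 2)
  1 - 2 * auc
}

#' Coverage breadth
#'
#' Fraction of unmasked bins (or per-base positions, if the profile's bins
#' are 1 bp wide) with count at least `min_depth`.
#'
#' @param profile a [coverage_profile()].
#' @param min_depth minimum count (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
breadth <- function(profile, min_depth = 1) {
  c_ <- profile_counts(profile)
  if (!length(c_)) stop("no unmasked bins")
  mean(c_ >= min_depth)
}

#' Coverage metric across bin sizes or subsampling depths
#'
#' Recomputes a uniformity metric while re-binning the profile at coarser
#' bin sizes (multiples of the native width, bins pooled by sum) and/or
#' thinning counts binomially to a fraction of the reads. Emulates
#' mean-CV/MAPD-versus-bin-size and metric-versus-depth sweeps.
#'
#' @param profile a [coverage_profile()] at the native bin width.
#' @param bin_sizes integer vector of target bin widths (each a multiple of
#'   the native width).
#' @param fractions numeric vector of subsample fractions in (0, 1].
#' @param metric function mapping a profile to a scalar, e.g. [cv] or
#'   [mapd].
#' @param seed seed for the binomial thinning.
#' @return data.frame with columns `bin_size`, `fraction`, `value`.
#' @export
metric_vs_scale <- function(profile, bin_sizes = NULL, fractions = 1,
                            metric = cv, seed = 1L) {
  native <- profile$bins$end[1L] - profile$bins$start[1L]
  if (is.null(bin_sizes)) bin_sizes <- native
  grid <- expand.grid(bin_size = bin_sizes, fraction = fractions)
  grid$value <- mapply(function(bs, fr) {
    p <- rebin_profile(profile, bs)
    if (fr < 1) {
      p$bins$count <- with_stream(seed, sprintf("thin/%d/%g", bs, fr),
                                  stats::rbinom(nrow(p$bins),
                                                size = p$bins$count,
                                                prob = fr))
    }
    metric(p)
  }, grid$bin_size, grid$fraction)
  grid
}

## Pool native bins into wider bins (sum of counts); a pooled bin is masked
## if any constituent is masked.
rebin_profile <- function(profile, bin_size) {
  b <- profile$bins
  native <- b$end[1L] - b$start[1L]
  if (bin_size == native) return(profile)
  if (bin_size %% native != 0)
    stop("bin_size must be a multiple of the native width ", native)
  grp <- paste(b$chrom, (b$start %/% bin_size) * bin_size)
  first <- !duplicated(grp)
  agg_count <- tapply(b$count, grp, sum)[grp[first]]
  agg_mask <- tapply(profile$masked, grp, any)[grp[first]]
  coverage_profile(data.frame(chrom = b$chrom[first],
                              start = (b$start[first] %/% bin_size) * bin_size,
                              end = (b$start[first] %/% bin_size) * bin_size +
                                bin_size,
                              count = as.numeric(agg_count)),
                   masked = as.logical(agg_mask))
}
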