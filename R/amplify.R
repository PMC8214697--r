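#' Configuration for the whole-genome amplification simulator
#'
#' The simulator is a discrete-round branching process over amplicons.
#' Each round, every template receives a Poisson number of primers
#' proportional to its effective length; each primed copy extends until it
#' either incorporates a chain terminator (per-base probability
#' `termination_prob`) or reaches the template end. Terminated daughter
#' amplicons re-enter the template pool down-weighted by `reprime_weight`;
#' the two primary haplotypes are always full-weight templates. Copies
#' inherit their template's copying errors and add new ones at
#' `error_rate` per base.
#'
#' Mode presets: `"quasilinear"` (terminator-rich, PTA-like) uses
#' `termination_prob = 2e-3` (mean amplicon ~500 b), `reprime_weight =
#' 0.05` and `priming_rate = 2` per kb per round, so amplification
#' originates mostly from the primary template, product piles up as many
#' short overlapping amplicons, and daughter errors propagate poorly.
#' `"exponential"` (MDA-like) uses `termination_prob = 5e-5` (mean
#' amplicon tens of kb), `reprime_weight = 1` and `priming_rate = 0.05`,
#' so early long daughters are re-amplified in full and both coverage
#' bias and errors compound across rounds. The two priming presets keep
#' total product mass on the same order between modes at the default
#' round count.
#'
#' @param mode `"quasilinear"` or `"exponential"`.
#' @param priming_rate expected primer bindings per kb of effective
#'   template per round; `NULL` takes the mode preset.
#' @param termination_prob per-base chance of incorporating a terminator
#'   (`0 <= alpha < 1`); `NULL` takes the mode preset.
#' @param reprime_weight relative template weight of terminated daughter
#'   amplicons; `NULL` takes the mode preset.
#' @param error_rate per-base copying error probability.
#' @param rounds number of amplification rounds (>= 1).
#' @param ploidy number of primary haplotypes (default 2).
#' @param seed integer seed; a fixed seed gives byte-identical pools.
#' @return A list of class `scwga_sim_config`.
#' @export
sim_config <- function(mode = c("quasilinear", "exponential"),
                       priming_rate = NULL, termination_prob = NULL,
                       reprime_weight = NULL, error_rate = 1e-4,
                       rounds = 6L, ploidy = 2L, seed = 1L) {
  mode <- match.arg(mode)
  priming_rate <- priming_rate %||%
    switch(mode, quasilinear = 2, exponential = 0.05)
  alpha <- termination_prob %||%
    switch(mode, quasilinear = 2e-3, exponential = 5e-5)
  rho <- reprime_weight %||% switch(mode, quasilinear = 0.05,
                                    exponential = 1.0)
  stopifnot(priming_rate >= 0, alpha >= 0, alpha < 1, rho >= 0, rho <= 1,
            error_rate >= 0, error_rate <= 1, ploidy >= 1)
  if (rounds < 1) stop("rounds must be >= 1")
  if (mode == "quasilinear" && alpha == 0)
    warning("termination_prob = 0 in quasilinear mode degenerates to ",
            "exponential amplification")
  structure(list(mode = mode, priming_rate = priming_rate,
                 termination_prob = alpha, reprime_weight = rho,
                 error_rate = error_rate, rounds = as.integer(rounds),
                 ploidy = as.integer(ploidy), seed = as.integer(seed)),
            class = "scwga_sim_config")
}

#' Simulate whole-genome amplification as a branching process
#'
#' Runs the branching process described in [sim_config()] over the
#' sequences of `genome`. Positions are 0-based half-open; errors are
#' stored as absolute genomic positions on the amplicon carrying them.
#' Generation 0 entries are the intact primary haplotypes.
#'
#' @param genome an [genome()]; only sequence lengths are used.
#' @param config an [sim_config()].
#' @return Object of class `scwga_amplicon_pool`: data.frame-like list
#'   with vectors `hap`, `chrom`, `start`, `end`, `gen`, `terminated` and
#'   a list column `errors` (integer positions per amplicon).
#' @export
simulate_amplification <- function(genome, config) {
  stopifnot(inherits(genome, "scwga_genome"), inherits(config,
                                                       "scwga_sim_config"))
  if (length(genome$seq) == 0L) stop("genome is empty")
  chroms <- names(genome$lengths)
  ## primaries: ploidy copies of every chromosome, generation 0
  hap <- rep(seq_len(config$ploidy), times = length(chroms))
  chrom <- rep(chroms, each = config$ploidy)
  start <- rep(0L, length(chrom))
  end <- as.integer(genome$lengths[chrom])
  gen <- rep(0L, length(chrom))
  terminated <- rep(FALSE, length(chrom))
  errors <- rep(list(integer()), length(chrom))

  alpha <- config$termination_prob
  rho <- config$reprime_weight
  with_stream(config$seed, "amplification", {
    for (r in seq_len(config$rounds)) {
      len <- end - start
      eff <- ifelse(gen == 0L, len,
                    ifelse(terminated, len * rho, len))
      n_new <- stats::rpois(length(eff), config$priming_rate * eff / 1000)
      tmpl <- rep.int(seq_along(n_new), n_new)
      if (!length(tmpl)) next
      ## primer position uniform along the template; extension runs toward
      ## the template 3' end until a terminator or the end
      s_new <- start[tmpl] + floor(stats::runif(length(tmpl)) *
                                     (end[tmpl] - start[tmpl]))
      ext <- if (alpha > 0) stats::rgeom(length(tmpl), alpha) + 1 else
        rep(Inf, length(tmpl))
      e_new <- pmin(s_new + ext, end[tmpl])
      term_new <- (s_new + ext) < end[tmpl]
      ## inherited + fresh copying errors
      n_err <- stats::rbinom(length(tmpl), size = as.integer(e_new - s_new),
                             prob = config$error_rate)
      err_new <- vector("list", length(tmpl))
      for (k in seq_along(tmpl)) {
        inh <- errors[[tmpl[k]]]
        inh <- inh[inh >= s_new[k] & inh < e_new[k]]
        fresh <- if (n_err[k] > 0)
          s_new[k] + sample.int(e_new[k] - s_new[k], n_err[k]) - 1L
        else integer()
        err_new[[k]] <- sort(unique(c(inh, as.integer(fresh))))
      }
      hap <- c(hap, hap[tmpl]); chrom <- c(chrom, chrom[tmpl])
      start <- c(start, as.integer(s_new)); end <- c(end, as.integer(e_new))
      gen <- c(gen, rep(r, length(tmpl)))
      terminated <- c(terminated, term_new)
      errors <- c(errors, err_new)
    }
  })
  structure(list(hap = hap, chrom = chrom, start = start, end = end,
                 gen = gen, terminated = terminated, errors = errors,
                 config = config, chrom_lengths = genome$lengths),
            class = "scwga_amplicon_pool")
}

#' @export
print.scwga_amplicon_pool <- function(x, ...) {
  cat(sprintf(paste0("scwga amplicon pool (%s): %d amplicons over %d",
                     " round(s), mean length %.0f b, %d error position(s)\n"),
              x$config$mode, length(x$start), x$config$rounds,
              mean(x$end - x$start), sum(lengths(x$errors))))
  invisible(x)
}

pool_size <- function(pool) length(pool$start)

#' Sample sequencing coverage from an amplicon pool
#'
#' Draws `reads` read start positions from the pool, choosing an amplicon
#' proportional to its length and a start uniformly within it, then bins
#' read starts into a coverage profile. Optionally tallies allele depths
#' (reads overlapping a site, split by source haplotype) at requested
#' sites.
#'
#' @param pool an amplicon pool from [simulate_amplification()].
#' @param bin_size bin width in bases.
#' @param reads number of reads to sample (>= 0).
#' @param seed integer seed.
#' @param read_len read length used for site overlap (default 100).
#' @param sites optional data.frame (`chrom`, `pos`, 0-based) at which to
#'   report allele depths.
#' @return List with `profile` (a [coverage_profile()]; bin counts sum to
#'   `reads`) and `allele_depths` (data.frame `chrom`, `pos`, `dp` and one
#'   `hap<k>` column per haplotype; `NULL` when `sites` is `NULL`).
#' @export
pool_to_coverage <- function(pool, bin_size, reads, seed = 1L,
                             read_len = 100L, sites = NULL) {
  stopifnot(inherits(pool, "scwga_amplicon_pool"), bin_size >= 1, reads >= 0)
  lens <- pool$end - pool$start
  empty <- length(lens) == 0L || sum(lens) == 0
  rs <- with_stream(seed, "reads", {
    if (reads == 0 || empty) {
      data.frame(amp = integer(), chrom = character(), pos = integer())
    } else {
      amp <- sample.int(length(lens), reads, replace = TRUE, prob = lens)
      pos <- pool$start[amp] +
        floor(stats::runif(reads) * lens[amp])
      data.frame(amp = amp, chrom = pool$chrom[amp], pos = as.integer(pos))
    }
  })
  bins <- do.call(rbind, lapply(names(pool$chrom_lengths), function(ch) {
    len <- pool$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, len))
  }))
  key <- paste(bins$chrom, bins$start)
  idx <- match(paste(rs$chrom, (rs$pos %/% bin_size) * bin_size), key)
  bins$count <- tabulate(idx, nbins = nrow(bins))
  ad <- NULL
  if (!is.null(sites)) {
    haps <- sort(unique(pool$hap))
    rend <- rs$pos + read_len
    ad <- sites[, c("chrom", "pos")]
    for (h in haps) ad[[paste0("hap", h)]] <- 0L
    for (i in seq_len(nrow(sites))) {
      hit <- rs$chrom == sites$chrom[i] & rs$pos <= sites$pos[i] &
        rend > sites$pos[i]
      if (any(hit)) {
        tab <- table(factor(pool$hap[rs$amp[hit]], levels = haps))
        for (h in haps) ad[i, paste0("hap", h)] <- as.integer(tab[[as.character(h)]])
      }
    }
    ad$dp <- rowSums(ad[, paste0("hap", haps), drop = FALSE])
  }
  list(profile = coverage_profile(bins), allele_depths = ad)
}

#' Exact allele fractions of copying errors in a pool
#'
#' For every distinct error position, returns the fraction of templates
#' covering that position that carry the error. Because reads are drawn
#' from amplicons proportional to length and a read covers an interior
#' position with probability `read_len / length`, the expected read-level
#' allele fraction at a position equals this amplicon-count fraction; the
#' exact value avoids read-sampling noise in downstream comparisons of
#' error propagation between amplification modes.
#'
#' @param pool an amplicon pool.
#' @return data.frame with `chrom`, `pos`, `n_carrier`, `n_cover`, `vaf`;
#'   zero rows when the pool has no errors.
#' @export
error_vaf <- function(pool) {
  stopifnot(inherits(pool, "scwga_amplicon_pool"))
  ne <- lengths(pool$errors)
  if (sum(ne) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      n_carrier = integer(), n_cover = integer(),
                      vaf = numeric()))
  echrom <- rep(pool$chrom, ne)
  epos <- unlist(pool$errors, use.names = FALSE)
  err <- unique(data.frame(chrom = echrom, pos = epos))
  err$n_carrier <- 0L
  err$n_cover <- 0L
  errkey <- paste(echrom, epos)
  ukey <- paste(err$chrom, err$pos)
  carrier_tab <- table(errkey)
  err$n_carrier <- as.integer(carrier_tab[ukey])
  for (i in seq_len(nrow(err))) {
    err$n_cover[i] <- sum(pool$chrom == err$chrom[i] &
                            pool$start <= err$pos[i] &
                            pool$end > err$pos[i])
  }
  err$vaf <- err$n_carrier / err$n_cover
  err
}
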