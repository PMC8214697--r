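## Kindred-cell pipeline: callable-site filtering, germline / somatic /
## false-positive classification, class summaries and the
## sensitivity-corrected per-cell somatic SNV rate. Genome-scale runs
## carry millions of germline records per cell, so germline carrier
## information is aggregated per cell during classification instead of
## being materialised row by row.

#' Callable-site filter
#'
#' A site is callable when the bulk has at least `bulk_min` reads and at
#' least `ceiling(cell_frac * n_cells)` cells have at least `cell_min`
#' reads. `depth` may be a dense per-base track (one row per position;
#' callable span is the number of passing rows) or a site-sampled table
#' over a genome of `genome_mb` megabases (callable span is the passing
#' fraction scaled to the genome).
#'
#' @param depth data.frame/data.table with columns `chrom`, `pos`, `bulk`
#'   and one depth column per cell (any other names).
#' @param bulk_min minimum bulk depth (default 15).
#' @param cell_min minimum single-cell depth (default 5).
#' @param cell_frac fraction of cells required at `cell_min` (default 0.5,
#'   ceiling convention).
#' @param genome_mb when given, `depth` rows are treated as a uniform site
#'   sample of a `genome_mb`-Mb genome.
#' @return List with `pass` (logical per row), `sites` (passing chrom/pos),
#'   `callable_mb`.
#' @export
callable_filter <- function(depth, bulk_min = 15, cell_min = 5,
                            cell_frac = 0.5, genome_mb = NULL) {
  depth <- data.table::as.data.table(depth)
  stopifnot(all(c("chrom", "pos", "bulk") %in% names(depth)))
  cell_cols <- setdiff(names(depth), c("chrom", "pos", "bulk"))
  if (!length(cell_cols)) stop("no cell depth columns")
  n_cells <- length(cell_cols)
  need <- ceiling(cell_frac * n_cells)
  enough <- rowSums(as.matrix(depth[, cell_cols, with = FALSE]) >=
                      cell_min) >= need
  pass <- depth$bulk >= bulk_min & enough
  callable_mb <- if (is.null(genome_mb)) sum(pass) / 1e6 else
    mean(pass) * genome_mb
  list(pass = pass,
       sites = depth[pass, c("chrom", "pos"), with = FALSE],
       callable_mb = callable_mb)
}

## Restrict a variant table to callable (chrom, pos) sites via keyed join.
restrict_to_sites <- function(v, sites) {
  if (is.null(sites)) return(data.table::as.data.table(v))
  v <- data.table::as.data.table(v)
  s <- data.table::as.data.table(sites)[, c("chrom", "pos"), with = FALSE]
  data.table::setkey(s, chrom, pos)
  v[!is.na(s[v, on = c("chrom", "pos"), which = TRUE])]
}

#' Classify single-cell variants against the bulk
#'
#' Germline: called in the bulk. Somatic: absent from the bulk and called
#' in at least two cells (recurrence rule). False positive: absent from
#' the bulk and private to one cell. When `callable` is supplied, all
#' call sets are first restricted to callable sites. Every variant gets
#' exactly one label. High-quality (HQ) flags (`DP >= 10`, `GQ >= 20`,
#' `VAF >= 0.35`) are computed per carrier cell and for the bulk record.
#'
#' Germline detections are additionally aggregated per cell
#' (`germline_stats`), which is what [summarize_classes()] and
#' [estimate_somatic_rate()] consume; with `germline_carriers = FALSE`
#' the (potentially enormous) per-variant germline carrier rows are not
#' materialised and `carriers` holds only non-bulk variants.
#'
#' @param bulk bulk `scwga_callset`.
#' @param cells list of cell `scwga_callset`s.
#' @param callable optional data.frame (`chrom`, `pos`) of callable sites
#'   (e.g. `callable_filter()$sites`).
#' @param hq_dp,hq_gq,hq_af HQ thresholds.
#' @param germline_carriers materialise germline rows in `carriers`
#'   (default TRUE; set FALSE for genome-scale inputs).
#' @return Object of class `scwga_classified`: list with
#'   `variants` (data.table: chrom, pos, ref, alt, label, n_carriers,
#'   bulk_gt, bulk_hq), `carriers` (data.table: chrom, pos, ref, alt,
#'   cell, dp, gq, vaf, gt, hq, label), `germline_stats` (data.table:
#'   cell, n_detected, n_het_calls, n_hq_det_of_bulk_hq_het,
#'   n_hq_det_of_bulk_hq), `n_bulk_hq`, `n_bulk_hq_het`, `n_cells`,
#'   `cell_names`.
#' @export
classify_variants <- function(bulk, cells, callable = NULL, hq_dp = 10,
                              hq_gq = 20, hq_af = 0.35,
                              germline_carriers = TRUE) {
  stopifnot(inherits(bulk, "scwga_callset"), length(cells) >= 1)
  chrom <- pos <- alt <- NULL  # data.table NSE
  bv <- restrict_to_sites(callset_called(bulk), callable)
  ## sort bulk once so join indices align with per-row bulk vectors
  data.table::setkey(bv, chrom, pos, alt)
  bvaf <- vaf_from_ad(bv$ad_ref, bv$ad_alt)
  bulk_hq <- hq_flag(bv$dp, bv$gq, bvaf, hq_dp, hq_gq, hq_af)
  bulk_het <- bv$gt == "0/1"
  bkey <- bv[, c("chrom", "pos", "alt"), with = FALSE]
  cell_names <- vapply(seq_along(cells), function(i)
    cells[[i]]$sample %||% as.character(i), character(1))

  germ_counts <- integer(nrow(bv))
  stats_rows <- vector("list", length(cells))
  nonbulk_rows <- vector("list", length(cells))
  germ_rows <- if (germline_carriers) vector("list", length(cells))
  for (i in seq_along(cells)) {
    v <- restrict_to_sites(callset_called(cells[[i]]), callable)
    vaf <- vaf_from_ad(v$ad_ref, v$ad_alt)
    hq <- hq_flag(v$dp, v$gq, vaf, hq_dp, hq_gq, hq_af)
    idx <- if (nrow(v)) bkey[v, on = c("chrom", "pos", "alt"),
                             which = TRUE] else integer()
    isg <- !is.na(idx)
    gidx <- idx[isg]
    if (length(gidx))
      germ_counts <- germ_counts + tabulate(gidx, nbins = nrow(bv))
    stats_rows[[i]] <- data.table::data.table(
      cell = cell_names[i],
      n_detected = sum(isg),
      n_het_calls = sum(isg & v$gt == "0/1"),
      n_hq_det_of_bulk_hq_het = sum(hq[isg] & bulk_hq[gidx] &
                                      bulk_het[gidx]),
      n_hq_det_of_bulk_hq = sum(hq[isg] & bulk_hq[gidx]))
    if (any(!isg))
      nonbulk_rows[[i]] <- data.table::data.table(
        chrom = v$chrom[!isg], pos = v$pos[!isg], ref = v$ref[!isg],
        alt = v$alt[!isg], cell = cell_names[i], dp = v$dp[!isg],
        gq = v$gq[!isg], vaf = vaf[!isg], gt = v$gt[!isg], hq = hq[!isg])
    if (germline_carriers && any(isg))
      germ_rows[[i]] <- data.table::data.table(
        chrom = v$chrom[isg], pos = v$pos[isg], ref = v$ref[isg],
        alt = v$alt[isg], cell = cell_names[i], dp = v$dp[isg],
        gq = v$gq[isg], vaf = vaf[isg], gt = v$gt[isg], hq = hq[isg],
        label = "germline")
  }
  germline_stats <- data.table::rbindlist(stats_rows)
  carriers <- data.table::rbindlist(nonbulk_rows)
  empty_car <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), cell = character(), dp = numeric(), gq = numeric(),
    vaf = numeric(), gt = character(), hq = logical(), label = character())
  if (is.null(carriers) || !nrow(carriers)) carriers <- empty_car
  ## recurrence rule on non-bulk variants
  nb <- NULL
  if (nrow(carriers)) {
    cnt <- carriers[, list(n_carriers = .N,
                           ref = data.table::first(ref)),
                    by = c("chrom", "pos", "alt")]
    cnt$label <- ifelse(cnt$n_carriers >= 2L, "somatic", "false_positive")
    data.table::setkey(cnt, chrom, pos, alt)
    carriers$label <- cnt[carriers, on = c("chrom", "pos", "alt")]$label
    nb <- data.table::data.table(chrom = cnt$chrom, pos = cnt$pos,
                                 ref = cnt$ref, alt = cnt$alt,
                                 label = cnt$label,
                                 n_carriers = cnt$n_carriers,
                                 bulk_gt = NA_character_, bulk_hq = NA)
  }
  if (germline_carriers) {
    gr <- data.table::rbindlist(germ_rows)
    if (!is.null(gr) && nrow(gr))
      carriers <- data.table::rbindlist(list(carriers, gr),
                                        use.names = TRUE, fill = TRUE)
  }
  germline <- if (nrow(bv)) data.table::data.table(
    chrom = bv$chrom, pos = bv$pos, ref = bv$ref, alt = bv$alt,
    label = "germline", n_carriers = germ_counts, bulk_gt = bv$gt,
    bulk_hq = bulk_hq)
  variants <- data.table::rbindlist(list(germline, nb), use.names = TRUE)
  structure(list(variants = variants, carriers = carriers,
                 germline_stats = germline_stats,
                 n_bulk_hq = sum(bulk_hq),
                 n_bulk_hq_het = sum(bulk_hq & bulk_het),
                 n_cells = length(cells), cell_names = cell_names),
            class = "scwga_classified")
}

#' @export
print.scwga_classified <- function(x, ...) {
  cat("scwga classified variants (", x$n_cells, " cells):\n", sep = "")
  print(table(x$variants$label))
  invisible(x)
}

#' Summarise variant classes
#'
#' Per-class counts, the fraction of carrier calls that are heterozygous,
#' and per-cell germline precision
#' (`germline detected / (germline detected + false positives)`).
#'
#' @param classified output of [classify_variants()].
#' @return List with `counts` (named, per class), `het_fraction` (named,
#'   per class), `per_cell` (data.frame: cell, n_germline, n_fp,
#'   n_somatic, precision).
#' @export
summarize_classes <- function(classified) {
  stopifnot(inherits(classified, "scwga_classified"))
  v <- classified$variants
  gs <- classified$germline_stats
  counts <- table(factor(v$label, levels = c("germline", "somatic",
                                             "false_positive")))
  nb <- classified$carriers[classified$carriers$label != "germline"]
  het <- c(germline = if (sum(gs$n_detected) > 0)
    sum(gs$n_het_calls) / sum(gs$n_detected) else NA_real_)
  if (nrow(nb)) {
    hdt <- nb[, list(het = mean(gt == "0/1")), by = "label"]
    het <- c(het, stats::setNames(hdt$het, hdt$label))
  }
  pc <- nb[, list(n_fp = sum(label == "false_positive"),
                  n_somatic = sum(label == "somatic")), by = "cell"]
  pc <- pc[match(classified$cell_names, pc$cell)]
  pc$cell <- classified$cell_names
  for (col in c("n_fp", "n_somatic"))
    pc[[col]][is.na(pc[[col]])] <- 0L
  pc$n_germline <- gs$n_detected[match(pc$cell, gs$cell)]
  pc$precision <- ifelse(pc$n_germline + pc$n_fp > 0,
                         pc$n_germline / (pc$n_germline + pc$n_fp),
                         NA_real_)
  pc <- pc[, c("cell", "n_germline", "n_fp", "n_somatic", "precision"),
           with = FALSE]
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       het_fraction = het, per_cell = as.data.frame(pc))
}

#' Sensitivity-corrected per-cell somatic SNV rate
#'
#' For each cell, the observed count of high-quality (HQ) somatic variants
#' it carries is divided by the product of the cell's HQ germline
#' detection sensitivity and the callable span:
#' `rate = observed / (sensitivity x callable_Mb)`. Sensitivity is
#' estimated within callable sites as the fraction of bulk-HQ germline
#' variants that the cell detected with an HQ call; by default only
#' bulk-heterozygous germline variants enter this estimate, since somatic
#' variants are heterozygous and homozygous variants are systematically
#' easier to detect. The genome-wide burden extrapolates the rate to
#' `genome_mb`.
#'
#' @param classified output of [classify_variants()].
#' @param callable_mb callable span in Mb (from [callable_filter()]).
#' @param genome_mb genome size for extrapolation (default 3088, GRCh38
#'   primary assembly).
#' @param include_private also count HQ private (single-cell) variants as
#'   somatic (default FALSE: recurrence rule only).
#' @param het_only restrict the sensitivity estimate to bulk-heterozygous
#'   germline variants (default TRUE).
#' @return Object of class `scwga_somatic_rate`: data.frame with one row
#'   per cell (`cell`, `n_hq_somatic`, `sensitivity`, `rate_per_mb`,
#'   `genome_wide`) plus attributes `mean_rate` and `se_rate`.
#' @export
estimate_somatic_rate <- function(classified, callable_mb,
                                  genome_mb = 3088,
                                  include_private = FALSE,
                                  het_only = TRUE) {
  stopifnot(inherits(classified, "scwga_classified"), callable_mb > 0)
  gs <- classified$germline_stats
  nb <- classified$carriers[classified$carriers$label != "germline"]
  n_denom <- if (het_only) classified$n_bulk_hq_het else
    classified$n_bulk_hq
  rows <- lapply(classified$cell_names, function(cn) {
    mine <- nb$cell == cn
    n_som <- sum(mine & nb$hq & nb$label == "somatic")
    if (include_private)
      n_som <- n_som + sum(mine & nb$hq & nb$label == "false_positive")
    g <- gs[gs$cell == cn]
    n_det <- if (het_only) g$n_hq_det_of_bulk_hq_het else
      g$n_hq_det_of_bulk_hq
    sens <- if (n_denom > 0) n_det / n_denom else NA_real_
    if (is.na(sens) || sens == 0)
      stop("HQ germline sensitivity is zero for cell ", cn,
           "; rate undefined")
    rate <- n_som / (sens * callable_mb)
    data.frame(cell = cn, n_hq_somatic = n_som, sensitivity = sens,
               rate_per_mb = rate, genome_wide = rate * genome_mb)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("scwga_somatic_rate", "data.frame"),
            mean_rate = mean(out$rate_per_mb),
            se_rate = stats::sd(out$rate_per_mb) / sqrt(nrow(out)),
            callable_mb = callable_mb, genome_mb = genome_mb)
}

#' @export
print.scwga_somatic_rate <- function(x, ...) {
  cat(sprintf(paste0("scwga somatic rate: %.3f +/- %.3f per Mb ",
                     "(%d cells, %.1f callable Mb; ~%.0f genome-wide)\n"),
              attr(x, "mean_rate"), attr(x, "se_rate"), nrow(x),
              attr(x, "callable_mb"),
              attr(x, "mean_rate") * attr(x, "genome_mb")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
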