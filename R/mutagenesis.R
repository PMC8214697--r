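## Direct measurement of environmental mutagenicity: per-cell
## mutagen-attributed variant extraction, dose-response summaries, and
## enrichment of mutations in DNase I hypersensitive sites.

#' Mutagen-attributed variants per cell
#'
#' A variant is attributed to the mutagen only if it was called in exactly
#' one cell, is absent from the bulk call set, and lies at a site with at
#' least `bulk_min_depth` bulk reads (so its absence from the bulk is
#' verifiable). The resulting per-cell sets are pairwise disjoint by
#' construction.
#'
#' @param cells list of cell `scwga_callset`s.
#' @param bulk bulk `scwga_callset`.
#' @param bulk_depth data.frame (`chrom`, `pos`, `dp`) of bulk depth at
#'   every candidate site; required.
#' @param bulk_min_depth minimum bulk depth (default 15).
#' @return Named list (per cell) of data.frames of kept variant records.
#' @export
mutagen_unique_variants <- function(cells, bulk, bulk_depth,
                                    bulk_min_depth = 15) {
  if (is.null(bulk_depth)) stop("bulk depth information is required")
  stopifnot(all(c("chrom", "pos", "dp") %in% names(bulk_depth)))
  cell_names <- unname(vapply(cells, `[[`, character(1), "sample"))
  allcalls <- data.table::rbindlist(lapply(seq_along(cells), function(i) {
    v <- callset_called(cells[[i]])
    if (!nrow(v)) return(NULL)
    data.table::data.table(vkey = variant_key(v$chrom, v$pos, v$alt))
  }))
  n_cells_with <- if (is.null(allcalls) || !nrow(allcalls)) integer() else
    table(allcalls$vkey)
  bkeys <- callset_keys(bulk)
  dep <- stats::setNames(bulk_depth$dp,
                         paste(bulk_depth$chrom, bulk_depth$pos))
  out <- stats::setNames(vector("list", length(cells)), cell_names)
  for (i in seq_along(cells)) {
    v <- callset_called(cells[[i]])
    if (!nrow(v)) { out[[i]] <- v; next }
    keys <- variant_key(v$chrom, v$pos, v$alt)
    d <- dep[paste(v$chrom, v$pos)]
    if (anyNA(d))
      stop("no bulk depth at ", paste(v$chrom, v$pos)[which(is.na(d))[1]])
    keep <- as.integer(n_cells_with[keys]) == 1L &
      !(keys %in% bkeys) & d >= bulk_min_depth
    out[[i]] <- v[keep, , drop = FALSE]
  }
  out
}

#' Dose-response table of per-cell mutation counts
#'
#' @param unique_sets named list of per-cell variant sets (from
#'   [mutagen_unique_variants()]).
#' @param metadata data.frame with columns `cell`, `compound`, `dose`.
#' @return List with `per_cell` (cell, compound, dose, count) and
#'   `groups` (compound, dose, n, mean, sd).
#' @export
dose_response_table <- function(unique_sets, metadata) {
  stopifnot(all(c("cell", "compound", "dose") %in% names(metadata)))
  counts <- data.frame(cell = names(unique_sets),
                       count = vapply(unique_sets, nrow, integer(1)))
  per_cell <- merge(metadata, counts, by = "cell", all.x = TRUE)
  per_cell$count[is.na(per_cell$count)] <- 0L
  per_cell <- per_cell[order(per_cell$compound, per_cell$dose,
                             per_cell$cell), ]
  groups <- do.call(rbind, lapply(
    split(per_cell, list(per_cell$compound, per_cell$dose), drop = TRUE),
    function(g) data.frame(compound = g$compound[1], dose = g$dose[1],
                           n = nrow(g), mean = mean(g$count),
                           sd = stats::sd(g$count))))
  groups <- groups[order(groups$compound, groups$dose), ]
  rownames(groups) <- NULL
  list(per_cell = per_cell, groups = groups)
}

#' DNase-hypersensitive-site panel
#'
#' DHS intervals are extended by `extension` bases (two nucleosomes, 340,
#' by default) in either direction, clipped at zero, and merged where
#' overlapping.
#'
#' @param intervals data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param extension bases added on each side (default 340).
#' @param min_depth per-base depth defining the covered genome
#'   (default 10).
#' @return List of class `scwga_dhs_panel` with merged extended intervals.
#' @export
dhs_panel <- function(intervals, extension = 340, min_depth = 10) {
  stopifnot(extension >= 0, min_depth >= 0)
  check_intervals(intervals)
  ext <- data.frame(chrom = intervals$chrom,
                    start = pmax(0, intervals$start - extension),
                    end = intervals$end + extension)
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(ext$chrom,
                           IRanges::IRanges(ext$start + 1L, ext$end)))
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr))
  structure(list(intervals = merged, extension = extension,
                 min_depth = min_depth), class = "scwga_dhs_panel")
}

#' Enrichment of variants in DNase-hypersensitive sites
#'
#' Computes, over the part of the genome covered at depth at least
#' `panel$min_depth`, the proportion of base pairs falling in (extended,
#' merged) DHS intervals and the proportion of the cell's variants at
#' covered positions falling in those intervals; the enrichment ratio is
#' variant proportion over genome proportion.
#'
#' @param variants data.frame (`chrom`, `pos`, 0-based) of one cell's
#'   variants.
#' @param panel a [dhs_panel()].
#' @param depth_track data.frame (`chrom`, `start`, `end`, `depth`)
#'   run-length intervals of per-base depth covering all variant sites.
#' @return List with `prop_snvs`, `prop_genome`, `ratio`,
#'   `n_snvs_covered`, `covered_bp`.
#' @export
dhs_enrichment <- function(variants, panel, depth_track) {
  stopifnot(inherits(panel, "scwga_dhs_panel"),
            all(c("chrom", "start", "end", "depth") %in%
                  names(depth_track)))
  cov <- depth_track[depth_track$depth >= panel$min_depth, , drop = FALSE]
  if (!nrow(cov)) stop("no genome covered at the depth threshold")
  gr_cov <- GenomicRanges::reduce(
    GenomicRanges::GRanges(cov$chrom,
                           IRanges::IRanges(cov$start + 1L, cov$end)))
  dhs <- panel$intervals
  gr_dhs <- GenomicRanges::GRanges(dhs$chrom,
                                   IRanges::IRanges(dhs$start + 1L,
                                                    dhs$end))
  covered_bp <- sum(as.numeric(GenomicRanges::width(gr_cov)))
  dhs_cov <- GenomicRanges::intersect(gr_cov, gr_dhs)
  dhs_cov_bp <- sum(as.numeric(GenomicRanges::width(dhs_cov)))
  prop_genome <- dhs_cov_bp / covered_bp
  if (prop_genome == 0) stop("no DHS overlap with the covered genome")
  gv <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos + 1L,
                                                variants$pos + 1L))
  in_cov <- IRanges::overlapsAny(gv, gr_cov)
  n_cov <- sum(in_cov)
  if (n_cov == 0)
    return(list(prop_snvs = NA_real_, prop_genome = prop_genome,
                ratio = NA_real_, n_snvs_covered = 0L,
                covered_bp = covered_bp))
  prop_snvs <- sum(in_cov & IRanges::overlapsAny(gv, dhs_cov)) / n_cov
  list(prop_snvs = prop_snvs, prop_genome = prop_genome,
       ratio = prop_snvs / prop_genome, n_snvs_covered = n_cov,
       covered_bp = covered_bp)
}
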