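#' Variant call set for one sample
#'
#' The package-wide container for per-sample variant calls. Variants live in
#' a data.frame with one row per biallelic record and columns
#' `chrom`, `pos` (0-based internally), `ref`, `alt`, `dp` (total read
#' depth), `gq` (phred genotype quality), `ad_ref`/`ad_alt` (allele depths)
#' and `gt` (`"0/0"`, `"0/1"`, `"1/1"` or `"./."`). Allele fraction is
#' always recomputed as `ad_alt / (ad_ref + ad_alt)`; an AF tag is never
#' trusted. A missing genotype (`"./."`) counts as "not called" in all set
#' logic.
#'
#' @param sample sample identifier.
#' @param variants data.frame as described above. Missing numeric columns
#'   are filled with `NA`; a missing `gt` defaults to `"0/1"`.
#' @param role `"bulk"` or `"cell"`.
#' @param meta named list of cell metadata (dose, gRNA, kit, ...).
#' @param validate check invariants (duplicate sites, DP vs allele depths);
#'   internal generators that construct records by design may skip this.
#' @return An object of class `scwga_callset`.
#' @export
callset <- function(sample, variants, role = c("cell", "bulk"),
                    meta = list(), validate = TRUE) {
  role <- match.arg(role)
  cols <- c("chrom", "pos", "ref", "alt")
  stopifnot(is.data.frame(variants), all(cols %in% names(variants)))
  v <- if (data.table::is.data.table(variants)) variants else
    as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("dp", "gq", "ad_ref", "ad_alt"))
    if (is.null(v[[col]])) v[[col]] <- rep(NA_real_, nrow(v))
  if (is.null(v$gt)) v$gt <- rep("0/1", nrow(v))
  if (validate && nrow(v)) {
    if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
    if (anyDuplicated(data.table::as.data.table(v)[, c("chrom", "pos",
                                                       "alt")]))
      stop("duplicate (chrom, pos, alt) records in sample ", sample)
    bad <- !is.na(v$dp) & !is.na(v$ad_ref) & !is.na(v$ad_alt) &
      v$dp < v$ad_ref + v$ad_alt
    if (any(bad)) stop("DP smaller than sum of allele depths at ",
                       variant_key(v$chrom, v$pos, v$alt)[which(bad)[1]])
  }
  structure(list(sample = sample, role = role, meta = meta, variants = v),
            class = "scwga_callset")
}

#' @export
print.scwga_callset <- function(x, ...) {
  cat(sprintf("scwga callset '%s' (%s): %d variant(s)\n",
              x$sample, x$role, nrow(x$variants)))
  invisible(x)
}

## Per-variant keys / called-subset helpers -------------------------------

## Keys of variants with a called non-reference genotype.
callset_keys <- function(cs) {
  v <- cs$variants
  called <- v$gt %in% c("0/1", "1/1")
  variant_key(v$chrom[called], v$pos[called], v$alt[called])
}

callset_called <- function(cs) {
  cs$variants[cs$variants$gt %in% c("0/1", "1/1"), , drop = FALSE]
}

#' Variant allele fractions of a call set
#' @param cs an `scwga_callset`.
#' @return Numeric vector (NA where allele depths are missing), one entry
#'   per called variant, named by variant key.
#' @export
callset_vaf <- function(cs) {
  v <- callset_called(cs)
  stats::setNames(vaf_from_ad(v$ad_ref, v$ad_alt),
                  variant_key(v$chrom, v$pos, v$alt))
}
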