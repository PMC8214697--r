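## Readers/writers for the formats the pipeline touches. All coordinates are
## 0-based half-open internally; VCF (1-based) and GRanges (1-based closed)
## are converted exactly at these boundaries.

#' Read genomic intervals from BED
#'
#' BED is 0-based half-open, which matches the package's internal
#' convention, so coordinates pass through unchanged.
#'
#' @param path BED3(+) file.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write genomic intervals to BED3
#' @param ivs data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @export
write_intervals <- function(ivs, path) {
  check_intervals(ivs)
  utils::write.table(ivs[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned coverage table
#'
#' Expects a tab-separated table with columns `chrom`, `start`, `end`,
#' `count` (and optionally `masked`), 0-based half-open, sorted, with
#' equal-width non-overlapping bins per chromosome.
#'
#' @param path TSV file written by [write_coverage_tsv()] or equivalent.
#' @return A [coverage_profile()].
#' @export
read_coverage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(df)))
  coverage_profile(df[, c("chrom", "start", "end", "count")],
                   masked = if (!is.null(df$masked)) as.logical(df$masked))
}

#' Write a coverage profile as TSV
#' @param profile a [coverage_profile()].
#' @param path output file.
#' @export
write_coverage_tsv <- function(profile, path) {
  df <- profile$bins
  df$masked <- profile$masked
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- VCF --

#' Write call sets as minimal VCF 4.2
#'
#' One sample column per call set; FORMAT is always `GT:DP:GQ:AD`. Records
#' are the union of all samples' sites; samples without a call at a site get
#' `./.` with missing fields. Internal 0-based positions are converted to
#' VCF's 1-based POS.
#'
#' @param callsets a single `scwga_callset` or a list of them.
#' @param path output file (uncompressed `.vcf`).
#' @param contigs optional named vector of contig lengths for the header.
#' @export
write_vcf <- function(callsets, path, contigs = NULL) {
  if (inherits(callsets, "scwga_callset")) callsets <- list(callsets)
  samples <- vapply(callsets, `[[`, character(1), "sample")
  if (anyDuplicated(samples)) stop("duplicate sample names")
  all_v <- data.table::rbindlist(lapply(callsets, function(cs) {
    v <- cs$variants
    if (nrow(v) == 0L) return(NULL)
    data.table::data.table(chrom = v$chrom, pos = v$pos, ref = v$ref,
                           alt = v$alt)
  }))
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(contigs))
                sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                        as.integer(contigs)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  if (is.null(all_v) || nrow(all_v) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  sites <- unique(all_v)
  data.table::setorder(sites, chrom, pos, alt)
  skey <- variant_key(sites$chrom, sites$pos, sites$alt)
  cols <- matrix(".:.:.:.", nrow = nrow(sites), ncol = length(samples))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                      trim = TRUE))
  for (j in seq_along(callsets)) {
    v <- callsets[[j]]$variants
    if (nrow(v) == 0L) next
    idx <- match(variant_key(v$chrom, v$pos, v$alt), skey)
    cols[idx, j] <- paste(v$gt, fmt_num(v$dp), fmt_num(round(v$gq)),
                          paste(fmt_num(v$ad_ref), fmt_num(v$ad_alt),
                                sep = ","), sep = ":")
  }
  body <- paste(sites$chrom, format(sites$pos + 1, scientific = FALSE,
                                    trim = TRUE),
                ".", sites$ref, sites$alt, ".", "PASS", ".", "GT:DP:GQ:AD",
                sep = "\t")
  for (j in seq_along(samples)) body <- paste(body, cols[, j], sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF into call sets
#'
#' Parses a VCF 4.x with per-sample GT/DP/GQ/AD, returning one
#' `scwga_callset` per sample column. Multiallelic records are split into
#' biallelic records: alt allele `k` keeps allele depths `(AD[1], AD[k+1])`.
#' Records where a sample has a missing genotype are dropped from that
#' sample's set (missing genotype = not called). Missing FORMAT keys
#' produce a warning and `NA` fields.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param role role to assign to every sample (`"cell"` or `"bulk"`), or a
#'   named character vector keyed by sample.
#' @return Named list of `scwga_callset` objects.
#' @export
read_vcf_min <- function(path, role = "cell") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gtm <- vcf@gt
  if (is.null(gtm) || ncol(gtm) < 2L) stop("VCF has no sample columns")
  samples <- colnames(gtm)[-1L]
  nrec <- nrow(fix)
  roles0 <- if (length(role) == 1L) stats::setNames(rep(role, length(samples)),
                                                    samples) else role
  if (nrec == 0L) {
    empty <- data.frame(chrom = character(), pos = numeric(),
                        ref = character(), alt = character())
    return(stats::setNames(lapply(samples, function(s)
      callset(s, empty, role = unname(roles0[s]))), samples))
  }
  get_field <- function(key) {
    if (nrec == 0L) return(matrix(character(), 0, length(samples)))
    m <- vcfR::extract.gt(vcf, element = key)
    if (is.null(m)) {
      warning("FORMAT key ", key, " absent; fields set missing")
      m <- matrix(NA_character_, nrec, length(samples))
    }
    m
  }
  gt <- get_field("GT")
  dp <- suppressWarnings(apply(get_field("DP"), 2, as.numeric))
  gq <- suppressWarnings(apply(get_field("GQ"), 2, as.numeric))
  ad <- get_field("AD")
  dim(gt) <- dim(dp) <- dim(gq) <- dim(ad) <- c(nrec, length(samples))
  roles <- if (length(role) == 1L) stats::setNames(rep(role, length(samples)),
                                                   samples) else role
  out <- list()
  for (j in seq_along(samples)) {
    rows <- list()
    for (i in seq_len(nrec)) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c("./.", ".|.", ".")) next
      g <- gsub("|", "/", g, fixed = TRUE)
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      ads <- if (is.na(ad[i, j])) rep(NA_real_, length(alts) + 1L) else
        suppressWarnings(as.numeric(strsplit(ad[i, j], ",", fixed = TRUE)[[1]]))
      gidx <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
      for (k in seq_along(alts)) {
        ## biallelic split: keep records whose alt is in the genotype, or
        ## every alt when the genotype is hom-ref (not called -> skip above)
        if (!any(gidx == k, na.rm = TRUE)) next
        gk <- if (all(gidx == k, na.rm = TRUE)) "1/1" else "0/1"
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]) - 1,
          ref = fix$REF[i], alt = alts[k], dp = dp[i, j], gq = gq[i, j],
          ad_ref = ads[1L], ad_alt = if (length(ads) > k) ads[k + 1L]
          else NA_real_, gt = gk, stringsAsFactors = FALSE)
      }
    }
    v <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), dp = numeric(), gq = numeric(),
                 ad_ref = numeric(), ad_alt = numeric(), gt = character())
    out[[samples[j]]] <- callset(samples[j], v,
                                 role = unname(roles[samples[j]]))
  }
  out
}
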