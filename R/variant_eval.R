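## Bulk-referenced SNV evaluation and mutation-spectrum machinery.
## Variant identity throughout is (chrom, pos, alt); genotype mismatches
## (0/1 vs 1/1) still count as the same detected variant.

#' Bulk-referenced SNV detection sensitivity
#'
#' Fraction of the variants identified in the unamplified bulk sample that
#' are also identified in the single cell, matching on (chrom, pos, alt).
#'
#' @param cell,bulk `scwga_callset` objects.
#' @return Number in `[0, 1]`.
#' @export
snv_sensitivity <- function(cell, bulk) {
  bk <- callset_keys(bulk)
  if (!length(bk)) stop("bulk call set is empty")
  mean(bk %in% callset_keys(cell))
}

#' Discordant single-cell calls
#'
#' Variants called in the cell but not in the bulk (false positives plus
#' true somatic variants), with their allele fractions.
#'
#' @param cell,bulk `scwga_callset` objects.
#' @return List with `variants` (data.frame of the discordant records),
#'   `count`, `rate` (fraction of the cell's calls that are discordant)
#'   and `vaf` (numeric vector).
#' @export
discordant_calls <- function(cell, bulk) {
  cv <- callset_called(cell)
  keys <- variant_key(cv$chrom, cv$pos, cv$alt)
  disc <- !(keys %in% callset_keys(bulk))
  v <- cv[disc, , drop = FALSE]
  list(variants = v, count = nrow(v),
       rate = if (nrow(cv)) nrow(v) / nrow(cv) else 0,
       vaf = vaf_from_ad(v$ad_ref, v$ad_alt))
}

#' Allele fractions and allelic dropout at bulk-heterozygous sites
#'
#' At every site the bulk calls 0/1 where the cell has depth at least
#' `min_depth`, computes the cell's VAF (`ad_alt / (ad_ref + ad_alt)`).
#' An allelic-dropout (ADO) event is a VAF outside `ado_bounds`, or a site
#' the cell did not call despite having coverage (VAF treated as 0). Sites
#' without a cell call are only evaluable when `cell_depth` supplies the
#' cell's depth there.
#'
#' @param cell,bulk `scwga_callset` objects; bulk genotypes required.
#' @param min_depth minimum cell depth for a site to be evaluable.
#' @param ado_bounds VAF interval regarded as biallelic (default
#'   `c(0.1, 0.9)`).
#' @param cell_depth optional data.frame (`chrom`, `pos`, `dp`) with the
#'   cell's depth at uncalled sites.
#' @return List with `vaf` (vector over evaluable sites), `ado_rate`,
#'   `n_evaluable`, `n_ado`.
#' @export
het_allele_metrics <- function(cell, bulk, min_depth = 10,
                               ado_bounds = c(0.1, 0.9),
                               cell_depth = NULL) {
  bv <- bulk$variants
  het <- bv[bv$gt == "0/1", , drop = FALSE]
  if (!nrow(het)) stop("bulk has no heterozygous calls")
  hkey <- variant_key(het$chrom, het$pos, het$alt)
  cvar <- callset_called(cell)
  m <- match(hkey, variant_key(cvar$chrom, cvar$pos, cvar$alt))
  vaf <- vaf_from_ad(cvar$ad_ref[m], cvar$ad_alt[m])
  dp <- cvar$dp[m]
  if (!is.null(cell_depth)) {
    dm <- match(paste(het$chrom, het$pos),
                paste(cell_depth$chrom, cell_depth$pos))
    uncalled <- is.na(m) & !is.na(dm)
    dp[uncalled] <- cell_depth$dp[dm[uncalled]]
    vaf[uncalled] <- 0   # covered but not called: all-reference
  }
  eval_ok <- !is.na(dp) & dp >= min_depth & !is.na(vaf)
  if (!any(eval_ok)) stop("no evaluable bulk-heterozygous sites")
  v <- vaf[eval_ok]
  ado <- v < ado_bounds[1] | v > ado_bounds[2]
  list(vaf = v, ado_rate = mean(ado), n_evaluable = sum(eval_ok),
       n_ado = sum(ado))
}

## ------------------------------------------------------- spectra -------

SBS6_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s) {
  vapply(strsplit(s, ""), function(b)
    paste(rev(unname(BASE_COMP[b])), collapse = ""), character(1))
}

#' The 96 single-base-substitution channels
#'
#' Channel labels of the form `A[C>T]G`, ordered by substitution class,
#' then 5' base, then 3' base (the conventional SBS-96 layout).
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(SBS6_CLASSES, function(cl)
    as.vector(t(outer(bases, bases, function(p5, p3)
      sprintf("%s[%s]%s", p5, cl, p3))))))
}

## Collapse ref/alt to the pyrimidine convention; returns list(class6,
## flipped) or NA class for non-SNVs.
collapse_strand <- function(ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt &
    ref %in% names(BASE_COMP) & alt %in% names(BASE_COMP)
  flipped <- snv & ref %in% c("A", "G")
  r <- ifelse(flipped, unname(BASE_COMP[ref]), ref)
  a <- ifelse(flipped, unname(BASE_COMP[alt]), alt)
  list(class6 = ifelse(snv, paste0(r, ">", a), NA_character_),
       flipped = flipped)
}

#' Six-class base-change spectrum
#'
#' Counts SNVs by substitution class in the pyrimidine convention:
#' purine-reference changes are mapped by reverse complement (G>A becomes
#' C>T, and so on). Non-SNV records are skipped and reported.
#'
#' @param variants data.frame with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genome optional [genome()]; when supplied, the reference allele
#'   is checked against the sequence and mismatching records are skipped.
#' @return Named integer vector over the 6 classes with attribute
#'   `n_skipped`.
#' @export
base_change_spectrum <- function(variants, genome = NULL) {
  cs <- collapse_strand(variants$ref, variants$alt)
  keep <- !is.na(cs$class6)
  if (!is.null(genome) && nrow(variants)) {
    gb <- unlist(lapply(seq_len(nrow(variants)), function(i)
      genome_base(genome, variants$chrom[i], variants$pos[i])))
    keep <- keep & gb == variants$ref
  }
  out <- table(factor(cs$class6[keep], levels = SBS6_CLASSES))
  out <- stats::setNames(as.integer(out), SBS6_CLASSES)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' 96-channel trinucleotide substitution spectrum
#'
#' Channels are keyed by 5' base, pyrimidine-convention substitution and
#' 3' base; purine-reference variants have both alleles and context
#' reverse-complemented. Variants at sequence edges or with `N` in the
#' context are skipped and reported.
#'
#' @param variants data.frame with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genome an [genome()] supplying trinucleotide contexts.
#' @return Named integer vector over [sbs96_channels()] with attribute
#'   `n_skipped`; channel sums equal the number of spectrum-eligible
#'   variants.
#' @export
trinucleotide_spectrum <- function(variants, genome) {
  channels <- sbs96_channels()
  if (!nrow(variants)) {
    out <- stats::setNames(integer(96), channels)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  cs <- collapse_strand(variants$ref, variants$alt)
  ctx <- genome_context(genome, variants$chrom, variants$pos)
  keep <- !is.na(cs$class6) & !is.na(ctx) & !grepl("N", ctx) &
    substr(ctx, 2, 2) == variants$ref
  lab <- rep(NA_character_, nrow(variants))
  if (any(keep)) {
    c2 <- ifelse(cs$flipped[keep], revcomp_chr(ctx[keep]), ctx[keep])
    lab[keep] <- sprintf("%s[%s]%s", substr(c2, 1, 1), cs$class6[keep],
                         substr(c2, 3, 3))
  }
  out <- table(factor(lab[keep], levels = channels))
  out <- stats::setNames(as.integer(out), channels)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Reconstruct a 96-channel spectrum from reference signatures
#'
#' Solves the non-negative least-squares problem
#' `min || spectrum - M e ||_2, e >= 0` for the exposure vector `e` over
#' the columns of the reference-signature matrix `M` (96 x k, columns
#' summing to 1), and reports the cosine similarity between the observed
#' spectrum and its reconstruction `M e`.
#'
#' @param spectrum numeric vector of 96 channel counts or proportions
#'   (normalised internally).
#' @param reference 96 x k matrix of reference signatures.
#' @return List of class `scwga_signature_fit`: `exposures` (named, >= 0),
#'   `reconstruction` (96-vector), `cosine`.
#' @export
reconstruct_signature <- function(spectrum, reference) {
  s <- as.numeric(spectrum)
  stopifnot(length(s) == nrow(reference), ncol(reference) >= 1)
  if (sum(s) <= 0) stop("spectrum is all zero")
  s <- s / sum(s)
  fit <- pracma::lsqnonneg(as.matrix(reference), s)
  e <- fit$x
  names(e) <- colnames(reference)
  recon <- as.numeric(as.matrix(reference) %*% e)
  cosine <- if (sum(recon^2) == 0) 0 else
    sum(s * recon) / sqrt(sum(s^2) * sum(recon^2))
  structure(list(exposures = e, reconstruction = recon, cosine = cosine),
            class = "scwga_signature_fit")
}

#' @export
print.scwga_signature_fit <- function(x, ...) {
  cat("scwga signature reconstruction: cosine =", round(x$cosine, 4), "\n")
  nz <- x$exposures[x$exposures > 1e-6]
  if (length(nz)) {
    cat("non-zero exposures:\n")
    print(round(nz, 4))
  }
  invisible(x)
}
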