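## Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setkey rbindlist
NULL

## data.table-aware package (enables data.table [] semantics internally)
.datatable.aware <- TRUE

#' Derive a reproducible child seed from a root seed and a label
#'
#' All generators in the package draw from labelled child streams so that,
#' e.g., adding a cell to a simulated experiment does not perturb the draws
#' of the other cells. The derivation is a small polynomial hash of the label
#' folded into the root seed; it is stable across platforms and sessions.
#'
#' @param seed integer root seed.
#' @param label character scalar naming the stream (e.g. "cell3/depth").
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label),
            length(label) == 1L)
  m <- 2147483647
  ## polynomial rolling hash seeded by the root seed; all intermediate
  ## products stay below 2^53, so the arithmetic is exact in doubles
  h <- abs(as.numeric(seed)) %% m
  for (v in c(utf8ToInt(label), 7L)) h <- (h * 131 + v) %% m
  as.integer(h)
}

## Run `expr` under a local RNG state seeded from (seed, label); restores the
## caller's RNG afterwards.
with_stream <- function(seed, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(derive_seed(seed, label))
  expr
}

## 0-based half-open interval sanity check against sequence lengths.
check_intervals <- function(ivs, seq_lengths = NULL) {
  stopifnot(is.data.frame(ivs), all(c("chrom", "start", "end") %in% names(ivs)))
  if (nrow(ivs) == 0L) return(invisible(ivs))
  if (any(ivs$start < 0) || any(ivs$end < ivs$start))
    stop("malformed interval: need 0 <= start <= end")
  if (!is.null(seq_lengths)) {
    if (!all(ivs$chrom %in% names(seq_lengths)))
      stop("interval on unknown sequence: ",
           paste(setdiff(unique(ivs$chrom), names(seq_lengths)), collapse = ", "))
    if (any(ivs$end > seq_lengths[as.character(ivs$chrom)]))
      stop("interval extends beyond sequence end")
  }
  invisible(ivs)
}

## Canonical per-variant identity used by all set logic: site + alt allele.
## Genotype is deliberately not part of the key.
variant_key <- function(chrom, pos, alt) {
  paste(chrom, pos, alt, sep = ":")
}

## Variant allele fraction recomputed from allele depths (never trusted from
## an AF tag). NA when no reads.
vaf_from_ad <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  out <- ad_alt / tot
  out[is.na(tot) | tot == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
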