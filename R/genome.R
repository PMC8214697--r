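#' Genome container
#'
#' A genome is an ordered set of named sequences plus optional masked
#' intervals (assembly gaps, segmental duplications) that are excluded from
#' coverage statistics. Intervals are 0-based half-open throughout the
#' package; conversion to/from 1-based conventions happens only at I/O
#' boundaries (VCF, GRanges).
#'
#' @param seqs a named [Biostrings::DNAStringSet], or a named character
#'   vector of sequences (upper-cased on ingest; `N` allowed).
#' @param masks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions to exclude from statistics.
#' @return An object of class `scwga_genome` with elements `seq`
#'   (DNAStringSet), `lengths` (named integer) and `masks` (data.frame).
#' @examples
#' g <- genome(c(chr1 = "ACGTACGTNN", chr2 = "GGGCCC"))
#' g$lengths
#' @export
genome <- function(seqs, masks = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (is.null(masks))
    masks <- data.frame(chrom = character(), start = integer(),
                        end = integer())
  check_intervals(masks, lens)
  structure(list(seq = seqs, lengths = lens, masks = masks),
            class = "scwga_genome")
}

#' @export
print.scwga_genome <- function(x, ...) {
  cat("scwga genome:", length(x$seq), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp,",
      nrow(x$masks), "masked interval(s)\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Case-insensitive; sequences are upper-cased, `N` is preserved.
#'
#' @param path FASTA file.
#' @param masks optional mask data.frame (see [genome()]) or a BED path
#'   readable by [read_intervals()].
#' @return An `scwga_genome`.
#' @export
read_fasta <- function(path, masks = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ## FASTA headers may carry descriptions; keep the first token as the name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (is.character(masks) && length(masks) == 1L) masks <- read_intervals(masks)
  genome(seqs, masks)
}

#' Write a genome to FASTA
#' @param g an `scwga_genome`.
#' @param path output file.
#' @export
write_fasta <- function(g, path) {
  stopifnot(inherits(g, "scwga_genome"))
  Biostrings::writeXStringSet(g$seq, path)
  invisible(path)
}

#' Generate a random toy genome
#'
#' Uniform base composition; used by the simulators and tests as a stand-in
#' scan/context space.
#'
#' @param lengths named integer vector of sequence lengths.
#' @param seed integer seed.
#' @param gc GC fraction (default 0.42, human-like).
#' @return An `scwga_genome`.
#' @export
random_genome <- function(lengths, seed = 1L, gc = 0.42) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_stream(seed, "genome", {
    vapply(as.integer(lengths), function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- names(lengths)
  genome(seqs)
}

## Extract the reference base (1 character) at 0-based position `pos`.
genome_base <- function(g, chrom, pos) {
  as.character(Biostrings::subseq(g$seq[chrom], start = pos + 1L,
                                  width = 1L))
}

## Trinucleotide context centred on 0-based `pos`; NA at sequence edges.
## Vectorised over (chrom, pos).
genome_context <- function(g, chrom, pos) {
  chrom <- as.character(chrom)
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- g$lengths[[ch]]
    ok <- i[pos[i] >= 1L & pos[i] <= len - 2L]
    if (length(ok)) {
      v <- Biostrings::Views(g$seq[[ch]], start = pos[ok], width = 3L)
      out[ok] <- as.character(v)
    }
  }
  out
}
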