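## CRISPR off-target analysis: exhaustive candidate-site enumeration on
## both strands, and per-cell indel / structural-variant attribution with
## bulk, cross-gRNA and recurrence exclusion rules.

#' Protospacer query
#'
#' @param protospacer 20-nt protospacer sequence (ACGT).
#' @param max_mismatches mismatch budget against the genome (default 5).
#' @return List of class `scwga_protospacer`.
#' @export
protospacer_query <- function(protospacer, max_mismatches = 5) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  if (grepl("[^ACGT]", protospacer))
    stop("protospacer alphabet must be ACGT")
  stopifnot(max_mismatches >= 0)
  structure(list(protospacer = protospacer, pam = "NGG",
                 max_mismatches = as.integer(max_mismatches)),
            class = "scwga_protospacer")
}

#' Enumerate candidate cleavage sites
#'
#' Scans both strands of every sequence for 23-mers whose first 20 bases
#' differ from the protospacer at no more than `max_mismatches` positions
#' and whose bases 22-23 are `GG` (the N of the NGG PAM is free). Windows
#' containing `N` are skipped. The canonical cleavage coordinate is the
#' blunt-cut boundary between protospacer positions 17 and 18 (3 bp 5' of
#' the PAM), reported as a 0-based forward-strand boundary coordinate.
#'
#' @param genome an [genome()].
#' @param query a [protospacer_query()].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open
#'   23-mer window on the forward strand), `strand`, `mismatches`, `cut`.
#' @export
enumerate_candidate_sites <- function(genome, query) {
  stopifnot(inherits(genome, "scwga_genome"),
            inherits(query, "scwga_protospacer"))
  if (length(genome$seq) == 0L) stop("genome is empty")
  proto <- Biostrings::DNAString(query$protospacer)
  mm_max <- query$max_mismatches
  scan_strand <- function(subject) {
    ## candidate protospacer starts (1-based), their mismatch counts
    m <- Biostrings::matchPattern(proto, subject, max.mismatch = mm_max,
                                  with.indels = FALSE)
    st <- Biostrings::start(m)
    len <- length(subject)
    keep <- st + 22L <= len
    st <- st[keep]
    if (!length(st)) return(NULL)
    ## PAM: GG at 23-mer positions 22-23
    pam <- as.character(Biostrings::Views(subject, start = st + 20L,
                                          width = 3L))
    keep <- substr(pam, 2, 3) == "GG"
    st <- st[keep]
    if (!length(st)) return(NULL)
    win <- as.character(Biostrings::Views(subject, start = st, width = 23L))
    keep <- !grepl("N", win, fixed = TRUE)
    st <- st[keep]
    if (!length(st)) return(NULL)
    mm <- vapply(st, function(s)
      Biostrings::neditStartingAt(proto, subject, starting.at = s,
                                  with.indels = FALSE), integer(1))
    keep <- mm <= mm_max
    data.frame(start1 = st[keep], mismatches = mm[keep])
  }
  out <- list()
  for (ch in names(genome$seq)) {
    subject <- genome$seq[[ch]]
    len <- length(subject)
    fw <- scan_strand(subject)
    if (!is.null(fw) && nrow(fw)) {
      s0 <- fw$start1 - 1L   # 0-based 23-mer start
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = s0, end = s0 + 23L, strand = "+",
                   mismatches = fw$mismatches, cut = s0 + 17L)
    }
    rv <- scan_strand(Biostrings::reverseComplement(subject))
    if (!is.null(rv) && nrow(rv)) {
      s_rc <- rv$start1
      w0 <- len - s_rc - 22L   # 0-based forward 23-mer start
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = w0, end = w0 + 23L, strand = "-",
                   mismatches = rv$mismatches, cut = w0 + 6L)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), cut = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

## distance from each position to the nearest cut of `cuts` on the same
## chromosome; ties broken toward the lower cut coordinate.
nearest_cut <- function(chrom, pos, sites) {
  n <- length(pos)
  dist <- rep(Inf, n)
  cut <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    cuts <- sort(sites$cut[sites$chrom == ch])
    if (!length(cuts)) next
    i <- which(chrom == ch)
    for (k in i) {
      d <- abs(cuts - pos[k])
      j <- which(d == min(d))[1L]   # ties -> lower coordinate (sorted)
      dist[k] <- d[j]; cut[k] <- cuts[j]
    }
  }
  list(dist = dist, cut = cut)
}

#' Attribute single-cell indels to candidate cleavage sites
#'
#' Keeps indels whose leftmost coordinate lies within `window` bases of a
#' candidate cleavage site of the gRNA the cell received; drops indels
#' present in the bulk or in any cell that received a different gRNA
#' (controls included); assigns each kept indel to the nearest cleavage
#' site (ties to the lower coordinate). Indels in control cells that fall
#' near any gRNA's candidate sites are reported separately as presumed
#' false positives. With `mode = "overlap"`, the indel's full reference
#' span may overlap the window instead of its leftmost coordinate alone.
#'
#' @param cells list of per-cell indel `scwga_callset`s.
#' @param sites_by_grna named list of candidate-site tables (from
#'   [enumerate_candidate_sites()]), one per gRNA.
#' @param bulk bulk indel `scwga_callset` or `NULL`.
#' @param grna_of named character vector mapping cell sample names to the
#'   gRNA received (`"control"` for control cells).
#' @param window half-width in bases around the cleavage site (default
#'   50).
#' @param mode `"leftmost"` (default) or `"overlap"`.
#' @return List with `attributed` (data.frame: cell, grna, chrom, pos,
#'   ref, alt, site_cut, dist) and `presumed_fp` (same columns, control
#'   cells).
#' @export
attribute_indels <- function(cells, sites_by_grna, bulk = NULL, grna_of,
                             window = 50, mode = c("leftmost", "overlap")) {
  mode <- match.arg(mode)
  if (!length(sites_by_grna) ||
      all(vapply(sites_by_grna, nrow, integer(1)) == 0L))
    stop("empty candidate site list")
  cell_names <- unname(vapply(cells, `[[`, character(1), "sample"))
  stopifnot(all(cell_names %in% names(grna_of)))
  bulk_keys <- if (is.null(bulk)) character() else callset_keys(bulk)
  keys_by_cell <- lapply(cells, callset_keys)
  names(keys_by_cell) <- cell_names
  all_grnas <- setdiff(unique(grna_of[cell_names]), "control")
  all_sites <- do.call(rbind, sites_by_grna[all_grnas])

  hit_window <- function(v, sites) {
    nc <- nearest_cut(v$chrom, v$pos, sites)
    within <- if (mode == "leftmost") nc$dist <= window else {
      span_end <- v$pos + nchar(v$ref) - 1L
      ok <- logical(nrow(v))
      for (k in seq_len(nrow(v))) {
        cuts <- sites$cut[sites$chrom == v$chrom[k]]
        ok[k] <- any(cuts >= v$pos[k] - window &
                       cuts <= span_end[k] + window)
      }
      ok
    }
    list(within = within, cut = nc$cut, dist = nc$dist)
  }

  attributed <- list(); presumed <- list()
  for (i in seq_along(cells)) {
    cn <- cell_names[i]
    g <- grna_of[[cn]]
    v <- callset_called(cells[[i]])
    if (!nrow(v)) next
    keys <- variant_key(v$chrom, v$pos, v$alt)
    if (g == "control") {
      ## control cells: report hits near any gRNA's sites as presumed FP
      h <- hit_window(v, all_sites)
      sel <- h$within
      if (any(sel))
        presumed[[cn]] <- data.frame(cell = cn, grna = "control",
                                     chrom = v$chrom[sel],
                                     pos = v$pos[sel], ref = v$ref[sel],
                                     alt = v$alt[sel],
                                     site_cut = h$cut[sel],
                                     dist = h$dist[sel])
      next
    }
    sites <- sites_by_grna[[g]]
    if (is.null(sites) || !nrow(sites))
      stop("no candidate sites for gRNA ", g)
    h <- hit_window(v, sites)
    other_keys <- unique(unlist(keys_by_cell[cell_names != cn &
                                               grna_of[cell_names] != g]))
    sel <- h$within & !(keys %in% bulk_keys) & !(keys %in% other_keys)
    if (any(sel))
      attributed[[cn]] <- data.frame(cell = cn, grna = g,
                                     chrom = v$chrom[sel], pos = v$pos[sel],
                                     ref = v$ref[sel], alt = v$alt[sel],
                                     site_cut = h$cut[sel],
                                     dist = h$dist[sel])
  }
  empty <- data.frame(cell = character(), grna = character(),
                      chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      site_cut = numeric(), dist = numeric())
  list(attributed = if (length(attributed))
    do.call(rbind, c(attributed, list(make.row.names = FALSE))) else empty,
    presumed_fp = if (length(presumed))
      do.call(rbind, c(presumed, list(make.row.names = FALSE))) else empty)
}

#' Remove non-recurrent single-base insertions
#'
#' Drops attributed 1-bp insertions observed at a site in exactly one
#' cell; deletions, multi-base insertions and recurrent 1-bp insertions
#' are kept.
#'
#' @param attributed data.frame as returned in
#'   `attribute_indels()$attributed`.
#' @return List with `kept`, `removed` (data.frames) and `n_removed`.
#' @export
recurrence_filter <- function(attributed) {
  a <- attributed
  if (!nrow(a))
    return(list(kept = a, removed = a, n_removed = 0L))
  is_1bp_ins <- nchar(a$ref) == 1L & nchar(a$alt) == 2L
  key <- variant_key(a$chrom, a$pos, a$alt)
  cells_per_site <- tapply(a$cell, key, function(x) length(unique(x)))
  drop <- is_1bp_ins & as.integer(cells_per_site[key]) == 1L
  list(kept = a[!drop, , drop = FALSE], removed = a[drop, , drop = FALSE],
       n_removed = sum(drop))
}

#' Attribute structural variants to candidate cleavage sites
#'
#' Keeps breakpoint-pair events for which both ends fall within `window`
#' bases of some candidate cleavage site of the gRNA the cell received
#' (the two ends may match different sites); drops events whose
#' breakpoint pair also appears in a control cell or in a cell that
#' received a different gRNA. Control-cell events near candidate sites
#' are counted but never attributed.
#'
#' @param sv_pairs data.frame with `cell`, `chromA`, `posA`, `chromB`,
#'   `posB` (one row per event; both ends required).
#' @param sites_by_grna named list of candidate-site tables per gRNA.
#' @param grna_of named character vector mapping cells to gRNAs
#'   (`"control"` for controls).
#' @param window half-width in bases (default 200).
#' @return List with `attributed` (data.frame: cell, grna, chromA, posA,
#'   cutA, chromB, posB, cutB), `per_cell` (named counts) and
#'   `n_control_window_hits`.
#' @export
attribute_svs <- function(sv_pairs, sites_by_grna, grna_of, window = 200) {
  need <- c("cell", "chromA", "posA", "chromB", "posB")
  stopifnot(all(need %in% names(sv_pairs)))
  bad <- is.na(sv_pairs$posA) | is.na(sv_pairs$posB) |
    is.na(sv_pairs$chromA) | is.na(sv_pairs$chromB)
  if (any(bad))
    stop("malformed breakpoint pair (single end) at row ",
         which(bad)[1L])
  ev_key <- with(sv_pairs, paste(chromA, posA, chromB, posB))
  n_ctrl_hits <- 0L
  attributed <- list()
  for (k in seq_len(nrow(sv_pairs))) {
    cn <- sv_pairs$cell[k]
    g <- grna_of[[cn]]
    test_sites <- if (g == "control")
      do.call(rbind, sites_by_grna) else sites_by_grna[[g]]
    ncA <- nearest_cut(sv_pairs$chromA[k], sv_pairs$posA[k], test_sites)
    ncB <- nearest_cut(sv_pairs$chromB[k], sv_pairs$posB[k], test_sites)
    hit <- ncA$dist <= window && ncB$dist <= window
    if (!hit) next
    if (g == "control") { n_ctrl_hits <- n_ctrl_hits + 1L; next }
    ## exclusion: same event seen in any control / other-gRNA cell
    others <- grna_of[sv_pairs$cell] != g
    if (ev_key[k] %in% ev_key[others]) next
    attributed[[length(attributed) + 1L]] <-
      data.frame(cell = cn, grna = g, chromA = sv_pairs$chromA[k],
                 posA = sv_pairs$posA[k], cutA = ncA$cut,
                 chromB = sv_pairs$chromB[k], posB = sv_pairs$posB[k],
                 cutB = ncB$cut)
  }
  att <- if (length(attributed)) do.call(rbind, attributed) else
    data.frame(cell = character(), grna = character(),
               chromA = character(), posA = numeric(), cutA = numeric(),
               chromB = character(), posB = numeric(), cutB = numeric())
  per_cell <- table(factor(att$cell, levels = unique(names(grna_of))))
  list(attributed = att,
       per_cell = stats::setNames(as.integer(per_cell), names(per_cell)),
       n_control_window_hits = n_ctrl_hits)
}
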