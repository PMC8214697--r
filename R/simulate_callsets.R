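## Synthetic call-set generators with recorded ground truth. These define
## the study conditions under which the evaluation pipeline is exercised;
## their defaults are the conditions of the experiments they emulate.

## Per-site sequencing depth: negative binomial, variance mu + disp * mu^2.
## Over-dispersion stands in for amplification bias without modelling reads.
draw_depth <- function(n, mean = 30, disp = 0.3) {
  as.integer(stats::rnbinom(n, mu = mean, size = 1 / disp))
}

## Deterministic genotype quality given depth and allele fraction: phred-like
## confidence that grows with depth and shrinks as the observed VAF departs
## from the genotype's expectation (0.5 het, 1 hom-alt).
gq_model <- function(dp, vaf, gt) {
  evaf <- 0.5 + 0.5 * (gt == "1/1")
  vaf[is.na(vaf)] <- 0
  as.integer(pmax(0, pmin(99, round(3 * dp * (1 - 2 * abs(vaf - evaf))))))
}

## High-quality call filter used throughout the kindred analysis.
hq_flag <- function(dp, gq, vaf, dp_min = 10, gq_min = 20, af_min = 0.35) {
  !is.na(dp) & !is.na(gq) & !is.na(vaf) &
    dp >= dp_min & gq >= gq_min & vaf >= af_min
}

## Map linear genome coordinates (numeric, 0-based over a concatenated
## genome) onto 100-Mb pseudo-chromosomes.
CHROM_UNIT <- 1e8
gpos_chrom <- function(gpos) paste0("chr", as.integer(gpos %/% CHROM_UNIT) + 1L)
gpos_pos <- function(gpos) gpos %% CHROM_UNIT

## Draw n distinct variant sites over a genome_mb-megabase genome; returns a
## data.table with chrom, pos, ref, alt (random alleles).
draw_sites <- function(n, genome_mb) {
  g <- floor(stats::runif(n) * genome_mb * 1e6)
  g <- unique(g)   # birthday collisions are dropped
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(g), replace = TRUE)
  alt <- sample(bases[-1], length(g), replace = TRUE)
  alt[alt == ref] <- "A"
  data.table::data.table(chrom = gpos_chrom(g),
                         pos = as.integer(gpos_pos(g)),
                         ref = ref, alt = alt)
}

#' Simulate a kindred-cell experiment
#'
#' Emulates plating a single founder cell, clonal expansion, and
#' re-isolation of near-identical single cells, with an unamplified bulk
#' of the same donor as reference. Germline variants are present in the
#' bulk and detected independently in each cell with probability
#' `detect_prob`; founder somatic variants are absent from the bulk,
#' carried by every cell, and detected with the same probability;
#' false-positive calls are private to one cell with a Poisson burden and
#' low-skewed allele fractions (Beta(2, 6)). DP/GQ/allele depths follow a
#' negative-binomial depth model (mean 30, dispersion 0.3) with binomial
#' allele splitting; GQ is deterministic in DP and VAF. Per-site depths
#' for every sample at every variant site are returned for the
#' callable-site filter.
#'
#' Defaults reflect the experiment the generator emulates: a somatic
#' burden of 0.33 SNVs per Mb per cell and a false-positive burden of
#' 2,785 calls per cell.
#'
#' @param n_cells number of kindred cells (>= 2).
#' @param genome_mb genome size in Mb (default 3088, human primary
#'   assembly).
#' @param germline_density germline variants per Mb (default 1000).
#' @param somatic_rate founder somatic variants per Mb (default 0.33).
#' @param fp_burden expected false-positive calls per cell (default 2785).
#' @param detect_prob per-variant detection probability in a cell.
#' @param het_frac fraction of germline variants that are heterozygous.
#' @param depth_mean,depth_disp negative-binomial depth model parameters.
#' @param bulk_depth_mean mean bulk depth (unamplified, default 45).
#' @param seed integer root seed; cells draw from labelled child streams,
#'   so adding a cell does not perturb the others.
#' @return List of class `scwga_kindred_sim` with elements `bulk`
#'   (callset), `cells` (list of callsets), `truth` (data.table: chrom,
#'   pos, ref, alt, class, n_carriers, planted_af), and `depth`
#'   (data.table: chrom, pos, bulk, cell1..cellN per-site depths).
#' @export
simulate_kindred_dataset <- function(n_cells = 5, genome_mb = 3088,
                                     germline_density = 1000,
                                     somatic_rate = 0.33, fp_burden = 2785,
                                     detect_prob = 0.85, het_frac = 0.67,
                                     depth_mean = 30, depth_disp = 0.3,
                                     bulk_depth_mean = 45, seed = 1L) {
  if (n_cells < 2) stop("kindred classification needs at least 2 cells")
  stopifnot(germline_density >= 0, somatic_rate >= 0, fp_burden >= 0,
            detect_prob > 0, detect_prob <= 1)
  germ <- with_stream(seed, "germline", {
    s <- draw_sites(stats::rpois(1, germline_density * genome_mb), genome_mb)
    s$gt <- ifelse(stats::runif(nrow(s)) < het_frac, "0/1", "1/1")
    s
  })
  som <- with_stream(seed, "somatic", {
    s <- draw_sites(stats::rpois(1, somatic_rate * genome_mb), genome_mb)
    if (nrow(s)) s$gt <- "0/1"
    s
  })
  ## founder somatics must not coincide with germline sites
  if (nrow(som)) {
    gk <- germ[, c("chrom", "pos")]
    data.table::setkey(gk, chrom, pos)
    som <- som[is.na(gk[som, on = c("chrom", "pos"), which = TRUE])]
  }

  site_af <- function(gt) 0.5 + 0.5 * (gt == "1/1")
  make_record <- function(sites, dp, af) {
    ad_alt <- as.integer(stats::rbinom(length(dp), dp, af))
    ## a called variant has at least one supporting read
    ad_alt[dp > 0L & ad_alt < 1L] <- 1L
    vaf <- vaf_from_ad(dp - ad_alt, ad_alt)
    data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
      alt = sites$alt, dp = dp, gq = gq_model(dp, vaf, sites$gt),
      ad_ref = dp - ad_alt, ad_alt = ad_alt, gt = sites$gt)
  }

  bulk_v <- with_stream(seed, "bulk", {
    dp <- draw_depth(nrow(germ), bulk_depth_mean, depth_disp)
    make_record(germ, dp, site_af(germ$gt))
  })
  bulk <- callset("bulk", bulk_v, role = "bulk", validate = FALSE)

  ## depth table over all candidate sites (germline + somatic + FPs added
  ## per cell below)
  all_sites <- data.table::rbindlist(list(
    germ[, c("chrom", "pos")], som[, c("chrom", "pos")]))
  cells <- vector("list", n_cells)
  fp_list <- vector("list", n_cells)
  cell_depth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    lab <- sprintf("cell%d", i)
    cells[[i]] <- with_stream(seed, lab, {
      det_g <- stats::runif(nrow(germ)) < detect_prob
      det_s <- if (nrow(som)) stats::runif(nrow(som)) < detect_prob else
        logical()
      n_fp <- stats::rpois(1, fp_burden)
      fp <- draw_sites(n_fp, genome_mb)
      if (nrow(fp)) fp$gt <- "0/1"
      fp_list[[i]] <- fp
      dp_g <- draw_depth(nrow(germ), depth_mean, depth_disp)
      dp_s <- draw_depth(nrow(som), depth_mean, depth_disp)
      dp_f <- draw_depth(nrow(fp), depth_mean, depth_disp)
      cell_depth[[i]] <- c(dp_g, dp_s)
      v <- data.table::rbindlist(list(
        make_record(germ[det_g, ], dp_g[det_g], site_af(germ$gt[det_g])),
        if (any(det_s)) make_record(som[det_s, ], dp_s[det_s], 0.5),
        if (nrow(fp)) make_record(fp, dp_f, stats::rbeta(nrow(fp), 2, 6))))
      ## drop FP records colliding with an already-present site
      v <- unique(v, by = c("chrom", "pos"))
      callset(lab, v, role = "cell", validate = FALSE)
    })
  }

  ## per-site depth table: germline + somatic sites for all samples; FP
  ## sites get each cell's call DP and fresh draws for the other samples
  depth <- data.table::data.table(chrom = all_sites$chrom,
                                  pos = all_sites$pos)
  depth$bulk <- c(bulk_v$dp, with_stream(seed, "bulkdepth/som",
                                         draw_depth(nrow(som),
                                                    bulk_depth_mean,
                                                    depth_disp)))
  for (i in seq_len(n_cells)) depth[[sprintf("cell%d", i)]] <- cell_depth[[i]]
  fp_all <- data.table::rbindlist(lapply(seq_len(n_cells), function(i) {
    f <- fp_list[[i]]
    if (nrow(f) == 0L) return(NULL)
    data.table::data.table(chrom = f$chrom, pos = f$pos, cell = i)
  }))
  if (!is.null(fp_all) && nrow(fp_all)) {
    fp_depth <- with_stream(seed, "fpdepth", {
      d <- data.table::data.table(chrom = fp_all$chrom, pos = fp_all$pos)
      d$bulk <- draw_depth(nrow(d), bulk_depth_mean, depth_disp)
      for (i in seq_len(n_cells)) {
        col <- draw_depth(nrow(d), depth_mean, depth_disp)
        ## the calling cell's DP must match its call record
        own <- which(fp_all$cell == i)
        cv <- data.table::as.data.table(
          cells[[i]]$variants[, c("chrom", "pos", "dp")])
        hit <- cv[d[own], on = c("chrom", "pos")]$dp
        col[own[!is.na(hit)]] <- hit[!is.na(hit)]
        d[[sprintf("cell%d", i)]] <- col
      }
      d
    })
    depth <- data.table::rbindlist(list(depth, fp_depth))
  }
  depth <- unique(depth, by = c("chrom", "pos"))

  truth <- data.table::rbindlist(list(
    if (nrow(germ)) data.table::data.table(
      chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
      class = "germline", n_carriers = n_cells, planted_af = site_af(germ$gt)),
    if (nrow(som)) data.table::data.table(
      chrom = som$chrom, pos = som$pos, ref = som$ref, alt = som$alt,
      class = "somatic", n_carriers = n_cells, planted_af = 0.5),
    data.table::rbindlist(lapply(seq_len(n_cells), function(i) {
      f <- fp_list[[i]]
      if (nrow(f) == 0L) return(NULL)
      data.table::data.table(chrom = f$chrom, pos = f$pos, ref = f$ref,
                             alt = f$alt, class = "false_positive",
                             n_carriers = 1L, planted_af = NA_real_)
    }))))
  structure(list(bulk = bulk, cells = cells, truth = truth, depth = depth,
                 params = list(n_cells = n_cells, genome_mb = genome_mb,
                               germline_density = germline_density,
                               somatic_rate = somatic_rate,
                               fp_burden = fp_burden,
                               detect_prob = detect_prob, seed = seed)),
            class = "scwga_kindred_sim")
}

#' @export
print.scwga_kindred_sim <- function(x, ...) {
  cat(sprintf(paste0("scwga kindred simulation: %d cells, %g Mb genome, ",
                     "%d germline / %d somatic / %d FP planted\n"),
              x$params$n_cells, x$params$genome_mb,
              sum(x$truth$class == "germline"),
              sum(x$truth$class == "somatic"),
              sum(x$truth$class == "false_positive")))
  invisible(x)
}

#' Simulate a mutagen-exposure (DMEM-style) experiment
#'
#' Each cell of each dose group acquires a Poisson number of private
#' mutagen-induced SNVs with 6-class base-change probabilities
#' `spectrum_probs` and positions drawn from the supplied toy genome
#' (positions are chosen so the reference base matches the class under the
#' pyrimidine convention; purine-reference placements exercise strand
#' collapse downstream). A small shared germline set and per-site bulk
#' depths are generated so the unique-to-one-cell / bulk-depth rule can be
#' applied.
#'
#' @param genome an [genome()] (toy scale; supplies bases and contexts).
#' @param doses numeric vector of doses, one group per entry (monotone).
#' @param cells_per_dose integer vector (recycled) of cells per group.
#' @param mutations_per_cell function(dose) -> expected mutation count, or
#'   a numeric vector parallel to `doses`.
#' @param spectrum_probs named length-6 vector of probabilities over
#'   `c("C>A","C>G","C>T","T>A","T>C","T>G")`, summing to 1.
#' @param compound label stored in cell metadata.
#' @param n_germline shared germline variants present in bulk and cells.
#' @param bulk_depth_mean mean bulk depth at variant sites.
#' @param seed integer root seed.
#' @return List of class `scwga_mutagen_sim`: `bulk`, `cells`, `truth`,
#'   `bulk_depth` (chrom, pos, dp), `metadata` (cell, compound, dose).
#' @export
simulate_mutagen_dataset <- function(genome, doses, cells_per_dose,
                                     mutations_per_cell, spectrum_probs,
                                     compound = "mutagen", n_germline = 50,
                                     bulk_depth_mean = 30, seed = 1L) {
  stopifnot(inherits(genome, "scwga_genome"))
  if (sum(as.numeric(genome$lengths)) == 0) stop("genome is empty")
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  stopifnot(setequal(names(spectrum_probs), classes))
  spectrum_probs <- spectrum_probs[classes]
  if (abs(sum(spectrum_probs) - 1) > 1e-8)
    stop("spectrum_probs must sum to 1")
  if (is.unsorted(doses)) stop("doses must be monotone non-decreasing")
  cells_per_dose <- rep_len(cells_per_dose, length(doses))
  mu_of <- if (is.function(mutations_per_cell)) mutations_per_cell else {
    mv <- rep_len(mutations_per_cell, length(doses))
    function(dose) mv[match(dose, doses)]
  }
  ## index genome positions by pyrimidine-convention base
  base_index <- local({
    idx <- list()
    for (ch in names(genome$lengths)) {
      b <- strsplit(as.character(genome$seq[[ch]]), "")[[1]]
      idx[[ch]] <- list(C = which(b %in% c("C", "G")) - 1L,
                        T = which(b %in% c("T", "A")) - 1L,
                        base = b)
    }
    idx
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  draw_mutations <- function(n) {
    cls <- sample(classes, n, replace = TRUE, prob = spectrum_probs)
    pyr <- substr(cls, 1, 1)
    alt_pyr <- substr(cls, 3, 3)
    ch <- sample(names(genome$lengths), n, replace = TRUE,
                 prob = as.numeric(genome$lengths))
    pos <- integer(n); ref <- character(n); alt <- character(n)
    for (k in seq_len(n)) {
      cand <- base_index[[ch[k]]][[pyr[k]]]
      if (!length(cand)) stop("genome has no ", pyr[k], "/",
                              comp[pyr[k]], " bases on ", ch[k])
      pos[k] <- cand[sample.int(length(cand), 1L)]
      ref[k] <- base_index[[ch[k]]]$base[pos[k] + 1L]
      alt[k] <- if (ref[k] == pyr[k]) alt_pyr[k] else comp[alt_pyr[k]]
    }
    data.table::data.table(chrom = ch, pos = pos, ref = ref, alt = alt,
                           class6 = cls)
  }

  germ <- with_stream(seed, "germline", {
    g <- draw_mutations(n_germline)
    if (nrow(g)) g[!duplicated(paste(g$chrom, g$pos)), ] else g
  })
  rec <- function(sites, dp_mean) {
    dp <- draw_depth(nrow(sites), dp_mean)
    ad_alt <- pmax(stats::rbinom(nrow(sites), dp, 0.5),
                   ifelse(dp > 0, 1L, 0L))
    data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                           ref = sites$ref, alt = sites$alt, dp = dp,
                           gq = gq_model(dp, vaf_from_ad(dp - ad_alt, ad_alt),
                                         "0/1"),
                           ad_ref = dp - ad_alt, ad_alt = ad_alt, gt = "0/1")
  }
  bulk <- with_stream(seed, "bulk",
                      callset("bulk", rec(germ, bulk_depth_mean),
                              role = "bulk"))
  cells <- list(); meta <- list(); truths <- list()
  idx <- 0L
  for (d in seq_along(doses)) {
    for (j in seq_len(cells_per_dose[d])) {
      idx <- idx + 1L
      lab <- sprintf("cell%d", idx)
      cells[[lab]] <- with_stream(seed, lab, {
        n_mut <- stats::rpois(1, mu_of(doses[d]))
        muts <- draw_mutations(n_mut)
        v <- data.table::rbindlist(list(rec(germ, 30), rec(muts, 30)))
        v <- v[!duplicated(paste(v$chrom, v$pos)), ]
        truths[[lab]] <- muts
        callset(lab, v, role = "cell",
                meta = list(compound = compound, dose = doses[d]))
      })
      meta[[lab]] <- data.frame(cell = lab, compound = compound,
                                dose = doses[d])
    }
  }
  truth <- data.table::rbindlist(lapply(names(truths), function(lab) {
    tt <- truths[[lab]]
    if (nrow(tt) == 0L) return(NULL)
    data.table::data.table(chrom = tt$chrom, pos = tt$pos, ref = tt$ref,
                           alt = tt$alt, class = "mutagen", carrier = lab,
                           class6 = tt$class6)
  }))
  all_pos <- unique(data.table::rbindlist(c(
    list(germ[, c("chrom", "pos")]),
    lapply(cells, function(cs) cs$variants[, c("chrom", "pos")]))))
  bulk_depth <- with_stream(seed, "bulkdepth", {
    data.table::data.table(chrom = all_pos$chrom, pos = all_pos$pos,
                           dp = draw_depth(nrow(all_pos), bulk_depth_mean))
  })
  ## bulk depth at called bulk sites matches the bulk call records
  m <- match(paste(bulk$variants$chrom, bulk$variants$pos),
             paste(bulk_depth$chrom, bulk_depth$pos))
  bulk_depth$dp[m] <- bulk$variants$dp
  structure(list(bulk = bulk, cells = cells, truth = truth,
                 bulk_depth = bulk_depth,
                 metadata = do.call(rbind, meta)),
            class = "scwga_mutagen_sim")
}

#' Simulate a CRISPR-edited single-cell experiment
#'
#' Edited cells carry planted indels at the on-target cleavage site and at
#' supplied off-target candidate sites (each with its own per-cell indel
#' probability) with small positional jitter; every cell (edited and
#' control) additionally carries background non-recurrent 1-bp insertions
#' at random positions. Planted structural variants are breakpoint pairs
#' whose ends fall within a window of planted cleavage sites. Every
#' planted off-target site is validated against
#' [enumerate_candidate_sites()] and rejected if it does not match the
#' protospacer within the mismatch budget.
#'
#' @param genome an [genome()] containing the on/off-target sequences.
#' @param protospacer 20-nt gRNA protospacer.
#' @param n_edited,n_control numbers of edited and control cells.
#' @param on_rate probability an edited cell carries the on-target indel.
#' @param offtarget_sites data.frame (`chrom`, `cut`, `prob`) of planted
#'   off-target cleavage coordinates and per-cell indel probabilities, or
#'   `NULL`.
#' @param sv_pairs data.frame (`chromA`, `cutA`, `chromB`, `cutB`, `prob`)
#'   of planted breakpoint pairs anchored at cleavage sites, or `NULL`.
#' @param bg_insertions expected background 1-bp insertions per cell.
#' @param grna label of the gRNA received by edited cells.
#' @param max_jitter maximum absolute indel-position jitter in bases.
#' @param seed integer root seed.
#' @return List of class `scwga_edited_sim`: `cells` (list of indel
#'   callsets), `sv` (data.frame cell, chromA, posA, chromB, posB),
#'   `grna_of` (named vector, `"control"` for controls), `truth`, `sites`
#'   (the enumerated candidate table).
#' @export
simulate_edited_dataset <- function(genome, protospacer, n_edited = 3,
                                    n_control = 3, on_rate = 0.9,
                                    offtarget_sites = NULL, sv_pairs = NULL,
                                    bg_insertions = 2, grna = "g1",
                                    max_jitter = 2, seed = 1L) {
  query <- protospacer_query(protospacer)
  sites <- enumerate_candidate_sites(genome, query)
  if (nrow(sites) == 0L) stop("protospacer has no candidate site in genome")
  on_site <- sites[sites$mismatches == 0L, ][1, ]
  if (is.na(on_site$chrom)) stop("no exact on-target site in genome")
  if (!is.null(offtarget_sites)) {
    ok <- paste(offtarget_sites$chrom, offtarget_sites$cut) %in%
      paste(sites$chrom, sites$cut)
    if (any(!ok))
      stop("planted off-target site not a candidate within the mismatch ",
           "budget: ",
           paste(offtarget_sites$chrom[!ok], offtarget_sites$cut[!ok],
                 sep = ":", collapse = ", "))
  }
  n_cells <- n_edited + n_control
  cell_ids <- sprintf("cell%d", seq_len(n_cells))
  grna_of <- stats::setNames(c(rep(grna, n_edited),
                               rep("control", n_control)), cell_ids)
  plant <- rbind(data.frame(chrom = on_site$chrom, cut = on_site$cut,
                            prob = on_rate, kind = "on"),
                 if (!is.null(offtarget_sites))
                   data.frame(chrom = offtarget_sites$chrom,
                              cut = offtarget_sites$cut,
                              prob = offtarget_sites$prob, kind = "off"))
  seq_of <- function(ch, from, len) {  # 0-based, `len` bases
    as.character(Biostrings::subseq(genome$seq[[ch]], from + 1L,
                                    width = len))
  }
  mk_del <- function(ch, cut, jit, len) {
    pos <- max(0L, cut - jit - 1L)   # anchor base before the deleted run
    data.frame(chrom = ch, pos = pos, ref = seq_of(ch, pos, len + 1L),
               alt = seq_of(ch, pos, 1L), gt = "0/1",
               dp = 30, gq = 60, ad_ref = 15, ad_alt = 15)
  }
  mk_ins1 <- function(ch, pos) {
    anchor <- seq_of(ch, pos, 1L)
    data.frame(chrom = ch, pos = pos,
               ref = anchor, alt = paste0(anchor, sample(c("A", "C", "G",
                                                           "T"), 1L)),
               gt = "0/1", dp = 30, gq = 60, ad_ref = 15, ad_alt = 15)
  }
  cells <- list(); truth <- list(); svs <- list()
  for (ci in seq_len(n_cells)) {
    id <- cell_ids[ci]
    cells[[id]] <- with_stream(seed, id, {
      rows <- list()
      if (grna_of[id] != "control") {
        for (k in seq_len(nrow(plant))) {
          if (stats::runif(1) < plant$prob[k]) {
            jit <- sample(-max_jitter:max_jitter, 1L)
            del_len <- sample(1:6, 1L)
            rows[[length(rows) + 1L]] <-
              mk_del(plant$chrom[k], plant$cut[k], jit, del_len)
            truth[[length(truth) + 1L]] <-
              data.frame(chrom = plant$chrom[k], cut = plant$cut[k],
                         cell = id, class = "edit_indel",
                         kind = plant$kind[k])
          }
        }
        if (!is.null(sv_pairs)) {
          for (k in seq_len(nrow(sv_pairs))) {
            if (stats::runif(1) < sv_pairs$prob[k]) {
              svs[[length(svs) + 1L]] <- data.frame(
                cell = id, chromA = sv_pairs$chromA[k],
                posA = sv_pairs$cutA[k] + sample(-50:50, 1L),
                chromB = sv_pairs$chromB[k],
                posB = sv_pairs$cutB[k] + sample(-50:50, 1L))
              truth[[length(truth) + 1L]] <-
                data.frame(chrom = sv_pairs$chromA[k],
                           cut = sv_pairs$cutA[k], cell = id,
                           class = "edit_sv", kind = "sv")
            }
          }
        }
      }
      n_bg <- stats::rpois(1, bg_insertions)
      for (b in seq_len(n_bg)) {
        ch <- sample(names(genome$lengths), 1L)
        pos <- sample.int(genome$lengths[[ch]] - 1L, 1L) - 1L
        rows[[length(rows) + 1L]] <- mk_ins1(ch, pos)
        truth[[length(truth) + 1L]] <-
          data.frame(chrom = ch, cut = pos, cell = id,
                     class = "background_insertion", kind = "bg")
      }
      v <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(), pos = numeric(), ref = character(),
                   alt = character())
      v <- v[!duplicated(paste(v$chrom, v$pos, v$alt)), , drop = FALSE]
      callset(id, v, role = "cell", meta = list(grna = grna_of[[id]]))
    })
  }
  structure(list(cells = cells,
                 sv = if (length(svs)) do.call(rbind, svs) else
                   data.frame(cell = character(), chromA = character(),
                              posA = numeric(), chromB = character(),
                              posB = numeric()),
                 grna_of = grna_of,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL,
                 sites = sites),
            class = "scwga_edited_sim")
}
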