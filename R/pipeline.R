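#' Run a configured analysis pipeline
#'
#' Executes one of the package's analysis workflows end to end from a
#' configuration list (or YAML file), writing one TSV per tabular output
#' plus a machine-readable `summary.yaml` into `outdir`. Any stage
#' failure aborts with the stage name and cause. Reruns of the same
#' configuration produce identical outputs.
#'
#' Supported `analysis` values:
#' \describe{
#'   \item{`coverage`}{simulate quasilinear and exponential amplification
#'     on a toy genome, sample reads, and tabulate CV, MAPD, Gini and
#'     breadth per mode.}
#'   \item{`kindred`}{simulate a kindred experiment, run the callable
#'     filter, classification and somatic-rate estimation.}
#'   \item{`mutagen`}{simulate a dosed mutagen experiment, extract
#'     unique-to-one-cell variants, tabulate dose response and the
#'     6-class spectrum.}
#'   \item{`offtarget`}{simulate an edited experiment, enumerate
#'     candidate sites, attribute indels and SVs, apply the recurrence
#'     filter.}
#' }
#'
#' @param config named list, or path to a YAML file with the same
#'   structure. Required: `analysis`, `outdir`. Optional: `seed`
#'   (default 1) and per-analysis parameter overrides under `params`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$analysis),
            !is.null(config$outdir))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params %||% list()
  for (f in c(config$genome_fasta, config$dhs_bed))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary <- list(analysis = config$analysis, seed = seed,
                  package_version = as.character(utils::packageVersion("scwga")))

  if (config$analysis == "coverage") {
    g <- stage("genome", {
      if (!is.null(config$genome_fasta)) read_fasta(config$genome_fasta)
      else random_genome(c(chr1 = as.integer(params$genome_bp %||% 2e5)),
                         seed = seed)
    })
    reads <- as.integer(params$reads %||% 20000)
    bin <- as.integer(params$bin_size %||% 5000)
    res <- stage("coverage-metrics", {
      do.call(rbind, lapply(c("quasilinear", "exponential"), function(m) {
        pool <- simulate_amplification(g, sim_config(mode = m, seed = seed))
        prof <- pool_to_coverage(pool, bin, reads, seed = seed)$profile
        lp <- lorenz_curve(prof)
        wtsv(lp, sprintf("lorenz_%s.tsv", m))
        data.frame(mode = m, cv = cv(prof), mapd = mapd(prof),
                   gini = gini(prof), breadth = breadth(prof))
      }))
    })
    wtsv(res, "coverage_metrics.tsv")
    summary$metrics <- split(res[, -1], res$mode)
  } else if (config$analysis == "kindred") {
    sim <- stage("simulate", do.call(simulate_kindred_dataset,
                                     c(params, list(seed = seed))))
    cf <- stage("callable-filter",
                callable_filter(sim$depth,
                                genome_mb = sim$params$genome_mb))
    cls <- stage("classify",
                 classify_variants(sim$bulk, sim$cells,
                                   callable = cf$sites))
    smry <- stage("summarize", summarize_classes(cls))
    rate <- stage("somatic-rate",
                  estimate_somatic_rate(cls, cf$callable_mb,
                                        genome_mb = sim$params$genome_mb))
    wtsv(cls$variants, "classification.tsv")
    wtsv(smry$per_cell, "per_cell.tsv")
    wtsv(as.data.frame(rate), "somatic_rate.tsv")
    summary$callable_mb <- cf$callable_mb
    summary$sensitivity <- mean(as.data.frame(rate)$sensitivity)
    summary$precision <- mean(smry$per_cell$precision, na.rm = TRUE)
    summary$somatic_rate_per_mb <- attr(rate, "mean_rate")
  } else if (config$analysis == "mutagen") {
    g <- stage("genome", {
      if (!is.null(config$genome_fasta)) read_fasta(config$genome_fasta)
      else random_genome(c(chr1 = as.integer(params$genome_bp %||% 5e4)),
                         seed = seed)
    })
    doses <- params$doses %||% c(0, 1, 10)
    probs <- unlist(params$spectrum_probs %||%
                      c("C>A" = 1, "C>G" = 1, "C>T" = 1, "T>A" = 1,
                        "T>C" = 1, "T>G" = 1) / 6)
    sim <- stage("simulate",
                 simulate_mutagen_dataset(
                   g, doses = doses,
                   cells_per_dose = params$cells_per_dose %||% 3,
                   mutations_per_cell = function(d)
                     (params$mutations_per_dose_unit %||% 20) * d +
                     (params$background_mutations %||% 5),
                   spectrum_probs = probs, seed = seed))
    uniq <- stage("unique-variants",
                  mutagen_unique_variants(sim$cells, sim$bulk,
                                          sim$bulk_depth))
    dr <- stage("dose-response", dose_response_table(uniq, sim$metadata))
    spec <- stage("spectrum", {
      allv <- do.call(rbind, lapply(uniq, function(v)
        v[, c("chrom", "pos", "ref", "alt")]))
      base_change_spectrum(allv, g)
    })
    wtsv(dr$per_cell, "dose_response_cells.tsv")
    wtsv(dr$groups, "dose_response_groups.tsv")
    wtsv(data.frame(class = names(spec), count = as.integer(spec)),
         "spectrum6.tsv")
    summary$group_means <- stats::setNames(dr$groups$mean,
                                           paste0("dose_", dr$groups$dose))
    summary$spectrum6 <- as.list(stats::setNames(as.integer(spec),
                                                 names(spec)))
  } else if (config$analysis == "offtarget") {
    proto <- params$protospacer %||% NULL
    sim <- stage("simulate", {
      if (is.null(proto)) {
        d <- demo_edited_genome(seed = seed)
        proto <- d$protospacer
        simulate_edited_dataset(d$genome, d$protospacer,
                                offtarget_sites = d$offtargets,
                                sv_pairs = d$sv_pairs, seed = seed)
      } else {
        g <- read_fasta(config$genome_fasta)
        simulate_edited_dataset(g, proto, seed = seed)
      }
    })
    sites <- list(g1 = sim$sites)
    att <- stage("attribute-indels",
                 attribute_indels(sim$cells, sites, bulk = NULL,
                                  grna_of = sim$grna_of))
    rec <- stage("recurrence-filter", recurrence_filter(att$attributed))
    sv <- stage("attribute-svs",
                attribute_svs(sim$sv, sites, sim$grna_of))
    wtsv(sim$sites, "candidate_sites.tsv")
    wtsv(rec$kept, "attributed_indels.tsv")
    wtsv(sv$attributed, "attributed_svs.tsv")
    summary$n_candidate_sites <- nrow(sim$sites)
    summary$n_attributed_indels <- nrow(rec$kept)
    summary$n_removed_nonrecurrent <- rec$n_removed
    summary$n_attributed_svs <- nrow(sv$attributed)
  } else stop("unknown analysis: ", config$analysis)

  yaml::write_yaml(summary, file.path(outdir, "summary.yaml"))
  invisible(summary)
}

#' Demo genome with planted CRISPR on- and off-target sites
#'
#' Builds a toy genome embedding one exact protospacer+PAM match and two
#' off-target sites (2 and 3 mismatches), plus planted SV breakpoint
#' anchors, for demonstrations and pipeline smoke tests.
#'
#' @param seed integer seed.
#' @return List with `genome`, `protospacer`, `offtargets` (chrom, cut,
#'   prob), `sv_pairs`.
#' @export
demo_edited_genome <- function(seed = 1L) {
  proto <- "GACGTTAACCGGATTCACGA"
  base <- random_genome(c(chr1 = 20000L, chr2 = 15000L), seed = seed)
  mutate_at <- function(s, i, b) {
    substr(s, i, i) <- b
    s
  }
  ot1 <- mutate_at(mutate_at(proto, 3, "T"), 11, "A")    # 2 mismatches
  ot2 <- mutate_at(mutate_at(mutate_at(proto, 2, "C"), 9, "T"), 18, "A")
  s1 <- as.character(base$seq[["chr1"]])
  s2 <- as.character(base$seq[["chr2"]])
  insert <- function(s, at, what) {   # overwrite, keeping length
    paste0(substr(s, 1, at - 1), what,
           substr(s, at + nchar(what), nchar(s)))
  }
  s1 <- insert(s1, 2001, paste0(proto, "AGG"))
  s1 <- insert(s1, 12001, paste0(ot1, "TGG"))
  s2 <- insert(s2, 6001, paste0(ot2, "CGG"))
  g <- genome(c(chr1 = s1, chr2 = s2))
  list(genome = g, protospacer = proto,
       offtargets = data.frame(chrom = c("chr1", "chr2"),
                               cut = c(12000L + 17L, 6000L + 17L),
                               prob = c(0.6, 0.4)),
       sv_pairs = data.frame(chromA = "chr1", cutA = 2000L + 17L,
                             chromB = "chr1", cutB = 12000L + 17L,
                             prob = 0.5))
}
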