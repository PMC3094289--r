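## End-to-end experiment runner: generate all packaged cohorts, optionally
## render + trace, then measure, classify and report.

#' Build a run manifest
#'
#' @param out_dir output directory.
#' @param seed master seed; per-genotype seeds are derived deterministically.
#' @param skip_render if `TRUE` (default), metrics are computed on the
#'   ground-truth trees (seconds); otherwise cohorts are rendered to image
#'   stacks and traced back (minutes).
#' @param genotypes character vector of genotype names (default: all nine
#'   packaged ones).
#' @param n_override optional named integer vector overriding cohort sizes.
#' @param write_swc write per-arbor SWC + varicosity CSV files.
#' @param write_tiff write rendered stacks as TIFF (render path only).
#' @return Named list (the manifest), recorded verbatim in the output.
#' @export
runManifest <- function(out_dir, seed = 1L, skip_render = TRUE,
                        genotypes = NULL, n_override = NULL,
                        write_swc = FALSE, write_tiff = FALSE) {
  list(out_dir = out_dir, seed = as.integer(seed), skip_render = skip_render,
       genotypes = genotypes, n_override = n_override,
       write_swc = write_swc, write_tiff = write_tiff,
       version = as.character(utils::packageVersion("arborquant")))
}

#' Run the full synthetic experiment
#'
#' Generates every configured genotype cohort at its configured size,
#' computes per-arbor metrics (ground-truth path, or render + trace when
#' `skip_render` is `FALSE`), classifies branches against the wildtype
#' consensus, and writes the summary table, per-arbor metrics, statistical
#' comparisons, histograms and the manifest to the output directory.
#' Identical manifest + seed produces identical CSV output.
#'
#' @param manifest from [runManifest()].
#' @return Invisibly, a list with the summary table (`table`), per-genotype
#'   metrics (`metrics`), test results (`tests`) and the consensus template.
#' @export
runExperiment <- function(manifest) {
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- wildtypeTemplate()
  cfgs <- packagedGenotypes(calibrate = TRUE, template = tpl)
  if (!is.null(manifest$genotypes))
    cfgs <- cfgs[manifest$genotypes]
  set.seed(manifest$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(cfgs))

  metrics <- list()
  cohorts <- list()
  log <- character(0)
  for (gi in seq_along(cfgs)) {
    cfg <- cfgs[[gi]]
    n <- cfg@nAnimals
    if (!is.null(manifest$n_override) && cfg@name %in% names(manifest$n_override))
      n <- manifest$n_override[[cfg@name]]
    cohort <- sampleCohort(cfg, tpl, seed = seeds[gi], n = n)
    log <- c(log, sprintf("genotype %s: n=%d seed=%d scale=%.4f", cfg@name, n,
                          seeds[gi], cfg@lengthScale))
    if (!manifest$skip_render) {
      rp <- renderParams()
      set.seed(seeds[gi] + 1L)
      traced <- lapply(seq_along(cohort), function(i) {
        st <- renderStack(cohort[[i]], rp)
        if (isTRUE(manifest$write_tiff))
          writeImageStack(st, file.path(manifest$out_dir,
                                        sprintf("%s_%02d.tif", cfg@name, i)))
        root <- cohort[[i]]@branches[[1]]@polyline[1, ]
        tr <- traceStack(st, entry_hint = root)
        ## animal size comes from the transmitted-light measurement, which
        ## the tracer does not see: carry it over from the ground truth
        tr@ganglionWidth <- cohort[[i]]@ganglionWidth
        tr@entryPoint <- cohort[[i]]@entryPoint
        tr@guidanceError <- cohort[[i]]@guidanceError
        tr@genotype <- cfg@name
        tr
      })
      measured <- traced
    } else measured <- cohort
    if (isTRUE(manifest$write_swc))
      for (i in seq_along(measured))
        writeSWC(measured[[i]], file.path(manifest$out_dir,
                                          sprintf("%s_%02d.swc", cfg@name, i)))
    filtered <- filterCohort(measured)
    cohorts[[cfg@name]] <- filtered
    metrics[[cfg@name]] <- summarizeCohort(filtered, genotype = cfg@name)
  }

  tab <- cohortTable(metrics)
  utils::write.csv(tab, file.path(manifest$out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  all_metrics <- do.call(rbind, metrics)
  utils::write.csv(all_metrics,
                   file.path(manifest$out_dir, "arbor_metrics.csv"),
                   row.names = FALSE)

  ## consensus skeleton from the wildtype cohort (when present)
  consensus <- NULL
  if ("w-" %in% names(cohorts))
    consensus <- buildConsensus(cohorts[["w-"]])
  if (!is.null(consensus))
    writeTemplate(consensus,
                  file.path(manifest$out_dir, "consensus_template.tsv"))

  ## statistical battery: each perturbed genotype against its control
  controlOf <- c("PlexA-LOF" = "w-", "PlexB-LOF" = "w-",
                 "PlexA-RNAi" = "455-Gal4", "PlexB-RNAi" = "455-Gal4",
                 "PlexA-RNAi-LOF" = "455-Gal4", "PlexB-RNAi-LOF" = "455-Gal4",
                 "PlexAB-RNAi" = "455-Gal4")
  tests <- list()
  for (g in names(metrics)) {
    ctrl <- controlOf[g]
    if (is.na(ctrl) || !(ctrl %in% names(metrics))) next
    a <- metrics[[g]]; b <- metrics[[ctrl]]
    tests[[g]] <- list(
      control = unname(ctrl),
      branches = rankSumTest(a$branch_count, b$branch_count),
      varicosities = rankSumTest(a$varicosity_count, b$varicosity_count),
      total_length_ks = ksTest(a$total_length, b$total_length),
      guidance = proportionTest(sum(a$guidance_error), nrow(a),
                                sum(b$guidance_error), nrow(b)))
  }
  if (length(metrics) >= 2) {
    tests[["anova_total_length"]] <-
      anovaBonferroni(lapply(metrics, function(m) m$total_length))
  }
  jsonlite::write_json(tests, file.path(manifest$out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)

  for (g in names(metrics)) {
    h <- lengthHistogram(metrics[[g]])
    utils::write.csv(h, file.path(manifest$out_dir,
                                  sprintf("hist_%s.csv", g)),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(manifest$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  writeLines(log, file.path(manifest$out_dir, "run.log"))
  invisible(list(table = tab, metrics = metrics, tests = tests,
                 consensus = consensus))
}
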