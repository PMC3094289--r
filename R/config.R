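## Genotype configurations: constructor, plain-text key-value round trip, and
## access to the nine packaged cohort configurations.

#' Construct a genotype configuration
#'
#' @param name genotype label.
#' @param n_animals cohort size.
#' @param branch_mean,branch_sem target mean and SEM of the per-arbor branch
#'   count (branches > 4 um, after normalization).
#' @param total_len_mean,total_len_sem target mean and SEM of total arbor
#'   size (um).
#' @param varicosity_mean,varicosity_sem target mean and SEM of the per-arbor
#'   varicosity count.
#' @param skeletal_mean target expected number of core (skeletal) branches
#'   present per arbor; splits the branch-count target into skeletal and
#'   variable contributions.
#' @param guidance_error_rate probability of entry through the wrong
#'   (metathoracic) pathway.
#' @param routing_error_rate per-skeletal-branch probability of an abnormal
#'   trajectory (> 45 degree deviation).
#' @param seed default cohort seed.
#' @return An uncalibrated [GenotypeConfig-class]; run [calibrateConfig()]
#'   before sampling.
#' @export
genotypeConfig <- function(name, n_animals, branch_mean, branch_sem,
                           total_len_mean, total_len_sem, varicosity_mean,
                           varicosity_sem, skeletal_mean,
                           guidance_error_rate = 0, routing_error_rate = 0,
                           seed = 1L) {
  new("GenotypeConfig", name = name, nAnimals = as.integer(n_animals),
      targets = c(branch_mean = branch_mean, branch_sem = branch_sem,
                  total_len_mean = total_len_mean,
                  total_len_sem = total_len_sem,
                  varicosity_mean = varicosity_mean,
                  varicosity_sem = varicosity_sem,
                  skeletal_mean = skeletal_mean),
      guidanceErrorRate = guidance_error_rate,
      routingErrorRate = routing_error_rate, seed = as.integer(seed))
}

.CFG_TARGETS <- c("branch_mean", "branch_sem", "total_len_mean",
                  "total_len_sem", "varicosity_mean", "varicosity_sem",
                  "skeletal_mean")
.CFG_SLOTS <- c(guidance_error_rate = "guidanceErrorRate",
                routing_error_rate = "routingErrorRate",
                variable_branch_rate = "variableBranchRate",
                variable_branch_sd = "variableBranchSD",
                length_scale = "lengthScale",
                varicosity_density = "varicosityDensity",
                skeleton_presence_scale = "skeletonPresenceScale",
                length_disp_cv = "lengthDispCV",
                varicosity_disp_cv = "varicosityDispCV")

#' Read / write genotype configurations as plain-text key-value files
#'
#' Lines are `key: value`; `#` starts a comment. Calibrated generator
#' parameters are included when present so a calibrated configuration
#' round-trips.
#'
#' @param path file path.
#' @return `readGenotypeConfig()` returns a [GenotypeConfig-class].
#' @export
readGenotypeConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")),
                 character(1))
  get <- function(k, required = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (required) stop(sprintf("config %s missing key '%s'", path, k))
      return(NA_character_)
    }
    vals[i]
  }
  cfg <- genotypeConfig(
    name = get("name"), n_animals = as.integer(get("n_animals")),
    branch_mean = as.numeric(get("branch_mean")),
    branch_sem = as.numeric(get("branch_sem")),
    total_len_mean = as.numeric(get("total_len_mean")),
    total_len_sem = as.numeric(get("total_len_sem")),
    varicosity_mean = as.numeric(get("varicosity_mean")),
    varicosity_sem = as.numeric(get("varicosity_sem")),
    skeletal_mean = as.numeric(get("skeletal_mean")),
    guidance_error_rate = as.numeric(get("guidance_error_rate")),
    routing_error_rate = as.numeric(get("routing_error_rate")),
    seed = as.integer(get("seed")))
  for (k in setdiff(names(.CFG_SLOTS), c("guidance_error_rate",
                                         "routing_error_rate"))) {
    v <- get(k, required = FALSE)
    if (!is.na(v)) slot(cfg, .CFG_SLOTS[[k]]) <- as.numeric(v)
  }
  cal <- get("calibrated", required = FALSE)
  cfg@calibrated <- identical(cal, "TRUE")
  validObject(cfg)
  cfg
}

#' @rdname readGenotypeConfig
#' @param config a [GenotypeConfig-class].
#' @export
writeGenotypeConfig <- function(config, path) {
  t <- config@targets
  lines <- c(sprintf("name: %s", config@name),
             sprintf("n_animals: %d", config@nAnimals),
             vapply(.CFG_TARGETS,
                    function(k) sprintf("%s: %.10g", k, t[[k]]), character(1)),
             vapply(names(.CFG_SLOTS), function(k)
               sprintf("%s: %.10g", k, slot(config, .CFG_SLOTS[[k]])),
               character(1)),
             sprintf("calibrated: %s", config@calibrated),
             sprintf("seed: %d", config@seed))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged genotype configurations
#'
#' Returns the nine packaged cohort configurations (uncalibrated), keyed by
#' genotype name, read from the plain-text files under
#' `system.file("extdata/genotypes", package = "arborquant")`.
#'
#' @param calibrate if `TRUE`, calibrate each configuration against
#'   `template` before returning.
#' @param template skeleton template used for calibration.
#' @return Named list of [GenotypeConfig-class] objects, in summary-table
#'   row order.
#' @export
packagedGenotypes <- function(calibrate = FALSE,
                              template = wildtypeTemplate()) {
  dir <- system.file("extdata", "genotypes", package = "arborquant")
  order <- c("w_minus", "gal4_455", "plexa_lof", "plexa_rnai",
             "plexa_rnai_lof", "plexb_lof", "plexb_rnai", "plexb_rnai_lof",
             "plexab_rnai")
  cfgs <- lapply(file.path(dir, paste0(order, ".cfg")), readGenotypeConfig)
  names(cfgs) <- vapply(cfgs, function(c) c@name, character(1))
  if (calibrate) cfgs <- lapply(cfgs, calibrateConfig, template = template)
  cfgs
}
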