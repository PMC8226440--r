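#' Full diversity panel for a reference population
#'
#' The standard studbook report: sex counts and ratio, equivalent complete
#' generations (mean and sd), mean inbreeding overall and by sex, the two
#' realized effective sizes (NeF, NeC) and their ratio, and the generation
#' interval of the whole pedigree.
#'
#' @param ped a [pedigree].
#' @param cohort reference-cohort ids (default: all individuals).
#' @return A `diversity_report` data frame with columns `metric`, `value`
#'   and `flag` (`"undefined"`/`"infinite"` where applicable).
#' @export
diversity_report <- function(ped, cohort = NULL) {
  if (is.null(cohort)) cohort <- ped$id
  ps <- pedigree_stats(ped, cohort)
  nef <- ne_inbreeding(ped, cohort)
  nec <- if (length(cohort) >= 2L) ne_coancestry(ped, cohort) else NA_real_
  ratio <- if (is.finite(nef) && is.finite(nec) && !is.na(nef) && !is.na(nec))
    as.numeric(nec) / as.numeric(nef) else NA_real_
  vals <- c("Males" = ps$n_males, "Females" = ps$n_females,
            "Ratio females/males" = ps$sex_ratio,
            "EG" = ps$mean_EG, "Standard deviation of EG" = ps$sd_EG,
            "Inbreeding" = ps$mean_F,
            "Inbreeding of males" = ps$mean_F_males,
            "Inbreeding of females" = ps$mean_F_females,
            "NeF" = as.numeric(nef), "NeC" = as.numeric(nec),
            "NeC/NeF" = ratio,
            "Generation interval" = ps$generation_interval)
  flag <- ifelse(is.na(vals), "undefined",
                 ifelse(is.infinite(vals), "infinite", ""))
  out <- data.frame(metric = names(vals), value = unname(vals),
                    flag = unname(flag), stringsAsFactors = FALSE)
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' @export
print.diversity_report <- function(x, digits = 3, ...) {
  cat("Reference population diversity panel\n")
  for (i in seq_len(nrow(x))) {
    v <- x$value[i]
    shown <- if (x$flag[i] != "") x$flag[i] else format(round(v, digits))
    cat(sprintf("  %-26s %s\n", x$metric[i], shown))
  }
  invisible(x)
}

#' Write a diversity report as CSV
#'
#' Undefined or infinite values are written as empty cells; the `flag`
#' column carries their status, so no numeric sentinel ever appears.
#'
#' @param x a [diversity_report()] (or [cohort_diversity()]) data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(x, path) {
  out <- as.data.frame(x)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]][!is.finite(out[[cn]])] <- NA
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a kinship matrix as square CSV
#'
#' @param kinship matrix from [kinship_matrix()].
#' @param path output path; ids appear as header row and first column.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kinship, path) {
  df <- data.frame(id = rownames(kinship), kinship, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pedigree statistics report from a file (CLI backend)
#'
#' Reads a pedigree, selects the reference cohort and emits the full
#' diversity panel, optionally writing it (and the cohort's kinship
#' matrix) to CSV.
#'
#' @param pedigree a [pedigree] object or a file path for
#'   [read_pedigree()].
#' @param flock,years,ids cohort filters, see [reference_cohort()].
#' @param out optional output CSV path for the panel.
#' @param kinship_out optional output CSV path for the cohort kinship
#'   matrix.
#' @return The `diversity_report`, invisibly.
#' @export
cli_stats <- function(pedigree, flock = NULL, years = NULL, ids = NULL,
                      out = NULL, kinship_out = NULL) {
  ped <- if (inherits(pedigree, "pedigree")) pedigree else read_pedigree(pedigree)
  cohort <- reference_cohort(ped, flock = flock, years = years, ids = ids)
  if (!length(cohort)) stop("reference cohort is empty")
  rep_ <- diversity_report(ped, cohort)
  print(rep_)
  if (!is.null(out)) write_diversity_report(rep_, out)
  if (!is.null(kinship_out)) write_kinship(kinship_matrix(ped, cohort), kinship_out)
  invisible(rep_)
}

#' Read a simulation configuration
#'
#' YAML configuration for [cli_simulate()]. Recognized fields:
#' `strategies` (list of names, or `"all"` for the full catalogue of 23),
#' `generations`, `replicates`, `seed`, and either `profile`
#' (`"almeria-like"`/`"lajita-like"`) or `pedigree` (path) with optional
#' `flock`/`years` cohort filters.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(strategies = "all", generations = 20L, replicates = 100L,
                   seed = 1L, profile = NULL, pedigree = NULL,
                   flock = NULL, years = NULL)
  cfg <- modifyList(defaults, cfg)
  if (identical(cfg$strategies, "all")) cfg$strategies <- list_strategies()
  cfg$strategies <- vapply(unlist(cfg$strategies),
                           function(s) strategy(s)$name, character(1),
                           USE.NAMES = FALSE)
  if (is.null(cfg$profile) && is.null(cfg$pedigree))
    stop("config must give either a scenario 'profile' or a 'pedigree' path")
  cfg$generations <- as.integer(cfg$generations)
  cfg$replicates <- as.integer(cfg$replicates)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run a configured experiment and write its outputs (CLI backend)
#'
#' Runs [run_experiment()] for the configured strategies and writes tidy
#' per-replicate trajectories, the per-generation summary, and a run
#' manifest (configuration snapshot, seeds, timings, warnings and a content
#' hash of every output file) into `out_dir`.
#'
#' @param config a configuration list ([read_sim_config()]) or a YAML path.
#' @param out_dir output directory, created if needed.
#' @return The `ne_experiment`, invisibly; side effect: files
#'   `trajectories.csv`, `summary.csv`, `manifest.json` in `out_dir`.
#' @export
cli_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$profile)) {
    base <- generate_base_pedigree(scenario_profile(config$profile,
                                                    seed = config$seed))
    cohort <- base$cohort
    ped <- base$pedigree
  } else {
    ped <- read_pedigree(config$pedigree)
    cohort <- reference_cohort(ped, flock = config$flock, years = config$years)
  }
  t1 <- proc.time()[["elapsed"]]
  exp_ <- run_experiment(ped, config$strategies, cohort = cohort,
                         n_generations = config$generations,
                         n_replicates = config$replicates, seed = config$seed)
  t2 <- proc.time()[["elapsed"]]
  traj_path <- file.path(out_dir, "trajectories.csv")
  sum_path <- file.path(out_dir, "summary.csv")
  tr <- exp_$trajectories
  tr$ne_f[!is.finite(tr$ne_f)] <- NA
  tr$ne_c[!is.finite(tr$ne_c)] <- NA
  utils::write.csv(tr, traj_path, row.names = FALSE, na = "")
  utils::write.csv(exp_$summary, sum_path, row.names = FALSE, na = "")
  clamped <- sum(exp_$trajectories$clamped)
  redraws <- sum(exp_$trajectories$sex_redraws)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pedmate")),
    config = config[!vapply(config, is.null, logical(1))],
    seed = config$seed,
    timings = list(setup_s = round(t1 - t0, 3),
                   simulate_s = round(t2 - t1, 3)),
    warnings = list(clamped_cohort_draws = clamped, sex_redraws = redraws,
                    aborted_replicates = nrow(exp_$aborted)),
    files = as.list(tools::md5sum(c(traj_path, sum_path))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(exp_)
}
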