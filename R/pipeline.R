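#' Analyze bilaterally averaged records
#'
#' Produces the full statistical output set from a long-format record
#' table: bilateral averaging with ordinal categorization, category counts,
#' cell means/SDs of measurable distances, rates of distances above 2 mm,
#' non-measurable rates, the paired left/right check, and the ordinal model
#' with subject-clustered inference.
#'
#' @param records long-format table from [measure_cohort()]
#' @param gee_formula model formula passed to [fit_ordinal_gee()]
#' @return list with `averaged`, `t2_categories`, `t3_means`, `t4_gt2`,
#'   `t5_nonmeasurable`, `paired_sides`, `gee`
#' @export
analyze_records <- function(records, gee_formula = NULL) {
  avg <- average_bilateral(records)
  gee <- if (is.null(gee_formula)) fit_ordinal_gee(avg)
         else fit_ordinal_gee(avg, gee_formula)
  list(averaged = avg,
       t2_categories = category_counts(avg),
       t3_means = summarize_measurable(avg),
       t4_gt2 = rate_gt2(avg),
       t5_nonmeasurable = nonmeasurable_rates(avg),
       paired_sides = paired_side_test(records),
       gee = gee)
}

#' Run the whole simulation pipeline
#'
#' Generator -> placement -> measurement -> statistics, with provenance.
#' The default configuration mirrors the study design: 20 subjects per
#' facial-type group (60 total), 4 interradicular sites, insertion angles
#' 0/30/45/60 degrees, bilateral placements averaged into
#' 60 x 16 = 960 analyzed records.
#'
#' @param config a [default_config()] list
#' @param out_dir optional output directory; when given, writes
#'   `scenes/cohort.json`, `records.csv`, `records_bilateral.csv`,
#'   `tables/t2.csv` ... `tables/t5.csv`, `gee.json` and `manifest.json`
#' @param gee_formula optional model formula override
#' @return (invisibly) list with `cohort`, `records`, `analysis`, `manifest`
#' @export
run_all <- function(config = default_config(), out_dir = NULL,
                    gee_formula = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", simulate_cohort(config$n_per_group, config))
  records <- stage("measure", measure_cohort(cohort, config))
  analysis <- stage("analyze", analyze_records(records, gee_formula))
  manifest <- list(package = "miniscrewsim",
                   version = as.character(utils::packageVersion("miniscrewsim")),
                   config = config[setdiff(names(config), "segment_overrides")],
                   seed = config$seed,
                   n_records = nrow(records),
                   n_averaged = nrow(analysis$averaged),
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "scenes"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    stage("write", {
      write_scene_json(cohort, file.path(out_dir, "scenes", "cohort.json"))
      utils::write.csv(records, file.path(out_dir, "records.csv"),
                       row.names = FALSE)
      utils::write.csv(analysis$averaged,
                       file.path(out_dir, "records_bilateral.csv"),
                       row.names = FALSE)
      utils::write.csv(analysis$t2_categories,
                       file.path(out_dir, "tables", "t2.csv"),
                       row.names = FALSE)
      t3 <- analysis$t3_means
      t3$mean <- round_half_up(t3$mean, 2)
      t3$sd <- round_half_up(t3$sd, 2)
      utils::write.csv(t3, file.path(out_dir, "tables", "t3.csv"),
                       row.names = FALSE)
      t4 <- analysis$t4_gt2
      t4$pct <- round_half_up(t4$pct, 1)
      utils::write.csv(t4, file.path(out_dir, "tables", "t4.csv"),
                       row.names = FALSE)
      t5 <- analysis$t5_nonmeasurable
      t5$pct_contact <- round_half_up(t5$pct_contact, 1)
      t5$pct_noncontact <- round_half_up(t5$pct_noncontact, 1)
      utils::write.csv(t5, file.path(out_dir, "tables", "t5.csv"),
                       row.names = FALSE)
      gee <- analysis$gee
      writeLines(jsonlite::toJSON(
        list(terms = gee$terms, coefficients = gee$coefficients,
             zeta = gee$zeta, levels = gee$levels, corstr = gee$corstr,
             n_clusters = gee$n_clusters, directions = gee$directions),
        auto_unbox = TRUE, digits = 10, pretty = TRUE, dataframe = "rows",
        na = "null"),
        file.path(out_dir, "gee.json"))
    })
    csvs <- list.files(out_dir, pattern = "\\.csv$", recursive = TRUE,
                       full.names = TRUE)
    manifest$digests <- as.list(tools::md5sum(csvs))
    names(manifest$digests) <- basename(csvs)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = 10, na = "null"),
               file.path(out_dir, "manifest.json"))
  }
  invisible(list(cohort = cohort, records = records, analysis = analysis,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (cohort to scene JSON), `measure` (scene JSON to
#' records CSV), `analyze` (records CSV to tables + model JSON), `run-all`.
#' Options: `--seed`, `--n-per-group`, `--out-dir`, `--voxel`.
#'
#' @param args character vector (defaults to the process arguments)
#' @return exit status, invisibly
#' @export
msr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: miniscrewsim <simulate|measure|analyze|run-all>",
        "[--seed N] [--n-per-group N] [--out-dir DIR] [--in FILE] [--voxel]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i)) args[i[1] + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  npg <- as.integer(opt("--n-per-group", "20"))
  out_dir <- opt("--out-dir", "miniscrewsim-out")
  mode <- if ("--voxel" %in% args) "voxel" else "analytic"
  cfg <- default_config(n_per_group = npg, seed = seed, mode = mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    "simulate" = {
      cohort <- simulate_cohort(npg, cfg)
      write_scene_json(cohort, file.path(out_dir, "cohort.json"))
      utils::write.csv(cohort_covariates(cohort),
                       file.path(out_dir, "covariates.csv"),
                       row.names = FALSE)
    },
    "measure" = {
      cohort <- read_scene_json(opt("--in", file.path(out_dir, "cohort.json")))
      cohort$config <- utils::modifyList(cfg, cohort$config %||% list())
      records <- measure_cohort(cohort, cohort$config)
      utils::write.csv(records, file.path(out_dir, "records.csv"),
                       row.names = FALSE)
    },
    "analyze" = {
      records <- utils::read.csv(opt("--in", file.path(out_dir, "records.csv")),
                                 stringsAsFactors = FALSE)
      an <- analyze_records(records)
      dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
      for (nm in c("t2_categories", "t3_means", "t4_gt2", "t5_nonmeasurable"))
        utils::write.csv(an[[nm]],
                         file.path(out_dir, "tables",
                                   paste0(substr(nm, 1, 2), ".csv")),
                         row.names = FALSE)
      print(an$gee)
    },
    "run-all" = run_all(cfg, out_dir),
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
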