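# Dataset reading/writing and the pipeline driver.
#
# Native on-disk format: NONMEM-style event-record CSV with header
# ID, OCC, TIME, TAD, DV, DVID, AMT, EVID, MDV, BLQ.
# EVID 1 = dose (MDV 1, DV empty), EVID 0 = observation.
# DVID: 1 = drug (µg/L), 2 = GH (ng/mL), 3 = PRL (ng/mL).
# TIME is clock-normalised: 0 = 6 a.m. of the first study day.

EVENT_COLUMNS <- c("ID", "OCC", "TIME", "TAD", "DV", "DVID", "AMT",
                   "EVID", "MDV", "BLQ")

#' Write an event table to CSV
#'
#' @param tab an `event_table` or data.frame with the canonical columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(tab, path) {
  stopifnot(all(EVENT_COLUMNS %in% names(tab)))
  write.csv(as.data.frame(tab)[, EVENT_COLUMNS], path, row.names = FALSE,
            quote = FALSE, na = ".")
  invisible(path)
}

#' Read and validate an event table
#'
#' Reads a NONMEM-style event-record CSV and validates its contract: all
#' canonical columns present, record times nondecreasing within a subject,
#' exactly one dose or observation per record, and no DV on dose records.
#' If the file carries wall-clock times (a `CLOCK` column in "HH:MM"),
#' they are normalised so that 06:00 of the first day maps to 0 h.
#'
#' @param path CSV file.
#' @return an `event_table` data.frame.
#' @export
read_event_table <- function(path) {
  tab <- read.csv(path, na.strings = c(".", "NA", ""))
  if ("CLOCK" %in% names(tab) && !"TIME" %in% names(tab)) {
    hm <- strsplit(as.character(tab$CLOCK), ":")
    hrs <- vapply(hm, function(x) as.numeric(x[1]) + as.numeric(x[2]) / 60,
                  0)
    day <- if ("DAY" %in% names(tab)) tab$DAY - 1 else 0
    tab$TIME <- hrs - 6 + 24 * day
    tab$CLOCK <- NULL
    tab$DAY <- NULL
  }
  missing_cols <- setdiff(EVENT_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, EVENT_COLUMNS]
  for (id in unique(tab$ID)) {
    tt <- tab$TIME[tab$ID == id]
    if (is.unsorted(tt)) {
      stop("non-monotone record times within subject ", id)
    }
  }
  bad_dose <- tab$EVID == 1 & !is.na(tab$DV)
  if (any(bad_dose)) {
    stop("DV present on dose (EVID 1) record(s) at row(s): ",
         paste(head(which(bad_dose), 5), collapse = ", "))
  }
  if (any(tab$EVID == 1 & tab$MDV != 1)) {
    stop("dose records must carry MDV 1")
  }
  structure(tab, class = c("event_table", "data.frame"))
}

#' Analysis configuration
#'
#' Nested, schema-checked configuration for [run_pipeline()]. Unknown keys
#' in any section are rejected.
#'
#' @param design list with `cohorts` (character) and `n_per_cohort`.
#' @param pk,gh,prl parameter objects ([pk_config()], [gh_params()],
#'   [prl_params()]); `gh`/`prl` may be `NULL` to skip that hormone.
#' @param stages character subset of `c("simulate", "deconvolve", "fit")`
#'   in pipeline order.
#' @param estimation list: `hormone` ("gh"/"prl"), `alpha` (deconvolution
#'   significance level), `control` (passed to [pkpd_fit()]).
#' @param seed master seed.
#' @param out_dir output directory for stage artifacts.
#' @return validated `analysis_config` object.
#' @export
analysis_config <- function(design = list(cohorts = "placebo",
                                          n_per_cohort = 8),
                            pk = pk_config(), gh = gh_params(),
                            prl = prl_params(),
                            stages = "simulate",
                            estimation = list(hormone = "gh", alpha = 0.05,
                                              control = list()),
                            seed = 1, out_dir = tempdir()) {
  allowed_design <- c("cohorts", "n_per_cohort")
  if (length(setdiff(names(design), allowed_design))) {
    stop("unknown design key(s): ",
         paste(setdiff(names(design), allowed_design), collapse = ", "))
  }
  allowed_est <- c("hormone", "alpha", "control")
  if (length(setdiff(names(estimation), allowed_est))) {
    stop("unknown estimation key(s): ",
         paste(setdiff(names(estimation), allowed_est), collapse = ", "))
  }
  bad <- setdiff(stages, c("simulate", "deconvolve", "fit"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (co in design$cohorts) build_design(co)  # validates names
  structure(list(design = design, pk = pk, gh = gh, prl = prl,
                 stages = stages, estimation = estimation, seed = seed,
                 out_dir = out_dir),
            class = "analysis_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (simulate -> deconvolve -> fit),
#' with inter-stage artifacts on disk under `config$out_dir`, and returns a
#' run manifest. Re-running with an identical configuration and seed
#' reproduces identical stage outputs.
#'
#' @param config an [analysis_config()].
#' @return a `run_manifest` list: config hash, seed, per-stage timings and
#'   output files with checksums.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  timings <- numeric(0)
  artifacts <- list()

  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  tab <- NULL
  if ("simulate" %in% config$stages) {
    tab <- run_stage("simulate", function() {
      simulate_trial(config$design$cohorts,
                     n_per_cohort = config$design$n_per_cohort,
                     pk = config$pk, gh = config$gh, prl = config$prl,
                     seed = config$seed)
    })
    f <- file.path(config$out_dir, "trial.csv")
    write_event_table(tab, f)
    files <- c(files, f)
  }
  pulses <- NULL
  if ("deconvolve" %in% config$stages) {
    if (is.null(tab)) tab <- read_event_table(file.path(config$out_dir,
                                                        "trial.csv"))
    pulses <- run_stage("deconvolve", function() {
      deconvolve_trial(tab, alpha = config$estimation$alpha)
    })
    f <- file.path(config$out_dir, "pulses.csv")
    write.csv(pulses, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if ("fit" %in% config$stages) {
    if (is.null(tab)) tab <- read_event_table(file.path(config$out_dir,
                                                        "trial.csv"))
    fit <- run_stage("fit", function() {
      pkpd_fit(tab, model = config$estimation$hormone,
               pulses = pulses, pk = config$pk,
               control = config$estimation$control)
    })
    f <- file.path(config$out_dir, "fit.rds")
    saveRDS(strip_fit(fit), f)
    files <- c(files, f)
    artifacts$fit <- fit
  }

  structure(list(config_hash = .config_hash(config), seed = config$seed,
                 stages = config$stages, timings = timings,
                 files = setNames(unname(tools::md5sum(files)), files),
                 artifacts = artifacts),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "(seed", x$seed, ")\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  for (f in names(x$files)) cat("  ", f, " [", x$files[[f]], "]\n", sep = "")
  invisible(x)
}
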