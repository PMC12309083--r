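#' Build a pipeline run configuration
#'
#' Collects everything one analysis run needs: the two atlas files with
#' their label tables, a per-patient table of mask (and optional transform)
#' paths, an optional clinical table, and the scoring settings.
#'
#' @param atlases list of one or two entries, each
#'   `list(volume = <nifti path>, table = <tsv path>)`; with two entries the
#'   first is treated as the cortical and the second as the subcortical
#'   atlas and they are merged into one region universe.
#' @param patients data.frame with columns `patient_id`, `primary`,
#'   `recurrence` and optionally `transform` (path or NA) and
#'   `transform_convention` (`"world"` or `"fsl"`, default `"fsl"`).
#' @param clinical_table optional clinical TSV/CSV path.
#' @param min_voxels,min_frac coverage thresholds (see [coverage_set()]).
#' @param mask_interp `"nearest"` (default) or `"trilinear"` resampling for
#'   masks that carry a transform.
#' @param threshold re-binarisation threshold after trilinear resampling.
#' @param assume_registered treat mask grids as already co-registered with
#'   the atlas grid; patients without a transform are resampled by the
#'   identity world map when their grid differs from the atlas grid.
#' @param strict abort on the first per-patient failure instead of recording
#'   it and continuing.
#' @param out_dir optional directory for `per_patient.tsv`, `cohort.tsv`,
#'   `report.json` and `run.log`.
#' @return A `run_config` list.
#' @export
run_config <- function(atlases, patients, clinical_table = NULL,
                       min_voxels = 1L, min_frac = NULL,
                       mask_interp = c("nearest", "trilinear"),
                       threshold = 0.5, assume_registered = TRUE,
                       strict = FALSE, out_dir = NULL) {
  mask_interp <- match.arg(mask_interp)
  if (!is.list(atlases) || !length(atlases) %in% 1:2 ||
      !all(vapply(atlases, function(a)
        is.list(a) && all(c("volume", "table") %in% names(a)), TRUE)))
    stop("atlases must be a list of 1-2 entries with fields volume and table")
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  need <- c("patient_id", "primary", "recurrence")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols))
    stop(sprintf("patients table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(patients$patient_id))
    stop("patient ids must be unique")
  if (is.null(patients$transform)) patients$transform <- NA_character_
  if (is.null(patients$transform_convention))
    patients$transform_convention <- "fsl"
  structure(list(atlases = atlases, patients = patients,
                 clinical_table = clinical_table,
                 min_voxels = as.integer(min_voxels), min_frac = min_frac,
                 mask_interp = mask_interp, threshold = threshold,
                 assume_registered = isTRUE(assume_registered),
                 strict = isTRUE(strict), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Paths in the file are resolved relative to the file's directory. The
#' per-patient entries may be given inline under `patients:` or as a
#' delimited manifest referenced by `patient_manifest:`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config '%s'", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || is.na(p)) p else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  atlases <- lapply(y$atlases, function(a)
    list(volume = rel(a$volume), table = rel(a$table)))
  patients <- if (!is.null(y$patient_manifest)) {
    read_delimited(rel(y$patient_manifest))
  } else {
    do.call(rbind, lapply(y$patients, function(p)
      data.frame(patient_id = p$patient_id, primary = p$primary,
                 recurrence = p$recurrence,
                 transform = p$transform %||% NA_character_,
                 transform_convention = p$transform_convention %||% "fsl",
                 stringsAsFactors = FALSE)))
  }
  for (col in c("primary", "recurrence", "transform"))
    patients[[col]] <- vapply(patients[[col]], function(p)
      if (is.na(p)) NA_character_ else rel(p), "")
  run_config(
    atlases = atlases, patients = patients,
    clinical_table = rel(y$clinical_table),
    min_voxels = y$min_voxels %||% 1L, min_frac = y$min_frac,
    mask_interp = y$mask_interp %||% "nearest",
    threshold = y$threshold %||% 0.5,
    assume_registered = y$assume_registered %||% TRUE,
    strict = y$strict %||% FALSE, out_dir = rel(y$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a run configuration for a generated synthetic cohort
#'
#' Reads the `manifest.json` that [write_cohort()] emitted and points a
#' [run_config()] at the cohort's files.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @param ... scoring settings passed on to [run_config()].
#' @return A `run_config`.
#' @export
synthetic_run_config <- function(dir, ...) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop(sprintf("no manifest.json in '%s'", dir))
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rel <- function(p) file.path(dir, p)
  patients <- m$patients
  patients$primary <- rel(patients$primary)
  patients$recurrence <- rel(patients$recurrence)
  if (!is.null(patients$transform)) {
    has <- !is.na(patients$transform) & patients$transform != ""
    patients$transform[has] <- rel(patients$transform[has])
    patients$transform[!has] <- NA_character_
  }
  run_config(
    atlases = list(
      list(volume = rel(m$atlases$cortical$volume),
           table = rel(m$atlases$cortical$table)),
      list(volume = rel(m$atlases$subcortical$volume),
           table = rel(m$atlases$subcortical$table))),
    patients = patients,
    clinical_table = rel(m$clinical_table), ...)
}

#' Validate a run configuration
#'
#' Checks that every referenced file exists and is readable, that patient
#' ids are unique, that atlas label volumes resolve against their tables,
#' and that mask grids are compatible with the atlas grid (or carry a
#' transform). Findings are returned, not thrown.
#'
#' @param config a `run_config`.
#' @return data.frame of findings with columns `level` (`"error"`/`"warning"`)
#'   and `message`; attribute `pass` is TRUE when no errors were found.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- data.frame(level = character(0), message = character(0),
                         stringsAsFactors = FALSE)
  note <- function(level, msg)
    findings <<- rbind(findings, data.frame(level = level, message = msg,
                                            stringsAsFactors = FALSE))
  atlas <- tryCatch(load_atlas(config), error = function(e) {
    note("error", conditionMessage(e)); NULL
  })
  for (i in seq_len(nrow(config$patients))) {
    p <- config$patients[i, ]
    for (col in c("primary", "recurrence")) {
      if (!file.exists(p[[col]])) {
        note("error", sprintf("patient %s: missing %s mask file '%s'",
                              p$patient_id, col, p[[col]]))
        next
      }
      if (is.null(atlas)) next
      m <- tryCatch(read_mask(p[[col]], role = col, patient_id = p$patient_id),
                    warning = function(w) {
                      note("warning", conditionMessage(w))
                      suppressWarnings(read_mask(p[[col]], role = col,
                                                 patient_id = p$patient_id))
                    },
                    error = function(e) {
                      note("error", sprintf("patient %s: %s", p$patient_id,
                                            conditionMessage(e)))
                      NULL
                    })
      if (!is.null(m) && is.na(p$transform) &&
          !grids_compatible(m$grid, atlas$grid))
        note("error", sprintf(
          "patient %s: %s mask grid (%s) incompatible with atlas grid (%s) and no transform given",
          p$patient_id, col, format(m$grid), format(atlas$grid)))
    }
    if (!is.na(p$transform) && !file.exists(p$transform))
      note("error", sprintf("patient %s: missing transform file '%s'",
                            p$patient_id, p$transform))
  }
  if (!is.null(config$clinical_table) && !file.exists(config$clinical_table))
    note("error", sprintf("missing clinical table '%s'", config$clinical_table))
  attr(findings, "pass") <- !any(findings$level == "error")
  findings
}

load_atlas <- function(config) {
  vols <- lapply(config$atlases, function(a)
    read_label_volume(a$volume, a$table))
  if (length(vols) == 1L) vols[[1]] else merge_atlases(vols[[1]], vols[[2]])
}

#' Run the full region-overlap analysis
#'
#' For every patient: load both masks, bring them onto the atlas grid
#' (through the supplied transform, or the identity map when the run assumes
#' co-registration), compute the primary and recurrence coverage sets, the
#' region-level confusion counts and the diagnostic metrics; then aggregate
#' the cohort both ways (pooled counts and patient-averaged metrics) and
#' summarise the clinical table if one is configured. With an `out_dir` the
#' results are also written as `per_patient.tsv`, `cohort.tsv`, a
#' `report.json` carrying the full settings block, and a timestamped
#' `run.log` (timestamps are confined to the log so reruns of the same
#' configuration are byte-identical).
#'
#' @param config a `run_config`.
#' @return A `regionscore_run` object; see [summary.regionscore_run()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- sprintf("[%s] run started", format(Sys.time()))
  atlas <- load_atlas(config)

  per <- list(); counts <- list(); coverage <- list(); errors <- list()
  for (i in seq_len(nrow(config$patients))) {
    p <- config$patients[i, ]
    res <- tryCatch(
      score_patient(p, atlas, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (config$strict)
        stop(sprintf("patient %s: %s", p$patient_id, conditionMessage(res)))
      errors[[p$patient_id]] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("[%s] patient %s FAILED: %s",
                                        format(Sys.time()), p$patient_id,
                                        conditionMessage(res)))
      next
    }
    counts[[p$patient_id]] <- res$counts
    coverage[[p$patient_id]] <- res$coverage
    met <- diagnostic_metrics(res$counts)
    per[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id,
      A = res$counts$A, B = res$counts$B, C = res$counts$C, D = res$counts$D,
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv,
      n_undefined = sum(is.na(c(met$sensitivity, met$specificity,
                                met$ppv, met$npv))),
      stringsAsFactors = FALSE)
    log_lines <- c(log_lines, sprintf("[%s] patient %s scored",
                                      format(Sys.time()), p$patient_id))
  }
  if (!length(counts))
    stop("no patient could be scored; aborting")
  per_patient <- do.call(rbind, per)
  rownames(per_patient) <- NULL

  cohort <- list(pooled = aggregate_metrics(counts, "pooled"),
                 mean = aggregate_metrics(counts, "mean"))

  clinical <- NULL
  if (!is.null(config$clinical_table))
    clinical <- cohort_summary(read_clinical_table(config$clinical_table))

  settings <- list(
    min_voxels = config$min_voxels, min_frac = config$min_frac,
    mask_interp = config$mask_interp, threshold = config$threshold,
    assume_registered = config$assume_registered, strict = config$strict,
    universe_size = nrow(atlas$label_table),
    atlas_offset = atlas$offset,
    n_atlases = length(config$atlases))

  run <- structure(list(per_patient = per_patient, counts = counts,
                        coverage = coverage, cohort = cohort,
                        clinical = clinical, settings = settings,
                        errors = errors),
                   class = "regionscore_run")
  if (!is.null(config$out_dir)) {
    write_run_report(run, config$out_dir)
    writeLines(c(log_lines, sprintf("[%s] run finished", format(Sys.time()))),
               file.path(config$out_dir, "run.log"))
  }
  run
}

score_patient <- function(p, atlas, config) {
  primary <- read_mask(p$primary, role = "primary", patient_id = p$patient_id)
  recurrence <- read_mask(p$recurrence, role = "recurrence",
                          patient_id = p$patient_id)
  align <- function(mask) {
    if (!is.na(p$transform)) {
      conv <- if (identical(p$transform_convention, "world")) "world_mm"
        else "fsl_scaled_mm"
      t <- read_transform(p$transform, mask$grid, atlas$grid, conv)
      apply_to_mask(mask, t, atlas$grid, interp = config$mask_interp,
                    threshold = config$threshold)
    } else if (grids_compatible(mask$grid, atlas$grid)) {
      mask
    } else if (config$assume_registered) {
      apply_to_mask(mask, NULL, atlas$grid, interp = config$mask_interp,
                    threshold = config$threshold)
    } else {
      stop_grid_mismatch(mask$grid, atlas$grid,
                         sprintf("patient %s mask vs atlas (no transform)",
                                 p$patient_id))
    }
  }
  primary <- align(primary)
  recurrence <- align(recurrence)
  p_cov <- coverage_set(primary, atlas, min_voxels = config$min_voxels,
                        min_frac = config$min_frac)
  r_cov <- coverage_set(recurrence, atlas, min_voxels = config$min_voxels,
                        min_frac = config$min_frac)
  list(coverage = list(primary = p_cov, recurrence = r_cov),
       counts = confusion_counts(p_cov, r_cov))
}

cohort_table <- function(run) {
  rows <- lapply(names(run$cohort), function(mode) {
    m <- run$cohort[[mode]]
    pooled_counts <- if (mode == "pooled") {
      Reduce(`+`, lapply(run$counts, function(cc) c(cc$A, cc$B, cc$C, cc$D)))
    } else c(NA, NA, NA, NA)
    data.frame(aggregation = mode, n_patients = m$n_patients,
               A = pooled_counts[1], B = pooled_counts[2],
               C = pooled_counts[3], D = pooled_counts[4],
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv,
               n_undefined = sum(m$n_undefined), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_run_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, file)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "undefined")
  write_tsv(run$per_patient, "per_patient.tsv")
  write_tsv(cohort_table(run), "cohort.tsv")
  report <- list(
    settings = run$settings,
    per_patient = run$per_patient,
    cohort = cohort_table(run),
    clinical = if (is.null(run$clinical)) NULL
      else cohort_summary_as_list(run$clinical),
    errors = run$errors)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(out_dir)
}

#' @export
print.regionscore_run <- function(x, ...) {
  cat(sprintf("<regionscore_run> %d patients scored, universe of %d regions\n",
              nrow(x$per_patient), x$settings$universe_size))
  if (length(x$errors))
    cat(sprintf("  %d patient(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  print(x$cohort$pooled)
  print(x$cohort$mean)
  invisible(x)
}

#' Summarise a pipeline run
#'
#' @param object a `regionscore_run`.
#' @param ... unused.
#' @return The run's cohort table (both aggregations) with the per-patient
#'   table attached as attribute `"per_patient"`.
#' @export
summary.regionscore_run <- function(object, ...) {
  out <- cohort_table(object)
  attr(out, "per_patient") <- object$per_patient
  out
}

#' @export
as.data.frame.regionscore_run <- function(x, ...) x$per_patient

#' Plot per-patient diagnostics of a run
#'
#' Dot plot of per-patient sensitivity and specificity with the pooled
#' cohort values as horizontal lines. Undefined values are omitted.
#'
#' @param x a `regionscore_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.regionscore_run <- function(x, ...) {
  pp <- x$per_patient
  n <- nrow(pp)
  graphics::plot(seq_len(n), pp$sensitivity, ylim = c(0, 1), pch = 19,
                 col = "firebrick", xlab = "patient",
                 ylab = "proportion", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(n), labels = pp$patient_id, las = 2,
                 cex.axis = 0.7)
  graphics::points(seq_len(n), pp$specificity, pch = 17, col = "steelblue")
  graphics::abline(h = x$cohort$pooled$sensitivity, col = "firebrick", lty = 2)
  graphics::abline(h = x$cohort$pooled$specificity, col = "steelblue", lty = 2)
  graphics::legend("bottomleft", legend = c("sensitivity", "specificity"),
                   pch = c(19, 17), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(x)
}
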