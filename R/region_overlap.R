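#' Atlas regions covered by a lesion mask
#'
#' Projects a parcellation onto a binary mask and records, per region, the
#' number of overlapping voxels. A region counts as covered when its overlap
#' reaches `min_voxels` voxels (default 1: any affected voxel marks the
#' region, the least strict and most common reading) or, when `min_frac` is
#' given, the larger of `min_voxels` and `min_frac` times the region's total
#' voxel count. The universe is the full label table, so regions absent from
#' the volume are trivially uncovered but still counted in denominators.
#' Dual-membership voxels (see [merge_atlases()]) count toward both regions.
#'
#' @param mask a `binary_mask`.
#' @param lv a `label_volume` on the same grid.
#' @param min_voxels positive integer overlap threshold.
#' @param min_frac optional fraction in (0, 1] of each region's voxel count.
#' @return A `coverage_set`: list with `patient_id`, `role`, sorted integer
#'   vector `covered`, named vector `voxel_counts` (every region with >= 1
#'   overlapping voxel), and `universe_size`.
#' @export
coverage_set <- function(mask, lv, min_voxels = 1L, min_frac = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(lv, "label_volume"))
  if (!grids_compatible(mask$grid, lv$grid))
    stop_grid_mismatch(mask$grid, lv$grid, "mask vs label volume")
  min_voxels <- as.integer(min_voxels)
  if (is.na(min_voxels) || min_voxels < 1L)
    stop("min_voxels must be a positive integer")
  if (!is.null(min_frac) &&
      (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1))
    stop("min_frac must lie in (0, 1]")

  hit <- lv$labels[mask$voxels]
  if (!is.null(lv$secondary)) hit <- c(hit, lv$secondary[mask$voxels])
  hit <- hit[hit > 0L]
  counts <- table(hit)
  voxel_counts <- as.integer(counts)
  names(voxel_counts) <- names(counts)

  need <- rep(min_voxels, length(voxel_counts))
  if (!is.null(min_frac)) {
    sizes <- region_voxel_counts(lv)
    need <- pmax(need, ceiling(min_frac * sizes[names(voxel_counts)]))
  }
  covered <- sort(as.integer(names(voxel_counts)[voxel_counts >= need]))

  structure(list(patient_id = mask$patient_id, role = mask$role,
                 covered = covered, voxel_counts = voxel_counts,
                 universe_size = nrow(lv$label_table)),
            class = "coverage_set")
}

# Total voxels per region id (primary + secondary memberships), named vector.
region_voxel_counts <- function(lv) {
  lab <- as.vector(lv$labels)
  if (!is.null(lv$secondary)) lab <- c(lab, as.vector(lv$secondary))
  lab <- lab[lab > 0L]
  counts <- table(lab)
  out <- integer(nrow(lv$label_table))
  names(out) <- as.character(lv$label_table$region_id)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Construct a coverage set directly from region ids
#'
#' Useful for planned cohorts and tests where the covered sets, not the
#' voxel data, are the object of interest.
#'
#' @param covered integer vector of covered region ids.
#' @param universe_size total number of regions in the universe.
#' @inheritParams read_mask
#' @param voxel_counts optional named overlap counts.
#' @return A `coverage_set`.
#' @export
coverage_from_regions <- function(covered, universe_size,
                                  patient_id = "unknown",
                                  role = c("primary", "recurrence"),
                                  voxel_counts = NULL) {
  role <- match.arg(role)
  covered <- sort(unique(as.integer(covered)))
  if (length(covered) > universe_size)
    stop("more covered regions than the universe holds")
  if (is.null(voxel_counts)) {
    voxel_counts <- rep(1L, length(covered))
    names(voxel_counts) <- as.character(covered)
  }
  structure(list(patient_id = patient_id, role = role, covered = covered,
                 voxel_counts = voxel_counts,
                 universe_size = as.integer(universe_size)),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> patient %s, role %s: %d / %d regions covered\n",
              x$patient_id, x$role, length(x$covered), x$universe_size))
  invisible(x)
}

#' Region-level confusion counts for one patient
#'
#' Classifies every atlas region against the recurrence coverage taken as
#' ground truth: A (true positives) regions covered by both masks, B (false
#' positives) covered only by the primary mask, C (false negatives) covered
#' only by the recurrence mask, D (true negatives) covered by neither.
#' A + B + C + D always equals the universe size.
#'
#' @param primary,recurrence `coverage_set`s for the same patient and
#'   universe, with roles `"primary"` and `"recurrence"`.
#' @return A `confusion_counts` object with fields `A`, `B`, `C`, `D`,
#'   `universe_size`, `patient_id`.
#' @export
confusion_counts <- function(primary, recurrence) {
  stopifnot(inherits(primary, "coverage_set"),
            inherits(recurrence, "coverage_set"))
  if (!identical(primary$patient_id, recurrence$patient_id))
    stop(sprintf("coverage sets belong to different patients: '%s' vs '%s'",
                 primary$patient_id, recurrence$patient_id))
  if (primary$universe_size != recurrence$universe_size)
    stop(sprintf("coverage sets disagree on universe size: %d vs %d",
                 primary$universe_size, recurrence$universe_size))
  p <- primary$covered
  r <- recurrence$covered
  a <- length(intersect(p, r))
  b <- length(setdiff(p, r))
  c_ <- length(setdiff(r, p))
  d <- primary$universe_size - length(union(p, r))
  structure(list(A = a, B = b, C = c_, D = d,
                 universe_size = primary$universe_size,
                 patient_id = primary$patient_id),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> patient %s: A=%d B=%d C=%d D=%d (universe %d)\n",
              x$patient_id, x$A, x$B, x$C, x$D, x$universe_size))
  invisible(x)
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity = A/(A+C), specificity = D/(D+B), PPV = A/(A+B),
#' NPV = D/(D+C). A zero denominator makes that metric undefined (NA),
#' never 0 or 1: an empty recurrence coverage, for instance, leaves
#' sensitivity meaningless rather than perfect.
#'
#' @param counts a `confusion_counts` object.
#' @return A `diagnostic_metrics` object: `sensitivity`, `specificity`,
#'   `ppv`, `npv` (each in \[0, 1\] or NA), `n_patients`, `aggregation`.
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = safe_ratio(counts$A, counts$A + counts$C),
    specificity = safe_ratio(counts$D, counts$D + counts$B),
    ppv = safe_ratio(counts$A, counts$A + counts$B),
    npv = safe_ratio(counts$D, counts$D + counts$C),
    n_patients = 1L, aggregation = "single",
    n_undefined = c(sensitivity = 0L, specificity = 0L, ppv = 0L, npv = 0L),
    patient_id = counts$patient_id),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(round(v, digits))
  cat(sprintf(
    "<diagnostic_metrics> (%s, n=%d)\n  sensitivity %s  specificity %s  ppv %s  npv %s\n",
    x$aggregation, x$n_patients, fmt(x$sensitivity), fmt(x$specificity),
    fmt(x$ppv), fmt(x$npv)))
  if (any(x$n_undefined > 0L))
    cat(sprintf("  undefined per-patient values skipped: %s\n",
                paste(sprintf("%s=%d", names(x$n_undefined),
                              x$n_undefined)[x$n_undefined > 0L],
                      collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.diagnostic_metrics <- function(x, ...) {
  data.frame(aggregation = x$aggregation, n_patients = x$n_patients,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv,
             n_undefined = sum(x$n_undefined))
}

#' Aggregate diagnostics over a cohort
#'
#' Two aggregation rules are in common use and they are not equivalent:
#' `"pooled"` sums A, B, C, D over patients and applies the formulas once
#' to the pooled counts; `"mean"` averages the per-patient metrics,
#' skipping patients for whom a metric is undefined (the skip count is
#' reported). Both are computed by [run_pipeline()] and reported side by
#' side.
#'
#' @param counts_list list of `confusion_counts`, one per patient, all on
#'   the same universe.
#' @param mode `"pooled"` or `"mean"`.
#' @return A `diagnostic_metrics` object with `n_patients = length(counts_list)`.
#' @export
aggregate_metrics <- function(counts_list, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (!length(counts_list)) stop("cannot aggregate an empty cohort")
  if (!all(vapply(counts_list, inherits, TRUE, "confusion_counts")))
    stop("counts_list must contain confusion_counts objects")
  field <- function(f)
    vapply(counts_list, function(cc) as.numeric(cc[[f]]), numeric(1))
  universes <- field("universe_size")
  if (length(unique(universes)) != 1L)
    stop("cannot aggregate over differing region universes")

  if (mode == "pooled") {
    pooled <- structure(list(
      A = sum(field("A")), B = sum(field("B")),
      C = sum(field("C")), D = sum(field("D")),
      universe_size = universes[1], patient_id = "pooled"),
      class = "confusion_counts")
    out <- diagnostic_metrics(pooled)
    out$n_patients <- length(counts_list)
    out$aggregation <- "pooled"
    out$patient_id <- NULL
    return(out)
  }

  per <- lapply(counts_list, diagnostic_metrics)
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  vals <- lapply(metrics, function(m) vapply(per, `[[`, 1, m))
  names(vals) <- metrics
  mean_defined <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  skipped <- vapply(vals, function(v) sum(is.na(v)), 1L)
  structure(c(lapply(vals, mean_defined),
              list(n_patients = length(counts_list), aggregation = "mean",
                   n_undefined = skipped)),
            class = "diagnostic_metrics")
}

#' Voxel-wise overlap diagnostics (Dice / Jaccard)
#'
#' Optional voxel-level agreement between two masks on the same grid;
#' provided as a side diagnostic, not as the headline region-level output.
#'
#' @param a,b `binary_mask`s on the same grid.
#' @return Named list with `dice`, `jaccard`, `n_a`, `n_b`, `n_intersection`.
#' @export
voxel_overlap <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!grids_compatible(a$grid, b$grid))
    stop_grid_mismatch(a$grid, b$grid, "voxel_overlap")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  ni <- sum(a$voxels & b$voxels)
  list(dice = if (na + nb == 0) NA_real_ else 2 * ni / (na + nb),
       jaccard = if (na + nb - ni == 0) NA_real_ else ni / (na + nb - ni),
       n_a = na, n_b = nb, n_intersection = ni)
}
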