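#' Read a binary lesion mask from a NIfTI file
#'
#' Loads a NIfTI volume of any numeric dtype and binarises it at `threshold`,
#' recording the grid geometry from the header. Masks are conceptually binary
#' (a lesion either includes a voxel or it does not); the threshold only
#' matters for masks that were resampled with interpolation upstream.
#'
#' @param path path to a `.nii`/`.nii.gz` volume.
#' @param role `"primary"` (preoperative lesion) or `"recurrence"`
#'   (follow-up recurrence).
#' @param patient_id identifier attached to the mask.
#' @param threshold binarisation threshold in (0, 1); voxels strictly above
#'   it are members. Default 0.5.
#' @return A `binary_mask`: list with `grid` ([voxel_grid]), logical array
#'   `voxels`, `role`, `patient_id`, and flag `empty` (TRUE when no voxel is
#'   a member, also signalled as a warning).
#' @export
read_mask <- function(path, role = c("primary", "recurrence"),
                      patient_id = "unknown", threshold = 0.5) {
  role <- match.arg(role)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  img <- read_nifti_checked(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("mask '%s' is %dD; expected a 3D volume",
                 path, length(dim(img))))
  grid <- grid_from_nifti(img)
  vox <- array(as.vector(img) > threshold, dim = grid$shape)
  binary_mask(vox, grid, role = role, patient_id = patient_id)
}

#' Construct a binary mask from an in-memory array
#'
#' @param voxels 3D logical (or coercible) array.
#' @param grid a [voxel_grid] matching `dim(voxels)`.
#' @inheritParams read_mask
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(voxels, grid, role = c("primary", "recurrence"),
                        patient_id = "unknown") {
  role <- match.arg(role)
  if (!is_voxel_grid(grid)) stop("grid must be a voxel_grid")
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (!identical(dim(voxels), grid$shape))
    stop("mask array shape does not match the grid shape")
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  empty <- !any(voxels)
  if (empty)
    warning(sprintf("mask '%s' (%s) has no member voxels (empty mask)",
                    patient_id, role), call. = FALSE)
  structure(list(grid = grid, voxels = voxels, role = role,
                 patient_id = patient_id, empty = empty),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> patient %s, role %s, %d member voxels, grid %s%s\n",
              x$patient_id, x$role, sum(x$voxels), format(x$grid),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Write a binary mask to NIfTI
#'
#' The inverse of [read_mask()]: membership is stored as 0/1 and the grid
#' affine goes into the sform. Round-tripping preserves the exact voxel set
#' and the affine.
#'
#' @param mask a `binary_mask`.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_volume_nifti(array(as.integer(mask$voxels), dim = mask$grid$shape),
                     mask$grid, path, datatype = "uint8")
  invisible(path)
}

#' Read an integer-label parcellation and its label table
#'
#' A parcellation assigns every voxel a non-negative integer region id
#' (0 = background). The label table gives each id a name, its atlas of
#' origin and hemisphere. Every nonzero id occurring in the volume must be
#' defined in the table; table entries absent from the volume are retained —
#' the region universe is the table, not the data.
#'
#' @param path NIfTI volume of non-negative integers.
#' @param table_path delimited text (TSV/CSV) with columns `region_id`,
#'   `name`, `atlas_source`, `hemisphere`.
#' @return A `label_volume`: list with `grid`, integer array `labels`,
#'   `secondary` (NULL, or a second label array after [merge_atlases()]),
#'   data.frame `label_table`, and `offset` metadata.
#' @export
read_label_volume <- function(path, table_path) {
  img <- read_nifti_checked(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("label volume '%s' is %dD; expected a 3D volume",
                 path, length(dim(img))))
  vals <- as.vector(img)
  if (any(vals != round(vals)) || any(vals < 0))
    stop(sprintf("label volume '%s' contains non-integer or negative voxel values",
                 path))
  grid <- grid_from_nifti(img)
  tab <- read_label_table(table_path)
  label_volume(array(as.integer(vals), dim = grid$shape), grid, tab)
}

read_label_table <- function(table_path) {
  tab <- read_delimited(table_path)
  required <- c("region_id", "name", "atlas_source", "hemisphere")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("label table '%s' lacks required column(s): %s",
                 table_path, paste(missing_cols, collapse = ", ")))
  tab$region_id <- as.integer(tab$region_id)
  ok_hemi <- c("left", "right", "midline", "n/a")
  bad <- setdiff(unique(tab$hemisphere), ok_hemi)
  if (length(bad))
    stop(sprintf("label table '%s': unrecognised hemisphere value(s): %s",
                 table_path, paste(bad, collapse = ", ")))
  tab[required]
}

#' @rdname read_label_volume
#' @param labels 3D integer array of region ids.
#' @param grid a [voxel_grid].
#' @param label_table data.frame as for `table_path`.
#' @param secondary optional second label array (dual membership).
#' @param offset integer id offset applied to the second atlas on merge.
#' @export
label_volume <- function(labels, grid, label_table, secondary = NULL,
                         offset = 0L) {
  if (!is_voxel_grid(grid)) stop("grid must be a voxel_grid")
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!identical(dim(labels), grid$shape))
    stop("label array shape does not match the grid shape")
  if (anyDuplicated(label_table$region_id))
    stop("label table region_ids must be unique")
  if (any(label_table$region_id <= 0L))
    stop("label table region_ids must be positive (0 is background)")
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!is.null(secondary))
    present <- union(present, setdiff(unique(as.vector(secondary)), 0L))
  orphans <- setdiff(present, label_table$region_id)
  if (length(orphans))
    stop(sprintf("label(s) present in volume but absent from table: %s",
                 paste(sort(orphans), collapse = ", ")))
  structure(list(grid = grid, labels = labels, secondary = secondary,
                 label_table = label_table, offset = as.integer(offset)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d regions (%s), grid %s%s\n",
              nrow(x$label_table),
              paste(sprintf("%s: %d", names(table(x$label_table$atlas_source)),
                            as.integer(table(x$label_table$atlas_source))),
                    collapse = ", "),
              format(x$grid),
              if (is.null(x$secondary)) "" else " [dual-membership sidecar]"))
  invisible(x)
}

#' Write a label volume and its table
#'
#' @param lv a `label_volume` (must not carry a dual-membership sidecar).
#' @param path output `.nii` path.
#' @param table_path output TSV path for the label table.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path, table_path = NULL) {
  stopifnot(inherits(lv, "label_volume"))
  if (!is.null(lv$secondary))
    stop("cannot serialise a merged label volume with dual memberships to a single NIfTI")
  write_volume_nifti(lv$labels, lv$grid, path, datatype = "int32")
  if (!is.null(table_path))
    utils::write.table(lv$label_table, table_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge a cortical and a subcortical parcellation into one region universe
#'
#' Both atlases live on the same template grid and together define the
#' region universe against which masks are scored. Region ids are made
#' globally unique: if the two tables collide, every subcortical id is
#' offset by the maximum cortical id (the offset is recorded in the result).
#' Where both atlases label the same voxel, the voxel keeps both memberships
#' through a sidecar secondary-label array, so neither atlas loses voxels.
#'
#' @param cortical,subcortical `label_volume` objects on the same grid
#'   (affines equal within 1e-4 mm).
#' @return A merged `label_volume` whose `label_table` is the disjoint union;
#'   `offset` gives the id shift applied to the subcortical atlas.
#' @export
merge_atlases <- function(cortical, subcortical) {
  stopifnot(inherits(cortical, "label_volume"),
            inherits(subcortical, "label_volume"))
  if (!grids_compatible(cortical$grid, subcortical$grid))
    stop_grid_mismatch(cortical$grid, subcortical$grid, "merge_atlases")
  if (!is.null(cortical$secondary) || !is.null(subcortical$secondary))
    stop("merge_atlases expects unmerged single-membership inputs")

  offset <- 0L
  sub_tab <- subcortical$label_table
  sub_lab <- subcortical$labels
  if (length(intersect(cortical$label_table$region_id, sub_tab$region_id))) {
    offset <- max(cortical$label_table$region_id)
    sub_tab$region_id <- sub_tab$region_id + offset
    sub_lab <- sub_lab + (sub_lab > 0L) * offset
  }
  tab <- rbind(cortical$label_table, sub_tab)

  merged <- cortical$labels
  secondary <- array(0L, dim = cortical$grid$shape)
  only_sub <- merged == 0L & sub_lab > 0L
  both <- merged > 0L & sub_lab > 0L
  merged[only_sub] <- sub_lab[only_sub]
  secondary[both] <- sub_lab[both]
  if (!any(secondary > 0L)) secondary <- NULL

  label_volume(merged, cortical$grid, tab, secondary = secondary,
               offset = offset)
}

#' Read a 4x4 affine transform from a plain-text file
#'
#' Accepts whitespace-delimited 4x4 matrices, including FLIRT `.mat` files
#' (use `convention = "fsl_scaled_mm"` for those; see [to_world_convention()]).
#'
#' @param path text file holding 4 rows of 4 numbers.
#' @param source,target the grids the transform maps between.
#' @param convention matrix dialect, `"world_mm"` or `"fsl_scaled_mm"`.
#' @return An [affine_transform].
#' @export
read_transform <- function(path, source, target,
                           convention = c("world_mm", "fsl_scaled_mm")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop(sprintf("cannot read transform file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4L)
    stop(sprintf("malformed transform '%s': expected 4 rows, found %d",
                 path, length(lines)))
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 4L || anyNA(v))
      stop(sprintf("malformed transform '%s' at line %d: expected 4 numbers",
                   path, i))
    v
  })
  affine_transform(do.call(rbind, rows), source, target, convention)
}

#' Read a clinical table
#'
#' Parses a delimited (TSV/CSV) clinical table with one row per patient:
#' identifier, age, sex, histology, localization, side, dates of diagnosis /
#' recurrence / last follow-up or death (year-month), and progression-free
#' and overall survival in months. Dates finer than year-month are not
#' modelled. A row with PFS > OS draws a warning but is kept; missing PFS/OS
#' become NA and are excluded pairwise from downstream medians.
#'
#' @param path TSV or CSV file with columns `patient`, `age`, `sex`,
#'   `histology`, `localization`, `side`, `dx_date`, `recurrence_date`,
#'   `last_date`, `pfs`, `os`.
#' @return A data.frame of class `clinical_cohort`.
#' @export
read_clinical_table <- function(path) {
  tab <- read_delimited(path)
  required <- c("patient", "age", "sex", "histology", "localization", "side",
                "dx_date", "recurrence_date", "last_date", "pfs", "os")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("clinical table '%s' lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0L) {
    warning(sprintf("clinical table '%s' has a header but no rows", path),
            call. = FALSE)
    tab <- tab[required]
    class(tab) <- c("clinical_cohort", "data.frame")
    return(tab)
  }
  tab <- tab[required]
  tab$patient <- as.character(tab$patient)
  if (anyDuplicated(tab$patient))
    stop(sprintf("clinical table '%s': duplicate patient id(s): %s", path,
                 paste(unique(tab$patient[duplicated(tab$patient)]),
                       collapse = ", ")))
  tab$age <- as.numeric(tab$age)
  sex <- tolower(trimws(as.character(tab$sex)))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  bad_sex <- which(!sex %in% c("male", "female"))
  if (length(bad_sex))
    stop(sprintf("clinical table '%s': unrecognised sex value in row(s) %s",
                 path, paste(bad_sex, collapse = ", ")))
  tab$sex <- sex
  for (col in c("dx_date", "recurrence_date", "last_date"))
    tab[[col]] <- parse_year_month(tab[[col]], path, col)
  tab$pfs <- parse_month_count(tab$pfs, path, "pfs")
  tab$os <- parse_month_count(tab$os, path, "os")
  bad <- which(!is.na(tab$pfs) & !is.na(tab$os) & tab$pfs > tab$os)
  for (i in bad)
    warning(sprintf("clinical table '%s': patient %s has PFS (%d) > OS (%d)",
                    path, tab$patient[i], tab$pfs[i], tab$os[i]),
            call. = FALSE)
  class(tab) <- c("clinical_cohort", "data.frame")
  tab
}

# "YYYY.MM" or "YYYY-MM" -> months since year 0 (integer); NA allowed.
parse_year_month <- function(x, path, col) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  has <- !is.na(x) & nzchar(x)
  m <- regmatches(x[has], regexec("^([0-9]{4})[.-]([0-9]{1,2})$", x[has]))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop(sprintf("clinical table '%s': column %s: cannot parse year-month '%s'",
                 path, col, x[has][bad][1]))
  year <- vapply(m, function(g) as.integer(g[2]), 1L)
  month <- vapply(m, function(g) as.integer(g[3]), 1L)
  if (any(month < 1L | month > 12L))
    stop(sprintf("clinical table '%s': column %s: month out of range", path, col))
  out[has] <- year * 12L + (month - 1L)
  out
}

format_year_month <- function(m) {
  ifelse(is.na(m), NA_character_,
         sprintf("%04d.%02d", m %/% 12L, m %% 12L + 1L))
}

parse_month_count <- function(x, path, col) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  has <- !is.na(x) & nzchar(x) & x != "NA"
  v <- suppressWarnings(as.numeric(x[has]))
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop(sprintf("clinical table '%s': column %s must hold non-negative integer months",
                 path, col))
  out[has] <- as.integer(v)
  out
}

# ---- shared low-level I/O helpers ----

read_nifti_checked <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("cannot read NIfTI file '%s': no such file", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  img
}

grid_from_nifti <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  voxel_grid(dim(img), matrix(as.numeric(aff), 4, 4))
}

write_volume_nifti <- function(arr, grid, path, datatype = "auto") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  # sform only: the qform quaternion form cannot represent every affine
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read table '%s': no such file", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"",
                    colClasses = "character")
}
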