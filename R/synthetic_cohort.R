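#' Configuration for a synthetic validation cohort
#'
#' Defines a fully seeded synthetic stand-in for a tumor-recurrence imaging
#' study: a template grid holding an ellipsoidal "brain", a two-atlas
#' parcellation of it (cortical shell + subcortical core, Voronoi regions),
#' and per-patient primary/recurrence mask pairs whose region-coverage
#' relationship is controlled by a regime:
#' \describe{
#'   \item{concordant}{recurrence is the primary blob displaced and scaled —
#'     coverage largely agrees.}
#'   \item{flair_overreach}{the primary (FLAIR-like) mask is much larger
#'     than the recurrence, so recurrence coverage is nearly contained in
#'     primary coverage: high sensitivity, low specificity.}
#'   \item{flair_underreach}{the reverse: a small primary mask inside a
#'     large recurrence — low sensitivity, high(er) specificity.}
#' }
#' Identical configurations generate bit-identical cohorts.
#'
#' @param seed integer master seed; patient substreams use `seed + index`.
#' @param grid_shape 3 voxel extents (default 64^3 at 1 mm isotropic).
#' @param n_cortical,n_subcortical region counts for the two atlases.
#' @param n_patients cohort size (default 16).
#' @param tumor_radius_range min/max primary sphere radius in mm.
#' @param recurrence_displacement expected recurrence-centroid shift in mm.
#' @param recurrence_scale recurrence/primary volume ratio (concordant regime).
#' @param regimes regimes cycled over the cohort, in order.
#' @param emit_transforms also write identity FLIRT-style `.mat` files.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L, grid_shape = c(64L, 64L, 64L),
                          n_cortical = 42L, n_subcortical = 28L,
                          n_patients = 16L,
                          tumor_radius_range = c(8, 14),
                          recurrence_displacement = 6,
                          recurrence_scale = 1,
                          regimes = c("concordant", "flair_overreach",
                                      "flair_underreach"),
                          emit_transforms = FALSE) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  cfg <- list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
              n_cortical = as.integer(n_cortical),
              n_subcortical = as.integer(n_subcortical),
              n_patients = as.integer(n_patients),
              tumor_radius_range = as.numeric(tumor_radius_range),
              recurrence_displacement = as.numeric(recurrence_displacement),
              recurrence_scale = as.numeric(recurrence_scale),
              regimes = regimes,
              emit_transforms = isTRUE(emit_transforms))
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape > 0L),
            cfg$n_cortical > 0L, cfg$n_subcortical > 0L, cfg$n_patients > 0L,
            length(cfg$tumor_radius_range) == 2L,
            all(cfg$tumor_radius_range > 0),
            diff(cfg$tumor_radius_range) >= 0,
            cfg$recurrence_displacement >= 0, cfg$recurrence_scale > 0,
            length(cfg$regimes) >= 1L)
  class(cfg) <- "cohort_config"
  cfg
}

cohort_regime <- function(cfg, i) cfg$regimes[(i - 1L) %% length(cfg$regimes) + 1L]

# Normalised ellipsoid radius of every voxel; <= 1 is "brain".
brain_rho <- function(grid) {
  shape <- grid$shape
  centre <- (shape - 1) / 2
  semi <- 0.44 * (shape - 1)
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  sqrt(((idx[, 1] - centre[1]) / semi[1])^2 +
         ((idx[, 2] - centre[2]) / semi[2])^2 +
         ((idx[, 3] - centre[3]) / semi[3])^2)
}

#' Generate the synthetic two-atlas parcellation
#'
#' Builds an ellipsoidal brain inside the configured grid and partitions it
#' into a cortical shell and a subcortical core, each split into Voronoi
#' regions around seed voxels drawn from that compartment. Every requested
#' region is nonempty (each owns at least its own seed voxel). Region ids
#' are 1..n_cortical for the shell and n_cortical+1 .. n_cortical+n_subcortical
#' for the core, i.e. the merged namespace [merge_atlases()] produces from
#' the two emitted atlas files.
#'
#' @param cfg a [cohort_config].
#' @return A `label_volume` spanning both atlas sources (`offset` set to
#'   `n_cortical`).
#' @export
make_parcellation <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  grid <- voxel_grid(cfg$grid_shape, diag(4))
  rho <- brain_rho(grid)
  shell <- which(rho <= 1 & rho > 0.62)
  core <- which(rho <= 0.62)
  if (length(shell) < cfg$n_cortical || length(core) < cfg$n_subcortical)
    stop(sprintf(
      "grid too small: %d shell / %d core voxels for %d cortical / %d subcortical regions",
      length(shell), length(core), cfg$n_cortical, cfg$n_subcortical))

  set.seed(cfg$seed)
  shape <- grid$shape
  coords_of <- function(lin) {
    lin0 <- lin - 1L
    cbind(lin0 %% shape[1],
          (lin0 %/% shape[1]) %% shape[2],
          lin0 %/% (shape[1] * shape[2]))
  }
  voronoi <- function(members, n_regions) {
    seeds <- sort(sample(members, n_regions))
    sc <- coords_of(seeds)
    mc <- coords_of(members)
    # nearest seed per member voxel; ties go to the lower region id
    best <- rep(1L, length(members))
    bestd <- colSums((t(mc) - sc[1, ])^2)
    if (n_regions > 1L) for (s in 2:n_regions) {
      d <- colSums((t(mc) - sc[s, ])^2)
      take <- d < bestd
      best[take] <- s
      bestd[take] <- d[take]
    }
    list(assignment = best, seeds = seeds)
  }

  labels <- integer(prod(shape))
  vc <- voronoi(shell, cfg$n_cortical)
  labels[shell] <- vc$assignment
  vs <- voronoi(core, cfg$n_subcortical)
  labels[core] <- vs$assignment + cfg$n_cortical

  hemi_of <- function(seeds) {
    x <- coords_of(seeds)[, 1]
    cx <- (shape[1] - 1) / 2
    ifelse(abs(x - cx) < 1, "midline", ifelse(x < cx, "left", "right"))
  }
  tab <- data.frame(
    region_id = seq_len(cfg$n_cortical + cfg$n_subcortical),
    name = c(sprintf("cortical_%02d", seq_len(cfg$n_cortical)),
             sprintf("subcortical_%02d", seq_len(cfg$n_subcortical))),
    atlas_source = rep(c("cortical", "subcortical"),
                       c(cfg$n_cortical, cfg$n_subcortical)),
    hemisphere = c(hemi_of(vc$seeds), hemi_of(vs$seeds)),
    stringsAsFactors = FALSE)

  label_volume(array(labels, dim = shape), grid, tab, offset = cfg$n_cortical)
}

# Split the generator's merged parcellation back into the two emitted
# atlases, with the subcortical namespace restarted at 1 (so that reading
# the files and merging reproduces the merged ids via the offset rule).
split_parcellation <- function(parc, cfg) {
  nc <- cfg$n_cortical
  cort_lab <- parc$labels * (parc$labels <= nc)
  sub_lab <- (parc$labels - nc) * (parc$labels > nc)
  cort_tab <- parc$label_table[parc$label_table$atlas_source == "cortical", ]
  sub_tab <- parc$label_table[parc$label_table$atlas_source == "subcortical", ]
  sub_tab$region_id <- sub_tab$region_id - nc
  list(cortical = label_volume(cort_lab, parc$grid, cort_tab),
       subcortical = label_volume(sub_lab, parc$grid, sub_tab))
}

# Membership array for a union of spheres; centres in world mm (n x 3).
sphere_union <- function(grid, centres, radii) {
  shape <- grid$shape
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  world <- t(grid$affine[1:3, 1:3] %*% t(idx) + grid$affine[1:3, 4])
  member <- rep(FALSE, nrow(world))
  for (s in seq_len(nrow(centres))) {
    d2 <- (world[, 1] - centres[s, 1])^2 + (world[, 2] - centres[s, 2])^2 +
      (world[, 3] - centres[s, 3])^2
    member <- member | d2 <= radii[s]^2
  }
  array(member, dim = shape)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate one synthetic patient's mask pair with ground truth
#'
#' Samples a primary blob (union of 1-3 spheres centred well inside the
#' brain), derives the recurrence blob per the regime, and measures the
#' ground-truth coverage sets and confusion counts by exact voxel counting
#' against the parcellation (min_voxels = 1). A blob that misses the brain
#' entirely is resampled up to 10 times.
#'
#' @param cfg a [cohort_config].
#' @param regime one of the three coverage regimes.
#' @param patient_seed integer seed for this patient's substream.
#' @param parc the cohort parcellation from [make_parcellation()].
#' @param patient_id identifier for the emitted masks.
#' @return List with `primary`, `recurrence` (binary_mask) and
#'   `ground_truth` (list: regime, covered sets, `confusion_counts`).
#' @export
make_patient <- function(cfg, regime, patient_seed, parc,
                         patient_id = "patient") {
  stopifnot(inherits(cfg, "cohort_config"), inherits(parc, "label_volume"))
  regime <- match.arg(regime, c("concordant", "flair_overreach",
                                "flair_underreach"))
  grid <- parc$grid
  brain <- parc$labels > 0L
  set.seed(patient_seed)

  shape <- grid$shape
  centre_world <- as.numeric(grid$affine %*% c((shape - 1) / 2, 1))[1:3]
  semi_mm <- 0.44 * (shape - 1) * grid$voxel_size

  for (attempt in 1:10) {
    n_sph <- sample(1:3, 1)
    radii <- stats::runif(n_sph, cfg$tumor_radius_range[1],
                          cfg$tumor_radius_range[2])
    # first centre at rho < 0.55 so blobs sit inside the brain
    repeat {
      u <- stats::runif(3, -0.55, 0.55)
      if (sum((u)^2) <= 0.55^2) break
    }
    c1 <- centre_world + u * semi_mm
    centres <- matrix(c1, nrow = 1)
    if (n_sph > 1L) for (s in 2:n_sph)
      centres <- rbind(centres, c1 + random_unit_vector() *
                         stats::runif(1, 0, 0.6 * radii[1]))

    disp <- random_unit_vector() * cfg$recurrence_displacement
    if (regime == "concordant") {
      p_centres <- centres; p_radii <- radii
      r_centres <- sweep(centres, 2, disp, `+`)
      r_radii <- radii * cfg$recurrence_scale^(1 / 3)
    } else if (regime == "flair_overreach") {
      p_centres <- centres; p_radii <- radii * 1.4
      r_centres <- matrix(centres[1, ] + 0.3 * disp, nrow = 1)
      r_radii <- radii[1] * 0.55
    } else {
      p_centres <- matrix(centres[1, ], nrow = 1)
      p_radii <- radii[1] * 0.55
      r_centres <- sweep(centres, 2, disp, `+`)
      r_radii <- radii * 1.4
    }

    p_vox <- sphere_union(grid, p_centres, p_radii)
    r_vox <- sphere_union(grid, r_centres, r_radii)
    if (any(p_vox & brain) && any(r_vox & brain)) {
      primary <- binary_mask(p_vox, grid, role = "primary",
                             patient_id = patient_id)
      recurrence <- binary_mask(r_vox, grid, role = "recurrence",
                                patient_id = patient_id)
      p_cov <- coverage_set(primary, parc, min_voxels = 1L)
      r_cov <- coverage_set(recurrence, parc, min_voxels = 1L)
      gt <- list(regime = regime,
                 primary_covered = p_cov$covered,
                 recurrence_covered = r_cov$covered,
                 counts = confusion_counts(p_cov, r_cov))
      return(list(primary = primary, recurrence = recurrence,
                  ground_truth = gt))
    }
  }
  stop(sprintf("patient %s: blob fell outside the brain in 10 attempts",
               patient_id))
}

#' Generate a synthetic clinical table
#'
#' Emits one row per patient with the same schema [read_clinical_table()]
#' expects. Ages are uniform on 20-80 years, sex is Bernoulli with 30%
#' female (loosely matching a typical high-grade-glioma cohort), histology
#' is predominantly glioblastoma, and PFS <= OS holds by construction with
#' recurrence/last-follow-up dates derived from the intervals.
#'
#' @param cfg a [cohort_config].
#' @return A data.frame ready to be written as TSV.
#' @export
make_clinical_table <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed + 7919L)
  n <- cfg$n_patients
  dx <- 2010L * 12L + sample(0L:(11L * 12L), n, replace = TRUE)
  pfs <- sample(1:40, n, replace = TRUE)
  os <- pfs + sample(0:30, n, replace = TRUE)
  data.frame(
    patient = sprintf("p%02d", seq_len(n)),
    age = sample(20:80, n, replace = TRUE),
    sex = ifelse(stats::runif(n) < 0.3, "female", "male"),
    histology = sample(c("glioblastoma", "oligodendroglioma_g3"), n,
                       replace = TRUE, prob = c(0.8, 0.2)),
    localization = sample(c("frontal", "temporal", "parietal", "occipital",
                            "fronto-parietal"), n, replace = TRUE),
    side = sample(c("left", "right"), n, replace = TRUE),
    dx_date = format_year_month(dx),
    recurrence_date = format_year_month(dx + pfs),
    last_date = format_year_month(dx + os),
    pfs = pfs, os = os,
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic cohort to disk
#'
#' Emits everything [run_pipeline()] consumes — two atlas volumes with label
#' tables, per-patient primary/recurrence masks (uncompressed NIfTI),
#' optional identity transform files, the clinical table — plus the
#' ground-truth coverage JSON and a manifest listing every file with its
#' MD5 checksum. Regimes are cycled over patients in configuration order.
#'
#' @param cfg a [cohort_config].
#' @param out_dir output directory (created if absent).
#' @return The manifest, invisibly (list with `files`, `patients`, `config`);
#'   also written as `manifest.json`.
#' @export
write_cohort <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir))

  parc <- make_parcellation(cfg)
  halves <- split_parcellation(parc, cfg)
  files <- c(cortical = "cortical.nii",
             cortical_table = "cortical_labels.tsv",
             subcortical = "subcortical.nii",
             subcortical_table = "subcortical_labels.tsv",
             clinical = "clinical.tsv",
             ground_truth = "ground_truth.json")
  write_label_volume(halves$cortical, file.path(out_dir, files["cortical"]),
                     file.path(out_dir, files["cortical_table"]))
  write_label_volume(halves$subcortical,
                     file.path(out_dir, files["subcortical"]),
                     file.path(out_dir, files["subcortical_table"]))

  patients <- data.frame(patient_id = character(0), regime = character(0),
                         primary = character(0), recurrence = character(0),
                         transform = character(0), stringsAsFactors = FALSE)
  gt <- list()
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("p%02d", i)
    regime <- cohort_regime(cfg, i)
    pat <- make_patient(cfg, regime, cfg$seed + i, parc, patient_id = pid)
    p_file <- sprintf("%s_primary.nii", pid)
    r_file <- sprintf("%s_recurrence.nii", pid)
    write_mask(pat$primary, file.path(out_dir, p_file))
    write_mask(pat$recurrence, file.path(out_dir, r_file))
    t_file <- NA_character_
    if (cfg$emit_transforms) {
      t_file <- sprintf("%s.mat", pid)
      writeLines(apply(diag(4), 1, paste, collapse = "  "),
                 file.path(out_dir, t_file))
    }
    patients <- rbind(patients, data.frame(
      patient_id = pid, regime = regime, primary = p_file,
      recurrence = r_file, transform = t_file, stringsAsFactors = FALSE))
    cc <- pat$ground_truth$counts
    gt[[pid]] <- list(regime = regime,
                      primary_covered = pat$ground_truth$primary_covered,
                      recurrence_covered = pat$ground_truth$recurrence_covered,
                      A = cc$A, B = cc$B, C = cc$C, D = cc$D,
                      universe_size = cc$universe_size)
  }

  utils::write.table(make_clinical_table(cfg),
                     file.path(out_dir, files["clinical"]),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(gt, file.path(out_dir, files["ground_truth"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  all_files <- c(unname(files), patients$primary, patients$recurrence,
                 patients$transform[!is.na(patients$transform)])
  sums <- as.character(tools::md5sum(file.path(out_dir, all_files)))
  manifest <- list(
    config = unclass(cfg),
    files = data.frame(file = all_files, md5 = sums,
                       stringsAsFactors = FALSE),
    atlases = list(
      cortical = list(volume = unname(files["cortical"]),
                      table = unname(files["cortical_table"])),
      subcortical = list(volume = unname(files["subcortical"]),
                         table = unname(files["subcortical_table"]))),
    clinical_table = unname(files["clinical"]),
    ground_truth = unname(files["ground_truth"]),
    patients = patients)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(manifest)
}

#' Read ground-truth coverage emitted by [write_cohort()]
#'
#' @param path `ground_truth.json` file.
#' @return Named list per patient with covered sets and A/B/C/D counts.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, function(g) {
    g$primary_covered <- as.integer(unlist(g$primary_covered))
    g$recurrence_covered <- as.integer(unlist(g$recurrence_covered))
    g
  })
}
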