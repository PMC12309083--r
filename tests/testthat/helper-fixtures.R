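# Shared fixtures and independent oracles, all built in code.

tiny_grid <- function(shape = c(6, 6, 6), affine = diag(4)) {
  voxel_grid(shape, affine)
}

# Write a raw array as NIfTI with a given affine, bypassing package writers
# so that read/write tests stay independent of them.
write_raw_nifti <- function(arr, affine = diag(4), path = tempfile(fileext = ".nii")) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  path
}

write_label_table <- function(region_ids,
                              atlas_source = "cortical",
                              hemisphere = "left",
                              path = tempfile(fileext = ".tsv")) {
  df <- data.frame(region_id = region_ids,
                   name = sprintf("region_%d", region_ids),
                   atlas_source = atlas_source,
                   hemisphere = hemisphere)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# A 10x10x10 parcellation with two box-shaped regions (ids 2 and 5) plus a
# configurable table universe; used by coverage tests.
box_label_volume <- function(universe_ids = c(2L, 5L)) {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[1:3, 1:3, 1] <- 2L      # 9 voxels
  lab[5:8, 5:8, 2:3] <- 5L    # 32 voxels
  tab <- data.frame(region_id = universe_ids,
                    name = sprintf("r%d", universe_ids),
                    atlas_source = "cortical", hemisphere = "left")
  label_volume(lab, tiny_grid(c(10, 10, 10)), tab)
}

# Independent per-region classifier: loops over every region of the universe
# and classifies it on its own.
oracle_confusion <- function(p_set, r_set, universe_size) {
  a <- b <- c_ <- d <- 0L
  for (g in seq_len(universe_size)) {
    in_p <- g %in% p_set
    in_r <- g %in% r_set
    if (in_p && in_r) a <- a + 1L
    else if (in_p) b <- b + 1L
    else if (in_r) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(A = a, B = b, C = c_, D = d)
}

# Independent triple-loop nearest-neighbour resampler over target voxels.
oracle_resample_nn <- function(src, src_affine, world, tgt_shape, tgt_affine) {
  out <- array(0, dim = tgt_shape)
  pull <- solve(src_affine) %*% solve(world) %*% tgt_affine
  for (i in 0:(tgt_shape[1] - 1))
    for (j in 0:(tgt_shape[2] - 1))
      for (k in 0:(tgt_shape[3] - 1)) {
        p <- pull %*% c(i, j, k, 1)
        ijk <- ceiling(p[1:3] - 0.5)
        if (all(ijk >= 0) && all(ijk < dim(src)))
          out[i + 1, j + 1, k + 1] <- src[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
      }
  out
}

# Random region subset of a universe.
random_set <- function(universe_size) {
  n <- sample(0:universe_size, 1)
  sort(sample(seq_len(universe_size), n))
}

# Months-since-year-0 back to the "YYYY.MM" text form used in tables.
format_ym <- function(m) sprintf("%04d.%02d", m %/% 12L, m %% 12L + 1L)

bundled_clinical <- function() {
  read_clinical_table(system.file("extdata", "table1_clinical.tsv",
                                  package = "regionscore"))
}

small_cohort_config <- function(seed = 11, n_patients = 4,
                                recurrence_displacement = 3, ...) {
  cohort_config(seed = seed, grid_shape = c(32, 32, 32), n_cortical = 10,
                n_subcortical = 6, n_patients = n_patients,
                tumor_radius_range = c(4, 7),
                recurrence_displacement = recurrence_displacement, ...)
}
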