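test_that("read_mask binarises at the threshold and keeps the header grid", {
  # already-binary data: identity
  arr <- array(0L, dim = c(4, 4, 4)); arr[2:3, 2, 2] <- 1L
  path <- write_raw_nifti(arr)
  m <- read_mask(path, "primary", "p1")
  expect_identical(m$voxels, array(arr == 1L, dim = dim(arr)))
  expect_equal(m$grid$shape, c(4L, 4L, 4L))
  expect_false(m$empty)

  # float values {0, 0.3, 0.9} against threshold 0.5: only 0.9 survives
  arr <- array(0, dim = c(3, 3, 3))
  arr[1, 1, 1] <- 0.3; arr[2, 2, 2] <- 0.9; arr[3, 3, 3] <- 0.3
  m <- read_mask(write_raw_nifti(arr), "primary", "p1", threshold = 0.5)
  expect_identical(which(m$voxels), which(arr == 0.9))

  # all-zero volume: accepted, flagged, warned
  expect_warning(
    m0 <- read_mask(write_raw_nifti(array(0, dim = c(3, 3, 3))), "recurrence", "p2"),
    "empty mask")
  expect_true(m0$empty)
  expect_identical(sum(m0$voxels), 0L)
})

test_that("read_mask rejects missing files and non-3D input", {
  expect_error(read_mask(tempfile(fileext = ".nii"), "primary"), "no such file")
  path4d <- write_raw_nifti(array(1, dim = c(3, 3, 3, 2)))
  expect_error(read_mask(path4d, "primary"), "4D")
})

test_that("mask write/read round-trips voxel membership and affine", {
  affine <- matrix(c(-1, 0, 0, 0,
                     0, 1, 0, 0,
                     0, 0, 1.5, 0,
                     20, -7, 3.5, 1), 4, 4)
  grid <- voxel_grid(c(5, 6, 7), affine)
  set.seed(3)
  vox <- array(runif(prod(grid$shape)) > 0.7, dim = grid$shape)
  m <- binary_mask(vox, grid, role = "recurrence", patient_id = "rt")
  path <- tempfile(fileext = ".nii")
  write_mask(m, path)
  m2 <- read_mask(path, "recurrence", "rt")
  expect_identical(m2$voxels, m$voxels)
  expect_lt(max(abs(m2$grid$affine - grid$affine)), 1e-6)
})

test_that("label volumes validate against their tables", {
  lab <- array(0L, dim = c(4, 4, 4)); lab[1, , ] <- 1L; lab[4, , ] <- 2L
  vol <- write_raw_nifti(lab)

  lv <- read_label_volume(vol, write_label_table(1:2))
  expect_s3_class(lv, "label_volume")
  expect_equal(nrow(lv$label_table), 2L)
  expect_setequal(setdiff(unique(as.vector(lv$labels)), 0L),
                  lv$label_table$region_id)

  # orphan label in the volume names the offender
  lab[2, 2, 2] <- 7L
  expect_error(read_label_volume(write_raw_nifti(lab), write_label_table(1:2)),
               "absent from table.*7")

  # regions in the table but absent from the volume stay in the universe
  lv10 <- read_label_volume(vol, write_label_table(1:10))
  expect_equal(nrow(lv10$label_table), 10L)
  m <- binary_mask(array(TRUE, dim = c(4, 4, 4)), lv10$grid, "primary", "p")
  expect_equal(coverage_set(m, lv10)$universe_size, 10L)

  # non-integer voxel values are a type error
  expect_error(read_label_volume(write_raw_nifti(array(0.5, dim = c(3, 3, 3))),
                                 write_label_table(1L)),
               "non-integer")
})

test_that("merge_atlases builds one universe without losing voxels", {
  grid <- tiny_grid(c(4, 4, 4))
  cort_lab <- array(0L, dim = c(4, 4, 4))
  cort_lab[1, 1, 1] <- 1L; cort_lab[2, 1, 1] <- 2L
  cort <- label_volume(cort_lab, grid,
                       data.frame(region_id = 1:2, name = c("a", "b"),
                                  atlas_source = "cortical", hemisphere = "left"))
  sub_lab <- array(0L, dim = c(4, 4, 4))
  sub_lab[4, 4, 4] <- 1L
  sub <- label_volume(sub_lab, grid,
                      data.frame(region_id = 1L, name = "w",
                                 atlas_source = "subcortical", hemisphere = "right"))

  # colliding ids: subcortical remapped by the recorded offset
  merged <- merge_atlases(cort, sub)
  expect_equal(nrow(merged$label_table), 3L)
  expect_false(anyDuplicated(merged$label_table$region_id) > 0)
  expect_equal(merged$offset, 2L)
  expect_equal(merged$labels[4, 4, 4], 3L)

  # spatially disjoint atlases: merged array is the elementwise sum of the
  # remapped arrays and there is no dual-membership sidecar
  expect_identical(merged$labels,
                   cort_lab + array(ifelse(sub_lab > 0L, sub_lab + 2L, 0L),
                                    dim = dim(sub_lab)))
  expect_null(merged$secondary)

  # voxel counts per source atlas are conserved
  expect_equal(sum(merged$labels %in% 1:2), sum(cort_lab > 0L))
  expect_equal(sum(merged$labels == 3L), sum(sub_lab > 0L))

  # a voxel labelled by both atlases keeps both memberships
  sub_lab2 <- sub_lab; sub_lab2[1, 1, 1] <- 1L
  sub2 <- label_volume(sub_lab2, grid, sub$label_table)
  merged2 <- merge_atlases(cort, sub2)
  expect_equal(merged2$labels[1, 1, 1], 1L)
  expect_equal(merged2$secondary[1, 1, 1], 3L)
  m <- binary_mask(array(TRUE, dim = c(4, 4, 4)), grid, "primary", "p")
  cov <- coverage_set(m, merged2)
  expect_equal(unname(cov$voxel_counts["1"]), 1L)
  expect_equal(unname(cov$voxel_counts["3"]), 2L)

  # grid mismatch is refused with both affines reported
  sub_off <- label_volume(sub_lab, voxel_grid(c(4, 4, 4), diag(c(2, 1, 1, 1))),
                          sub$label_table)
  expect_error(merge_atlases(cort, sub_off), "incompatible grids")
})

test_that("read_transform parses 4x4 text matrices and rejects bad ones", {
  g <- tiny_grid()
  path <- tempfile()
  writeLines(apply(diag(4), 1, paste, collapse = " "), path)
  t <- read_transform(path, g, g, "world_mm")
  expect_equal(t$matrix, diag(4))

  # translation-only matrix: rotation block is the identity
  tr <- diag(4); tr[1:3, 4] <- c(3, -2, 1)
  writeLines(apply(tr, 1, paste, collapse = "\t"), path)
  t2 <- read_transform(path, g, g, "world_mm")
  expect_equal(t2$matrix[1:3, 1:3], diag(3))
  expect_equal(t2$matrix[1:3, 4], c(3, -2, 1))

  # singular matrix
  sing <- diag(4); sing[1, 1] <- 0
  writeLines(apply(sing, 1, paste, collapse = " "), path)
  expect_error(read_transform(path, g, g, "world_mm"), "singular")

  # malformed rows carry the line number
  writeLines(c("1 0 0 0", "0 1 0", "0 0 1 0", "0 0 0 1"), path)
  expect_error(read_transform(path, g, g, "world_mm"), "line 2")
  writeLines(c("1 0 0 0", "0 1 0 0"), path)
  expect_error(read_transform(path, g, g, "world_mm"), "expected 4 rows")
})

test_that("clinical tables parse, validate, and tolerate missing survival", {
  tab <- bundled_clinical()
  expect_equal(nrow(tab), 16L)
  expect_s3_class(tab, "clinical_cohort")

  # header-only file: empty cohort with a warning
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(c("patient", "age", "sex", "histology", "localization",
                     "side", "dx_date", "recurrence_date", "last_date",
                     "pfs", "os"), collapse = "\t"), path)
  expect_warning(empty <- read_clinical_table(path), "no rows")
  expect_equal(nrow(empty), 0L)

  # a blank OS becomes NA and is excluded from the median
  df <- as.data.frame(tab[1:3, ])
  df$dx_date <- format_ym(df$dx_date)
  df$recurrence_date <- format_ym(df$recurrence_date)
  df$last_date <- format_ym(df$last_date)
  df$os[2] <- NA
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab3 <- read_clinical_table(path)
  expect_true(is.na(tab3$os[2]))
  med <- median_of(tab3, "os")
  expect_equal(med$n, 2L)
  expect_equal(med$median, median(df$os[-2]))

  # a missing column is a schema error naming it
  df$sex <- NULL
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_clinical_table(path), "sex")

  # PFS > OS warns but does not abort
  df2 <- as.data.frame(tab[1, ])
  df2$dx_date <- format_ym(df2$dx_date)
  df2$recurrence_date <- format_ym(df2$recurrence_date)
  df2$last_date <- format_ym(df2$last_date)
  df2$pfs <- 50L; df2$os <- 10L
  write.table(df2, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(one <- read_clinical_table(path), "PFS \\(50\\) > OS \\(10\\)")
  expect_equal(nrow(one), 1L)
})
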