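test_that("coverage_set counts overlap voxels and applies min_voxels", {
  lv <- box_label_volume(universe_ids = c(2L, 5L, 9L))
  grid <- lv$grid

  # mask exactly equal to region 2's voxel set
  vox <- array(FALSE, dim = c(10, 10, 10)); vox[1:3, 1:3, 1] <- TRUE
  cs <- coverage_set(binary_mask(vox, grid, "primary", "p"), lv)
  expect_identical(cs$covered, 2L)
  expect_equal(cs$universe_size, 3L)

  # empty mask: warned, empty coverage
  expect_warning(
    cs0 <- coverage_set(binary_mask(array(FALSE, dim = c(10, 10, 10)), grid,
                                    "recurrence", "p"), lv),
    "empty mask")
  expect_length(cs0$covered, 0L)

  # 3 voxels in region 2, 12 in region 5, min_voxels = 5: only 5 passes,
  # but both appear in the voxel counts (brute-force counted fixture)
  vox <- array(FALSE, dim = c(10, 10, 10))
  vox[1:3, 1, 1] <- TRUE              # 3 voxels of region 2
  vox[5:7, 5:8, 2] <- TRUE            # 12 voxels of region 5
  m <- binary_mask(vox, grid, "primary", "p")
  brute <- table(lv$labels[vox])
  expect_equal(unname(brute[c("2", "5")]), c(3L, 12L), ignore_attr = TRUE)
  cs2 <- coverage_set(m, lv, min_voxels = 5)
  expect_identical(cs2$covered, 5L)
  expect_equal(cs2$voxel_counts, c(`2` = 3L, `5` = 12L))

  # fractional threshold: region 5 has 32 voxels, 12/32 < 0.5
  cs3 <- coverage_set(m, lv, min_voxels = 1, min_frac = 0.5)
  expect_length(cs3$covered, 0L)
  cs4 <- coverage_set(m, lv, min_voxels = 1, min_frac = 1 / 3)
  expect_identical(cs4$covered, c(2L, 5L))

  # grid mismatch is refused
  other <- binary_mask(array(TRUE, dim = c(10, 10, 10)),
                       voxel_grid(c(10, 10, 10), diag(c(2, 1, 1, 1))),
                       "primary", "p")
  expect_error(coverage_set(other, lv), "incompatible grids")
})

test_that("confusion counts classify every region of the universe", {
  cc <- confusion_counts(
    coverage_from_regions(1:4, 10, "p", "primary"),
    coverage_from_regions(3:5, 10, "p", "recurrence"))
  expect_equal(c(cc$A, cc$B, cc$C, cc$D), c(2L, 2L, 1L, 5L))
  expect_equal(oracle_confusion(1:4, 3:5, 10), c(A = 2L, B = 2L, C = 1L, D = 5L))

  # identical coverage: no false calls
  same <- confusion_counts(coverage_from_regions(c(2, 7), 10, "p", "primary"),
                           coverage_from_regions(c(2, 7), 10, "p", "recurrence"))
  expect_equal(c(same$B, same$C), c(0L, 0L))

  # disjoint coverage
  dis <- confusion_counts(coverage_from_regions(1, 10, "p", "primary"),
                          coverage_from_regions(2, 10, "p", "recurrence"))
  expect_equal(c(dis$A, dis$B, dis$C, dis$D), c(0L, 1L, 1L, 8L))

  # mismatched metadata is refused
  expect_error(confusion_counts(coverage_from_regions(1, 10, "p1", "primary"),
                                coverage_from_regions(1, 10, "p2", "recurrence")),
               "different patients")
  expect_error(confusion_counts(coverage_from_regions(1, 10, "p", "primary"),
                                coverage_from_regions(1, 12, "p", "recurrence")),
               "universe size")
})

test_that("confusion counts equal the per-region brute-force classifier", {
  set.seed(97)
  for (i in 1:200) {
    universe <- sample(5:200, 1)
    p <- random_set(universe)
    r <- random_set(universe)
    cc <- confusion_counts(coverage_from_regions(p, universe, "p", "primary"),
                           coverage_from_regions(r, universe, "p", "recurrence"))
    expect_identical(c(A = cc$A, B = cc$B, C = cc$C, D = cc$D),
                     oracle_confusion(p, r, universe))
    expect_equal(cc$A + cc$B + cc$C + cc$D, universe)
  }
})

test_that("diagnostic metrics follow the four ratio formulas", {
  mk <- function(a, b, c_, d)
    structure(list(A = a, B = b, C = c_, D = d, universe_size = a + b + c_ + d,
                   patient_id = "p"), class = "confusion_counts")

  perfect <- diagnostic_metrics(mk(3, 0, 0, 7))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  m <- diagnostic_metrics(mk(2, 2, 1, 5))
  expect_equal(m$sensitivity, 2 / 3, tolerance = 1e-15)
  expect_equal(m$specificity, 5 / 7, tolerance = 1e-15)
  expect_equal(m$ppv, 1 / 2, tolerance = 1e-15)
  expect_equal(m$npv, 5 / 6, tolerance = 1e-15)

  # zero denominators are undefined, never numbers
  z <- diagnostic_metrics(mk(0, 4, 0, 6))
  expect_true(is.na(z$sensitivity))
  expect_equal(z$specificity, 0.6)
  expect_equal(z$ppv, 0)
  expect_equal(z$npv, 1)
})

test_that("cohort aggregation: pooled counts vs patient-averaged metrics", {
  mk <- function(a, b, c_, d, id = "p")
    structure(list(A = a, B = b, C = c_, D = d, universe_size = a + b + c_ + d,
                   patient_id = id), class = "confusion_counts")

  # a single patient: both modes reduce to that patient's metrics
  one <- mk(2, 2, 1, 5)
  for (mode in c("pooled", "mean")) {
    agg <- aggregate_metrics(list(one), mode)
    expect_equal(agg$sensitivity, 2 / 3)
    expect_equal(agg$n_patients, 1L)
  }

  # hand-evaluated two-patient cohort
  two <- list(mk(2, 2, 1, 5, "p1"), mk(4, 0, 0, 6, "p2"))
  pooled <- aggregate_metrics(two, "pooled")
  expect_equal(pooled$sensitivity, 6 / 7, tolerance = 1e-15)
  expect_equal(pooled$aggregation, "pooled")
  avg <- aggregate_metrics(two, "mean")
  expect_equal(avg$sensitivity, (2 / 3 + 1) / 2, tolerance = 1e-15)
  expect_equal(avg$aggregation, "mean")

  # an undefined per-patient value is skipped and the skip is counted
  with_undef <- list(mk(0, 0, 1, 9, "p1"), mk(2, 2, 1, 5, "p2"))
  m <- aggregate_metrics(with_undef, "mean")
  expect_equal(unname(m$n_undefined["ppv"]), 1L)
  expect_equal(m$ppv, 1 / 2)   # only the defined patient contributes

  expect_error(aggregate_metrics(list(), "pooled"), "empty cohort")
  expect_error(aggregate_metrics(list(mk(1, 1, 1, 1), mk(1, 1, 1, 2)), "pooled"),
               "universe")
})

test_that("swapping the mask roles swaps B with C and sensitivity with PPV", {
  set.seed(41)
  for (i in 1:50) {
    universe <- sample(5:150, 1)
    p <- random_set(universe)
    r <- random_set(universe)
    fwd <- confusion_counts(coverage_from_regions(p, universe, "x", "primary"),
                            coverage_from_regions(r, universe, "x", "recurrence"))
    rev <- confusion_counts(coverage_from_regions(r, universe, "x", "primary"),
                            coverage_from_regions(p, universe, "x", "recurrence"))
    expect_identical(c(rev$B, rev$C), c(fwd$C, fwd$B))
    mf <- diagnostic_metrics(fwd); mr <- diagnostic_metrics(rev)
    expect_identical(mf$sensitivity, mr$ppv)
    expect_identical(mf$ppv, mr$sensitivity)
  }
})

test_that("enlarging the primary coverage never hurts sensitivity nor helps specificity", {
  set.seed(59)
  for (i in 1:50) {
    universe <- sample(10:150, 1)
    p <- random_set(universe)
    r <- sort(sample(seq_len(universe), sample(1:universe, 1)))  # nonempty
    extra <- setdiff(seq_len(universe), p)
    p_big <- sort(c(p, sample(extra, min(length(extra), sample(0:5, 1)))))
    cc <- confusion_counts(coverage_from_regions(p, universe, "x", "primary"),
                           coverage_from_regions(r, universe, "x", "recurrence"))
    cc_big <- confusion_counts(coverage_from_regions(p_big, universe, "x", "primary"),
                               coverage_from_regions(r, universe, "x", "recurrence"))
    expect_gte(cc_big$A, cc$A)
    m <- diagnostic_metrics(cc); m_big <- diagnostic_metrics(cc_big)
    expect_gte(m_big$sensitivity, m$sensitivity)
    if (!is.na(m$specificity) && !is.na(m_big$specificity))
      expect_lte(m_big$specificity, m$specificity)
  }
})

test_that("metrics stay in [0,1] and pooled values sit inside the per-patient range", {
  set.seed(71)
  for (rep in 1:20) {
    universe <- sample(20:120, 1)
    cohort <- lapply(1:6, function(j) {
      p <- random_set(universe)
      r <- sort(sample(seq_len(universe), sample(1:universe, 1)))
      confusion_counts(coverage_from_regions(p, universe, sprintf("p%d", j), "primary"),
                       coverage_from_regions(r, universe, sprintf("p%d", j), "recurrence"))
    })
    per <- lapply(cohort, diagnostic_metrics)
    pooled <- aggregate_metrics(cohort, "pooled")
    for (metric in c("sensitivity", "specificity", "ppv", "npv")) {
      vals <- vapply(per, `[[`, 1, metric)
      defined <- vals[!is.na(vals)]
      expect_true(all(defined >= 0 & defined <= 1))
      pv <- pooled[[metric]]
      if (!is.na(pv) && length(defined)) {
        expect_gte(pv, min(defined) - 1e-12)
        expect_lte(pv, max(defined) + 1e-12)
      }
    }
  }
})

test_that("voxel-level Dice/Jaccard side diagnostics behave", {
  g <- tiny_grid(c(6, 6, 6))
  a <- array(FALSE, dim = c(6, 6, 6)); a[1:3, , ] <- TRUE
  b <- array(FALSE, dim = c(6, 6, 6)); b[2:4, , ] <- TRUE
  vo <- voxel_overlap(binary_mask(a, g, "primary", "p"),
                      binary_mask(b, g, "recurrence", "p"))
  expect_equal(vo$dice, 2 * 72 / (108 + 108))
  expect_equal(vo$jaccard, 72 / 144)
})
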