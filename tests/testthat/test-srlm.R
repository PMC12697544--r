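test_that("the medial DG point is the minimum DG column", {
  dg <- blank_mask()
  dg[12:30, 15:20] <- TRUE
  expect_identical(medial_dg_point(dg), 12L)
  dg2 <- blank_mask()
  dg2[7, 9] <- TRUE
  expect_identical(medial_dg_point(dg2), 7L)
  expect_identical(medial_dg_point(blank_mask()), NA_integer_)
})

test_that("sector-ring proportions match the angular fractions", {
  ph <- phantom_generate(sector_phantom_spec(c(CA1 = 150, CA2 = 20, CA3 = 10)))
  v <- ph$volume
  z <- 150L
  mdx <- medial_dg_point(slice_mask(v, z, "DG"))
  pr <- project_onto_srlm(
    slice_mask(v, z, "SRLM"), slice_mask(v, z, "CA1"),
    slice_mask(v, z, "CA2"), slice_mask(v, z, "CA3"),
    medial_dg_x = mdx, spacing = 0.2
  )
  expect_lt(abs(pr$prop_CA1 - 150 / 180), 0.03)
  expect_lt(abs(pr$prop_CA2 - 20 / 180), 0.03)
  expect_lt(abs(pr$prop_CA3 - 10 / 180), 0.03)
  expect_false(pr$sub_border_lateral_case)
})

test_that("a band covered by a single CA field gets proportion one", {
  srlm <- blank_mask()
  ca1 <- blank_mask()
  srlm[15:30, 10] <- TRUE
  ca1[15:30, 12] <- TRUE
  pr <- project_onto_srlm(srlm, ca1, blank_mask(), blank_mask(),
    medial_dg_x = 15L, spacing = 0.2
  )
  expect_equal(pr$prop_CA1, 1)
  expect_equal(pr$prop_CA2 + pr$prop_CA3, 0)
})

test_that("every lateral band voxel is assigned exactly once (partition)", {
  ph <- default_phantom()
  pr <- srlm_profile(ph$volume, ph$landmarks)
  ok <- is.na(pr$skipped_reason)
  expect_true(all(
    pr$n_CA1[ok] + pr$n_CA2[ok] + pr$n_CA3[ok] + pr$n_unassigned[ok] ==
      pr$n_srlm_total[ok]
  ))
  expect_true(all(pr$prop_CA1[ok] + pr$prop_CA2[ok] + pr$prop_CA3[ok] <= 1 + 1e-9))
})

test_that("a lateral SUB-CA1 interface leaves a medial band stretch unassigned", {
  ph <- phantom_generate(phantom_spec(border_rel = c(start = 0.4, end = 0.4)))
  pr <- srlm_profile(ph$volume, ph$landmarks)
  ok <- is.na(pr$skipped_reason)
  expect_true(all(pr$sub_border_lateral_case[ok]))
  sums <- pr$prop_CA1[ok] + pr$prop_CA2[ok] + pr$prop_CA3[ok]
  expect_true(all(sums < 1))
  expect_true(all(pr$n_unassigned[ok] > 0))
})

test_that("errors and skips follow the per-slice contracts", {
  srlm <- blank_mask()
  srlm[10:20, 10] <- TRUE
  expect_error(
    project_onto_srlm(srlm, blank_mask(), blank_mask(), blank_mask(),
      medial_dg_x = 10L, spacing = 0.2
    ),
    class = "hippomorph_projection_error"
  )
  expect_error(
    project_onto_srlm(blank_mask(), srlm, blank_mask(), blank_mask(),
      medial_dg_x = 10L, spacing = 0.2
    ),
    class = "hippomorph_projection_error"
  )
})

test_that("moving the medial cut medially never shrinks the band", {
  ph <- default_phantom()
  z <- 150L
  srlm <- slice_mask(ph$volume, z, "SRLM")
  ca <- lapply(c("CA1", "CA2", "CA3"), function(l) slice_mask(ph$volume, z, l))
  mdx <- medial_dg_point(slice_mask(ph$volume, z, "DG"))
  n_at <- function(x) {
    project_onto_srlm(srlm, ca[[1]], ca[[2]], ca[[3]],
      medial_dg_x = x, spacing = 0.2
    )$n_srlm_total
  }
  ns <- vapply(c(mdx + 4L, mdx, mdx - 4L), n_at, numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("constant angular spans give a flat profile; a CA1 ramp a monotone one", {
  ph <- default_phantom()
  pr <- srlm_profile(ph$volume, ph$landmarks)
  ok <- is.na(pr$skipped_reason)
  expect_lt(max(pr$prop_CA1[ok]) - min(pr$prop_CA1[ok]), 0.02)
  ramped <- phantom_generate(sector_phantom_spec(
    spans_deg = c(CA1 = 140, CA2 = 25, CA3 = 15),
    spans_deg_end = c(CA1 = 160, CA2 = 10, CA3 = 10)
  ))
  prr <- srlm_profile(ramped$volume, ramped$landmarks)
  okr <- is.na(prr$skipped_reason)
  expect_true(all(diff(prr$prop_CA1[okr]) >= 0))
  expect_gt(
    prr$prop_CA1[okr][sum(okr)] - prr$prop_CA1[okr][1],
    0.04
  )
  single <- srlm_profile(ph$volume, ph$landmarks, increments_pct = 30)
  expect_identical(nrow(single), 1L)
})

test_that("the medial DG point is hemisphere-invariant through the loader", {
  ph <- default_phantom()
  v2 <- reload_mirrored(ph$volume)
  z <- 150L
  expect_identical(
    medial_dg_point(slice_mask(v2, z, "DG")),
    medial_dg_point(slice_mask(ph$volume, z, "DG"))
  )
  expect_equal(
    srlm_profile(v2, ph$landmarks),
    srlm_profile(ph$volume, ph$landmarks)
  )
})

test_that("occupancy from two SRLM border positions is their difference", {
  expect_equal(ca_occupancy_from_borders(33, 80), 47)
  expect_error(ca_occupancy_from_borders(80, 33))
})
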