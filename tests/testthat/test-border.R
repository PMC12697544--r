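test_that("the medial anchor drops from the most medial CA3/DG voxel to SUB/CA1", {
  dg <- blank_mask()
  ca3 <- blank_mask()
  sub <- blank_mask()
  ca1 <- blank_mask()
  dg[14:25, 15:22] <- TRUE
  ca3[18:25, 23:26] <- TRUE
  sub[5:30, 8:9] <- TRUE
  a <- medial_anchor(ca3, dg, sub, ca1)
  expect_equal(unname(a), c(14, 9))
  # CA3 more medial than DG wins the column
  ca3b <- blank_mask()
  ca3b[11:13, 15:22] <- TRUE
  a2 <- medial_anchor(ca3b, dg, sub, ca1)
  expect_equal(unname(a2), c(11, 9))
  # nothing below and nothing above -> anchor error
  expect_error(
    medial_anchor(ca3, dg, blank_mask(), blank_mask()),
    class = "hippomorph_anchor_error"
  )
})

test_that("a blocked inferior march falls back to a superior march with warning", {
  dg <- blank_mask()
  sub <- blank_mask()
  dg[10:20, 10:15] <- TRUE
  sub[10:20, 25:26] <- TRUE # only superior tissue
  expect_warning(
    a <- medial_anchor(blank_mask(), dg, sub, blank_mask()),
    "superior march"
  )
  expect_equal(unname(a), c(10, 25))
})

test_that("relative border position follows the sign and width conventions", {
  mk <- function(border_x, anchor = c(x = 10, y = 9)) {
    ca1 <- blank_mask(60, 40)
    sub <- blank_mask(60, 40)
    dg <- blank_mask(60, 40)
    sub[5:(border_x - 1), 8:10] <- TRUE
    ca1[border_x:50, 8:10] <- TRUE
    dg[12:30, 15:20] <- TRUE
    border_position(ca1, sub, dg, anchor, spacing = 1)
  }
  b <- mk(20)
  expect_equal(b$border_line_x, 20)
  expect_equal(b$full_width_mm, 50.5 - 10)
  expect_equal(b$dg_width_mm, 30.5 - 10)
  expect_equal(b$pct_of_full_width, 10 / 40.5 * 100)
  expect_equal(b$pct_of_dg_width, 10 / 20.5 * 100)
  # border medial of the anchor is negative
  b2 <- mk(8)
  expect_lt(b2$pct_of_full_width, 0)
  expect_lt(b2$pct_of_dg_width, 0)
  # DG width <= full width, so the DG-referenced magnitude is larger
  expect_gt(abs(b$pct_of_dg_width), abs(b$pct_of_full_width))
  expect_gt(abs(b2$pct_of_dg_width), abs(b2$pct_of_full_width))
})

test_that("missing SUB-CA1 adjacency is a border-absent error", {
  ca1 <- blank_mask()
  sub <- blank_mask()
  dg <- blank_mask()
  ca1[20:30, 8:10] <- TRUE
  sub[5:15, 20:22] <- TRUE # not adjacent
  dg[12:30, 14:18] <- TRUE
  expect_error(
    border_position(ca1, sub, dg, c(x = 10, y = 9), spacing = 0.2),
    class = "hippomorph_border_error"
  )
})

test_that("phantom border positions are recovered exactly at both offsets", {
  ph <- default_phantom()
  got <- measure_border_at_offsets(ph$volume, ph$landmarks)
  tr <- ph$truth$border
  expect_identical(got$z_used, tr$z)
  expect_equal(got$pct_of_full_width, tr$pct_of_full_width)
  expect_equal(got$pct_of_dg_width, tr$pct_of_dg_width)
})

test_that("the medial shift along the ramp makes the 20 mm value smaller", {
  ph <- default_phantom()
  got <- measure_border_at_offsets(ph$volume, ph$landmarks)
  expect_lt(got$pct_of_full_width[got$offset_mm == 20],
    got$pct_of_full_width[got$offset_mm == 0])
})

test_that("unusable target slices fall back within the 3 mm window, else absent", {
  ph <- default_phantom()
  lm_bad <- hippo_landmarks(
    ph$landmarks$anterior_tip_z,
    ph$landmarks$posterior_tip_z - 2L, # "apex" so posterior the 20 mm slice is empty
    ph$landmarks$posterior_tip_z
  )
  got <- measure_border_at_offsets(ph$volume, lm_bad, offsets_mm = 20)
  expect_true(is.na(got$z_used))
  # 0 mm target beyond the drawn extent recovers via the search window
  lm_edge <- hippo_landmarks(
    ph$landmarks$anterior_tip_z,
    ph$landmarks$posterior_tip_z, # target apex+1 is past the last drawn slice
    ph$landmarks$posterior_tip_z
  )
  got2 <- measure_border_at_offsets(ph$volume, lm_edge, offsets_mm = 0)
  expect_false(is.na(got2$z_used))
  expect_lte(abs(got2$z_used - (lm_edge$uncal_apex_z + 1L)), 15L)
})

test_that("border measurements are hemisphere-invariant through the loader", {
  ph <- default_phantom()
  v2 <- reload_mirrored(ph$volume)
  expect_equal(
    measure_border_at_offsets(v2, ph$landmarks),
    measure_border_at_offsets(ph$volume, ph$landmarks)
  )
})

test_that("random ramp phantoms recover the border within two percentage points", {
  for (s in 201:210) {
    ph <- phantom_generate(random_phantom_spec(s))
    got <- measure_border_at_offsets(ph$volume, ph$landmarks)
    tr <- ph$truth$border
    for (i in 1:2) {
      if (is.na(got$z_used[i]) || got$z_used[i] != tr$z[i]) next
      expect_lt(abs(got$pct_of_full_width[i] - tr$pct_of_full_width[i]), 2)
    }
  }
})
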