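test_that("body slices sit at percent increments of total length from the apex", {
  lm <- hippo_landmarks(1, 101, 201)
  zs <- select_body_slices(lm)
  expect_equal(unname(zs), c(121, 141, 161, 181, 201))
  expect_equal(unname(select_body_slices(lm, 10)), 121)
  expect_error(select_body_slices(lm, 60), class = "hippomorph_landmark_error")
  # 26 mm total at 0.2 mm -> 2.6 mm increments
  lm2 <- hippo_landmarks(10, 60, 140)
  zs2 <- select_body_slices(lm2)
  expect_equal(diff(unname(zs2)) * 0.2, rep(2.6, 4))
})

test_that("the straight-strip oracle recovers length and proportions", {
  s <- strip_masks()
  p <- trace_ribbon(s$sub, s$prs, s$pas, spacing = 0.2)
  # 60 columns -> 59 axial steps -> 11.8 mm, within 2%
  expect_lt(abs(attr(p, "length_mm") - 11.8) / 11.8, 0.02)
  pr <- subicular_proportions(p)
  expect_lt(abs(pr$pct_SUB - 50), 2)
  expect_lt(abs(pr$pct_PrS - 30), 2)
  expect_lt(abs(pr$pct_PaS - 20), 2)
  expect_lt(abs(pr$boundary_sub_prs_pct - 50), 2)
  expect_lt(abs(pr$boundary_prs_pas_pct - 80), 2)
})

test_that("the quarter-annulus centerline length matches the analytic arc", {
  a <- arc_masks(rc = 20)
  p <- trace_ribbon(a$sub, a$prs, spacing = 0.2)
  ideal <- pi / 2 * 20 * 0.2
  expect_lt(abs(attr(p, "length_mm") - ideal) / ideal, 0.03)
})

test_that("without PaS the path ends at the medial PrS extreme and PrS absorbs its share", {
  s <- strip_masks()
  p_full <- trace_ribbon(s$sub, s$prs, s$pas, spacing = 0.2)
  p_nopas <- trace_ribbon(s$sub, s$prs, spacing = 0.2)
  expect_lt(min(p_nopas$x), 24) # reaches the medial PrS end
  pr_full <- subicular_proportions(p_full)
  pr_nopas <- subicular_proportions(p_nopas)
  expect_true(is.na(pr_nopas$pct_PaS))
  # SUB share against the shortened ribbon: 30/(30+18)
  expect_lt(abs(pr_nopas$pct_SUB - 62.5), 2.5)
  expect_lt(abs(pr_nopas$pct_PrS - 37.5), 2.5)
  # equal SUB and PrS path lengths -> 50/50
  sub2 <- blank_mask(60, 16)
  prs2 <- blank_mask(60, 16)
  sub2[26:45, 6:11] <- TRUE
  prs2[6:25, 6:11] <- TRUE
  pr5050 <- subicular_proportions(trace_ribbon(sub2, prs2, spacing = 0.2))
  expect_lt(abs(pr5050$pct_SUB - 50), 1)
})

test_that("present-region percentages sum to 100", {
  s <- strip_masks()
  pr <- subicular_proportions(trace_ribbon(s$sub, s$prs, s$pas, spacing = 0.2))
  expect_lt(abs(pr$pct_SUB + pr$pct_PrS + pr$pct_PaS - 100), 0.1)
  ph <- default_phantom()
  tbl <- measure_subicular(ph$volume, ph$landmarks)
  ok <- is.na(tbl$skipped_reason)
  sums <- rowSums(cbind(tbl$pct_SUB, tbl$pct_PrS, tbl$pct_PaS)[ok, , drop = FALSE],
    na.rm = TRUE
  )
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("disconnected ribbons raise a topology error with the component count", {
  s <- strip_masks()
  s$prs[30, ] <- FALSE # cut the strip
  expect_error(
    trace_ribbon(s$sub, s$prs, s$pas, spacing = 0.2),
    regexp = "2 connected components", class = "hippomorph_topology_error"
  )
})

test_that("proportions are stable under in-plane resolution doubling", {
  s <- strip_masks()
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  pr1 <- subicular_proportions(trace_ribbon(s$sub, s$prs, s$pas, spacing = 0.2))
  pr2 <- subicular_proportions(trace_ribbon(up(s$sub), up(s$prs), up(s$pas), spacing = 0.1))
  expect_lt(abs(pr1$pct_SUB - pr2$pct_SUB), 1.5)
  expect_lt(abs(pr1$pct_PrS - pr2$pct_PrS), 1.5)
  expect_lt(abs(pr1$pct_PaS - pr2$pct_PaS), 1.5)
})

test_that("proportions are robust to a 30-degree rotation of the strip", {
  rotated <- function(deg) {
    th <- deg * pi / 180
    f <- function(u0, u1) {
      out <- blank_mask(90, 60)
      for (u in seq(u0, u1, by = 0.25)) {
        for (v in seq(0, 5, by = 0.25)) {
          x <- round(10 + u * cos(th) - v * sin(th))
          y <- round(8 + u * sin(th) + v * cos(th))
          if (x >= 1 && x <= 90 && y >= 1 && y <= 60) out[x, y] <- TRUE
        }
      }
      out
    }
    # lateral SUB 30 / PrS 18 / PaS 12 voxels along the strip axis
    list(pas = f(0, 11.8), prs = f(12, 29.8), sub = f(30, 59.8))
  }
  r0 <- rotated(0)
  r30 <- rotated(30)
  pr0 <- subicular_proportions(trace_ribbon(r0$sub, r0$prs, r0$pas, spacing = 0.2))
  pr30 <- subicular_proportions(trace_ribbon(r30$sub, r30$prs, r30$pas, spacing = 0.2))
  expect_lt(abs(pr0$pct_SUB - pr30$pct_SUB), 3)
  expect_lt(abs(pr0$pct_PrS - pr30$pct_PrS), 3)
  expect_lt(abs(pr0$pct_PaS - pr30$pct_PaS), 3)
})

test_that("phantom fractional splits are recovered within tolerance along the body", {
  sp <- phantom_spec(splits = c(SUB = 0.46, PrS = 0.38, PaS = 0.16))
  ph <- phantom_generate(sp)
  tbl <- measure_subicular(ph$volume, ph$landmarks)
  tr <- ph$truth$subicular
  for (i in seq_len(nrow(tbl))) {
    if (!is.na(tbl$skipped_reason[i])) next
    expect_lt(abs(tbl$pct_SUB[i] - tr$pct_SUB[i]), 3)
    if (!is.na(tr$pct_PaS[i])) expect_lt(abs(tbl$pct_PaS[i] - tr$pct_PaS[i]), 3)
  }
})

test_that("mirroring the hemisphere leaves subicular proportions unchanged", {
  ph <- default_phantom()
  mv <- canonicalize_volume(mirror_volume(ph$volume))
  expect_equal(
    measure_subicular(mv, ph$landmarks),
    measure_subicular(ph$volume, ph$landmarks)
  )
})
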