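test_that("appearance needs a 4-voxel 8-connected cluster; corners count", {
  # 2x2 block at z=7 only
  v <- mini_volume(list(
    list(5, 5, 7, "CA1"), list(6, 5, 7, "CA1"),
    list(5, 6, 7, "CA1"), list(6, 6, 7, "CA1")
  ))
  expect_identical(detect_appearance(v, "CA1"), 7L)
  # 3-in-a-row at z=5 (below threshold), 4-voxel diagonal chain at z=6
  v2 <- mini_volume(list(
    list(4, 4, 5, "CA1"), list(5, 4, 5, "CA1"), list(6, 4, 5, "CA1"),
    list(4, 4, 6, "CA1"), list(5, 5, 6, "CA1"),
    list(6, 6, 6, "CA1"), list(7, 7, 6, "CA1")
  ))
  expect_identical(detect_appearance(v2, "CA1"), 6L)
  # two separate pairs never reach 4 in one component
  v3 <- mini_volume(list(
    list(2, 2, 4, "CA1"), list(3, 2, 4, "CA1"),
    list(10, 10, 4, "CA1"), list(11, 10, 4, "CA1")
  ))
  expect_identical(detect_appearance(v3, "CA1"), NA_integer_)
})

test_that("a coverage gap immediately anterior lowers the threshold to one voxel", {
  v <- mini_volume(list(list(4, 4, 4, "CA1")))
  cov <- rep(TRUE, 20)
  expect_identical(detect_appearance(v, "CA1", coverage = cov), NA_integer_)
  cov[3] <- FALSE
  expect_identical(detect_appearance(v, "CA1", coverage = cov), 4L)
})

test_that("raising min_cluster never yields an earlier appearance", {
  ph <- default_phantom()
  for (lb in c("CA1", "CA2", "PaS")) {
    a1 <- detect_appearance(ph$volume, lb, min_cluster = 1L)
    a4 <- detect_appearance(ph$volume, lb, min_cluster = 4L)
    a9 <- detect_appearance(ph$volume, lb, min_cluster = 9L)
    expect_true(a1 <= a4 && a4 <= a9)
  }
})

test_that("disappearance is the last segmented slice, one voxel sufficing", {
  v <- mini_volume(list(list(3, 3, 10, "PaS"), list(3, 3, 14, "PaS")))
  expect_identical(detect_disappearance(v, "PaS"), 14L)
  expect_identical(detect_disappearance(v, "CA2"), NA_integer_)
})

test_that("DG appearance requires full enclosure by the dark band", {
  pts <- list()
  # z=30: DG pixel ringed by SRLM; z=29: ring broken by background
  for (dx in -1:1) {
    for (dy in -1:1) {
      lbl <- if (dx == 0 && dy == 0) "DG" else "SRLM"
      pts <- c(pts, list(list(8 + dx, 8 + dy, 15, lbl)))
      if (!(dx == 1 && dy == 0)) pts <- c(pts, list(list(8 + dx, 8 + dy, 14, lbl)))
    }
  }
  v <- mini_volume(pts)
  expect_identical(dg_enclosure_appearance(v), 15L)
  # no SRLM at all -> absent
  v2 <- mini_volume(list(list(5, 5, 3, "DG")))
  expect_identical(dg_enclosure_appearance(v2), NA_integer_)
})

test_that("length measures follow the inter-slice convention", {
  lm <- hippo_landmarks(10, 110, 210)
  expect_equal(head_length(lm, 0.2), 20)
  expect_equal(head_length(hippo_landmarks(10, 15, 20), 0.2), 1) # 5 slices
  expect_warning(head_length(hippo_landmarks(10, 10, 10), 0.2), "Degenerate")
  lr <- total_length_and_ratio(lm, 0.2)
  expect_equal(lr$total_length_mm, 40)
  expect_equal(lr$head_to_total_ratio_pct, 50)
  lr2 <- total_length_and_ratio(hippo_landmarks(10, 110), 0.2)
  expect_equal(lr2$head_length_mm, 20)
  expect_true(is.na(lr2$total_length_mm) && is.na(lr2$head_to_total_ratio_pct))
})

test_that("appearance order and gaps are recovered on the default phantom", {
  ph <- default_phantom()
  ord <- appearance_order(ph$volume, landmarks = ph$landmarks)
  expect_identical(ord$label, c("SUB", "CA1", "DG", "CA3", "CA2"))
  expect_equal(ord$gap_mm[-1], c(2.0, 3.6, 1.6, 3.0))
  expect_equal(
    ord$gap_pct[-1], ord$gap_mm[-1] / ph$truth$head_length_mm * 100
  )
  expect_false(any(ord$tied_with_previous))
})

test_that("simultaneous appearance is reported as a tie with zero gap", {
  pts <- list()
  for (dx in 0:1) {
    for (dy in 0:1) {
      pts <- c(pts, list(
        list(4 + dx, 4 + dy, 8, "CA2"), list(10 + dx, 10 + dy, 8, "CA3")
      ))
    }
  }
  v <- mini_volume(pts)
  lm <- hippo_landmarks(2, 12, 18)
  ord <- suppressWarnings(
    appearance_order(v, labels = c("CA2", "CA3"), landmarks = lm)
  )
  expect_equal(ord$gap_mm[2], 0)
  expect_true(ord$tied_with_previous[2])
})

test_that("tail presence uses the offset slices and excludes uncovered ones", {
  ph <- default_phantom()
  tp <- tail_presence(ph$volume, landmarks = ph$landmarks)
  expect_setequal(unique(tp$offset_mm), c(2, 1))
  # offsets are 10 and 5 slices anterior to the posterior tip at 0.2 mm
  expect_identical(unique(tp$z[tp$offset_mm == 2]), ph$landmarks$posterior_tip_z - 10L)
  expect_identical(unique(tp$z[tp$offset_mm == 1]), ph$landmarks$posterior_tip_z - 5L)
  ext <- ph$truth$extents
  for (i in seq_len(nrow(tp))) {
    e <- ext[ext$label == tp$label[i], ]
    expect_identical(
      tp$present[i], tp$z[i] >= e$z_start && tp$z[i] <= e$z_end,
      label = sprintf("%s at %g mm", tp$label[i], tp$offset_mm[i])
    )
  }
  cov <- rep(TRUE, dim(ph$volume)[3])
  cov[ph$landmarks$posterior_tip_z - 10L] <- FALSE
  tp2 <- tail_presence(ph$volume, landmarks = ph$landmarks, coverage = cov)
  expect_true(all(is.na(tp2$present[tp2$offset_mm == 2])))
  expect_false(anyNA(tp2$present[tp2$offset_mm == 1]))
})

test_that("nested subicular extents disappear last-in-first-out", {
  ph <- default_phantom()
  app <- c(
    SUB = ph$landmarks$anterior_tip_z,
    PrS = detect_appearance(ph$volume, "PrS"),
    PaS = detect_appearance(ph$volume, "PaS")
  )
  dis <- c(
    SUB = detect_disappearance(ph$volume, "SUB"),
    PrS = detect_disappearance(ph$volume, "PrS"),
    PaS = detect_disappearance(ph$volume, "PaS")
  )
  expect_identical(names(sort(app)), c("SUB", "PrS", "PaS"))
  expect_identical(names(sort(dis, decreasing = TRUE)), c("SUB", "PrS", "PaS"))
})

test_that("shifting content and landmarks along z leaves mm outputs unchanged", {
  base <- phantom_spec()
  k <- 7L
  shifted <- phantom_spec(
    anterior_tip_z = base$anterior_tip_z + k,
    uncal_apex_z = base$uncal_apex_z + k,
    posterior_tip_z = base$posterior_tip_z + k,
    extents = lapply(base$extents, function(e) e + k)
  )
  a <- phantom_generate(base)
  b <- phantom_generate(shifted)
  ord_a <- appearance_order(a$volume, landmarks = a$landmarks)
  ord_b <- appearance_order(b$volume, landmarks = b$landmarks)
  expect_equal(ord_a$gap_mm, ord_b$gap_mm)
  expect_equal(ord_a$distance_from_tip_mm, ord_b$distance_from_tip_mm)
  expect_equal(
    total_length_and_ratio(a$landmarks, 0.2),
    total_length_and_ratio(b$landmarks, 0.2)
  )
})

test_that("subfield extents table ties appearance, disappearance and lengths together", {
  ph <- default_phantom()
  ext <- subfield_extents(ph$volume, landmarks = ph$landmarks)
  tr <- ph$truth$extents
  for (lb in c("PrS", "PaS", "CA2", "CA3", "DG")) {
    expect_identical(
      ext$first_slice[ext$label == lb], tr$z_start[tr$label == lb],
      label = paste("first", lb)
    )
    expect_identical(
      ext$last_slice[ext$label == lb], tr$z_end[tr$label == lb],
      label = paste("last", lb)
    )
  }
  prs <- ext[ext$label == "PrS", ]
  expect_equal(prs$length_mm, (prs$last_slice - prs$first_slice) * 0.2)
  expect_equal(prs$length_pct_total, prs$length_mm / ph$truth$total_length_mm * 100)
})
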