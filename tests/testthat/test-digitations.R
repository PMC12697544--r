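# Constructed digitation slices: a gray-matter block whose superior
# surface carries a known number of sinusoidal bumps, with an SRLM/DG core
# and a CA3 strip placed by construction.

digitated_slice <- function(n_peaks, amplitude, nx = 80, ny = 60,
                            ca3_at = NULL, ca3_halfwidth = 2L) {
  sch <- unclass(default_schema())
  lab <- matrix(0L, nx, ny)
  xl <- 11L
  xr <- 70L
  base <- 30L
  lab[xl:xr, 10:base] <- sch[["CA1"]]
  lab[(xl + 1L):(xr - 1L), 12:16] <- sch[["SRLM"]]
  lab[20:60, 13:15] <- sch[["DG"]]
  for (x in xl:xr) {
    u <- (x - xl) / (xr - xl)
    d <- round(amplitude * (0.5 + 0.5 * cos(2 * pi * n_peaks * u - pi)))
    if (d > 0) lab[x, (base + 1L):(base + d)] <- sch[["CA1"]]
  }
  if (!is.null(ca3_at)) {
    cols <- max(xl, ca3_at - ca3_halfwidth):min(xr, ca3_at + ca3_halfwidth)
    for (x in cols) {
      top <- max(which(lab[x, ] > 0L))
      lab[x, (top - 1L):top] <- sch[["CA3"]]
    }
  }
  lab
}

peak_positions <- function(n_peaks, xl = 11, xr = 70) {
  xl + (2 * seq_len(n_peaks) - 1) / (2 * n_peaks) * (xr - xl)
}

trough_positions <- function(n_peaks, xl = 11, xr = 70) {
  xl + (seq_len(n_peaks - 1)) / n_peaks * (xr - xl)
}

test_that("peak counting matches the constructed surface", {
  flat <- digitated_slice(1, 0)
  expect_identical(digitation_profile(flat)$n_digitations, 1L)
  for (n in 2:4) {
    prof <- digitation_profile(digitated_slice(n, 6))
    expect_identical(prof$n_digitations, as.integer(n))
  }
  # amplitude below the prominence threshold collapses to one plateau peak
  low <- digitation_profile(digitated_slice(3, 1), prominence_voxels = 2L)
  expect_identical(low$n_digitations, 1L)
  # profile error on a footprint narrower than 5 columns
  sch <- unclass(default_schema())
  tiny <- matrix(0L, 10, 10)
  tiny[4:6, 4] <- sch[["CA1"]]
  expect_error(digitation_profile(tiny), class = "hippomorph_profile_error")
})

test_that("peaks and troughs alternate", {
  prof <- digitation_profile(digitated_slice(4, 8))
  pts <- sort(c(prof$peaks_x, prof$troughs_x))
  kinds <- ifelse(pts %in% prof$peaks_x, "p", "t")
  expect_true(all(kinds[seq(1, length(kinds), 2)] == "p"))
  expect_identical(length(prof$troughs_x), length(prof$peaks_x) - 1L)
})

test_that("the anterior CA3 slice is the first with CA3 above the DG/SRLM roof", {
  sch <- unclass(default_schema())
  vox <- array(0L, c(40, 40, 30))
  # z < 12: CA3 only inferior to the DG/SRLM core
  for (z in 8:29) {
    vox[15:25, 14:18, z] <- sch[["SRLM"]]
    vox[17:23, 15:17, z] <- sch[["DG"]]
    vox[15:25, 5:8, z] <- sch[["CA3"]]
  }
  for (z in 12:29) vox[18:22, 22:24, z] <- sch[["CA3"]] # superior strip from z=12
  v <- hippo_volume(vox)
  expect_identical(anterior_ca3_slice(v), 12L)
  ph <- default_phantom()
  expect_identical(anterior_ca3_slice(ph$volume), ph$truth$anterior_ca3_z)
})

test_that("CA3 placement at peaks and troughs classifies correctly", {
  for (n in c(2L, 3L)) {
    pk <- peak_positions(n)
    tr <- trough_positions(n)
    for (i in seq_along(pk)) {
      lab <- digitated_slice(n, 8, ca3_at = round(pk[i]))
      cls <- classify_ca3(
        digitation_profile(lab),
        ca3_superior_strip(lab)
      )
      expect_identical(cls$relation, "on_top", label = sprintf("peak %d of %d", i, n))
    }
    for (i in seq_along(tr)) {
      lab <- digitated_slice(n, 8, ca3_at = round(tr[i]))
      cls <- classify_ca3(
        digitation_profile(lab),
        ca3_superior_strip(lab)
      )
      expect_identical(cls$relation, "in_between", label = sprintf("trough %d of %d", i, n))
    }
  }
})

test_that("medial/lateral position follows the footprint thirds", {
  lab_med <- digitated_slice(3, 8, ca3_at = 16)
  lab_mid <- digitated_slice(3, 8, ca3_at = 40)
  lab_lat <- digitated_slice(3, 8, ca3_at = 65)
  expect_identical(
    classify_ca3(digitation_profile(lab_med), ca3_superior_strip(lab_med))$position,
    "medial"
  )
  expect_identical(
    classify_ca3(digitation_profile(lab_mid), ca3_superior_strip(lab_mid))$position,
    "midpoint"
  )
  expect_identical(
    classify_ca3(digitation_profile(lab_lat), ca3_superior_strip(lab_lat))$position,
    "lateral"
  )
})

test_that("classification is deterministic and mirror-consistent on phantoms", {
  ph <- default_phantom()
  d1 <- measure_digitations(ph$volume)
  d2 <- measure_digitations(ph$volume)
  expect_identical(d1, d2)
  expect_identical(d1$n_digitations, as.integer(ph$truth$n_digitations))
  v2 <- reload_mirrored(ph$volume)
  expect_identical(measure_digitations(v2), d1)
})

test_that("random digitated slices classify CA3 at construction accuracy", {
  correct <- 0L
  total <- 0L
  for (s in 1:30) {
    cfg <- withr::with_seed(s, list(
      n = sample(2:4, 1), at_peak = runif(1) < 0.5, idx = runif(1)
    ))
    pos <- if (cfg$at_peak) peak_positions(cfg$n) else trough_positions(cfg$n)
    target <- pos[1 + floor(cfg$idx * length(pos))]
    lab <- digitated_slice(cfg$n, 8, ca3_at = round(target))
    cls <- classify_ca3(digitation_profile(lab), ca3_superior_strip(lab))
    total <- total + 1L
    want <- if (cfg$at_peak) "on_top" else "in_between"
    if (cls$relation == want) correct <- correct + 1L
  }
  expect_identical(correct, total) # amplitude 8 >= 3x the prominence threshold
})
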