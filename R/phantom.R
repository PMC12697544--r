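# Synthetic hippocampus phantom: a label volume with hippocampus-like
# topology and exhaustively known ground truth, so that every measurement
# has an oracle without external data.
#
# Cross-section model (one coronal slice): a DG disc enclosed by an SRLM
# annulus, surrounded by a C-shaped CA ribbon partitioned by angle into
# CA1 (lateral), CA2 (superior) and CA3 (medial), opening inferiorly; an
# inferior horizontal plate carries the subicular complex running medially
# PaS | PrS | SUB and continues laterally as CA1, so the SUB-CA1 border is
# a vertical interface at a known, optionally z-ramping column. Head
# slices may carry digitations (sinusoidal bumps of the superior surface).

#' Phantom specification
#'
#' All slice indices are 1-based; `spacing` defaults to the 0.2 mm
#' isotropic resolution of ultra-high-field postmortem MRI. The default
#' geometry produces a 24 mm-wide, 50 mm-long volume with a 16.8 mm head,
#' 43.0 mm total length, and subfield extents that echo the mean
#' appearance/disappearance distances of histology-annotated specimens.
#'
#' @param shape Volume dimensions `c(nx, ny, nz)`.
#' @param spacing Isotropic voxel size in mm.
#' @param hemisphere `"right"` or `"left"`.
#' @param anterior_tip_z,uncal_apex_z,posterior_tip_z Landmark slices.
#' @param extents Named list of `c(z_start, z_end)` per subfield.
#' @param center Cross-section centre `c(cx, cy)` of the DG disc.
#' @param r_dg DG disc radius (voxels).
#' @param t_srlm SRLM annulus thickness (voxels).
#' @param t_ca CA ribbon thickness (voxels).
#' @param ca_start_deg Angle (degrees, counterclockwise; 0 = lateral,
#'   90 = superior) where CA1 begins.
#' @param spans_deg Angular spans `c(CA1=, CA2=, CA3=)` of the CA ribbon.
#' @param spans_deg_end Optional spans at the posterior tip; spans
#'   interpolate linearly along the body (constant if `NULL`).
#' @param srlm_arc Optional `c(start_deg, end_deg)`: draw the SRLM only on
#'   this angular range (sector phantoms for projection oracles). The full
#'   annulus (`NULL`) is required for DG enclosure.
#' @param draw_bar Draw the subicular plate (default `TRUE`).
#' @param bar_y Vertical extent `c(y0, y1)` of the plate.
#' @param bar_lateral_x Lateral end of the plate's CA1 stretch.
#' @param subic_width_vox Medial-lateral width of the subicular complex.
#' @param splits Fractions `c(SUB=, PrS=, PaS=)` of the subicular width,
#'   lateral to medial; must sum to 1.
#' @param border_rel `c(start, end)`: relative SUB-CA1 border position as a
#'   fraction of the full (anchor to lateral CA1 edge) width, at one slice
#'   posterior to the uncal apex and at the posterior tip; linear ramp in
#'   between emulates the posterior medial shift.
#' @param digitations `list(n =, amplitude =)` digitation count and bump
#'   amplitude (voxels) for head slices; `NULL` for none.
#' @param dropout_prob Per-slice probability of a segmentation gap.
#' @param dropout_range Optional `c(z0, z1)` restricting dropout.
#' @param jitter_vox SD (voxels) of per-slice boundary jitter applied to
#'   the SUB-CA1 border column and the ring radii, after ground truth is
#'   fixed (noise quantifies robustness; it never redefines truth).
#' @param require_enclosure Validate that the SRLM can enclose the DG.
#' @param seed Random seed for the noise channels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(120, 120, 250),
                         spacing = 0.2,
                         hemisphere = "right",
                         anterior_tip_z = 6L,
                         uncal_apex_z = 90L,
                         posterior_tip_z = 221L,
                         extents = NULL,
                         center = c(60, 64),
                         r_dg = 10,
                         t_srlm = 3,
                         t_ca = 6,
                         ca_start_deg = 280,
                         spans_deg = c(CA1 = 150, CA2 = 60, CA3 = 90),
                         spans_deg_end = NULL,
                         srlm_arc = NULL,
                         draw_bar = TRUE,
                         bar_y = c(30, 37),
                         bar_lateral_x = 70,
                         subic_width_vox = 40,
                         splits = c(SUB = 0.4613, PrS = 0.3855, PaS = 0.1533),
                         border_rel = c(start = 0.25, end = -0.05),
                         digitations = list(n = 3, amplitude = 6),
                         dropout_prob = 0,
                         dropout_range = NULL,
                         jitter_vox = 0,
                         require_enclosure = is.null(srlm_arc),
                         seed = 1L) {
  if (is.null(extents)) {
    extents <- list(
      SUB = c(anterior_tip_z, posterior_tip_z),
      CA1 = c(anterior_tip_z + 10L, posterior_tip_z),
      PrS = c(anterior_tip_z + 13L, posterior_tip_z - 38L),
      SRLM = c(anterior_tip_z + 24L, posterior_tip_z - 3L),
      DG = c(anterior_tip_z + 28L, posterior_tip_z - 7L),
      CA3 = c(anterior_tip_z + 36L, posterior_tip_z - 2L),
      PaS = c(anterior_tip_z + 50L, anterior_tip_z + 132L),
      CA2 = c(anterior_tip_z + 51L, posterior_tip_z - 8L)
    )
  }
  spec <- list(
    shape = as.integer(shape), spacing = spacing, hemisphere = hemisphere,
    anterior_tip_z = as.integer(anterior_tip_z),
    uncal_apex_z = as.integer(uncal_apex_z),
    posterior_tip_z = as.integer(posterior_tip_z),
    extents = lapply(extents, as.integer),
    center = center, r_dg = r_dg, t_srlm = t_srlm, t_ca = t_ca,
    ca_start_deg = ca_start_deg,
    spans_deg = spans_deg, spans_deg_end = spans_deg_end,
    srlm_arc = srlm_arc, draw_bar = draw_bar,
    bar_y = as.integer(bar_y), bar_lateral_x = as.integer(bar_lateral_x),
    subic_width_vox = as.integer(subic_width_vox),
    splits = splits, border_rel = border_rel,
    digitations = digitations,
    dropout_prob = dropout_prob, dropout_range = dropout_range,
    jitter_vox = jitter_vox, require_enclosure = require_enclosure,
    seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  spec$splits <- spec$splits / sum(spec$splits) # absorb printed-precision slack
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  err <- function(msg) rlang::abort(msg, class = "hippomorph_spec_error")
  if (spec$anterior_tip_z > spec$uncal_apex_z || spec$uncal_apex_z > spec$posterior_tip_z) {
    err("Landmarks must be ordered anterior tip <= uncal apex <= posterior tip.")
  }
  if (spec$posterior_tip_z > spec$shape[3] || spec$anterior_tip_z < 1L) {
    err("Landmarks outside the volume.")
  }
  for (lb in names(spec$extents)) {
    e <- spec$extents[[lb]]
    if (e[1] > e[2] || e[1] < 1L || e[2] > spec$shape[3]) {
      err(paste0("Extent of ", lb, " is invalid or outside the volume."))
    }
  }
  if (abs(sum(spec$splits) - 1) > 1e-3) err("Subicular splits must sum to 1.")
  if (sum(spec$spans_deg) > 360) err("CA angular spans must sum to <= 360 degrees.")
  if (spec$require_enclosure) {
    if (!is.null(spec$srlm_arc)) {
      err("DG enclosure requires a full SRLM annulus (srlm_arc must be NULL).")
    }
    dg <- spec$extents$DG
    srlm <- spec$extents$SRLM
    if (dg[1] < srlm[1] || dg[2] > srlm[2]) {
      err("DG extent must lie within the SRLM extent for enclosure.")
    }
  }
  r_out <- spec$r_dg + spec$t_srlm + spec$t_ca
  if (spec$center[1] - r_out < 1 || spec$center[1] + r_out > spec$shape[1] ||
    spec$center[2] - r_out < 1 || spec$center[2] + r_out > spec$shape[2]) {
    err("Ring geometry exceeds the in-plane volume bounds.")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d x %d @ %.2g mm, tip/apex/post = %d/%d/%d, seed %d\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing,
    x$anterior_tip_z, x$uncal_apex_z, x$posterior_tip_z, x$seed
  ))
  invisible(x)
}

# Relative SUB-CA1 border (fraction of full width) at slice z: constant
# anterior of the apex, linear ramp from apex+1 to the posterior tip.
border_rel_at <- function(spec, z) {
  z0 <- spec$uncal_apex_z + 1L
  z1 <- spec$posterior_tip_z
  r0 <- spec$border_rel[[1]]
  r1 <- spec$border_rel[[2]]
  if (z <= z0 || z1 == z0) {
    return(r0)
  }
  r0 + (r1 - r0) * (z - z0) / (z1 - z0)
}

spans_at <- function(spec, z) {
  if (is.null(spec$spans_deg_end)) {
    return(spec$spans_deg)
  }
  z0 <- spec$uncal_apex_z
  z1 <- spec$posterior_tip_z
  f <- min(1, max(0, (z - z0) / max(1L, z1 - z0)))
  spec$spans_deg + f * (spec$spans_deg_end - spec$spans_deg)
}

phantom_anchor_x <- function(spec) spec$center[1] - floor(spec$r_dg + spec$t_srlm + spec$t_ca)

phantom_full_width_vox <- function(spec) {
  r_out <- floor(spec$r_dg + spec$t_srlm + spec$t_ca)
  (spec$center[1] + r_out + 0.5) - phantom_anchor_x(spec)
}

phantom_border_x <- function(spec, z) {
  phantom_anchor_x(spec) + round(border_rel_at(spec, z) * phantom_full_width_vox(spec))
}

in_extent <- function(spec, label, z) {
  e <- spec$extents[[label]]
  !is.null(e) && z >= e[1] && z <= e[2]
}

#' Generate a phantom volume with ground truth
#'
#' Draws the label volume slice by slice from the spec, computes the exact
#' ground truth of every measurable quantity from the construction
#' parameters, and only then applies the noise channels (slice dropout,
#' boundary jitter), so recovery under noise quantifies robustness.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([hippo_volume()]), `landmarks`
#'   ([hippo_landmarks()]), `coverage` (logical per slice) and `truth`
#'   (list of ground-truth quantities; see Details).
#' @details `truth` contains: `extents` (tibble of per-subfield first/last
#'   slices, with `dg_enclosure_z`), `head_length_mm`, `total_length_mm`,
#'   `head_to_total_ratio_pct`, `appearance` (ordered tibble with gaps),
#'   `subicular(z)`/`border(z)` per-slice tables for the body increments,
#'   `srlm_props` (sector phantoms only), `n_digitations`.
#' @export
phantom_generate <- function(spec) {
  nx <- spec$shape[1]
  ny <- spec$shape[2]
  nz <- spec$shape[3]
  schema <- default_schema()
  code <- function(lb) schema_code(schema, lb)
  cx <- spec$center[1]
  cy <- spec$center[2]
  r_in_srlm <- spec$r_dg
  r_out_srlm <- spec$r_dg + spec$t_srlm
  r_out <- r_out_srlm + spec$t_ca

  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  truth <- phantom_truth(spec)

  jitter <- phantom_noise_draws(spec, nz)

  vox <- array(0L, dim = c(nx, ny, nz))
  # ring computations restricted to a bounding box around the annulus
  pad <- 2L + ceiling(3 * max(spec$jitter_vox, 0))
  bx <- max(1L, floor(cx - r_out - pad)):min(nx, ceiling(cx + r_out + pad))
  by <- max(1L, floor(cy - r_out - pad)):min(ny, ceiling(cy + r_out + pad))
  Xb <- X[bx, by]
  Yb <- Y[bx, by]
  RR <- sqrt((Xb - cx)^2 + (Yb - cy)^2)
  TH <- (atan2(Yb - cy, Xb - cx) * 180 / pi) %% 360
  for (z in seq(spec$anterior_tip_z, spec$posterior_tip_z)) {
    jb <- jitter$border[z]
    jr <- jitter$radius[z]
    lab <- matrix(0L, nx, ny)
    ring_lab <- matrix(0L, length(bx), length(by))

    # inferior plate: PaS | PrS | SUB | CA1 with a vertical SUB-CA1 border
    if (spec$draw_bar && in_extent(spec, "SUB", z)) {
      xb <- phantom_border_x(spec, z) + jb
      w <- subic_widths(spec)
      ys <- spec$bar_y[1]:spec$bar_y[2]
      sub_x <- (xb - w["SUB"]):(xb - 1L)
      lab[sub_x[sub_x >= 1], ys] <- code("SUB")
      if (in_extent(spec, "PrS", z)) {
        prs_x <- (xb - w["SUB"] - w["PrS"]):(xb - w["SUB"] - 1L)
        lab[prs_x[prs_x >= 1], ys] <- code("PrS")
      }
      if (in_extent(spec, "PaS", z)) {
        pas_x <- (xb - sum(w)):(xb - w["SUB"] - w["PrS"] - 1L)
        lab[pas_x[pas_x >= 1], ys] <- code("PaS")
      }
      if (in_extent(spec, "CA1", z)) {
        ca1_x <- xb:min(spec$bar_lateral_x, nx)
        lab[ca1_x[ca1_x >= 1], ys] <- code("CA1")
      }
    }

    # concentric ring: DG disc, SRLM annulus, CA ribbon by angle
    if (in_extent(spec, "DG", z)) {
      ring_lab[RR <= spec$r_dg + jr] <- code("DG")
    }
    if (in_extent(spec, "SRLM", z)) {
      m <- RR > r_in_srlm + jr & RR <= r_out_srlm + jr
      if (!is.null(spec$srlm_arc)) {
        m <- m & angle_in_range(TH, spec$srlm_arc[1], spec$srlm_arc[2])
      }
      ring_lab[m] <- code("SRLM")
    }
    spans <- spans_at(spec, z)
    s_off <- (TH - spec$ca_start_deg) %% 360
    ring <- RR > r_out_srlm + jr & RR <= r_out + jr
    cum <- cumsum(spans)
    for (k in seq_along(spans)) {
      lb <- names(spans)[k]
      if (!in_extent(spec, lb, z)) next
      lo <- if (k == 1L) 0 else cum[k - 1L]
      m <- ring & s_off >= lo & s_off < cum[k]
      ring_lab[m] <- code(lb)
    }
    nonzero <- ring_lab != 0L
    lab[bx, by][nonzero] <- ring_lab[nonzero]

    # head digitations: flatten the superior ring surface onto a base and
    # add n sinusoidal bumps, filling with each column's top label
    if (!is.null(spec$digitations) && spec$digitations$n > 0 &&
      z >= spec$anterior_tip_z && z <= spec$uncal_apex_z) {
      lab <- add_digitations(
        lab, cx, r_out, cy,
        spec$digitations$n, spec$digitations$amplitude
      )
    }

    vox[, , z] <- lab
  }

  covered <- rep(TRUE, nz)
  drop_range <- if (is.null(spec$dropout_range)) {
    c(spec$anterior_tip_z, spec$posterior_tip_z)
  } else {
    spec$dropout_range
  }
  if (spec$dropout_prob > 0) {
    zs <- drop_range[1]:drop_range[2]
    drop <- zs[jitter$dropout[zs] < spec$dropout_prob]
    if (length(drop) > 0L) {
      vox[, , drop] <- 0L
      covered[drop] <- FALSE
    }
  }

  volume <- hippo_volume(vox,
    spacing = spec$spacing, hemisphere = spec$hemisphere,
    schema = schema
  )
  landmarks <- hippo_landmarks(
    spec$anterior_tip_z, spec$uncal_apex_z, spec$posterior_tip_z
  )
  list(volume = volume, landmarks = landmarks, coverage = covered, truth = truth)
}

# noise draws are made up-front, in a fixed order, so that the volume is a
# deterministic function of (spec, seed) regardless of extent layout
phantom_noise_draws <- function(spec, nz) {
  withr::with_seed(spec$seed, {
    list(
      dropout = stats::runif(nz),
      border = if (spec$jitter_vox > 0) {
        as.integer(round(stats::rnorm(nz, 0, spec$jitter_vox)))
      } else {
        integer(nz)
      },
      radius = if (spec$jitter_vox > 0) stats::rnorm(nz, 0, spec$jitter_vox) else numeric(nz)
    )
  })
}

angle_in_range <- function(theta, lo, hi) {
  lo <- lo %% 360
  hi <- hi %% 360
  if (lo <= hi) theta >= lo & theta <= hi else theta >= lo | theta <= hi
}

subic_widths <- function(spec) {
  w_sub <- round(spec$splits[["SUB"]] * spec$subic_width_vox)
  w_prs <- round(spec$splits[["PrS"]] * spec$subic_width_vox)
  c(SUB = w_sub, PrS = w_prs, PaS = spec$subic_width_vox - w_sub - w_prs)
}

add_digitations <- function(lab, cx, r_out, cy, n, amplitude) {
  cols <- which(vapply(seq_len(nrow(lab)), function(x) {
    abs(x - cx) <= r_out && any(lab[x, ] > 0L & seq_len(ncol(lab)) > cy)
  }, logical(1)))
  if (length(cols) < 2L) {
    return(lab)
  }
  xl <- min(cols)
  xr <- max(cols)
  base_y <- as.integer(ceiling(cy + r_out + 1))
  for (x in cols) {
    u <- (x - xl) / (xr - xl)
    d <- round(amplitude * (0.5 + 0.5 * cos(2 * pi * n * u - pi)))
    top <- max(which(lab[x, ] > 0L))
    fill_to <- min(base_y + d, ncol(lab))
    if (fill_to > top) lab[x, (top + 1L):fill_to] <- lab[x, top]
  }
  lab
}

digitation_peak_columns <- function(spec) {
  r_out <- spec$r_dg + spec$t_srlm + spec$t_ca
  xl <- ceiling(spec$center[1] - r_out)
  xr <- floor(spec$center[1] + r_out)
  n <- spec$digitations$n
  xl + (2 * seq_len(n) - 1) / (2 * n) * (xr - xl)
}

# Exact ground truth from construction parameters (pre-noise).
phantom_truth <- function(spec) {
  dz <- spec$spacing
  labels <- names(spec$extents)
  ext <- tibble::tibble(
    label = labels,
    z_start = unname(vapply(labels, function(l) spec$extents[[l]][1], integer(1))),
    z_end = unname(vapply(labels, function(l) spec$extents[[l]][2], integer(1)))
  )
  head_mm <- (spec$uncal_apex_z - spec$anterior_tip_z) * dz
  total_mm <- (spec$posterior_tip_z - spec$anterior_tip_z) * dz

  order_labels <- c("SUB", "CA1", "DG", "CA3", "CA2")
  starts <- unname(vapply(order_labels, function(l) spec$extents[[l]][1], integer(1)))
  ord <- order(starts)
  app <- tibble::tibble(
    label = order_labels[ord], slice = starts[ord],
    gap_mm = c(NA, diff(starts[ord])) * dz
  )

  w <- subic_widths(spec)
  total_slices <- spec$posterior_tip_z - spec$anterior_tip_z
  body_z <- spec$uncal_apex_z + as.integer(round(seq(10, 50, 10) / 100 * total_slices))
  subic <- purrr::map_dfr(body_z, function(z) {
    has_pas <- in_extent(spec, "PaS", z)
    has_prs <- in_extent(spec, "PrS", z)
    denom <- w["SUB"] + ifelse(has_prs, w["PrS"], 0) + ifelse(has_pas, w["PaS"], 0)
    tibble::tibble(
      z = z,
      pct_SUB = unname(w["SUB"] / denom * 100),
      pct_PrS = ifelse(has_prs, unname(w["PrS"] / denom * 100), NA_real_),
      pct_PaS = ifelse(has_pas, unname(w["PaS"] / denom * 100), NA_real_)
    )
  })

  anchor_x <- phantom_anchor_x(spec)
  full_w <- phantom_full_width_vox(spec)
  dg_w <- (spec$center[1] + floor(spec$r_dg) + 0.5) - anchor_x
  border <- purrr::map_dfr(
    c(spec$uncal_apex_z + 1L, spec$uncal_apex_z + as.integer(round(20 / dz))),
    function(z) {
      xb <- phantom_border_x(spec, z)
      tibble::tibble(
        z = z, border_x = xb, anchor_x = anchor_x,
        pct_of_full_width = (xb - anchor_x) / full_w * 100,
        pct_of_dg_width = (xb - anchor_x) / dg_w * 100
      )
    }
  )

  srlm_props <- if (!is.null(spec$srlm_arc)) {
    spans <- spec$spans_deg
    stats::setNames(as.numeric(spans / sum(spans)), names(spans))
  } else {
    NULL
  }

  list(
    extents = ext,
    dg_enclosure_z = spec$extents$DG[1],
    anterior_ca3_z = spec$extents$CA3[1],
    head_length_mm = head_mm,
    total_length_mm = total_mm,
    head_to_total_ratio_pct = head_mm / total_mm * 100,
    appearance = app,
    subicular = subic,
    splits = stats::setNames(as.numeric(w / sum(w)), names(w)),
    border = border,
    srlm_props = srlm_props,
    n_digitations = if (is.null(spec$digitations)) 0L else spec$digitations$n
  )
}

#' Randomized phantom specification
#'
#' Draws a valid spec with randomized size, landmarks, subfield extents,
#' ring geometry, subicular splits and border ramp — the raw material for
#' property-style recovery tests ("over N random phantoms...").
#'
#' @param seed Integer seed (fully determines the spec).
#' @param ... Overrides passed on to [phantom_spec()] after randomization.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, prs_through_body = FALSE, ...) {
  withr::with_seed(seed, {
    nxy <- sample(100:120, 1)
    nz <- sample(200:240, 1)
    tip <- sample(4:8, 1)
    post <- nz - sample(4:10, 1)
    total <- post - tip
    head_slices <- round(stats::runif(1, 0.38, 0.45) * total)
    apex <- tip + head_slices
    r_dg <- sample(8:12, 1)
    t_ca <- sample(5:7, 1)
    r_out <- r_dg + 3 + t_ca
    cx <- sample((r_out + 52):(nxy - r_out - 2), 1)
    cy <- sample((r_out + 26):(nxy - r_out - 9), 1)
    splits <- c(
      SUB = stats::runif(1, 0.40, 0.52),
      PrS = stats::runif(1, 0.30, 0.45),
      PaS = stats::runif(1, 0.10, 0.22)
    )
    splits <- splits / sum(splits)
    W <- sample(36:44, 1)
    b0 <- stats::runif(1, 0.15, 0.30)
    b1 <- stats::runif(1, -0.12, 0.05)
    extents <- list(
      SUB = c(tip, post),
      CA1 = c(tip + sample(6:14, 1), post),
      PrS = c(
        tip + sample(12:18, 1),
        if (prs_through_body) post else post - sample(30:45, 1)
      ),
      SRLM = c(tip + sample(20:26, 1), post - sample(2:4, 1)),
      DG = c(tip + sample(27:32, 1), post - sample(5:9, 1)),
      CA3 = c(tip + sample(33:40, 1), post - sample(1:2, 1)),
      PaS = c(
        tip + sample(45:55, 1),
        if (prs_through_body) apex + round(0.55 * (post - apex)) else apex + sample(30:60, 1)
      ),
      CA2 = c(tip + sample(48:56, 1), post - sample(6:10, 1))
    )
    args <- list(
      shape = c(nxy, nxy, nz), anterior_tip_z = tip, uncal_apex_z = apex,
      posterior_tip_z = post, extents = extents, center = c(cx, cy),
      r_dg = r_dg, t_ca = t_ca, subic_width_vox = W, splits = splits,
      border_rel = c(start = b0, end = b1),
      bar_y = c(cy - r_out - 16, cy - r_out - 9),
      bar_lateral_x = cx + sample(8:12, 1),
      seed = sample.int(.Machine$integer.max, 1)
    )
  })
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

#' Sector phantom for projection oracles
#'
#' A phantom whose SRLM is drawn only on an angular arc fully lateral to
#' the medial DG point, with CA sectors spanning exactly that arc; the
#' expected lateral-SRLM proportions are then the angular fractions.
#'
#' @param spans_deg `c(CA1=, CA2=, CA3=)` spans in degrees, summing to at
#'   most 180 (the arc is placed in the lateral half-plane).
#' @param ... Overrides passed to [phantom_spec()].
#' @return A [phantom_spec()] with `srlm_arc` set and the plate disabled.
#' @export
sector_phantom_spec <- function(spans_deg = c(CA1 = 150, CA2 = 20, CA3 = 10), ...) {
  total <- sum(spans_deg)
  if (total > 180 + 1e-6) {
    rlang::abort("Sector spans must sum to <= 180 degrees.",
      class = "hippomorph_spec_error"
    )
  }
  start <- -total / 2
  phantom_spec(
    spans_deg = spans_deg,
    ca_start_deg = start,
    srlm_arc = c(start, start + total),
    draw_bar = FALSE,
    digitations = NULL,
    ...
  )
}

#' Read or write a phantom spec as YAML
#'
#' @param path File path.
#' @return `read_phantom_spec()` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  for (nm in c("spans_deg", "spans_deg_end", "splits", "border_rel")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  }
  do.call(phantom_spec, obj)
}

#' @rdname read_phantom_spec
#' @param spec A [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$extents <- lapply(obj$extents, as.integer)
  for (nm in c("spans_deg", "spans_deg_end", "splits", "border_rel")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.list(obj[[nm]]) # keep names in YAML
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}
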