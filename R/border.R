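# Relative medial-lateral position of the SUB-CA1 border in body slices,
# measured from a medial anchor point against the full (CA+DG) width or the
# DG width.

#' Medial anchor point of a body slice
#'
#' The anchor is found by taking the most medial CA3 or DG voxel (whichever
#' subfield reaches furthest medially), then marching straight down
#' (inferior, -y) from the most inferior CA3/DG voxel in that column until
#' the first SUB or CA1 voxel. If nothing is hit inferiorly, a superior
#' march is attempted with a warning (folded geometry); if that also fails
#' the slice is unusable.
#'
#' @param ca3,dg,sub,ca1 Logical in-plane masks.
#' @return Named numeric `c(x, y)` of the anchor voxel.
#' @export
medial_anchor <- function(ca3, dg, sub, ca1) {
  seed <- ca3 | dg
  target <- sub | ca1
  if (!any(seed)) {
    rlang::abort("Neither CA3 nor DG present; no medial anchor.",
      class = "hippomorph_anchor_error"
    )
  }
  if (!any(target)) {
    rlang::abort("Neither SUB nor CA1 present; no medial anchor.",
      class = "hippomorph_anchor_error"
    )
  }
  sc <- mask_coords(seed)
  x_star <- min(sc[, 1])
  y_start <- min(sc[sc[, 1] == x_star, 2])
  ys_down <- if (y_start > 1L) seq(y_start - 1L, 1L) else integer(0)
  hit <- ys_down[target[x_star, ys_down]]
  if (length(hit) > 0L) {
    return(c(x = x_star, y = hit[1]))
  }
  rlang::warn("No SUB/CA1 inferior to the medial anchor column; trying a superior march.")
  y_top <- max(sc[sc[, 1] == x_star, 2])
  ys_up <- if (y_top < ncol(dg)) seq(y_top + 1L, ncol(dg)) else integer(0)
  hit <- ys_up[target[x_star, ys_up]]
  if (length(hit) > 0L) {
    return(c(x = x_star, y = hit[1]))
  }
  rlang::abort("March from the medial CA3/DG voxel never reaches SUB or CA1.",
    class = "hippomorph_anchor_error"
  )
}

#' SUB-CA1 border position relative to reference widths
#'
#' The border interface is the set of CA1 voxels 8-adjacent to SUB voxels;
#' its "midpoint, if at an angle" is the mean x of those voxels, through
#' which the vertical border line runs. Widths use the voxel-edge
#' convention laterally (lateral edge at max x + 0.5 voxel):
#' full width = anchor to the lateral CA1 edge, DG width = anchor to the
#' lateral DG edge. The relative position is
#' `(border_line_x - anchor_x) * dx / width * 100` and may be negative when
#' the border lies medial to the anchor.
#'
#' @param ca1,sub,dg Logical in-plane masks.
#' @param anchor Anchor point from [medial_anchor()].
#' @param spacing In-plane voxel size in mm.
#' @return One-row tibble: `anchor_x`, `anchor_y`, `border_line_x`,
#'   `full_width_mm`, `dg_width_mm`, `pct_of_full_width`, `pct_of_dg_width`.
#' @export
border_position <- function(ca1, sub, dg, anchor, spacing = 0.2) {
  if (!any(ca1) || !any(dg)) {
    rlang::abort("CA1 and DG must be non-empty for a border measurement.",
      class = "hippomorph_border_error"
    )
  }
  cc <- mask_coords(ca1)
  nb <- neighbourhood_8(cc, nrow(ca1), ncol(ca1))
  touch <- nb$inside & sub[cbind(pmax(nb$x, 1L), pmax(nb$y, 1L))]
  iface_rows <- unique(ceiling(which(touch) / 8L))
  if (length(iface_rows) == 0L) {
    rlang::abort("No SUB-CA1 adjacency on this slice; border absent.",
      class = "hippomorph_border_error"
    )
  }
  border_x <- mean(cc[iface_rows, 1])
  lat_ca1 <- max(cc[, 1]) + 0.5
  lat_dg <- max(mask_coords(dg)[, 1]) + 0.5
  full_w <- (lat_ca1 - anchor["x"]) * spacing
  dg_w <- (lat_dg - anchor["x"]) * spacing
  if (full_w <= 0 || dg_w <= 0) {
    rlang::abort("Non-positive reference width; slice unusable.",
      class = "hippomorph_border_error"
    )
  }
  rel <- (border_x - anchor["x"]) * spacing
  tibble::tibble(
    anchor_x = unname(anchor["x"]), anchor_y = unname(anchor["y"]),
    border_line_x = border_x,
    full_width_mm = unname(full_w), dg_width_mm = unname(dg_w),
    pct_of_full_width = unname(rel / full_w * 100),
    pct_of_dg_width = unname(rel / dg_w * 100)
  )
}

measure_border_slice <- function(volume, z) {
  ca1 <- slice_mask(volume, z, "CA1")
  ca3 <- slice_mask(volume, z, "CA3")
  sub <- slice_mask(volume, z, "SUB")
  dg <- slice_mask(volume, z, "DG")
  anchor <- medial_anchor(ca3, dg, sub, ca1)
  border_position(ca1, sub, dg, anchor, spacing = volume$spacing[1])
}

#' Border position at standard long-axis offsets
#'
#' Measures the SUB-CA1 border one slice posterior to the uncal apex
#' ("0 mm") and at 20 mm posterior to the apex. If the target slice is
#' unusable (missing labels, no SUB-CA1 adjacency), neighbouring slices are
#' tried alternating +/-1, +/-2, ... up to `tolerance_mm`; if none works the
#' offset is reported absent (`NA` row) rather than failing the case.
#'
#' @param volume A [hippo_volume()].
#' @param landmarks A [hippo_landmarks()].
#' @param offsets_mm Offsets posterior to the uncal apex, in mm.
#' @param tolerance_mm Search half-window around the target slice.
#' @return A tibble with one row per offset: `offset_mm`, `z_target`,
#'   `z_used` (`NA` if no usable slice) and the columns of
#'   [border_position()].
#' @export
measure_border_at_offsets <- function(volume, landmarks, offsets_mm = c(0, 20),
                                      tolerance_mm = 3) {
  dz <- volume$spacing[3]
  nz <- n_slices(volume)
  purrr::map_dfr(offsets_mm, function(off) {
    target <- if (off == 0) {
      landmarks$uncal_apex_z + 1L
    } else {
      landmarks$uncal_apex_z + as.integer(round(off / dz))
    }
    max_step <- as.integer(round(tolerance_mm / dz))
    deltas <- c(0L, as.vector(rbind(seq_len(max_step), -seq_len(max_step))))
    for (d in deltas) {
      z <- target + d
      if (z < 1L || z > nz) next
      res <- tryCatch(measure_border_slice(volume, z), error = function(e) NULL)
      if (!is.null(res)) {
        return(cbind(tibble::tibble(offset_mm = off, z_target = target, z_used = z), res))
      }
    }
    tibble::tibble(
      offset_mm = off, z_target = target, z_used = NA_integer_,
      anchor_x = NA_real_, anchor_y = NA_real_, border_line_x = NA_real_,
      full_width_mm = NA_real_, dg_width_mm = NA_real_,
      pct_of_full_width = NA_real_, pct_of_dg_width = NA_real_
    )
  })
}
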