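# Digitation counting on the anterior-CA3 slice and classification of CA3
# relative to the digitations and the hippocampal width. The paper-style
# visual judgement is operationalized with explicit, configurable
# thresholds (see `digitation_config()`).

#' Thresholds for the digitation classification
#'
#' @param prominence_voxels Minimum peak prominence, in voxels, for a bump
#'   of the superior surface to count as a digitation.
#' @param on_top_frac Fraction of CA3 columns near a peak at or above which
#'   the relation is `on_top`.
#' @param in_between_frac Fraction at or below which it is `in_between`.
#' @param peak_window_frac Half-window around a peak, as a fraction of the
#'   median peak spacing, within which a column counts as "near a peak".
#' @return A named list of thresholds.
#' @export
digitation_config <- function(prominence_voxels = 2L, on_top_frac = 0.7,
                              in_between_frac = 0.3, peak_window_frac = 0.25) {
  list(
    prominence_voxels = prominence_voxels, on_top_frac = on_top_frac,
    in_between_frac = in_between_frac, peak_window_frac = peak_window_frac
  )
}

#' Superior-surface digitation profile of a slice
#'
#' Builds the superior surface height `y_top(x)` over the hippocampal
#' grey-matter footprint (any non-background label), smooths it with a
#' 3-column moving average, and counts local maxima with prominence at
#' least `prominence_voxels` as digitations. A flat or single-bump surface
#' yields one digitation.
#'
#' @param labels Integer label matrix of the slice (see [slice_labels()]).
#' @param prominence_voxels Peak prominence threshold in voxels.
#' @return A `digitation_profile` object: list with `x` (footprint
#'   columns), `y_top`, `y_smooth`, `peaks_x`, `troughs_x`, `n_digitations`.
#' @export
digitation_profile <- function(labels, prominence_voxels = 2L) {
  footprint_cols <- which(apply(labels > 0L, 1, any))
  if (length(footprint_cols) < 5L) {
    rlang::abort("Hippocampal footprint narrower than 5 columns.",
      class = "hippomorph_profile_error"
    )
  }
  xs <- seq(min(footprint_cols), max(footprint_cols))
  y_top <- vapply(xs, function(x) {
    ys <- which(labels[x, ] > 0L)
    if (length(ys) == 0L) NA_real_ else max(ys)
  }, numeric(1))
  y_filled <- fill_na_linear(y_top)
  y_smooth <- stats::filter(y_filled, rep(1 / 3, 3), sides = 2)
  y_smooth[1] <- y_filled[1]
  y_smooth[length(y_smooth)] <- y_filled[length(y_filled)]
  y_smooth <- as.numeric(y_smooth)
  peaks <- find_peaks(y_smooth, prominence = prominence_voxels)
  if (length(peaks) == 0L) {
    peaks <- as.integer(round(which.max(y_smooth))) # single plateau peak
  }
  troughs <- integer(0)
  if (length(peaks) > 1L) {
    troughs <- vapply(seq_len(length(peaks) - 1L), function(i) {
      seg <- peaks[i]:peaks[i + 1L]
      seg[which.min(y_smooth[seg])]
    }, integer(1))
  }
  structure(
    list(
      x = xs, y_top = y_top, y_smooth = y_smooth,
      peaks_x = xs[peaks], troughs_x = xs[troughs],
      n_digitations = length(peaks)
    ),
    class = "digitation_profile"
  )
}

#' @export
print.digitation_profile <- function(x, ...) {
  cat(sprintf(
    "<digitation_profile> %d digitation(s), peaks at x = %s\n",
    x$n_digitations, paste(x$peaks_x, collapse = ", ")
  ))
  invisible(x)
}

fill_na_linear <- function(y) {
  if (!anyNA(y)) {
    return(y)
  }
  ok <- which(!is.na(y))
  stats::approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
}

#' Most anterior slice with CA3 in the superior CA strip
#'
#' Scans anterior to posterior for the first slice where at least one CA3
#' voxel lies strictly superior to every DG/SRLM voxel in its own or an
#' adjacent column. When a candidate slice has no DG or SRLM at all, CA3
#' above the footprint's median height is accepted with a warning.
#'
#' @param volume A [hippo_volume()].
#' @param coverage Optional per-slice coverage vector.
#' @return 1-based slice index or `NA_integer_`.
#' @export
anterior_ca3_slice <- function(volume, coverage = NULL) {
  counts <- slice_label_counts(volume, "CA3")
  for (z in which(counts > 0L)) {
    lab <- slice_labels(volume, z)
    strip <- ca3_superior_strip(lab, volume$schema)
    if (any(strip)) {
      return(z)
    }
  }
  NA_integer_
}

#' CA3 voxels superior to the DG/SRLM roof
#'
#' @param labels Integer label matrix.
#' @param schema A [subfield_schema()].
#' @return Logical mask of CA3 voxels with `y` strictly greater than the
#'   maximum DG/SRLM `y` within one column of their own.
#' @export
ca3_superior_strip <- function(labels, schema = default_schema()) {
  ca3 <- labels == schema_code(schema, "CA3")
  roofsrc <- labels == schema_code(schema, "DG") | labels == schema_code(schema, "SRLM")
  out <- matrix(FALSE, nrow(labels), ncol(labels))
  if (!any(ca3)) {
    return(out)
  }
  if (!any(roofsrc)) {
    rlang::warn("No DG/SRLM on slice; using the footprint median height as the roof.")
    med_y <- stats::median(mask_coords(labels > 0L)[, 2])
    cc <- mask_coords(ca3)
    keep <- cc[, 2] > med_y
    out[cc[keep, , drop = FALSE]] <- TRUE
    return(out)
  }
  roof_y <- vapply(seq_len(nrow(labels)), function(x) {
    ys <- which(roofsrc[x, ])
    if (length(ys) == 0L) -Inf else max(ys)
  }, numeric(1))
  cc <- mask_coords(ca3)
  keep <- vapply(seq_len(nrow(cc)), function(i) {
    x <- cc[i, 1]
    cols <- max(1L, x - 1L):min(nrow(labels), x + 1L)
    roof <- max(roof_y[cols])
    is.finite(roof) && cc[i, 2] > roof
  }, logical(1))
  out[cc[keep, , drop = FALSE]] <- TRUE
  out
}

#' Classify CA3 relative to digitations and hippocampal width
#'
#' Relation: the fraction of CA3 strip columns lying within a quarter of
#' the median peak spacing of a digitation peak decides `on_top`
#' (>= `on_top_frac`), `in_between` (<= `in_between_frac`) or `both`.
#' Position: the column-count centroid of the CA3 strip against thirds of
#' the footprint extent gives `medial`, `midpoint` or `lateral`
#' (low x is medial in the canonical frame).
#'
#' @param profile A [digitation_profile()].
#' @param ca3_strip Logical mask of the CA3 superior strip
#'   (see [ca3_superior_strip()]).
#' @param config Thresholds from [digitation_config()].
#' @return One-row tibble: `relation`, `position`, `frac_near_peak`,
#'   `centroid_x`, `n_digitations`.
#' @export
classify_ca3 <- function(profile, ca3_strip, config = digitation_config()) {
  cols <- unique(mask_coords(ca3_strip)[, 1])
  if (length(cols) == 0L) {
    rlang::abort("Empty CA3 superior strip.", class = "hippomorph_profile_error")
  }
  peaks <- profile$peaks_x
  w <- if (length(peaks) >= 2L) {
    stats::median(diff(sort(peaks)))
  } else {
    (max(profile$x) - min(profile$x)) / 2
  }
  near <- vapply(cols, function(x) any(abs(x - peaks) <= config$peak_window_frac * w),
    logical(1)
  )
  frac <- mean(near)
  relation <- if (frac >= config$on_top_frac) {
    "on_top"
  } else if (frac <= config$in_between_frac) {
    "in_between"
  } else {
    "both"
  }
  centroid <- mean(mask_coords(ca3_strip)[, 1])
  lo <- min(profile$x)
  hi <- max(profile$x)
  t1 <- lo + (hi - lo) / 3
  t2 <- lo + 2 * (hi - lo) / 3
  position <- if (centroid < t1) "medial" else if (centroid > t2) "lateral" else "midpoint"
  tibble::tibble(
    relation = relation, position = position,
    frac_near_peak = frac, centroid_x = centroid,
    n_digitations = profile$n_digitations
  )
}

#' Digitation record for a case
#'
#' Finds the anterior-CA3 slice, builds the digitation profile there, and
#' classifies CA3.
#'
#' @param volume A [hippo_volume()].
#' @param coverage Optional per-slice coverage.
#' @param config Thresholds from [digitation_config()].
#' @return One-row tibble: `z`, `n_digitations`, `relation`, `position`
#'   (all `NA` when CA3 never reaches the superior strip).
#' @export
measure_digitations <- function(volume, coverage = NULL, config = digitation_config()) {
  z <- anterior_ca3_slice(volume, coverage)
  if (is.na(z)) {
    return(tibble::tibble(
      z = NA_integer_, n_digitations = NA_integer_,
      relation = NA_character_, position = NA_character_
    ))
  }
  lab <- slice_labels(volume, z)
  prof <- digitation_profile(lab, prominence_voxels = config$prominence_voxels)
  strip <- ca3_superior_strip(lab, volume$schema)
  cls <- classify_ca3(prof, strip, config)
  tibble::tibble(
    z = z, n_digitations = prof$n_digitations,
    relation = cls$relation, position = cls$position
  )
}
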