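# Longitudinal extent measurements: where subfields appear and disappear
# along the anterior-posterior axis, and the length measures derived from
# the anatomical landmarks.

slice_label_counts <- function(volume, label) {
  code <- schema_code(volume$schema, label)
  d <- dim(volume$voxels)
  colSums(matrix(volume$voxels == code, d[1] * d[2], d[3]))
}

#' Detect the appearance slice of a subfield
#'
#' The appearance of a subfield is the first (most anterior) coronal slice
#' containing a connected cluster of at least `min_cluster` voxels of the
#' label, with in-plane 8-connectivity (voxels touching by edges *or*
#' corners). When the slice immediately anterior to a candidate slice lacks
#' segmentation coverage, a single voxel is sufficient on that candidate
#' (the cluster rule cannot be trusted across a gap).
#'
#' @param volume A [hippo_volume()].
#' @param label Subfield name.
#' @param coverage Optional logical per-slice coverage vector
#'   (see [read_coverage()]); `NULL` means fully covered.
#' @param min_cluster Cluster-size threshold (default 4 voxels).
#' @return The 1-based slice index, or `NA_integer_` if the label never
#'   satisfies the rule (absence is a value, not an error).
#' @export
detect_appearance <- function(volume, label, coverage = NULL, min_cluster = 4L) {
  covered <- coverage_or_default(coverage, volume)
  counts <- slice_label_counts(volume, label)
  for (z in which(counts > 0L)) {
    thr <- if (z > 1L && !covered[z - 1L]) 1L else min_cluster
    if (counts[z] < thr) next
    if (thr == 1L || largest_component_size(slice_mask(volume, z, label)) >= thr) {
      return(z)
    }
  }
  NA_integer_
}

#' Detect the disappearance slice of a subfield
#'
#' The most posterior slice containing at least one voxel of the label.
#' No cluster threshold is applied posteriorly; the disappearance criterion
#' is simply the last segmented slice.
#'
#' @inheritParams detect_appearance
#' @return 1-based slice index or `NA_integer_` if the label is absent.
#' @export
detect_disappearance <- function(volume, label) {
  counts <- slice_label_counts(volume, label)
  nz <- which(counts > 0L)
  if (length(nz) == 0L) {
    return(NA_integer_)
  }
  max(nz)
}

#' DG appearance by dark-band enclosure
#'
#' The dentate gyrus is identifiable on MRI as grey matter fully surrounded
#' by the dark band (SRLM). Its appearance slice is therefore the first
#' slice where some DG connected component's entire 8-neighbourhood boundary
#' consists of DG or SRLM voxels (components touching the image edge or any
#' other label are not enclosed).
#'
#' @inheritParams detect_appearance
#' @return 1-based slice index or `NA_integer_`.
#' @export
dg_enclosure_appearance <- function(volume) {
  dg_code <- schema_code(volume$schema, "DG")
  srlm_code <- schema_code(volume$schema, "SRLM")
  counts <- slice_label_counts(volume, "DG")
  for (z in which(counts > 0L)) {
    lab <- slice_labels(volume, z)
    if (slice_has_enclosed_dg(lab, dg_code, srlm_code)) {
      return(z)
    }
  }
  NA_integer_
}

slice_has_enclosed_dg <- function(lab, dg_code, srlm_code) {
  mask <- lab == dg_code
  comps <- label_components_8(mask)
  ncomp <- max(comps)
  if (ncomp == 0L) {
    return(FALSE)
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  for (k in seq_len(ncomp)) {
    coords <- mask_coords(comps == k)
    nb <- neighbourhood_8(coords, nr, nc)
    if (!all(nb$inside)) next # touches the image edge
    vals <- lab[cbind(nb$x, nb$y)]
    if (all(vals == dg_code | vals == srlm_code)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Head length from landmarks
#'
#' Distance from the anterior hippocampal tip to the posterior tip of the
#' uncal apex: `(uncal_apex_z - anterior_tip_z) * dz` mm.
#'
#' @param landmarks A [hippo_landmarks()].
#' @param spacing Voxel spacing in mm (scalar or length 3; the z component
#'   is used).
#' @return Head length in mm.
#' @export
head_length <- function(landmarks, spacing = 0.2) {
  dz <- spacing[length(spacing)]
  if (is.na(landmarks$anterior_tip_z) || is.na(landmarks$uncal_apex_z)) {
    rlang::abort("Head length needs both the anterior tip and the uncal apex.",
      class = "hippomorph_landmark_error"
    )
  }
  len <- (landmarks$uncal_apex_z - landmarks$anterior_tip_z) * dz
  if (len == 0) {
    rlang::warn("Degenerate head length of 0 mm (anterior tip equals uncal apex).")
  }
  len
}

#' Head length, total length and their ratio
#'
#' Total length runs from the anterior tip to the most posterior hippocampal
#' slice; the ratio is head length divided by total length, in percent.
#' When the posterior tip is flagged undeterminable, total length and ratio
#' are `NA` while head length is still reported.
#'
#' @inheritParams head_length
#' @return A one-row tibble with `head_length_mm`, `total_length_mm`,
#'   `head_to_total_ratio_pct`.
#' @export
total_length_and_ratio <- function(landmarks, spacing = 0.2) {
  dz <- spacing[length(spacing)]
  head_mm <- head_length(landmarks, spacing)
  if (landmarks$posterior_undeterminable || is.na(landmarks$posterior_tip_z)) {
    return(tibble::tibble(
      head_length_mm = head_mm,
      total_length_mm = NA_real_,
      head_to_total_ratio_pct = NA_real_
    ))
  }
  total_mm <- (landmarks$posterior_tip_z - landmarks$anterior_tip_z) * dz
  tibble::tibble(
    head_length_mm = head_mm,
    total_length_mm = total_mm,
    head_to_total_ratio_pct = head_mm / total_mm * 100
  )
}

#' Order of subfield appearance in the hippocampal head
#'
#' Determines appearance slices for the requested subfields and sorts them
#' anterior to posterior. Rules per subfield: `SUB` appears on the anterior
#' tip slice by definition (a QC warning is raised when that slice carries
#' no SUB voxel); `DG` uses the dark-band enclosure rule
#' ([dg_enclosure_appearance()]); all other subfields use the cluster rule
#' ([detect_appearance()]). Gaps are distances to the previously appearing
#' subfield, in mm and as % of head length; ties are simultaneous (gap 0).
#'
#' @inheritParams detect_appearance
#' @param labels Character vector of subfield names to order.
#' @param landmarks A [hippo_landmarks()].
#' @return A tibble sorted by appearance with columns `label`, `slice`,
#'   `distance_from_tip_mm`, `distance_from_tip_pct`, `gap_mm`, `gap_pct`,
#'   `tied_with_previous`.
#' @export
appearance_order <- function(volume, labels = c("SUB", "CA1", "DG", "CA3", "CA2"),
                             landmarks, coverage = NULL) {
  dz <- volume$spacing[3]
  head_mm <- head_length(landmarks, volume$spacing)
  slices <- vapply(labels, function(lb) {
    if (lb == "SUB") {
      if (sum(slice_mask(volume, landmarks$anterior_tip_z, "SUB")) == 0L) {
        rlang::warn("Anterior tip slice carries no SUB label (QC).")
      }
      landmarks$anterior_tip_z
    } else if (lb == "DG") {
      dg_enclosure_appearance(volume)
    } else {
      detect_appearance(volume, lb, coverage = coverage)
    }
  }, integer(1))
  out <- tibble::tibble(label = labels, slice = unname(slices))
  out <- out[order(out$slice), ]
  out$distance_from_tip_mm <- (out$slice - landmarks$anterior_tip_z) * dz
  out$distance_from_tip_pct <- out$distance_from_tip_mm / head_mm * 100
  prev <- c(NA_integer_, out$slice[-nrow(out)])
  out$gap_mm <- (out$slice - prev) * dz
  out$gap_pct <- out$gap_mm / head_mm * 100
  out$tied_with_previous <- !is.na(out$gap_mm) & out$gap_mm == 0
  out
}

#' Subfield presence near the posterior tip
#'
#' Reports, for each offset (default 2 mm and 1 mm anterior to the most
#' posterior hippocampal slice), whether each subfield has at least one
#' labeled voxel on the target slice. Offsets that are not integer multiples
#' of dz are rounded to the nearest slice (ties toward anterior). When the
#' target slice lacks coverage, presence is `NA` (undetermined) so cohort
#' denominators can exclude it.
#'
#' @inheritParams appearance_order
#' @param offsets_mm Offsets anterior to the posterior tip, in mm.
#' @return A tibble with columns `offset_mm`, `z`, `label`, `present`.
#' @export
tail_presence <- function(volume, labels = c("SUB", "CA1", "CA2", "CA3", "DG"),
                          landmarks, coverage = NULL, offsets_mm = c(2, 1)) {
  if (landmarks$posterior_undeterminable || is.na(landmarks$posterior_tip_z)) {
    rlang::abort("Tail presence needs a determinable posterior tip.",
      class = "hippomorph_landmark_error"
    )
  }
  covered <- coverage_or_default(coverage, volume)
  dz <- volume$spacing[3]
  purrr::map_dfr(offsets_mm, function(off) {
    n_back <- floor(off / dz + 0.5) # round, ties toward anterior (larger shift)
    z <- landmarks$posterior_tip_z - as.integer(n_back)
    z <- max(1L, min(z, n_slices(volume)))
    lab <- slice_labels(volume, z)
    purrr::map_dfr(labels, function(lb) {
      present <- if (!covered[z]) {
        NA
      } else {
        any(lab == schema_code(volume$schema, lb))
      }
      tibble::tibble(offset_mm = off, z = z, label = lb, present = present)
    })
  })
}

#' Longitudinal extent record per subfield
#'
#' Combines appearance (cluster rule; enclosure rule for DG), disappearance
#' (last segmented slice) and the landmark-based lengths into one record per
#' subfield.
#'
#' @inheritParams appearance_order
#' @return A tibble with `label`, `first_slice`, `last_slice`,
#'   `appearance_from_tip_mm`, `appearance_from_tip_pct_head`,
#'   `length_mm`, `length_pct_total`.
#' @export
subfield_extents <- function(volume,
                             labels = c("SUB", "PrS", "PaS", "CA1", "CA2", "CA3", "DG"),
                             landmarks, coverage = NULL) {
  dz <- volume$spacing[3]
  head_mm <- head_length(landmarks, volume$spacing)
  total <- total_length_and_ratio(landmarks, volume$spacing)
  purrr::map_dfr(labels, function(lb) {
    first <- if (lb == "SUB") {
      landmarks$anterior_tip_z
    } else if (lb == "DG") {
      dg_enclosure_appearance(volume)
    } else {
      detect_appearance(volume, lb, coverage = coverage)
    }
    last <- detect_disappearance(volume, lb)
    len_mm <- if (is.na(first) || is.na(last)) NA_real_ else (last - first) * dz
    tibble::tibble(
      label = lb,
      first_slice = first,
      last_slice = last,
      appearance_from_tip_mm = (first - landmarks$anterior_tip_z) * dz,
      appearance_from_tip_pct_head = (first - landmarks$anterior_tip_z) * dz / head_mm * 100,
      length_mm = len_mm,
      length_pct_total = len_mm / total$total_length_mm * 100
    )
  })
}
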