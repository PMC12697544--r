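# Projection of the CA subfields onto the SRLM band ("flashlight"
# relabeling): each SRLM voxel lateral to the most medial DG point is
# assigned to the nearest CA subfield, and per-subfield volume proportions
# of the lateral SRLM are reported.

#' Most medial DG column on a slice
#'
#' @param dg Logical DG mask.
#' @return Minimum x over DG voxels (canonical frame: minimum x is most
#'   medial), or `NA_integer_` when DG is empty.
#' @export
medial_dg_point <- function(dg) {
  if (!any(dg)) {
    return(NA_integer_)
  }
  min(mask_coords(dg)[, 1])
}

#' Project CA subfields onto the lateral SRLM band
#'
#' The lateral SRLM mask consists of SRLM voxels with `x >= medial_dg_x`.
#' Each such voxel is assigned the label of its nearest CA1/CA2/CA3 voxel
#' (in-plane Euclidean distance); distance ties are broken by priority
#' CA3 > CA2 > CA1. When the SUB-CA1 interface lies lateral to
#' `medial_dg_x`, the interface midpoint is projected to its nearest
#' lateral-SRLM voxel and all band voxels medial (along the band path) of
#' that projection stay unassigned, so the proportions sum to less than 1.
#'
#' @param srlm,ca1,ca2,ca3 Logical in-plane masks.
#' @param sub Logical SUB mask (used only to locate the SUB-CA1 interface).
#' @param medial_dg_x Column index from [medial_dg_point()].
#' @param spacing In-plane voxel size in mm.
#' @return A one-row tibble: `medial_dg_x`, `n_srlm_total`, `n_CA1`,
#'   `n_CA2`, `n_CA3`, `n_unassigned`, `prop_CA1`, `prop_CA2`, `prop_CA3`,
#'   `sub_border_lateral_case`; the relabeled band is attached as the
#'   `relabeled` attribute (matrix coded 0 = unassigned, 1..3 = CA1..CA3).
#' @export
project_onto_srlm <- function(srlm, ca1, ca2, ca3, sub = NULL,
                              medial_dg_x, spacing = 0.2) {
  lateral <- srlm
  lateral[seq_len(min(nrow(srlm), max(medial_dg_x - 1L, 0L))), ] <- FALSE
  if (!any(lateral)) {
    rlang::abort("No SRLM voxels lateral to the medial DG point.",
      class = "hippomorph_projection_error"
    )
  }
  ca_masks <- list(CA1 = ca1, CA2 = ca2, CA3 = ca3)
  if (!any(ca1) && !any(ca2) && !any(ca3)) {
    rlang::abort("All three CA masks are empty; nothing to project.",
      class = "hippomorph_projection_error"
    )
  }
  band <- mask_coords(lateral)
  # nearest-CA assignment with CA3 > CA2 > CA1 tie priority
  best_d2 <- rep(Inf, nrow(band))
  assign <- integer(nrow(band))
  for (k in c(1L, 2L, 3L)) { # ascending priority: later >= wins ties
    m <- ca_masks[[k]]
    if (!any(m)) next
    np <- nearest_point(band, mask_coords(m))
    take <- np$dist2 <= best_d2
    assign[take] <- k
    best_d2[take] <- np$dist2[take]
  }

  sub_border_lateral <- FALSE
  if (!is.null(sub) && any(sub) && any(ca1)) {
    mid <- sub_ca1_interface_centroid(sub, ca1)
    if (!is.null(mid) && mid[1] >= medial_dg_x) {
      sub_border_lateral <- TRUE
      ord <- band_path_order(lateral, spacing)
      proj <- nearest_point(matrix(mid, nrow = 1), band)$index
      cutoff <- ord[proj]
      assign[ord < cutoff] <- 0L
    }
  }

  n_total <- nrow(band)
  n_by <- vapply(1:3, function(k) sum(assign == k), integer(1))
  relab <- matrix(0L, nrow(srlm), ncol(srlm))
  relab[band] <- assign
  out <- tibble::tibble(
    medial_dg_x = as.integer(medial_dg_x),
    n_srlm_total = n_total,
    n_CA1 = n_by[1], n_CA2 = n_by[2], n_CA3 = n_by[3],
    n_unassigned = n_total - sum(n_by),
    prop_CA1 = n_by[1] / n_total,
    prop_CA2 = n_by[2] / n_total,
    prop_CA3 = n_by[3] / n_total,
    sub_border_lateral_case = sub_border_lateral
  )
  attr(out, "relabeled") <- relab
  out
}

# Position of each band voxel along the band: skeletonize the lateral SRLM
# mask, take the skeleton path from its most medial endpoint, and give each
# band voxel the path position of its nearest skeleton point.
band_path_order <- function(lateral, spacing) {
  band <- mask_coords(lateral)
  skel <- prune_spurs(skeletonize(lateral), min_len = 3L)
  sg <- skeleton_graph(skel, dx = spacing)
  nv <- igraph::vcount(sg$graph)
  if (nv < 2L) {
    return(rank(band[, 1], ties.method = "first")) # tiny band: order by x
  }
  deg <- igraph::degree(sg$graph)
  endpoints <- which(deg <= 1L)
  if (length(endpoints) < 2L) endpoints <- seq_len(nv)
  medial_end <- endpoints[order(sg$coords[endpoints, 1], sg$coords[endpoints, 2])][1]
  dist_along <- igraph::distances(sg$graph, v = medial_end)[1, ]
  far_end <- endpoints[which.max(dist_along[endpoints])]
  path <- igraph::shortest_paths(sg$graph, from = medial_end, to = far_end,
    output = "vpath"
  )$vpath[[1]]
  path <- as.integer(path)
  np <- nearest_point(band, sg$coords[path, , drop = FALSE])
  np$index # position index along the path, 1 = medial end
}

#' SRLM projection profile along the hippocampal body
#'
#' Runs [project_onto_srlm()] on body slices selected by
#' [select_body_slices()]. Slices missing DG, missing lateral SRLM, or with
#' no CA voxels are skipped with a reason rather than failing the case.
#'
#' @param volume A [hippo_volume()].
#' @param landmarks A [hippo_landmarks()].
#' @param increments_pct Long-axis increments, % of total length.
#' @return A tibble, one row per increment, with `position_pct`, `z`, the
#'   columns of [project_onto_srlm()] and `skipped_reason`.
#' @export
srlm_profile <- function(volume, landmarks, increments_pct = seq(10, 50, by = 10)) {
  zs <- select_body_slices(landmarks, increments_pct)
  purrr::map2_dfr(zs, increments_pct, function(z, pct) {
    res <- tryCatch(
      {
        dg <- slice_mask(volume, z, "DG")
        mdx <- medial_dg_point(dg)
        if (is.na(mdx)) {
          rlang::abort("DG empty on slice.", class = "hippomorph_projection_error")
        }
        pr <- project_onto_srlm(
          srlm = slice_mask(volume, z, "SRLM"),
          ca1 = slice_mask(volume, z, "CA1"),
          ca2 = slice_mask(volume, z, "CA2"),
          ca3 = slice_mask(volume, z, "CA3"),
          sub = slice_mask(volume, z, "SUB"),
          medial_dg_x = mdx, spacing = volume$spacing[1]
        )
        attr(pr, "relabeled") <- NULL
        cbind(tibble::tibble(position_pct = pct, z = z), pr,
          skipped_reason = NA_character_
        )
      },
      error = function(e) {
        tibble::tibble(
          position_pct = pct, z = z, medial_dg_x = NA_integer_,
          n_srlm_total = NA_integer_, n_CA1 = NA_integer_, n_CA2 = NA_integer_,
          n_CA3 = NA_integer_, n_unassigned = NA_integer_,
          prop_CA1 = NA_real_, prop_CA2 = NA_real_, prop_CA3 = NA_real_,
          sub_border_lateral_case = NA, skipped_reason = conditionMessage(e)
        )
      }
    )
    tibble::as_tibble(res)
  })
}

#' Subfield occupancy from two border positions along the SRLM
#'
#' Curvilinear border-position studies report where each subfield border
#' falls along the SRLM length (in % from the medial DG point). The length
#' occupied by the subfield between two consecutive borders is simply their
#' difference; e.g. borders at 33% and 80% give a 47% occupancy.
#'
#' @param border_start_pct,border_end_pct Border positions in percent along
#'   the SRLM (start is the more medial border).
#' @return Occupancy in percent.
#' @export
ca_occupancy_from_borders <- function(border_start_pct, border_end_pct) {
  if (any(border_end_pct < border_start_pct)) {
    rlang::abort("`border_end_pct` must be lateral of (>=) `border_start_pct`.")
  }
  border_end_pct - border_start_pct
}
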