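# Medial-lateral proportions of the subicular complex (SUB / PrS / PaS)
# on coronal slices of the hippocampal body, measured along a mid-cortical
# ribbon centerline obtained from the medial-axis skeleton.

#' Select body slices at long-axis increments
#'
#' Slices are taken posterior from the uncal apex at percentages of total
#' hippocampal length: `z_k = uncal_apex_z + round(k% * total_slices)`.
#'
#' @param landmarks A [hippo_landmarks()].
#' @param increments_pct Percent increments (default 10..50 by 10).
#' @return Integer slice indices, named by increment.
#' @export
select_body_slices <- function(landmarks, increments_pct = seq(10, 50, by = 10)) {
  if (landmarks$posterior_undeterminable || is.na(landmarks$posterior_tip_z)) {
    rlang::abort("Body-slice selection needs a determinable posterior tip.",
      class = "hippomorph_landmark_error"
    )
  }
  total_slices <- landmarks$posterior_tip_z - landmarks$anterior_tip_z
  z <- landmarks$uncal_apex_z + as.integer(round(increments_pct / 100 * total_slices))
  if (any(z > landmarks$posterior_tip_z)) {
    rlang::abort("Requested increment lies posterior to the posterior tip.",
      class = "hippomorph_landmark_error"
    )
  }
  stats::setNames(z, paste0(increments_pct, "%"))
}

#' Trace the subicular-complex ribbon centerline on one slice
#'
#' Computes the medial-axis skeleton of the SUB + PrS + PaS union mask,
#' prunes spurs shorter than 3 voxels, and returns the shortest skeleton
#' path from the end nearest the SUB-CA1 interface (the lateral origin of
#' the ribbon) to the end nearest the medial extreme of the most medial
#' present region. Each path point carries the region label underneath it.
#'
#' @param sub,prs,pas,ca1 Logical in-plane masks (PaS and CA1 may be empty).
#' @param spacing In-plane voxel size in mm.
#' @return A `ribbon_path`: tibble with columns `x`, `y`, `region`, plus
#'   attributes `spacing` and `length_mm`.
#' @export
trace_ribbon <- function(sub, prs, pas = NULL, ca1 = NULL, spacing = 0.2) {
  if (is.null(pas)) pas <- matrix(FALSE, nrow(sub), ncol(sub))
  if (is.null(ca1)) ca1 <- matrix(FALSE, nrow(sub), ncol(sub))
  if (!any(sub) || !any(prs)) {
    rlang::abort("Ribbon tracing needs non-empty SUB and PrS masks.",
      class = "hippomorph_topology_error"
    )
  }
  union <- sub | prs | pas
  comps <- label_components_8(union)
  ncomp <- max(comps)
  if (ncomp > 1L) {
    rlang::abort(
      sprintf("Subicular-complex union mask has %d connected components (need 1).", ncomp),
      class = "hippomorph_topology_error"
    )
  }
  skel <- prune_spurs(skeletonize(union), min_len = 3L)
  sg <- skeleton_graph(skel, dx = spacing)
  if (igraph::vcount(sg$graph) < 2L) {
    rlang::abort("Degenerate slice: ribbon skeleton has fewer than 2 points.",
      class = "hippomorph_degenerate_error"
    )
  }
  deg <- igraph::degree(sg$graph)
  endpoints <- which(deg <= 1L)
  if (length(endpoints) < 2L) endpoints <- seq_len(igraph::vcount(sg$graph))

  start_ref <- sub_ca1_interface_centroid(sub, ca1)
  if (is.null(start_ref)) {
    # no CA1 on the slice: the ribbon originates at the lateral SUB border
    sc <- mask_coords(sub)
    start_ref <- colMeans(sc[sc[, 1] == max(sc[, 1]), , drop = FALSE])
  }
  medial_region <- if (any(pas)) pas else prs
  mc <- mask_coords(medial_region)
  end_ref <- colMeans(mc[mc[, 1] == min(mc[, 1]), , drop = FALSE])

  dstart <- (sg$coords[endpoints, 1] - start_ref[1])^2 + (sg$coords[endpoints, 2] - start_ref[2])^2
  start_cand <- endpoints[dstart == min(dstart)]
  if (length(start_cand) > 1L) {
    rlang::warn("Ribbon start ambiguous; tie broken toward the more lateral endpoint.")
    start_cand <- start_cand[which.max(sg$coords[start_cand, 1])]
  }
  start_node <- start_cand[1]
  # the end is the skeleton point (not necessarily a graph endpoint)
  # nearest the medial extreme, avoiding corner forks at the blunt end
  dend_all <- (sg$coords[, 1] - end_ref[1])^2 + (sg$coords[, 2] - end_ref[2])^2
  dend_all[start_node] <- Inf
  end_node <- which.min(dend_all)

  path <- igraph::shortest_paths(sg$graph, from = start_node, to = end_node,
    output = "vpath"
  )$vpath[[1]]
  xy <- sg$coords[as.integer(path), , drop = FALSE]
  region <- character(nrow(xy))
  region[sub[xy]] <- "SUB"
  region[prs[xy]] <- "PrS"
  region[pas[xy]] <- "PaS"
  region[region == ""] <- NA_character_
  region <- fill_nearest(region)
  # Thinning erodes the ends of the ribbon by about half its thickness;
  # extend the centerline along its end tangents to the true ribbon ends
  # so lengths and end-region shares are unbiased.
  ext_start <- tangent_extension(xy, union, from_start = TRUE)
  ext_end <- tangent_extension(xy, union, from_start = FALSE)
  if (!is.null(ext_start)) {
    regs <- vapply(seq_len(nrow(ext_start)), function(i) {
      region_at(ext_start[i, ], sub, prs, pas, region[1])
    }, character(1))
    xy <- rbind(ext_start, xy)
    region <- c(regs, region)
  }
  if (!is.null(ext_end)) {
    regs <- vapply(seq_len(nrow(ext_end)), function(i) {
      region_at(ext_end[i, ], sub, prs, pas, region[length(region)])
    }, character(1))
    xy <- rbind(xy, ext_end)
    region <- c(region, regs)
  }
  out <- tibble::tibble(x = xy[, 1], y = xy[, 2], region = region)
  attr(out, "spacing") <- spacing
  attr(out, "length_mm") <- smoothed_path_length(xy, dx = spacing)
  class(out) <- c("ribbon_path", class(out))
  out
}

sub_ca1_interface_centroid <- function(sub, ca1) {
  if (!any(ca1) || !any(sub)) {
    return(NULL)
  }
  sc <- mask_coords(sub)
  nb <- neighbourhood_8(sc, nrow(sub), ncol(sub))
  touching <- nb$inside & ca1[cbind(pmax(nb$x, 1L), pmax(nb$y, 1L))]
  rows <- unique(ceiling(which(touching) / 8L))
  if (length(rows) == 0L) {
    return(NULL)
  }
  colMeans(sc[rows, , drop = FALSE])
}

region_at <- function(pt, sub, prs, pas, fallback) {
  x <- max(1L, min(nrow(sub), as.integer(round(pt[1]))))
  y <- max(1L, min(ncol(sub), as.integer(round(pt[2]))))
  if (pas[x, y]) {
    "PaS"
  } else if (prs[x, y]) {
    "PrS"
  } else if (sub[x, y]) {
    "SUB"
  } else {
    fallback
  }
}

fill_nearest <- function(x) {
  na <- which(is.na(x))
  ok <- which(!is.na(x))
  if (length(na) == 0L || length(ok) == 0L) {
    return(x)
  }
  for (i in na) x[i] <- x[ok[which.min(abs(ok - i))]]
  x
}

#' Region proportions along a ribbon path
#'
#' Per-region percentage of the total centerline length. Segment lengths
#' come from the smoothed path; each segment contributes half its length to
#' the region of each endpoint, which splits interface voxels half-half
#' between adjacent regions. Boundary positions are reported as % from the
#' lateral (SUB-CA1) end.
#'
#' @param path A `ribbon_path` from [trace_ribbon()].
#' @return A one-row tibble: `pct_SUB`, `pct_PrS`, `pct_PaS` (`NA` when PaS
#'   is absent), `boundary_sub_prs_pct`, `boundary_prs_pas_pct`,
#'   `path_length_mm`.
#' @export
subicular_proportions <- function(path) {
  n <- nrow(path)
  if (n < 2L) {
    rlang::abort("Zero-length ribbon path.", class = "hippomorph_degenerate_error")
  }
  spacing <- attr(path, "spacing")
  sm <- smooth_polyline(cbind(path$x, path$y))
  seg <- sqrt(rowSums((sm[-1, , drop = FALSE] - sm[-n, , drop = FALSE])^2)) * spacing
  # half of each segment to the region at each of its endpoints
  contrib <- stats::setNames(numeric(3), c("SUB", "PrS", "PaS"))
  pos <- numeric(n) # arc position of each point from the lateral end
  pos[-1] <- cumsum(seg)
  for (i in seq_len(n - 1L)) {
    contrib[path$region[i]] <- contrib[path$region[i]] + seg[i] / 2
    contrib[path$region[i + 1L]] <- contrib[path$region[i + 1L]] + seg[i] / 2
  }
  total <- sum(contrib)
  pct <- contrib / total * 100
  has_pas <- any(path$region == "PaS")
  boundary_at <- function(a, b) {
    ix <- which(path$region[-n] == a & path$region[-1] == b)
    if (length(ix) == 0L) {
      return(NA_real_)
    }
    mean(pos[ix[1]] + seg[ix[1]] / 2) / total * 100
  }
  tibble::tibble(
    pct_SUB = unname(pct["SUB"]),
    pct_PrS = unname(pct["PrS"]),
    pct_PaS = if (has_pas) unname(pct["PaS"]) else NA_real_,
    boundary_sub_prs_pct = boundary_at("SUB", "PrS"),
    boundary_prs_pas_pct = boundary_at("PrS", "PaS"),
    path_length_mm = total
  )
}

#' Subicular-complex proportions along the body
#'
#' Runs [trace_ribbon()] + [subicular_proportions()] on body slices selected
#' by [select_body_slices()]. Slices where tracing fails (missing regions,
#' disconnected masks) are skipped and flagged.
#'
#' @param volume A [hippo_volume()].
#' @param landmarks A [hippo_landmarks()].
#' @param increments_pct Long-axis increments, % of total length.
#' @return A tibble with one row per usable slice: `position_pct`, `z`, the
#'   proportion columns of [subicular_proportions()], and `skipped_reason`
#'   (`NA` for usable slices).
#' @export
measure_subicular <- function(volume, landmarks, increments_pct = seq(10, 50, by = 10)) {
  zs <- select_body_slices(landmarks, increments_pct)
  purrr::map2_dfr(zs, increments_pct, function(z, pct) {
    res <- tryCatch(
      {
        p <- trace_ribbon(
          sub = slice_mask(volume, z, "SUB"),
          prs = slice_mask(volume, z, "PrS"),
          pas = slice_mask(volume, z, "PaS"),
          ca1 = slice_mask(volume, z, "CA1"),
          spacing = volume$spacing[1]
        )
        cbind(tibble::tibble(position_pct = pct, z = z), subicular_proportions(p),
          skipped_reason = NA_character_
        )
      },
      error = function(e) {
        tibble::tibble(
          position_pct = pct, z = z, pct_SUB = NA_real_, pct_PrS = NA_real_,
          pct_PaS = NA_real_, boundary_sub_prs_pct = NA_real_,
          boundary_prs_pas_pct = NA_real_, path_length_mm = NA_real_,
          skipped_reason = conditionMessage(e)
        )
      }
    )
    tibble::as_tibble(res)
  })
}
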