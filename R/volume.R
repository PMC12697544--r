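#' Labeled hippocampus volume in the canonical frame
#'
#' A `hippo_volume` wraps a 3D integer label array in a fixed anatomical
#' frame so that "medial", "lateral", "superior" and "anterior" mean the same
#' thing in every downstream measurement:
#'
#' * `+x` runs medial to lateral,
#' * `+y` runs inferior to superior,
#' * `+z` runs anterior to posterior (so a coronal slice is a fixed `z`).
#'
#' Slice indices are 1-based; distances between slices `z1 < z2` are
#' `(z2 - z1) * dz` mm (inter-slice distance, not an inclusive count).
#'
#' @param voxels 3D integer array indexed `[x, y, z]` already in the
#'   canonical frame.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param hemisphere `"left"` or `"right"`.
#' @param schema A [subfield_schema()]; every non-zero voxel value must
#'   appear in it.
#' @return An object of class `hippo_volume`.
#' @seealso [load_label_volume()] to construct one from a NIfTI file.
#' @export
hippo_volume <- function(voxels, spacing = 0.2, hemisphere = c("right", "left"),
                         schema = default_schema()) {
  hemisphere <- match.arg(hemisphere)
  if (length(dim(voxels)) != 3L) {
    rlang::abort("`voxels` must be a 3D array.", class = "hippomorph_format_error")
  }
  if (is.double(voxels)) {
    if (any(voxels != round(voxels), na.rm = TRUE)) {
      rlang::abort("Label volume contains non-integer values.",
        class = "hippomorph_format_error"
      )
    }
    storage.mode(voxels) <- "integer"
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) {
    rlang::abort("`spacing` must be strictly positive.", class = "hippomorph_format_error")
  }
  if (length(unique(spacing)) > 1L) {
    rlang::warn("Anisotropic spacing: all measurements assume isotropy in-plane.")
  }
  codes <- sort(unique(as.vector(voxels)))
  unknown <- setdiff(codes, unclass(schema))
  if (length(unknown) > 0L) {
    rlang::abort(
      paste0(
        "Volume contains label codes absent from the schema: ",
        paste(unknown, collapse = ", ")
      ),
      class = "hippomorph_schema_error"
    )
  }
  structure(
    list(
      voxels = voxels, spacing = as.numeric(spacing),
      hemisphere = hemisphere, schema = schema, canonical = TRUE
    ),
    class = "hippo_volume"
  )
}

#' @export
print.hippo_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<hippo_volume> %d x %d x %d voxels, %.3g mm, %s hemisphere\n",
    d[1], d[2], d[3], x$spacing[1], x$hemisphere
  ))
  counts <- label_counts(x)
  cat("  labeled voxels:", sum(counts$n), "\n")
  invisible(x)
}

#' @export
dim.hippo_volume <- function(x) dim(x$voxels)

n_slices <- function(volume) dim(volume$voxels)[3]

#' Per-label voxel counts
#'
#' @param volume A [hippo_volume()].
#' @return A tibble with columns `label` and `n`.
#' @export
label_counts <- function(volume) {
  sch <- unclass(volume$schema)
  sch <- sch[names(sch) != "background"]
  tab <- tabulate(volume$voxels + 1L, nbins = max(sch) + 1L)
  tibble::tibble(label = names(sch), n = tab[sch + 1L])
}

#' Load a NIfTI label map into the canonical frame
#'
#' Reads a NIfTI-1 file, checks that it holds integer labels known to the
#' schema, and reorients it into the canonical frame using its qform/sform
#' metadata plus the hemisphere flag (so that `+x` is always lateral).
#'
#' @param path Path to a `.nii` / `.nii.gz` label map.
#' @inheritParams hippo_volume
#' @param orientation_hint Optional 3-letter orientation string (e.g.
#'   `"RAS"`, `"LPI"`) stating the axis meaning of the *stored* array, used
#'   only when the file carries no usable qform/sform. Without metadata and
#'   without a hint, loading fails with an orientation error.
#' @return A [hippo_volume()].
#' @export
load_label_volume <- function(path, schema = default_schema(),
                              hemisphere = c("right", "left"),
                              orientation_hint = NULL) {
  hemisphere <- match.arg(hemisphere)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  vox <- as.array(img)
  if (any(vox != round(vox), na.rm = TRUE)) {
    rlang::abort("NIfTI file does not contain integer label data.",
      class = "hippomorph_format_error"
    )
  }
  if (hdr$qform_code == 0L && hdr$sform_code == 0L) {
    if (is.null(orientation_hint)) {
      rlang::abort(
        paste0(
          "File carries no orientation metadata (qform and sform codes are 0); ",
          "pass `orientation_hint` (e.g. \"RAS\") to state the stored axis order."
        ),
        class = "hippomorph_orientation_error"
      )
    }
    ras <- reorient_array(vox, orientation_hint)
    perm <- axis_permutation(orientation_hint)
    spacing <- numeric(3)
    spacing[perm] <- abs(RNifti::pixdim(img))[1:3]
  } else {
    RNifti::orientation(img) <- "RAS"
    ras <- as.array(img)
    spacing <- abs(RNifti::pixdim(img))[1:3]
    storage.mode(ras) <- storage.mode(vox)
  }
  canon <- ras_to_canonical(ras, hemisphere)
  hippo_volume(canon,
    spacing = spacing[c(1, 3, 2)], hemisphere = hemisphere,
    schema = schema
  )
}

#' Save a canonical label volume as NIfTI
#'
#' Writes an RAS-oriented NIfTI-1 file; [load_label_volume()] on the result
#' (with the same hemisphere flag) reproduces the voxel array exactly.
#'
#' @param volume A [hippo_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_label_volume <- function(volume, path) {
  ras <- canonical_to_ras(volume$voxels, volume$hemisphere)
  sp <- volume$spacing[c(1, 3, 2)] # canonical (x,y,z) -> RAS (x,y,z)
  img <- RNifti::asNifti(ras)
  aff <- diag(c(sp, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# RAS array -> canonical (x medial->lateral, y inferior->superior,
# z anterior->posterior). RAS: +x right, +y anterior, +z superior.
ras_to_canonical <- function(ras, hemisphere) {
  canon <- aperm(ras, c(1, 3, 2)) # (R, S, A)
  canon <- canon[, , dim(canon)[3]:1, drop = FALSE] # A -> P
  if (hemisphere == "left") {
    canon <- canon[dim(canon)[1]:1, , , drop = FALSE] # right -> lateral flip
  }
  canon
}

canonical_to_ras <- function(canon, hemisphere) {
  if (hemisphere == "left") {
    canon <- canon[dim(canon)[1]:1, , , drop = FALSE]
  }
  canon <- canon[, , dim(canon)[3]:1, drop = FALSE]
  aperm(canon, c(1, 3, 2))
}

axis_permutation <- function(orientation) {
  letters3 <- strsplit(toupper(orientation), "")[[1]]
  axis_of <- c(R = 1, L = 1, A = 2, P = 2, S = 3, I = 3)
  unname(axis_of[letters3])
}

# Rearrange an array whose axes mean `orientation` (e.g. "LPI") into RAS.
reorient_array <- function(arr, orientation) {
  letters3 <- strsplit(toupper(orientation), "")[[1]]
  if (length(letters3) != 3L || !all(letters3 %in% c("R", "L", "A", "P", "S", "I"))) {
    rlang::abort("`orientation_hint` must be a 3-letter code such as \"RAS\".",
      class = "hippomorph_orientation_error"
    )
  }
  perm <- axis_permutation(orientation)
  if (anyDuplicated(perm)) {
    rlang::abort("`orientation_hint` must name three distinct axes.",
      class = "hippomorph_orientation_error"
    )
  }
  arr <- aperm(arr, order(perm))
  letters3 <- letters3[order(perm)]
  for (ax in 1:3) {
    if (letters3[ax] %in% c("L", "P", "I")) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- dim(arr)[ax]:1
      arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
  }
  arr
}

#' Extract a coronal slice mask for one label
#'
#' @param volume A [hippo_volume()].
#' @param z Slice index (1-based).
#' @param label Subfield name present in the schema.
#' @return A logical `nx x ny` matrix; `mask[x, y]` is `TRUE` iff voxel
#'   `(x, y, z)` carries the label's code.
#' @export
slice_mask <- function(volume, z, label) {
  nz <- n_slices(volume)
  if (z < 1L || z > nz) {
    rlang::abort(sprintf("Slice index %d out of range [1, %d].", z, nz),
      class = "hippomorph_index_error"
    )
  }
  volume$voxels[, , z] == schema_code(volume$schema, label)
}

#' Full label matrix of one coronal slice
#'
#' @inheritParams slice_mask
#' @return An integer `nx x ny` matrix of label codes.
#' @export
slice_labels <- function(volume, z) {
  nz <- n_slices(volume)
  if (z < 1L || z > nz) {
    rlang::abort(sprintf("Slice index %d out of range [1, %d].", z, nz),
      class = "hippomorph_index_error"
    )
  }
  volume$voxels[, , z]
}

#' Mirror a volume across the medial-lateral axis
#'
#' Reverses the x axis and flips the hemisphere flag, producing the
#' opposite-hemisphere specimen *as stored*. Because the canonical frame
#' defines `+x` as medial-to-lateral anatomically, the mirrored array is no
#' longer canonical (its `+x` runs lateral-to-medial); pass it through
#' [canonicalize_volume()] before in-plane measurements. Along-axis
#' (z-based) measurements are unaffected either way.
#'
#' @param volume A [hippo_volume()].
#' @return The mirrored [hippo_volume()] with `canonical = FALSE`.
#' @export
mirror_volume <- function(volume) {
  volume$voxels <- volume$voxels[dim(volume$voxels)[1]:1, , , drop = FALSE]
  volume$hemisphere <- if (volume$hemisphere == "right") "left" else "right"
  volume$canonical <- !volume$canonical
  volume
}

#' Restore the canonical frame of a mirrored volume
#'
#' Flips the x axis of a non-canonical (storage-mirrored) volume so that
#' `+x` is medial-to-lateral again. Applying [mirror_volume()] and then
#' `canonicalize_volume()` yields a volume whose every measurement equals
#' the original's — the hemisphere-invariance property.
#'
#' @param volume A [hippo_volume()].
#' @return A canonical [hippo_volume()].
#' @export
canonicalize_volume <- function(volume) {
  if (isTRUE(volume$canonical)) {
    return(volume)
  }
  volume$voxels <- volume$voxels[dim(volume$voxels)[1]:1, , , drop = FALSE]
  volume$canonical <- TRUE
  volume
}

#' Anterior/posterior landmarks of a case
#'
#' Landmarks locate the anterior hippocampal tip, the posterior tip of the
#' uncal apex (head/body boundary) and the most posterior hippocampal slice.
#' They require visual identification on the image and are therefore always
#' supplied, never auto-detected.
#'
#' @param anterior_tip_z,uncal_apex_z,posterior_tip_z 1-based slice indices.
#' @param posterior_undeterminable `TRUE` when the posterior tip could not be
#'   established; total length and the head/total ratio are then unavailable.
#' @return An object of class `hippo_landmarks`.
#' @export
hippo_landmarks <- function(anterior_tip_z, uncal_apex_z,
                            posterior_tip_z = NA_integer_,
                            posterior_undeterminable = is.na(posterior_tip_z)) {
  lm <- list(
    anterior_tip_z = as.integer(anterior_tip_z),
    uncal_apex_z = as.integer(uncal_apex_z),
    posterior_tip_z = as.integer(posterior_tip_z),
    posterior_undeterminable = isTRUE(posterior_undeterminable)
  )
  zs <- c(lm$anterior_tip_z, lm$uncal_apex_z, lm$posterior_tip_z)
  zs <- zs[!is.na(zs)]
  if (is.unsorted(zs)) {
    rlang::abort("Landmarks must satisfy anterior_tip_z <= uncal_apex_z <= posterior_tip_z.",
      class = "hippomorph_landmark_error"
    )
  }
  structure(lm, class = "hippo_landmarks")
}

#' @export
print.hippo_landmarks <- function(x, ...) {
  cat(sprintf(
    "<hippo_landmarks> tip=%d apex=%d posterior=%s\n",
    x$anterior_tip_z, x$uncal_apex_z,
    if (x$posterior_undeterminable) "undeterminable" else as.character(x$posterior_tip_z)
  ))
  invisible(x)
}

#' Read or write landmarks as a JSON sidecar
#'
#' @param path File path.
#' @return `read_landmarks()` returns a [hippo_landmarks()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hippo_landmarks(
    anterior_tip_z = obj$anterior_tip_z,
    uncal_apex_z = obj$uncal_apex_z,
    posterior_tip_z = if (is.null(obj$posterior_tip_z)) NA_integer_ else obj$posterior_tip_z,
    posterior_undeterminable = isTRUE(obj$posterior_undeterminable)
  )
}

#' @rdname read_landmarks
#' @param landmarks A [hippo_landmarks()].
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Per-slice segmentation coverage
#'
#' Histology-derived segmentations can miss slices (gaps between blocks,
#' torn sections). Coverage is a logical vector over slices; measurements
#' treat uncovered slices specially (e.g. the single-voxel fallback of the
#' appearance rule). `NULL` coverage means fully covered.
#'
#' @param path TSV file with columns `z` and `covered` (0/1 or TRUE/FALSE).
#' @param nz Number of slices in the volume.
#' @return A logical vector of length `nz`.
#' @export
read_coverage <- function(path, nz) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  covered <- rep(TRUE, nz)
  covered[tab$z] <- as.logical(tab$covered)
  covered
}

#' @rdname read_coverage
#' @param covered Logical vector of per-slice coverage.
#' @export
write_coverage <- function(covered, path) {
  readr::write_tsv(
    tibble::tibble(z = seq_along(covered), covered = as.integer(covered)),
    path
  )
  invisible(path)
}

coverage_or_default <- function(coverage, volume) {
  if (is.null(coverage)) rep(TRUE, n_slices(volume)) else coverage
}
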