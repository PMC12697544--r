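# Shared fixtures, all built in code.

blank_mask <- function(nx = 40, ny = 40) matrix(FALSE, nx, ny)

# Tiny canonical volume from a list of (x, y, z, label-name) rows.
mini_volume <- function(points, dims = c(20, 20, 20), spacing = 0.2,
                        hemisphere = "right") {
  sch <- default_schema()
  vox <- array(0L, dim = dims)
  for (p in points) {
    vox[p[[1]], p[[2]], p[[3]]] <- unclass(sch)[[p[[4]]]]
  }
  hippo_volume(vox, spacing = spacing, hemisphere = hemisphere, schema = sch)
}

# Horizontal three-region strip masks (SUB lateral, PaS medial), the
# analytic ribbon oracle: 60 columns x 6 rows, SUB 30 / PrS 18 / PaS 12.
strip_masks <- function(nx = 80, ny = 20) {
  sub <- blank_mask(nx, ny)
  prs <- blank_mask(nx, ny)
  pas <- blank_mask(nx, ny)
  sub[41:70, 8:13] <- TRUE
  prs[23:40, 8:13] <- TRUE
  pas[11:22, 8:13] <- TRUE
  list(sub = sub, prs = prs, pas = pas)
}

# Quarter-annulus ribbon masks with centerline radius `rc`, thickness 6.
arc_masks <- function(rc = 20, nn = 70, cx = 10, cy = 10) {
  X <- matrix(seq_len(nn), nn, nn)
  Y <- matrix(seq_len(nn), nn, nn, byrow = TRUE)
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  TH <- atan2(Y - cy, X - cx) * 180 / pi
  ring <- R >= rc - 3 & R <= rc + 3 & TH >= 0 & TH <= 90
  list(sub = ring & TH < 45, prs = ring & TH >= 45)
}

# The default anatomical phantom, generated once per test run.
.phantom_cache <- new.env(parent = emptyenv())
default_phantom <- function() {
  if (is.null(.phantom_cache$ph)) {
    .phantom_cache$ph <- phantom_generate(phantom_spec())
  }
  .phantom_cache$ph
}

# Mirror a saved volume in storage space and reload with the opposite
# hemisphere flag (the loader-level hemisphere-invariance route).
reload_mirrored <- function(volume) {
  f <- tempfile(fileext = ".nii.gz")
  save_label_volume(volume, f)
  img <- RNifti::readNifti(f)
  arr <- as.array(img)
  arr <- arr[dim(arr)[1]:1, , , drop = FALSE]
  out <- RNifti::asNifti(arr)
  sp <- volume$spacing[c(1, 3, 2)]
  aff <- diag(c(sp, 1))
  RNifti::sform(out) <- structure(aff, code = 2L)
  RNifti::qform(out) <- structure(aff, code = 1L)
  RNifti::pixdim(out) <- sp
  f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(out, f2)
  opposite <- if (volume$hemisphere == "right") "left" else "right"
  load_label_volume(f2, hemisphere = opposite)
}

# Synthetic covariates for a cohort of n cases, deterministic in seed.
synthetic_covariates <- function(case_ids, seed = 1) {
  n <- length(case_ids)
  withr::with_seed(seed, covariate_table(
    case_id = case_ids,
    dementia = rep_len(c(TRUE, FALSE), n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(rnorm(n, 75, 9)),
    fixation_days = round(runif(n, 20, 500)),
    pmi_hours = round(runif(n, 4, 28), 1)
  ))
}

make_cohort_manifest <- function(n, seed = 500) {
  specs <- lapply(seq_len(n), function(i) random_phantom_spec(seed + i))
  phs <- lapply(specs, phantom_generate)
  tibble::tibble(
    case_id = sprintf("PH%02d", seq_len(n)),
    volume = lapply(phs, `[[`, "volume"),
    landmarks = lapply(phs, `[[`, "landmarks")
  )
}

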