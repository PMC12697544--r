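# Cohort orchestration: run every measurement module per case, assemble
# outcome tables, and apply the statistics layer (Mann-Whitney U for
# dementia status and sex, Spearman for age / fixation time / postmortem
# interval, Benjamini-Hochberg FDR within each analysis family).

#' Measure one case
#'
#' Runs the full measurement battery on one volume: lengths, per-subfield
#' extents, appearance order, tail presence, subicular proportions, SRLM
#' projection profile, SUB-CA1 border at the standard offsets, and the
#' digitation record. Per-assay failures are captured as QC notes rather
#' than failing the case.
#'
#' @param volume A [hippo_volume()].
#' @param landmarks A [hippo_landmarks()].
#' @param coverage Optional logical per-slice coverage.
#' @param case_id Identifier carried into every output table.
#' @return A `hippo_case`: list of tibbles (`lengths`, `extents`, `order`,
#'   `tail`, `subicular`, `srlm`, `border`, `digitations`) plus `qc` notes
#'   and provenance.
#' @export
measure_case <- function(volume, landmarks, coverage = NULL, case_id = "case") {
  qc <- character(0)
  note <- function(e) {
    qc <<- c(qc, conditionMessage(e))
    NULL
  }
  run <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = note),
      warning = function(w) {
        qc <<- c(qc, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }
  add_id <- function(tbl) {
    if (is.null(tbl)) {
      return(NULL)
    }
    dplyr::mutate(tibble::as_tibble(tbl), case_id = case_id, .before = 1)
  }
  out <- list(
    case_id = case_id,
    lengths = add_id(run(total_length_and_ratio(landmarks, volume$spacing))),
    extents = add_id(run(subfield_extents(volume, landmarks = landmarks, coverage = coverage))),
    order = add_id(run(appearance_order(volume, landmarks = landmarks, coverage = coverage))),
    tail = add_id(run(tail_presence(volume, landmarks = landmarks, coverage = coverage))),
    subicular = add_id(run(measure_subicular(volume, landmarks))),
    srlm = add_id(run(srlm_profile(volume, landmarks))),
    border = add_id(run(measure_border_at_offsets(volume, landmarks))),
    digitations = add_id(run(measure_digitations(volume, coverage))),
    qc = qc,
    provenance = list(
      hemisphere = volume$hemisphere,
      spacing = volume$spacing,
      landmarks_hash = rlang::hash(unclass(landmarks)),
      config_hash = rlang::hash(list(version = "hippomorph-0.1.0"))
    )
  )
  structure(out, class = "hippo_case")
}

#' @export
print.hippo_case <- function(x, ...) {
  cat(sprintf(
    "<hippo_case> %s: head %.1f mm, total %s mm\n", x$case_id,
    x$lengths$head_length_mm,
    ifelse(is.na(x$lengths$total_length_mm), "NA", sprintf("%.1f", x$lengths$total_length_mm))
  ))
  if (length(x$qc) > 0) cat("  QC notes:", length(x$qc), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a measured case
#'
#' @param x A `hippo_case`.
#' @param record Which record to return: one of `"lengths"`, `"extents"`,
#'   `"order"`, `"tail"`, `"subicular"`, `"srlm"`, `"border"`,
#'   `"digitations"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.hippo_case <- function(x, record = "lengths", ...) {
  rec <- x[[rlang::arg_match0(record, c(
    "lengths", "extents", "order", "tail",
    "subicular", "srlm", "border", "digitations"
  ))]]
  if (is.null(rec)) tibble::tibble() else rec
}

#' @rdname tidy.hippo_case
#' @export
glance.hippo_case <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id,
    head_length_mm = x$lengths$head_length_mm,
    total_length_mm = x$lengths$total_length_mm,
    head_to_total_ratio_pct = x$lengths$head_to_total_ratio_pct,
    n_digitations = if (is.null(x$digitations)) NA_integer_ else x$digitations$n_digitations,
    n_qc_notes = length(x$qc)
  )
}

#' Covariate table for a cohort
#'
#' @param case_id Character ids (unique).
#' @param dementia Logical dementia status.
#' @param sex Character `"F"`/`"M"` (or any two levels).
#' @param age,fixation_days,pmi_hours Numeric covariates; `NA` allowed
#'   (cases drop out of the affected test only).
#' @return A validated tibble.
#' @export
covariate_table <- function(case_id, dementia, sex, age, fixation_days, pmi_hours) {
  if (anyDuplicated(case_id)) {
    rlang::abort("Case ids must be unique.", class = "hippomorph_cohort_error")
  }
  tibble::tibble(
    case_id = as.character(case_id), dementia = as.logical(dementia),
    sex = as.character(sex), age = as.numeric(age),
    fixation_days = as.numeric(fixation_days), pmi_hours = as.numeric(pmi_hours)
  )
}

#' Outcome-by-covariate test grid with per-family FDR
#'
#' For each outcome column, runs: Mann-Whitney U against dementia status
#' (all cases) and against sex (non-dementia cases only), and Spearman
#' correlations with age, fixation time and postmortem interval
#' (non-dementia cases only). Each outcome forms one Benjamini-Hochberg
#' family. Tests with fewer than 2 observations per group (or fewer than 3
#' pairs) are reported as skipped with a reason.
#'
#' @param data Tibble with `case_id` and the outcome columns.
#' @param covariates A [covariate_table()].
#' @param outcomes Character vector of outcome column names.
#' @param mode Test mode passed to [mann_whitney_u()] / [spearman_rho()].
#' @return A `hippo_stats` tibble: `outcome`, `covariate`, `test`,
#'   `statistic`, `p_value`, `family`, `p_adjusted`, `n`, `skipped_reason`.
#' @export
cohort_statistics <- function(data, covariates, outcomes, mode = "auto") {
  df <- dplyr::inner_join(data, covariates, by = "case_id")
  res <- purrr::map_dfr(outcomes, function(oc) {
    y <- df[[oc]]
    nd <- !df$dementia # subgroup for non-dementia-only tests
    one <- function(covariate, test, value) {
      tibble::tibble(
        outcome = oc, covariate = covariate, test = test,
        statistic = value$statistic, p_value = value$p_value,
        family = oc, n = value$n, skipped_reason = value$reason
      )
    }
    mw <- function(keep, group) {
      g <- group[keep]
      v <- y[keep]
      ok <- !is.na(g) & !is.na(v)
      g <- g[ok]
      v <- v[ok]
      lv <- unique(g)
      if (length(lv) != 2L || min(table(g)) < 2L) {
        return(list(statistic = NA_real_, p_value = NA_real_, n = length(v), reason = "insufficient n"))
      }
      r <- mann_whitney_u(v[g == lv[1]], v[g == lv[2]], mode = mode)
      list(statistic = r$statistic, p_value = r$p_value, n = length(v), reason = NA_character_)
    }
    sp <- function(keep, xvar) {
      xv <- xvar[keep]
      v <- y[keep]
      ok <- !is.na(xv) & !is.na(v)
      if (sum(ok) < 3L || length(unique(xv[ok])) < 2L || length(unique(v[ok])) < 2L) {
        return(list(statistic = NA_real_, p_value = NA_real_, n = sum(ok), reason = "insufficient n"))
      }
      r <- spearman_rho(xv[ok], v[ok], mode = mode)
      list(statistic = r$statistic, p_value = r$p_value, n = r$n, reason = NA_character_)
    }
    dplyr::bind_rows(
      one("dementia", "U", mw(rep(TRUE, nrow(df)), df$dementia)),
      one("sex", "U", mw(nd, df$sex)),
      one("age", "rho", sp(nd, df$age)),
      one("fixation_days", "rho", sp(nd, df$fixation_days)),
      one("pmi_hours", "rho", sp(nd, df$pmi_hours))
    )
  })
  res <- res |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(
      p_adjusted = adjust_within_family(.data$p_value)
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("p_adjusted", .after = "p_value")
  class(res) <- c("hippo_stats", class(res))
  res
}

adjust_within_family <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- benjamini_hochberg(p[ok])
  out
}

#' @export
tidy.hippo_stats <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.hippo_stats <- function(x, ...) {
  tibble::tibble(
    n_tests = sum(!is.na(x$p_value)),
    n_skipped = sum(!is.na(x$skipped_reason)),
    n_families = dplyr::n_distinct(x$family),
    n_significant = sum(x$p_adjusted < 0.05, na.rm = TRUE)
  )
}

#' Run the full cohort pipeline
#'
#' Measures every case in the manifest, assembles the length and border
#' outcome tables, and runs the statistics grids: one family per length
#' measure (head, total, ratio) and one family per border offset and
#' reference width. Identical inputs give identical outputs.
#'
#' @param manifest Tibble with columns `case_id`, `volume`, `landmarks`
#'   and optionally `coverage`. `volume`/`landmarks`/`coverage` may be
#'   list-columns of in-memory objects or character paths
#'   (NIfTI / JSON / TSV).
#' @param covariates A [covariate_table()].
#' @param schema Schema used when volumes are read from paths.
#' @param hemisphere Optional character column name or vector used when
#'   reading volumes from paths (defaults to `"right"`).
#' @param mode Statistics mode (see [cohort_statistics()]).
#' @return A `hippo_cohort`: list with `cases` (list of `hippo_case`),
#'   `lengths`, `border`, `tail`, `subicular`, `srlm`, `digitations`
#'   tables, `length_stats`, `border_stats`, and `qc`.
#' @export
run_cohort <- function(manifest, covariates, schema = default_schema(),
                       hemisphere = NULL, mode = "auto") {
  if (anyDuplicated(manifest$case_id)) {
    rlang::abort("Manifest case ids must be unique.", class = "hippomorph_cohort_error")
  }
  cases <- purrr::pmap(
    list(seq_len(nrow(manifest))),
    function(i) {
      vol <- manifest$volume[[i]]
      if (is.character(vol)) {
        hemi <- if (is.null(hemisphere)) "right" else hemisphere[[i]]
        vol <- load_label_volume(vol, schema = schema, hemisphere = hemi)
      }
      lmk <- manifest$landmarks[[i]]
      if (is.character(lmk)) lmk <- read_landmarks(lmk)
      cov <- if ("coverage" %in% names(manifest)) manifest$coverage[[i]] else NULL
      if (is.character(cov)) cov <- read_coverage(cov, n_slices(vol))
      measure_case(vol, lmk, cov, case_id = manifest$case_id[[i]])
    }
  )
  lengths <- purrr::map_dfr(cases, "lengths")
  border <- purrr::map_dfr(cases, "border")
  out <- list(
    cases = cases,
    lengths = lengths,
    border = border,
    tail = purrr::map_dfr(cases, "tail"),
    subicular = purrr::map_dfr(cases, "subicular"),
    srlm = purrr::map_dfr(cases, "srlm"),
    digitations = purrr::map_dfr(cases, "digitations"),
    qc = tibble::tibble(
      case_id = purrr::map_chr(cases, "case_id"),
      n_notes = purrr::map_int(cases, ~ length(.x$qc))
    )
  )
  out$length_stats <- cohort_statistics(
    lengths, covariates,
    outcomes = c("head_length_mm", "total_length_mm", "head_to_total_ratio_pct"),
    mode = mode
  )
  if (nrow(border) > 0) {
    wide <- border |>
      dplyr::select("case_id", "offset_mm", "pct_of_full_width", "pct_of_dg_width") |>
      tidyr::pivot_wider(
        names_from = "offset_mm",
        values_from = c("pct_of_full_width", "pct_of_dg_width"),
        names_glue = "{.value}_{offset_mm}mm"
      )
    out$border_stats <- cohort_statistics(
      wide, covariates,
      outcomes = setdiff(names(wide), "case_id"),
      mode = mode
    )
  }
  structure(out, class = "hippo_cohort")
}

#' @export
print.hippo_cohort <- function(x, ...) {
  cat(sprintf("<hippo_cohort> %d cases\n", length(x$cases)))
  invisible(x)
}

#' Write deterministic cohort reports
#'
#' Emits TSV tables (lengths, border, tail presence, subicular, SRLM,
#' digitations, both statistics grids) plus a JSON summary. Rerunning on
#' identical inputs reproduces the files byte-for-byte.
#'
#' @param cohort A `hippo_cohort` from [run_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_reports <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_tsv(tibble::as_tibble(unclass(tbl)), file.path(dir, paste0(name, ".tsv")))
    }
  }
  w(cohort$lengths, "lengths")
  w(cohort$border, "border")
  w(cohort$tail, "tail_presence")
  w(cohort$subicular, "subicular_proportions")
  w(cohort$srlm, "srlm_projection")
  w(cohort$digitations, "digitations")
  w(cohort$length_stats, "length_stats")
  w(cohort$border_stats, "border_stats")
  summary <- list(
    n_cases = length(cohort$cases),
    length_stats = if (!is.null(cohort$length_stats)) glance(cohort$length_stats) else NULL,
    border_stats = if (!is.null(cohort$border_stats)) glance(cohort$border_stats) else NULL
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
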