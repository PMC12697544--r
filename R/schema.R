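#' Subfield label schema
#'
#' A schema maps subfield names to the integer codes used in a label volume.
#' The eight names required for hippocampal morphometry are `SUB`, `PrS`,
#' `PaS`, `CA1`, `CA2`, `CA3`, `DG` and `SRLM`; background is always code 0.
#' Extra codes may be present in a volume but are ignored by all measurements.
#'
#' @param ... Named integer codes, e.g. `SUB = 1, PrS = 2, ...`. A single
#'   named vector or list may be supplied instead.
#' @return An object of class `subfield_schema` (a named integer vector that
#'   always includes `background = 0`).
#' @examples
#' subfield_schema(
#'   SUB = 1, PrS = 2, PaS = 3, CA1 = 4,
#'   CA2 = 5, CA3 = 6, DG = 7, SRLM = 8
#' )
#' @export
subfield_schema <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  codes <- vapply(dots, function(x) as.integer(x), integer(1))
  required <- c("SUB", "PrS", "PaS", "CA1", "CA2", "CA3", "DG", "SRLM")
  missing <- setdiff(required, names(codes))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0("Schema is missing required subfields: ", paste(missing, collapse = ", ")),
      class = "hippomorph_schema_error"
    )
  }
  codes <- codes[!names(codes) %in% "background"]
  if (any(codes <= 0L) || anyNA(codes)) {
    rlang::abort("Schema codes must be positive integers (background is fixed at 0).",
      class = "hippomorph_schema_error"
    )
  }
  if (anyDuplicated(codes)) {
    rlang::abort("Schema codes must be distinct.", class = "hippomorph_schema_error")
  }
  out <- c(background = 0L, codes)
  structure(out, class = "subfield_schema")
}

#' @export
print.subfield_schema <- function(x, ...) {
  cat("<subfield_schema>\n")
  cat(paste0("  ", format(names(x), width = 10), " = ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Default subfield schema
#'
#' Codes 1-8 in the order SUB, PrS, PaS, CA1, CA2, CA3, DG, SRLM.
#' @return A [subfield_schema()].
#' @export
default_schema <- function() {
  subfield_schema(
    SUB = 1, PrS = 2, PaS = 3, CA1 = 4,
    CA2 = 5, CA3 = 6, DG = 7, SRLM = 8
  )
}

#' Read or write a schema as JSON
#'
#' The on-disk format is a flat JSON object `{"SUB": 1, "PrS": 2, ...}`.
#'
#' @param path File path.
#' @return `read_schema()` returns a [subfield_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  subfield_schema(unlist(obj))
}

#' @rdname read_schema
#' @param schema A [subfield_schema()].
#' @export
write_schema <- function(schema, path) {
  codes <- as.list(unclass(schema)[names(schema) != "background"])
  jsonlite::write_json(codes, path, auto_unbox = TRUE)
  invisible(path)
}

schema_code <- function(schema, label) {
  if (!label %in% names(schema)) {
    rlang::abort(paste0("Label '", label, "' is not in the schema."),
      class = "hippomorph_schema_error"
    )
  }
  unname(unclass(schema)[label])
}
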