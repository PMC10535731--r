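#' @name assay_io
#' @title CSV readers and writers for the four assay schemas
#'
#' @description
#' All stages exchange plain UTF-8 CSV with a single header row and decimal
#' points. Four schemas are recognized:
#'
#' * `viability`: `well_id, dose_um, a570, a600, is_negative_control`
#' * `clonogenic`: `radiation_gy, drug_um, cells_plated, colonies, replicate`
#' * `caliper`: `animal_id, group, day, length_mm, width_mm, height_mm`
#'   and/or `volume_mm3`
#' * `animal`: `animal_id, group, body_weight_g, spleen_weight_g,
#'   alp, alb, alt, ast, bun, cre`
#'
#' Group labels form a closed vocabulary (`normal`, `control`, `radiation`,
#' `drug`, `combination`), matched case-insensitively; unknown labels are
#' errors rather than silently kept, because downstream arithmetic (delay vs
#' control, normalization to the normal group) must be able to identify its
#' reference groups. Days count from treatment start (day 0 = irradiation
#' day).
NULL

.radsyn_groups <- c("normal", "control", "radiation", "drug", "combination")

.schemas <- list(
  viability = list(
    required = c("well_id", "dose_um", "a570", "a600", "is_negative_control"),
    numeric = c("dose_um", "a570", "a600")
  ),
  clonogenic = list(
    required = c("radiation_gy", "drug_um", "cells_plated", "colonies", "replicate"),
    numeric = c("radiation_gy", "drug_um", "cells_plated", "colonies", "replicate")
  ),
  caliper = list(
    required = c("animal_id", "group", "day"),
    numeric = c("day", "length_mm", "width_mm", "height_mm", "volume_mm3")
  ),
  animal = list(
    required = c("animal_id", "group", "body_weight_g", "spleen_weight_g"),
    numeric = c("body_weight_g", "spleen_weight_g",
                "alp", "alb", "alt", "ast", "bun", "cre")
  )
)

# internal: coerce a character column to numeric, reporting offending rows
.coerce_numeric <- function(df, col, schema) {
  if (!col %in% names(df)) return(df)
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !is.na(raw) & trimws(as.character(raw)) != "")
  if (length(bad))
    abort_radsyn(
      sprintf("%s: non-numeric value in column '%s' at data row(s) %s",
              schema, col, paste(bad, collapse = ", ")),
      "radsyn_parse_error")
  df[[col]] <- val
  df
}

# internal: normalize and validate group labels
.normalize_group <- function(g, schema) {
  g <- tolower(trimws(as.character(g)))
  bad <- setdiff(unique(g), .radsyn_groups)
  if (length(bad))
    abort_radsyn(
      sprintf("%s: unknown group label(s): %s (expected one of %s)",
              schema, paste(bad, collapse = ", "),
              paste(.radsyn_groups, collapse = ", ")),
      "radsyn_schema_error")
  factor(g, levels = .radsyn_groups)
}

#' Read and validate an assay CSV
#'
#' @param path CSV file path.
#' @param schema one of `"viability"`, `"clonogenic"`, `"caliper"`,
#'   `"animal"`.
#' @return a validated `data.frame`; row order preserved. Caliper tables gain
#'   a `volume_mm3` column when only dimensions were supplied (computed
#'   downstream), and group columns become factors over the closed
#'   vocabulary.
#' @seealso [write_report_table()], [tumor_volume()]
#' @export
read_assay_table <- function(path, schema = c("viability", "clonogenic", "caliper", "animal")) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    abort_radsyn(paste0("file not found: ", path), "radsyn_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  spec <- .schemas[[schema]]
  missing <- setdiff(spec$required, names(df))
  if (length(missing))
    abort_radsyn(
      sprintf("%s: missing required column(s): %s", schema,
              paste(missing, collapse = ", ")),
      "radsyn_schema_error")
  for (col in intersect(spec$numeric, names(df)))
    df <- .coerce_numeric(df, col, schema)
  validate_assay_table(df, schema)
}

#' Validate an in-memory assay table
#'
#' Applies the same record-level invariants as [read_assay_table()]:
#' non-negative doses and counts, `colonies <= cells_plated`, positive caliper
#' dimensions, unique `(animal_id, day)` pairs, spleen weight below body
#' weight, closed group vocabulary.
#'
#' @param df data frame shaped like one of the four schemas.
#' @inheritParams read_assay_table
#' @return the validated (possibly normalized) data frame.
#' @export
validate_assay_table <- function(df, schema = c("viability", "clonogenic", "caliper", "animal")) {
  schema <- match.arg(schema)
  fail <- function(rows, what)
    abort_radsyn(sprintf("%s: %s at data row(s) %s", schema, what,
                         paste(rows, collapse = ", ")),
                 "radsyn_validation_error")
  if (schema == "viability") {
    df$is_negative_control <- .as_flag(df$is_negative_control)
    if (!any(df$is_negative_control))
      abort_radsyn("viability: no negative-control well on the plate",
                   "radsyn_validation_error")
    bad <- which(!is.finite(df$a570) | !is.finite(df$a600))
    if (length(bad)) fail(bad, "non-finite absorbance")
    bad <- which(!df$is_negative_control & (is.na(df$dose_um) | df$dose_um < 0))
    if (length(bad)) fail(bad, "negative or missing dose")
  } else if (schema == "clonogenic") {
    bad <- which(df$radiation_gy < 0 | df$drug_um < 0)
    if (length(bad)) fail(bad, "negative dose")
    bad <- which(df$cells_plated <= 0 | df$colonies < 0 |
                   df$cells_plated != round(df$cells_plated) |
                   df$colonies != round(df$colonies))
    if (length(bad)) fail(bad, "counts must be non-negative integers with cells_plated > 0")
    bad <- which(df$colonies > df$cells_plated)
    if (length(bad)) fail(bad, "colonies exceed cells plated")
  } else if (schema == "caliper") {
    df$group <- .normalize_group(df$group, schema)
    if (is.null(df$volume_mm3) &&
        !all(c("length_mm", "width_mm", "height_mm") %in% names(df)))
      abort_radsyn("caliper: need length_mm/width_mm/height_mm or volume_mm3",
                   "radsyn_schema_error")
    if (all(c("length_mm", "width_mm", "height_mm") %in% names(df))) {
      dims_present <- !(is.na(df$length_mm) & is.na(df$width_mm) & is.na(df$height_mm))
      bad <- which(dims_present &
                     (is.na(df$length_mm) | is.na(df$width_mm) | is.na(df$height_mm) |
                        df$length_mm <= 0 | df$width_mm <= 0 | df$height_mm <= 0))
      if (length(bad)) fail(bad, "caliper dimensions must all be present and > 0")
      if (!is.null(df$volume_mm3)) {
        bad <- which(!dims_present & is.na(df$volume_mm3))
        if (length(bad)) fail(bad, "neither dimensions nor volume present")
      }
    }
    bad <- which(df$day < 0)
    if (length(bad)) fail(bad, "negative day")
    key <- paste(df$animal_id, df$day, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) fail(dup, "duplicated (animal_id, day)")
  } else if (schema == "animal") {
    df$group <- .normalize_group(df$group, schema)
    bad <- which(df$body_weight_g <= 0)
    if (length(bad)) fail(bad, "body weight must be > 0")
    bad <- which(df$spleen_weight_g < 0 | df$spleen_weight_g >= df$body_weight_g)
    if (length(bad)) fail(bad, "spleen weight must be in [0, body weight)")
  }
  df
}

.as_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  xl <- tolower(trimws(as.character(x)))
  xl %in% c("true", "t", "1", "yes", "y")
}

#' Write a summary table to CSV
#'
#' Values survive a write/read round trip at full stored precision (15
#' significant digits).
#'
#' @param rows non-empty data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    abort_radsyn("rows must be a non-empty data frame", "radsyn_validation_error")
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_radsyn(paste0("cannot write ", path, ": ", conditionMessage(ok)),
                 "radsyn_io_error")
  invisible(path)
}
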