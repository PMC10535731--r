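#' Spleen index of a single animal
#'
#' Spleen weight divided by body weight.
#'
#' @param spleen_weight_g spleen weight (g, >= 0).
#' @param body_weight_g body weight (g, > 0).
#' @return dimensionless index (vectorized).
#' @export
spleen_index <- function(spleen_weight_g, body_weight_g) {
  if (any(body_weight_g <= 0))
    abort_radsyn("body weight must be > 0", "radsyn_validation_error")
  if (any(spleen_weight_g < 0))
    abort_radsyn("spleen weight must be >= 0", "radsyn_validation_error")
  if (any(spleen_weight_g >= body_weight_g))
    warning("spleen weight >= body weight; index is degenerate")
  spleen_weight_g / body_weight_g
}

#' Relative spleen index per group
#'
#' Group mean spleen indices normalized to the untreated normal group, whose
#' RSI is 1 by construction.
#'
#' @param animals data frame in the `animal` schema.
#' @return data frame with `group`, `n`, `mean_spleen_index`, `rsi`.
#' @export
relative_spleen_index <- function(animals) {
  animals <- validate_assay_table(animals, "animal")
  idx <- spleen_index(animals$spleen_weight_g, animals$body_weight_g)
  grp <- split(idx, animals$group)
  grp <- grp[lengths(grp) > 0]
  if (!"normal" %in% names(grp))
    abort_radsyn("normal group required to anchor the relative spleen index",
                 "radsyn_validation_error")
  means <- vapply(grp, mean, numeric(1))
  data.frame(group = names(means),
             n = vapply(grp, length, integer(1)),
             mean_spleen_index = unname(means),
             rsi = unname(means) / means[["normal"]],
             row.names = NULL)
}

#' Per-group mean and standard error of an analyte
#'
#' @param values per-animal measurements.
#' @param group group label per value.
#' @param analyte label carried into the output (e.g. `"CD4_percent"`).
#' @return data frame with `group`, `analyte`, `mean`, `se`, `n`; `se` is
#'   `NA` for singleton groups.
#' @examples
#' summarize_groups(c(10, 14), c("control", "control"))  # mean 12, se 2
#' @export
summarize_groups <- function(values, group, analyte = NA_character_) {
  if (length(values) != length(group))
    abort_radsyn("values and group must have equal length", "radsyn_validation_error")
  grp <- split(values, group)
  grp <- grp[lengths(grp) > 0]
  if (length(grp) == 0L)
    abort_radsyn("no non-empty group", "radsyn_validation_error")
  data.frame(
    group = names(grp),
    analyte = analyte,
    mean = vapply(grp, mean, numeric(1)),
    se = vapply(grp, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    n = vapply(grp, length, integer(1)),
    row.names = NULL
  )
}

.reference_glyphs <- c(control = "*", radiation = "#", drug = "$")

#' Tiered significance annotation against reference groups
#'
#' For each non-reference group, a two-sided two-sample Student t test
#' (pooled variance, as named; Welch available via `var_equal = FALSE`)
#' against each requested reference family: `*` versus control, `#` versus
#' radiation-alone, `$` versus drug-alone. The glyph is repeated once per
#' significance threshold crossed (defaults 0.05 / 0.01 / 0.001), so e.g.
#' `p = 0.0005` against control renders `"***"`. No multiple-testing
#' correction is applied by default, matching common reporting practice in
#' preclinical tables; `adjust = "bonferroni"` applies a Bonferroni
#' correction across the comparisons of one reference family.
#'
#' @param values per-animal measurements.
#' @param group group label per value.
#' @param references subset of `c("control", "radiation", "drug")`.
#' @param config a [run_config()] supplying `significance_thresholds`.
#' @param var_equal pooled-variance t test when `TRUE` (default), Welch
#'   otherwise.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data frame with `group`, `reference`, `p_value`, `symbol`.
#'   Comparisons with fewer than 2 animals on either side are skipped with a
#'   warning.
#' @export
annotate_comparisons <- function(values, group, references = "control",
                                 config = run_config(), var_equal = TRUE,
                                 adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  references <- match.arg(references, names(.reference_glyphs), several.ok = TRUE)
  grp <- split(values, group)
  grp <- grp[lengths(grp) > 0]
  out <- list()
  for (ref in references) {
    if (!ref %in% names(grp)) {
      warning("reference group '", ref, "' absent; family skipped")
      next
    }
    others <- setdiff(names(grp), ref)
    fam <- list()
    for (g in others) {
      if (length(grp[[g]]) < 2L || length(grp[[ref]]) < 2L) {
        warning("comparison ", g, " vs ", ref, " skipped: n < 2")
        next
      }
      p <- if (stats::sd(grp[[g]]) == 0 && stats::sd(grp[[ref]]) == 0) {
        if (mean(grp[[g]]) == mean(grp[[ref]])) 1 else 0
      } else {
        stats::t.test(grp[[g]], grp[[ref]], var.equal = var_equal)$p.value
      }
      fam[[g]] <- data.frame(group = g, reference = ref, p_value = p)
    }
    if (!length(fam)) next
    fam <- do.call(rbind, fam)
    if (adjust == "bonferroni")
      fam$p_value <- pmin(1, fam$p_value * nrow(fam))
    fam$symbol <- vapply(fam$p_value, function(p)
      strrep(.reference_glyphs[[ref]], sum(p < config$significance_thresholds)),
      character(1))
    out[[ref]] <- fam
  }
  if (!length(out))
    abort_radsyn("no comparison could be made", "radsyn_validation_error")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag group means against biochemistry reference ranges
#'
#' Compares each analyte's group mean to its `[low, high]` reference range,
#' boundaries inclusive.
#'
#' @param means named numeric vector (or data frame with `analyte`, `mean`)
#'   of group-mean biochemistry values.
#' @param ranges data frame with columns `analyte`, `low`, `high` (and
#'   optionally `units`).
#' @return data frame with `analyte`, `mean`, `low`, `high`, `flag` in
#'   `{"within", "below", "above", NA}`; analytes without a known range get
#'   `NA` with a warning.
#' @examples
#' flag_reference_ranges(c(ALP = 163, BUN = 33),
#'                       data.frame(analyte = c("ALP", "BUN"),
#'                                  low = c(62, 18), high = c(209, 29)))
#' @export
flag_reference_ranges <- function(means, ranges) {
  if (is.data.frame(means))
    means <- stats::setNames(means$mean, means$analyte)
  if (any(ranges$low >= ranges$high))
    abort_radsyn("reference ranges must have low < high", "radsyn_validation_error")
  key <- toupper(ranges$analyte)
  i <- match(toupper(names(means)), key)
  if (anyNA(i))
    warning("no reference range for: ",
            paste(names(means)[is.na(i)], collapse = ", "))
  low <- ranges$low[i]; high <- ranges$high[i]
  flag <- ifelse(is.na(low), NA_character_,
          ifelse(means < low, "below",
          ifelse(means > high, "above", "within")))
  data.frame(analyte = names(means), mean = unname(means),
             low = low, high = high, flag = flag, row.names = NULL)
}
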