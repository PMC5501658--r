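#' Define a dichotomization rule
#'
#' One rule per upstream predictor, turning its published output into a
#' harmful/neutral call. Three kinds exist: `numeric_threshold`
#' (harmful when the score strictly exceeds, or falls strictly below,
#' a cutoff), `categorical_map` (an exact, total lookup over the
#' predictor's published categories) and `significance_pair` (harmful
#' when p-value and FDR both fall below their cutoffs).
#'
#' @param predictor predictor name the rule applies to.
#' @param kind one of `"numeric_threshold"`, `"categorical_map"`,
#'   `"significance_pair"`.
#' @param threshold numeric cutoff (numeric_threshold).
#' @param direction `"greater"` if scores above the threshold are
#'   harmful, `"less"` otherwise.
#' @param map named character vector category -> `"harmful"`/`"neutral"`
#'   (categorical_map).
#' @param p_cut,fdr_cut significance cutoffs (significance_pair).
#' @param p_col,fdr_col names of the raw p-value and FDR columns
#'   feeding a significance_pair rule.
#' @return an object of class `dichotomization_rule`.
#' @export
dichotomization_rule <- function(predictor,
                                 kind = c("numeric_threshold",
                                          "categorical_map",
                                          "significance_pair"),
                                 threshold = NULL, direction = "greater",
                                 map = NULL, p_cut = 0.05, fdr_cut = 0.2,
                                 p_col = NULL, fdr_col = NULL) {
  kind <- match.arg(kind)
  if (kind == "numeric_threshold") {
    if (is.null(threshold) || !is.finite(threshold))
      validation_error("numeric_threshold rule needs a finite threshold")
    if (!direction %in% c("greater", "less"))
      validation_error("direction must be 'greater' or 'less'")
  }
  if (kind == "categorical_map") {
    if (is.null(map) || is.null(names(map)))
      validation_error("categorical_map rule needs a named map")
    bad <- setdiff(unique(map), c("harmful", "neutral"))
    if (length(bad) > 0)
      validation_error("map values must be 'harmful' or 'neutral'")
  }
  if (kind == "significance_pair") {
    if (is.null(p_col)) p_col <- paste0(predictor, "_p")
    if (is.null(fdr_col)) fdr_col <- paste0(predictor, "_fdr")
  }
  structure(list(predictor = predictor, kind = kind, threshold = threshold,
                 direction = direction, map = as.list(map),
                 p_cut = p_cut, fdr_cut = fdr_cut,
                 p_col = p_col, fdr_col = fdr_col),
            class = "dichotomization_rule")
}

#' Dichotomize a numeric score
#'
#' Strictly-greater (or strictly-less) comparison against the rule's
#' threshold; equality with the threshold is neutral. Missing or
#' non-finite scores propagate as missing, never as errors.
#'
#' @param x numeric score vector.
#' @param rule a `numeric_threshold` [dichotomization_rule()].
#' @return character vector of `"harmful"`/`"neutral"`/`NA`.
#' @export
dichotomize_numeric <- function(x, rule) {
  stopifnot(rule$kind == "numeric_threshold")
  x <- as.numeric(x)
  x[!is.finite(x)] <- NA_real_
  harmful <- if (rule$direction == "greater") x > rule$threshold
             else x < rule$threshold
  ifelse(is.na(x), NA_character_,
         ifelse(harmful, "harmful", "neutral"))
}

#' Dichotomize a categorical call
#'
#' @param call character vector of predictor categories.
#' @param rule a `categorical_map` [dichotomization_rule()].
#' @return character vector of `"harmful"`/`"neutral"`/`NA`; an
#'   unmapped category raises an error naming predictor and category.
#' @export
dichotomize_categorical <- function(call, rule) {
  stopifnot(rule$kind == "categorical_map")
  call <- as.character(call)
  known <- names(rule$map)
  bad <- setdiff(unique(call[!is.na(call)]), known)
  if (length(bad) > 0)
    apogee_error(paste0("unmapped categor", if (length(bad) > 1) "ies" else "y",
                        " for predictor ", rule$predictor, ": ",
                        paste(bad, collapse = ", ")),
                 "apogee_unmapped_category_error")
  out <- unlist(rule$map)[call]
  out[is.na(call)] <- NA_character_
  unname(out)
}

#' Significance-based call from a p-value/FDR pair
#'
#' Harmful iff p-value < `p_cut` and FDR < `fdr_cut` (both strict);
#' if either member of the pair is missing the call is missing.
#'
#' @param p_value,fdr numeric vectors in \[0, 1\].
#' @param rule a `significance_pair` [dichotomization_rule()] (defaults
#'   p < 0.05 and FDR < 0.2).
#' @return character vector of `"harmful"`/`"neutral"`/`NA`.
#' @export
significance_call <- function(p_value, fdr,
                              rule = dichotomization_rule("sig",
                                                          "significance_pair")) {
  p_value <- as.numeric(p_value); fdr <- as.numeric(fdr)
  chk <- c(p_value, fdr)
  if (any(chk < 0 | chk > 1, na.rm = TRUE))
    validation_error("p-values and FDRs must lie in [0, 1]")
  ifelse(is.na(p_value) | is.na(fdr), NA_character_,
         ifelse(p_value < rule$p_cut & fdr < rule$fdr_cut,
                "harmful", "neutral"))
}

#' Default dichotomization rule set
#'
#' The published cutoffs for the assembled predictors: CADD phred
#' scores exceeding 12 are harmful; MToolBox disease scores exceeding
#' 0.4311 are harmful; a positive COVEC weighted-majority score is
#' harmful (0 is neutral); VEST/CHASM calls are harmful when p < 0.05
#' and FDR < 0.2; MutationAssessor low/neutral map to neutral and
#' medium/high to harmful; PolyPhen-2 is provided in two variants, A
#' mapping "possibly damaging" to neutral and B mapping it to harmful;
#' SIFT, FatHmm and PROVEAN use their canonical two-category maps.
#'
#' @return named list of [dichotomization_rule()]s.
#' @export
default_rules <- function() {
  list(
    cadd_phred = dichotomization_rule("cadd_phred", "numeric_threshold",
                                      threshold = 12),
    mtoolbox_ds = dichotomization_rule("mtoolbox_ds", "numeric_threshold",
                                       threshold = 0.4311),
    covec_wmv = dichotomization_rule("covec_wmv", "numeric_threshold",
                                     threshold = 0),
    vest = dichotomization_rule("vest", "significance_pair"),
    chasm = dichotomization_rule("chasm", "significance_pair"),
    polyphen2 = dichotomization_rule("polyphen2", "categorical_map",
      map = c("probably damaging" = "harmful",
              "possibly damaging" = "neutral",
              "benign" = "neutral")),
    polyphen2b = dichotomization_rule("polyphen2b", "categorical_map",
      map = c("probably damaging" = "harmful",
              "possibly damaging" = "harmful",
              "benign" = "neutral")),
    mutation_assessor = dichotomization_rule("mutation_assessor",
      "categorical_map",
      map = c("high" = "harmful", "medium" = "harmful",
              "low" = "neutral", "neutral" = "neutral")),
    sift = dichotomization_rule("sift", "categorical_map",
      map = c("deleterious" = "harmful", "tolerated" = "neutral")),
    fathmm = dichotomization_rule("fathmm", "categorical_map",
      map = c("damaging" = "harmful", "tolerated" = "neutral")),
    provean = dichotomization_rule("provean", "categorical_map",
      map = c("deleterious" = "harmful", "neutral" = "neutral"))
  )
}

#' Write rules to a YAML file
#' @param rules named list of [dichotomization_rule()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, unclass), path)
  invisible(path)
}

#' Read rules from a YAML file
#' @param path rules file written by [write_rules()] (or hand-edited in
#'   the same layout).
#' @return named list of [dichotomization_rule()]s.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(r)
    dichotomization_rule(r$predictor, r$kind,
                         threshold = r$threshold,
                         direction = if (is.null(r$direction)) "greater" else r$direction,
                         map = unlist(r$map),
                         p_cut = if (is.null(r$p_cut)) 0.05 else r$p_cut,
                         fdr_cut = if (is.null(r$fdr_cut)) 0.2 else r$fdr_cut,
                         p_col = r$p_col, fdr_col = r$fdr_col))
  names(rules) <- names(raw)
  rules
}
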