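#' Construct a feature matrix
#'
#' The n x p numeric design matrix consumed by the learner, together
#' with an explicit missingness mask and a per-column kind tag. Missing
#' cells are `NA` in `values` and `TRUE` in `mask`; they carry no
#' information downstream until an imputer fitted on training rows
#' fills them.
#'
#' @param values numeric matrix (missing cells `NA`); column names
#'   must be unique.
#' @param kinds per-column kind: `"raw_numeric"`, `"dichotomized"` or
#'   `"coevolution"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kinds = rep("raw_numeric", ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) > 0) {
    if (is.null(colnames(values)))
      colnames(values) <- paste0("x", seq_len(ncol(values)))
    if (anyDuplicated(colnames(values)))
      validation_error("feature column names must be unique")
  }
  kinds <- as.character(kinds)
  if (length(kinds) != ncol(values))
    validation_error("one kind per feature column required")
  bad <- setdiff(unique(kinds), c("raw_numeric", "dichotomized", "coevolution"))
  if (length(bad) > 0)
    validation_error(paste0("unknown column kind(s): ", paste(bad, collapse = ", ")))
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, mask = is.na(values), kinds = kinds),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d x %d (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Per-site coevolution summaries from an MI Z-score matrix
#'
#' Given a symmetric L x L matrix of mutual-information Z-scores for
#' one protein, keeps only residue pairs whose Z-score strictly
#' exceeds `z_cut` (the published coevolving-pair cutoff, 6.5) and
#' summarizes each site by the fraction of partners it coevolves with
#' and the mean Z-score over those partners.
#'
#' @param m square symmetric numeric matrix; the diagonal is ignored.
#' @param z_cut coevolution threshold (strict `>`).
#' @return data.frame with `site`, `coevolving_frequency` (in
#'   \[0, 1\], denominator L - 1) and `mean_z` (`NA` when a site has
#'   no supra-threshold partner).
#' @export
coevolution_site_stats <- function(m, z_cut = 6.5) {
  m <- as.matrix(m)
  L <- nrow(m)
  if (ncol(m) != L || L < 2)
    validation_error("coevolution matrix must be square with L >= 2")
  off <- upper.tri(m)
  d <- abs(m - t(m))
  if (any(d[off] > 1e-9, na.rm = TRUE))
    validation_error("coevolution matrix is asymmetric beyond tolerance 1e-9")
  diag(m) <- NA
  hot <- !is.na(m) & m > z_cut
  freq <- rowSums(hot) / (L - 1)
  mean_z <- vapply(seq_len(L), function(i)
    if (any(hot[i, ])) mean(m[i, hot[i, ]]) else NA_real_, numeric(1))
  data.frame(site = seq_len(L), coevolving_frequency = freq,
             mean_z = mean_z, row.names = NULL)
}

#' Encode raw predictor outputs into a design matrix
#'
#' Raw numeric scores pass through unchanged; columns covered by a
#' dichotomization rule are encoded harmful = 1, neutral = 0; paired
#' p-value/FDR columns named by a significance rule collapse into one
#' dichotomized column. Columns that are entirely missing are dropped
#' with a warning and noted in the provenance log attached to the
#' result (`attr(, "provenance")`).
#'
#' @param raw data.frame of predictor columns (numeric scores and/or
#'   character category calls).
#' @param rules named list of [dichotomization_rule()]s; names are the
#'   raw columns (for `significance_pair` rules, the output column) the
#'   rule applies to. Columns without a rule must be numeric.
#' @return a [feature_matrix()].
#' @export
encode_features <- function(raw, rules = list()) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE, check.names = FALSE)
  n <- nrow(raw)
  out <- list(); kinds <- character(0); log <- character(0)
  consumed <- character(0)
  for (rule_name in names(rules)) {
    rule <- rules[[rule_name]]
    if (rule$kind == "significance_pair") {
      if (!all(c(rule$p_col, rule$fdr_col) %in% names(raw)))
        format_error(paste0("significance rule '", rule_name,
                            "' needs columns ", rule$p_col, " and ", rule$fdr_col))
      call <- significance_call(raw[[rule$p_col]], raw[[rule$fdr_col]], rule)
      consumed <- c(consumed, rule$p_col, rule$fdr_col)
    } else {
      if (!(rule_name %in% names(raw))) next
      call <- if (rule$kind == "numeric_threshold")
        dichotomize_numeric(as.numeric(raw[[rule_name]]), rule)
      else dichotomize_categorical(raw[[rule_name]], rule)
      consumed <- c(consumed, rule_name)
    }
    out[[rule_name]] <- ifelse(is.na(call), NA_real_,
                               as.numeric(call == "harmful"))
    kinds <- c(kinds, "dichotomized")
  }
  for (col in setdiff(names(raw), consumed)) {
    if (col %in% names(out)) next
    x <- raw[[col]]
    if (!is.numeric(x)) {
      num <- suppressWarnings(as.numeric(x))
      if (all(is.na(num[!is.na(x)])))
        format_error(paste0("column '", col,
                            "' is categorical but has no dichotomization rule"))
      x <- num
    }
    out[[col]] <- as.numeric(x)
    kinds <- c(kinds, "raw_numeric")
  }
  keep <- vapply(out, function(v) !all(is.na(v)), logical(1))
  if (any(!keep)) {
    dropped <- names(out)[!keep]
    log <- c(log, paste0("dropped all-missing column: ", dropped))
    warning("dropped all-missing column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  values <- matrix(unlist(out[keep], use.names = FALSE), nrow = n)
  colnames(values) <- names(out)[keep]
  fm <- feature_matrix(values, kinds = kinds[keep])
  attr(fm, "provenance") <- log
  fm
}

#' Decode dichotomized columns back to calls
#'
#' Inverse of the harmful = 1 / neutral = 0 encoding, for round-trip
#' checks and report output.
#'
#' @param fm a [feature_matrix()].
#' @return data.frame of `"harmful"`/`"neutral"`/`NA` calls for the
#'   dichotomized columns.
#' @export
decode_dichotomized <- function(fm) {
  idx <- which(fm$kinds == "dichotomized")
  as.data.frame(lapply(idx, function(j) {
    v <- fm$values[, j]
    ifelse(is.na(v), NA_character_, ifelse(v == 1, "harmful", "neutral"))
  }), col.names = colnames(fm$values)[idx], stringsAsFactors = FALSE)
}

#' Fit an imputer on training rows
#'
#' Per-column imputation constants for dense consumers: the training
#' mean for raw numeric and coevolution columns, 0 (neutral) for
#' dichotomized columns. In the bootstrap ensemble this is fitted on
#' each in-bag sample only, never on out-of-bag rows.
#'
#' @param fm a [feature_matrix()].
#' @param rows training row indices (default all rows).
#' @return an object of class `apogee_imputer`.
#' @export
impute_fit <- function(fm, rows = seq_len(nrow(fm$values))) {
  vals <- fm$values[rows, , drop = FALSE]
  fill <- vapply(seq_len(ncol(vals)), function(j) {
    if (fm$kinds[j] == "dichotomized") return(0)
    mu <- mean(vals[, j], na.rm = TRUE)
    if (is.nan(mu)) 0 else mu
  }, numeric(1))
  names(fill) <- colnames(fm$values)
  structure(list(fill = fill), class = "apogee_imputer")
}

#' Apply an imputer
#'
#' @param fm a [feature_matrix()] with the same columns the imputer
#'   was fitted on.
#' @param imputer an [impute_fit()] result.
#' @return dense numeric matrix with no missing cells.
#' @export
impute_apply <- function(fm, imputer) {
  vals <- fm$values
  if (!identical(colnames(vals), names(imputer$fill)))
    validation_error("imputer/feature-matrix column mismatch")
  for (j in seq_len(ncol(vals))) {
    miss <- fm$mask[, j]
    if (any(miss)) vals[miss, j] <- imputer$fill[j]
  }
  vals
}
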