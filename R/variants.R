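#' The 13 mitochondrial protein-coding gene symbols
#'
#' Gene symbols of the 13 polypeptides encoded by the human mitochondrial
#' genome (rCRS), the only genes in which missense variants can occur.
#'
#' @format character vector of length 13.
#' @export
mito_genes <- c("ATP6", "ATP8", "COX1", "COX2", "COX3", "CYB",
                "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")

# rCRS coding spans (1-based inclusive) of the 13 protein genes; ND6 is
# the only protein gene on the reverse strand. Used by the synthetic
# generator to place plausible variant coordinates.
mito_gene_spans <- data.frame(
  gene   = c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
             "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"),
  start  = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L,
             10059L, 10470L, 10760L, 12337L, 14149L, 14747L),
  end    = c(4262L, 5511L, 7445L, 8269L, 8572L, 9207L, 9990L,
             10404L, 10766L, 12137L, 14148L, 14673L, 15887L),
  strand = c("+", "+", "+", "+", "+", "+", "+",
             "+", "+", "+", "+", "-", "+"),
  stringsAsFactors = FALSE
)

.identity_cols <- c("gene", "position", "ref", "alt", "aa_change")
.valid_bases <- c("A", "C", "G", "T")

#' Construct a labeled variant dataset
#'
#' Bundles per-variant identity records with a row-aligned
#' [feature_matrix()]. Labels are `"pathogenic"`, `"neutral"` or
#' `"unknown"`; internally the classifier codes them as y = +1 for
#' neutral and y = -1 for pathogenic.
#'
#' @param records data.frame with columns `gene`, `position`, `ref`,
#'   `alt`, `aa_change` and optionally `label`.
#' @param features a [feature_matrix()] with `nrow(records)` rows, or
#'   `NULL`.
#' @param validate check record invariants (gene symbol set, allele
#'   alphabet, coordinate range, duplicate keys).
#' @return an object of class `variant_dataset`.
#' @export
variant_dataset <- function(records, features = NULL, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!("label" %in% names(records))) records$label <- "unknown"
  if (validate) .validate_records(records)
  if (!is.null(features)) {
    stopifnot(inherits(features, "feature_matrix"))
    if (nrow(features$values) != nrow(records))
      validation_error(sprintf(
        "feature matrix has %d rows but dataset has %d records",
        nrow(features$values), nrow(records)))
  }
  structure(list(records = records, features = features),
            class = "variant_dataset")
}

.validate_records <- function(records) {
  missing_cols <- setdiff(.identity_cols, names(records))
  if (length(missing_cols) > 0)
    format_error(paste0("missing identity column(s): ",
                        paste(missing_cols, collapse = ", ")))
  bad_gene <- setdiff(unique(records$gene), mito_genes)
  if (length(bad_gene) > 0)
    validation_error(paste0("unknown gene symbol(s): ",
                            paste(bad_gene, collapse = ", ")))
  pos <- records$position
  if (any(is.na(pos)) || any(pos < 1 | pos > 16569))
    validation_error("positions must be rCRS coordinates in [1, 16569]")
  if (!all(records$ref %in% .valid_bases) ||
      !all(records$alt %in% .valid_bases))
    validation_error("ref/alt must be single nucleotides (A/C/G/T)")
  if (any(records$ref == records$alt))
    validation_error("ref and alt alleles must differ")
  key <- paste(records$position, records$alt, sep = ":")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0)
    apogee_error(paste0("duplicate (position, alt) variant key(s): ",
                        paste(dup, collapse = ", ")),
                 "apogee_duplicate_variant_error")
  bad_label <- setdiff(unique(records$label),
                       c("pathogenic", "neutral", "unknown"))
  if (length(bad_label) > 0)
    validation_error(paste0("invalid label value(s): ",
                            paste(bad_label, collapse = ", ")))
  invisible(records)
}

#' @export
print.variant_dataset <- function(x, ...) {
  n <- nrow(x$records)
  tab <- table(factor(x$records$label,
                      levels = c("pathogenic", "neutral", "unknown")))
  cat(sprintf("variant_dataset: %d variants (%d pathogenic, %d neutral, %d unknown)\n",
              n, tab[["pathogenic"]], tab[["neutral"]], tab[["unknown"]]))
  if (!is.null(x$features))
    cat(sprintf("  features: %d column(s): %s\n", ncol(x$features$values),
                paste(utils::head(colnames(x$features$values), 8),
                      collapse = ", ")))
  invisible(x)
}

#' Numeric class coding of dataset labels
#'
#' @param dataset a [variant_dataset()].
#' @return integer vector, +1 for neutral and -1 for pathogenic; an
#'   error if any label is `"unknown"`.
#' @export
label_code <- function(dataset) {
  lab <- dataset$records$label
  if (any(lab == "unknown"))
    validation_error("training labels must be pathogenic or neutral")
  ifelse(lab == "neutral", 1L, -1L)
}

#' Read a variant feature table
#'
#' Parses the flat-file layout in which upstream predictor scores are
#' distributed: variants as rows, scores as columns. Identity columns
#' (`gene`, `position`, `ref`, `alt`, `aa_change`, optional `label`)
#' are consumed into variant records; every remaining column becomes a
#' feature. Cells equal to one of the missing-value sentinels, and any
#' cell of a numeric column that does not parse as a number, are
#' recorded as missing.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param na_sentinels strings treated as missing.
#' @return a [variant_dataset()] whose `$features` is a
#'   [feature_matrix()] preserving the file's column order.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "csv"),
                               na_sentinels = c("", "NA", ".")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_sentinels, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.identity_cols, names(raw))
  if (length(missing_cols) > 0)
    format_error(paste0("header lacks identity column(s): ",
                        paste(missing_cols, collapse = ", ")))
  records <- data.frame(
    gene = raw$gene,
    position = as.integer(raw$position),
    ref = toupper(raw$ref), alt = toupper(raw$alt),
    aa_change = raw$aa_change,
    label = if ("label" %in% names(raw)) raw$label else "unknown",
    stringsAsFactors = FALSE)
  records$label[is.na(records$label)] <- "unknown"
  feat_cols <- setdiff(names(raw), c(.identity_cols, "label"))
  features <- NULL
  if (length(feat_cols) > 0) {
    cols <- lapply(raw[feat_cols], function(col) {
      num <- suppressWarnings(as.numeric(col))
      if (all(is.na(num[!is.na(col)]))) col else num  # keep text columns
    })
    numeric_cols <- vapply(cols, is.numeric, logical(1))
    if (!all(numeric_cols)) {
      # categorical predictor calls are carried as character columns in
      # the raw table slot; the numeric design matrix takes the rest
      attr_cat <- as.data.frame(cols[!numeric_cols],
                                stringsAsFactors = FALSE, check.names = FALSE)
    } else attr_cat <- NULL
    if (any(numeric_cols)) {
      values <- do.call(cbind, cols[numeric_cols])
      colnames(values) <- feat_cols[numeric_cols]
      features <- feature_matrix(values,
                                 kinds = rep("raw_numeric", ncol(values)))
    }
    if (!is.null(attr_cat) && is.null(features)) {
      features <- feature_matrix(matrix(numeric(0), nrow(raw), 0))
    }
    if (!is.null(features)) attr(features, "categorical") <- attr_cat
  }
  variant_dataset(records, features)
}

#' Write a variant feature table
#'
#' Inverse of [read_variant_table()]: values are serialized at full
#' double precision (17 significant digits) so a write/read round trip
#' is lossless for both values and missingness.
#'
#' @param dataset a [variant_dataset()].
#' @param path output file.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(dataset, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- dataset$records
  if (all(out$label == "unknown")) out$label <- NULL
  fm <- dataset$features
  if (!is.null(fm)) {
    vals <- fm$values
    txt <- apply(vals, 2, function(col)
      ifelse(is.na(col), NA_character_, formatC(col, digits = 17, format = "g")))
    txt <- as.data.frame(matrix(txt, nrow = nrow(vals)),
                         stringsAsFactors = FALSE)
    names(txt) <- colnames(vals)
    cat_cols <- attr(fm, "categorical")
    if (!is.null(cat_cols)) txt <- cbind(txt, cat_cols)
    out <- cbind(out, txt)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Derive pathogenicity labels from curation evidence
#'
#' Applies the curation rules used to build the training corpus from
#' MITOMAP and dbSNP evidence: a variant described in MITOMAP
#' (confirmed or reported) is pathogenic unless MITOMAP explicitly
#' marks it non-pathogenic, in which case it is neutral; a variant
#' known only to dbSNP with no reported pathological consequence is
#' neutral; a dbSNP pathological flag makes it pathogenic.
#'
#' @param entries data.frame with columns `mitomap_status`
#'   (`"confirmed"`, `"reported"`, `"absent"`), `mitomap_pathogenic`
#'   (logical, `NA` when MITOMAP gives no explicit polarity) and
#'   `dbsnp_clinical` (`"pathological"`, `"none"`, `"absent"`).
#' @return character vector of `"pathogenic"`/`"neutral"`, one per entry.
#' @export
assign_labels <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("mitomap_status", "mitomap_pathogenic", "dbsnp_clinical")
  miss <- setdiff(needed, names(entries))
  if (length(miss) > 0)
    format_error(paste0("curation table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  ms <- entries$mitomap_status
  mp <- entries$mitomap_pathogenic
  db <- entries$dbsnp_clinical
  if (any(ms == "absent" & db == "absent"))
    curation_error("entries with neither MITOMAP nor dbSNP evidence cannot be labeled")
  conflict <- which(!is.na(mp) & !mp & db == "pathological")
  if (length(conflict) > 0)
    curation_error(paste0(
      "contradictory curation (explicitly non-pathogenic in MITOMAP but ",
      "pathological in dbSNP) at entry ", paste(conflict, collapse = ", ")))
  in_mitomap <- ms %in% c("confirmed", "reported")
  out <- ifelse(in_mitomap & !(!is.na(mp) & !mp), "pathogenic",
         ifelse(in_mitomap, "neutral",
         ifelse(db == "pathological", "pathogenic", "neutral")))
  out
}

#' Per-gene variant counts and pathogenic fractions
#'
#' @param dataset a labeled [variant_dataset()].
#' @return data.frame with one row per gene present: `gene`, `total`,
#'   `pathogenic`, `pathogenic_pct` (one decimal).
#' @export
summarize_by_gene <- function(dataset) {
  rec <- dataset$records
  if (nrow(rec) == 0)
    return(data.frame(gene = character(0), total = integer(0),
                      pathogenic = integer(0), pathogenic_pct = numeric(0)))
  genes <- sort(unique(rec$gene))
  total <- vapply(genes, function(g) sum(rec$gene == g), integer(1))
  path  <- vapply(genes, function(g)
    sum(rec$gene == g & rec$label == "pathogenic"), integer(1))
  data.frame(gene = genes, total = total, pathogenic = path,
             pathogenic_pct = round_half_up(100 * path / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
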