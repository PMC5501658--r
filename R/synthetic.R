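# Synthetic two-class variant feature tables with the statistical
# structure the classifier assumes: class-conditional normal scores
# for numeric predictors, class-conditional Bernoulli harmful-call
# rates for categorical predictors, and per-predictor missingness.
# Defaults mirror the real training corpus: 223 pathogenic and 641
# neutral variants. No attempt is made to imitate the correlation
# structure among real predictors.

#' Describe one synthetic predictor
#'
#' @param name column name.
#' @param kind `"numeric"` (class-conditional normal score) or
#'   `"categorical"` (class-conditional harmful-call rate, encoded
#'   harmful = 1 / neutral = 0).
#' @param mean_pathogenic,mean_neutral,sd normal parameters (numeric
#'   kind).
#' @param p_harmful_pathogenic,p_harmful_neutral harmful-call
#'   probability per class (categorical kind).
#' @param missing_rate per-cell Bernoulli missingness rate.
#' @return a list describing the predictor.
#' @export
predictor_spec <- function(name, kind = c("numeric", "categorical"),
                           mean_pathogenic = 1, mean_neutral = 0, sd = 1,
                           p_harmful_pathogenic = 0.6,
                           p_harmful_neutral = 0.3,
                           missing_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(missing_rate >= 0, missing_rate <= 1, sd > 0)
  list(name = name, kind = kind,
       mean_pathogenic = mean_pathogenic, mean_neutral = mean_neutral,
       sd = sd, p_harmful_pathogenic = p_harmful_pathogenic,
       p_harmful_neutral = p_harmful_neutral, missing_rate = missing_rate)
}

#' Default synthetic predictor panel
#'
#' Ten predictors emulating a realistic score table: seven numeric
#' scores whose class means are one pooled standard deviation apart
#' (individually weak predictors, informative in aggregate, as the
#' real panel is) and three dichotomous callers. Missingness rates on
#' three of the columns mirror the coverage gaps of the real panel
#' (about 15%, 12% and 3% unpredicted), exercising the
#' excluded-from-counts logic downstream.
#'
#' @return list of [predictor_spec()]s.
#' @export
default_predictor_panel <- function() {
  list(
    predictor_spec("score_a", "numeric", 1, 0, 1),
    predictor_spec("score_b", "numeric", 1, 0, 1),
    predictor_spec("score_c", "numeric", 1, 0, 1),
    predictor_spec("score_d", "numeric", 1, 0, 1, missing_rate = 0.15),
    predictor_spec("score_e", "numeric", 1, 0, 1, missing_rate = 0.12),
    predictor_spec("score_f", "numeric", 1, 0, 1, missing_rate = 0.03),
    predictor_spec("score_g", "numeric", 1, 0, 1),
    predictor_spec("call_a", "categorical", p_harmful_pathogenic = 0.6,
                   p_harmful_neutral = 0.3),
    predictor_spec("call_b", "categorical", p_harmful_pathogenic = 0.6,
                   p_harmful_neutral = 0.3),
    predictor_spec("call_c", "categorical", p_harmful_pathogenic = 0.55,
                   p_harmful_neutral = 0.35))
}

#' Simulation configuration
#'
#' @param n_pathogenic,n_neutral class sizes; the defaults (223 and
#'   641) match the real training corpus of 864 variants.
#' @param predictors list of [predictor_spec()]s.
#' @param seed RNG seed; the generated table is fully reproducible
#'   from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_pathogenic = 223, n_neutral = 641,
                              predictors = default_predictor_panel(),
                              seed = 42) {
  if (n_pathogenic < 1 || n_neutral < 1)
    apogee_error("both class sizes must be positive", "apogee_config_error")
  structure(list(n_pathogenic = as.integer(n_pathogenic),
                 n_neutral = as.integer(n_neutral),
                 predictors = predictors, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a labeled synthetic dataset
#'
#' Rows are drawn i.i.d. from the class-conditional distributions of
#' the configured predictors; missing cells are placed by independent
#' Bernoulli draws per column. Variant identities are synthesized over
#' the 13 real mitochondrial protein-coding gene symbols with
#' positions inside the genes' rCRS coding spans and unique
#' (position, alt) keys.
#'
#' @param config a [simulation_config()].
#' @return a [variant_dataset()] with a row-aligned
#'   [feature_matrix()]; pathogenic rows come first.
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_pathogenic + config$n_neutral
  label <- rep(c("pathogenic", "neutral"),
               c(config$n_pathogenic, config$n_neutral))
  is_path <- label == "pathogenic"
  cols <- list(); kinds <- character(0)
  for (ps in config$predictors) {
    if (ps$kind == "numeric") {
      x <- stats::rnorm(n, mean = ifelse(is_path, ps$mean_pathogenic,
                                         ps$mean_neutral), sd = ps$sd)
      kinds <- c(kinds, "raw_numeric")
    } else {
      x <- as.numeric(stats::runif(n) <
                        ifelse(is_path, ps$p_harmful_pathogenic,
                               ps$p_harmful_neutral))
      kinds <- c(kinds, "dichotomized")
    }
    if (ps$missing_rate > 0)
      x[stats::runif(n) < ps$missing_rate] <- NA_real_
    cols[[ps$name]] <- x
  }
  values <- matrix(unlist(cols, use.names = FALSE), nrow = n)
  colnames(values) <- names(cols)
  features <- feature_matrix(values, kinds = kinds)
  records <- .synth_identities(n)
  records$label <- label
  variant_dataset(records, features)
}

# identities over the real gene spans with unique (position, alt) keys
.synth_identities <- function(n) {
  spans <- mito_gene_spans
  weights <- spans$end - spans$start + 1
  bases <- c("A", "C", "G", "T")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  gi <- sample(nrow(spans), n, replace = TRUE, prob = weights)
  # unique positions guarantee unique (position, alt) keys
  position <- integer(n)
  used <- new.env(hash = TRUE)
  for (k in seq_len(n)) {
    repeat {
      p <- sample(spans$start[gi[k]]:spans$end[gi[k]], 1)
      key <- as.character(p)
      if (is.null(used[[key]])) { used[[key]] <- TRUE; break }
    }
    position[k] <- p
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  aa_pos <- pmax(1L, (position - spans$start[gi]) %/% 3L + 1L)
  data.frame(gene = spans$gene[gi], position = position,
             ref = ref, alt = unname(alt),
             aa_change = paste0(sample(aa, n, replace = TRUE), aa_pos,
                                sample(aa, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

#' Generate a coevolution matrix with planted signal
#'
#' Symmetric L x L matrix of background noise strictly below the
#' coevolution cutoff, plus exactly `n_hot_pairs` planted pairs at
#' `z_hot`; a fixture for the supra-threshold pair-selection rule.
#'
#' @param L protein length (matrix dimension).
#' @param n_hot_pairs number of planted coevolving pairs (at most
#'   L(L-1)/2).
#' @param z_hot Z-score of the planted pairs (above the 6.5 cutoff).
#' @param seed RNG seed.
#' @param z_cut background stays strictly below this value.
#' @return symmetric numeric matrix with `NA` diagonal.
#' @export
generate_mi_matrix <- function(L, n_hot_pairs, z_hot = 8, seed = 1,
                               z_cut = 6.5) {
  stopifnot(L >= 2, n_hot_pairs >= 0, n_hot_pairs <= L * (L - 1) / 2,
            z_hot > z_cut)
  set.seed(as.integer(seed))
  m <- matrix(0, L, L)
  bg <- stats::rnorm(L * (L - 1) / 2, mean = 0, sd = 2)
  bg <- pmin(bg, z_cut - 1e-6)
  m[upper.tri(m)] <- bg
  if (n_hot_pairs > 0) {
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    hot <- pairs[sample(nrow(pairs), n_hot_pairs), , drop = FALSE]
    m[hot] <- z_hot
  }
  m <- m + t(m)
  diag(m) <- NA
  m
}

#' Permute the labels of a dataset
#'
#' Null-model fixture: the label multiset is preserved while the
#' assignment to variants is permuted uniformly at random.
#'
#' @param dataset a labeled [variant_dataset()].
#' @param seed RNG seed.
#' @return the dataset with shuffled labels.
#' @export
permute_labels <- function(dataset, seed = 1) {
  set.seed(as.integer(seed))
  dataset$records$label <- sample(dataset$records$label)
  dataset
}
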