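# Class-balanced bootstrap aggregation of logistic model trees with
# out-of-bag probability accumulation. Each of the (by default 100)
# iterations draws, with replacement, 70% of the pathogenic variants
# and the same number of neutral variants, fits an LMT on the in-bag
# sample, and scores the out-of-bag variants; a variant's final
# probability is the mean of its out-of-bag probabilities and it is
# called pathogenic when that mean strictly exceeds 0.5.

#' Bootstrap specification
#'
#' @param n_iterations bootstrap resamples (default 100).
#' @param pathogenic_fraction fraction of the pathogenic class drawn
#'   per iteration; the same *number* of neutral variants is drawn, so
#'   every in-bag sample is class-balanced (default 0.7).
#' @param seed master seed; one sub-seed per iteration is derived from
#'   it deterministically.
#' @param control per-iteration [lmt_control()].
#' @return an object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_iterations = 100, pathogenic_fraction = 0.7,
                           seed = 1, control = lmt_control()) {
  stopifnot(n_iterations >= 1,
            pathogenic_fraction > 0, pathogenic_fraction <= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 pathogenic_fraction = pathogenic_fraction,
                 seed = as.integer(seed), control = control),
            class = "bootstrap_spec")
}

#' Draw one class-balanced bootstrap sample
#'
#' Draws m = round(fraction x n_pathogenic) indices with replacement
#' from the pathogenic class and m more from the neutral class; the
#' out-of-bag set is every index never drawn.
#'
#' @param y labels (+1/-1 or `"neutral"`/`"pathogenic"`).
#' @param spec a [bootstrap_spec()].
#' @param iteration_seed RNG seed for this draw.
#' @return list with `in_bag` (index multiset of length 2m) and `oob`
#'   (sorted index set).
#' @export
draw_balanced_bootstrap <- function(y, spec, iteration_seed) {
  y <- .coerce_pm1(y)
  path_idx <- which(y == -1L)
  neut_idx <- which(y == 1L)
  if (length(path_idx) == 0 || length(neut_idx) == 0)
    validation_error("both classes must be present")
  m <- round(spec$pathogenic_fraction * length(path_idx))
  if (m == 0)
    apogee_error("pathogenic_fraction too small: zero draws per class",
                 "apogee_spec_error")
  set.seed(as.integer(iteration_seed))
  in_bag <- c(sample(path_idx, m, replace = TRUE),
              sample(neut_idx, m, replace = TRUE))
  list(in_bag = in_bag, oob = setdiff(seq_along(y), in_bag))
}

#' Analytic bootstrap inclusion frequency
#'
#' Probability that a given member of a class of size `n` appears at
#' least once among `m` draws with replacement from that class:
#' 1 - (1 - 1/n)^m. With the default balanced scheme (m = round(0.7 x
#' 223) = 156 draws) this gives 50% for the pathogenic class (n = 223)
#' and 22% for the neutral class (n = 641), to the nearest percent.
#'
#' @param class_size class size n (>= 1).
#' @param draws number of with-replacement draws m (>= 0).
#' @return inclusion probability in \[0, 1\].
#' @export
expected_inclusion_frequency <- function(class_size, draws) {
  stopifnot(class_size >= 1, draws >= 0)
  1 - (1 - 1 / class_size)^draws
}

#' Train the bootstrap LMT ensemble
#'
#' Per iteration: draw a class-balanced bootstrap sample, fit the
#' missing-value imputer on the in-bag rows only, induce an LMT on the
#' imputed in-bag sample, and score the out-of-bag rows, appending
#' their pathogenicity probabilities to per-variant accumulators. The
#' whole run is reproducible from the master seed.
#'
#' @param X a [feature_matrix()] or dense numeric matrix.
#' @param y labels (+1/-1 or `"neutral"`/`"pathogenic"`).
#' @param spec a [bootstrap_spec()].
#' @param verbose print a progress line every 20 iterations.
#' @return an object of class `apogee_ensemble` holding the member
#'   models, in-bag index multisets, per-variant OOB accumulators and
#'   the [bootstrap_spec()].
#' @export
train_ensemble <- function(X, y, spec = bootstrap_spec(), verbose = FALSE) {
  fm <- if (inherits(X, "feature_matrix")) X
        else feature_matrix(as.matrix(X))
  y <- .coerce_pm1(y)
  if (length(y) != nrow(fm$values))
    validation_error("length(y) != nrow(X)")
  n <- length(y)
  # reserve extra sub-seeds for (rare) degenerate-sample redraws
  seeds <- spawn_seeds(spec$seed, 2L * spec$n_iterations)
  next_spare <- spec$n_iterations + 1L
  members <- vector("list", spec$n_iterations)
  oob_probs <- vector("list", n)
  redraws <- integer(0)
  for (b in seq_len(spec$n_iterations)) {
    draw_seed <- seeds[b]
    repeat {
      draw <- draw_balanced_bootstrap(y, spec, draw_seed)
      if (length(unique(y[draw$in_bag])) == 2) break
      redraws <- c(redraws, b)
      draw_seed <- seeds[next_spare]; next_spare <- next_spare + 1L
    }
    imputer <- impute_fit(fm, rows = draw$in_bag)
    dense <- impute_apply(fm, imputer)
    model <- induce_lmt(dense[draw$in_bag, , drop = FALSE], y[draw$in_bag],
                        control = spec$control)
    if (length(draw$oob) > 0) {
      p <- predict_proba(model, dense[draw$oob, , drop = FALSE])
      for (k in seq_along(draw$oob)) {
        i <- draw$oob[k]
        oob_probs[[i]] <- c(oob_probs[[i]], p[k])
      }
    }
    members[[b]] <- list(model = model, imputer = imputer,
                         in_bag = draw$in_bag, seed = draw_seed)
    if (verbose && b %% 20 == 0)
      message(sprintf("iteration %d/%d", b, spec$n_iterations))
  }
  structure(list(members = members, spec = spec,
                 vocab = colnames(fm$values), features = fm, y = y,
                 oob_probs = oob_probs, redraws = redraws),
            class = "apogee_ensemble")
}

#' @export
print.apogee_ensemble <- function(x, ...) {
  cat(sprintf("apogee_ensemble: %d member LMT(s) over %d variants, %d feature(s)\n",
              length(x$members), length(x$y), length(x$vocab)))
  invisible(x)
}

#' Aggregate out-of-bag probabilities into final calls
#'
#' A variant's probability is the mean of the out-of-bag probabilities
#' accumulated over every iteration in which it was out-of-bag; the
#' call is pathogenic when the mean strictly exceeds 0.5 (a mean of
#' exactly 0.5 is neutral). A variant that was never out-of-bag (the
#' event is vanishingly rare at 100 iterations) receives the mean
#' probability over all member models instead, and is flagged.
#'
#' @param ensemble a trained [train_ensemble()] result.
#' @return data.frame with `mean_prob`, `call` (`"P"`/`"N"`), `n_oob`
#'   and `never_oob`, one row per training variant.
#' @export
classify_oob <- function(ensemble) {
  n <- length(ensemble$y)
  n_oob <- vapply(ensemble$oob_probs, length, integer(1))
  mean_prob <- vapply(ensemble$oob_probs, function(p)
    if (length(p) > 0) mean(p) else NA_real_, numeric(1))
  never <- which(n_oob == 0)
  if (length(never) > 0) {
    dense_rows <- ensemble$features
    fallback <- .ensemble_mean_prob(ensemble, dense_rows, rows = never)
    mean_prob[never] <- fallback
  }
  data.frame(mean_prob = mean_prob,
             call = ifelse(mean_prob > 0.5, "P", "N"),
             n_oob = n_oob, never_oob = n_oob == 0)
}

.ensemble_mean_prob <- function(ensemble, fm, rows = seq_len(nrow(fm$values))) {
  acc <- numeric(length(rows))
  for (member in ensemble$members) {
    dense <- impute_apply(fm, member$imputer)
    acc <- acc + predict_proba(member$model, dense[rows, , drop = FALSE])
  }
  acc / length(ensemble$members)
}

#' Predict new variants with a trained ensemble
#'
#' Mean probability over all member models (each member imputes
#' missing cells with its own in-bag imputer); calls use the same
#' strict > 0.5 rule as the out-of-bag aggregation.
#'
#' @param ensemble a trained [train_ensemble()] result.
#' @param X_new [feature_matrix()] or dense matrix over the training
#'   vocabulary.
#' @return data.frame with `prob` and `call` columns.
#' @export
predict_new <- function(ensemble, X_new) {
  fm <- if (inherits(X_new, "feature_matrix")) X_new
        else feature_matrix(as.matrix(X_new))
  if (!identical(colnames(fm$values), ensemble$vocab))
    validation_error(paste0("feature vocabulary mismatch; expected: ",
                            paste(ensemble$vocab, collapse = ", ")))
  all_missing <- rowSums(!fm$mask) == 0
  if (any(all_missing))
    warning(sum(all_missing),
            " row(s) have no observed features; predictions are imputed",
            call. = FALSE)
  prob <- .ensemble_mean_prob(ensemble, fm)
  data.frame(prob = prob, call = ifelse(prob > 0.5, "P", "N"))
}

# ---- serialization -------------------------------------------------

#' Save an ensemble to a directory
#'
#' Writes one JSON document per member model plus a manifest carrying
#' the bootstrap spec, per-member seeds, imputers, in-bag indices, accumulated
#' OOB probabilities and a vocabulary checksum.
#'
#' @param ensemble a trained [train_ensemble()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in seq_along(ensemble$members))
    lmt_to_json(ensemble$members[[b]]$model,
                file.path(dir, sprintf("member_%03d.json", b)))
  manifest <- list(
    format = "apogee-ensemble", version = 1L,
    n_iterations = ensemble$spec$n_iterations,
    pathogenic_fraction = ensemble$spec$pathogenic_fraction,
    seed = ensemble$spec$seed,
    control = unclass(ensemble$spec$control),
    vocab = ensemble$vocab,
    vocab_checksum = sum(utf8ToInt(paste(ensemble$vocab, collapse = "|"))),
    y = ensemble$y,
    redraws = ensemble$redraws,
    member_seeds = vapply(ensemble$members, `[[`, numeric(1), "seed"),
    imputers = lapply(ensemble$members, function(m) as.list(m$imputer$fill)),
    in_bag = lapply(ensemble$members, `[[`, "in_bag"),
    oob_probs = ensemble$oob_probs)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load an ensemble saved with [save_ensemble()]
#'
#' The reloaded ensemble predicts but does not retain the training
#' feature matrix; [predict_new()] works, [classify_oob()] works for
#' variants with a non-empty accumulator.
#'
#' @param dir directory written by [save_ensemble()].
#' @return an `apogee_ensemble`.
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  if (!identical(man$format, "apogee-ensemble"))
    format_error("not an apogee ensemble directory")
  vocab <- vapply(man$vocab, as.character, character(1))
  ctl <- man$control
  control <- lmt_control(ctl$min_node_size,
                         if (is.null(ctl$max_depth)) Inf
                         else as.numeric(ctl$max_depth),
                         ctl$purity_stop, ctl$boost_iterations,
                         ctl$cv_folds, ctl$max_boost_iterations)
  spec <- bootstrap_spec(man$n_iterations, man$pathogenic_fraction,
                         man$seed, control)
  members <- lapply(seq_len(spec$n_iterations), function(b) {
    model <- lmt_from_json(file.path(dir, sprintf("member_%03d.json", b)))
    fill <- vapply(man$imputers[[b]], as.numeric, numeric(1))
    names(fill) <- names(man$imputers[[b]])
    list(model = model,
         imputer = structure(list(fill = fill), class = "apogee_imputer"),
         in_bag = vapply(man$in_bag[[b]], as.integer, integer(1)),
         seed = man$member_seeds[[b]])
  })
  structure(list(members = members, spec = spec, vocab = vocab,
                 features = NULL,
                 y = vapply(man$y, as.integer, integer(1)),
                 oob_probs = lapply(man$oob_probs, function(p)
                   vapply(p, as.numeric, numeric(1))),
                 redraws = vapply(man$redraws, as.integer, integer(1))),
            class = "apogee_ensemble")
}
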