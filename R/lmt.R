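# Logistic model tree: top-down induction of a binary decision tree by
# information gain on the class labels, with a LogitBoost additive
# logistic model at every leaf, warm-started from the parent node's
# model so that deeper leaves refine rather than restart the fit.

#' Logistic-model-tree hyperparameters
#'
#' @param min_node_size nodes with fewer training instances become
#'   leaves.
#' @param max_depth maximum split depth (`Inf` = unlimited).
#' @param purity_stop a node whose majority-class fraction reaches this
#'   value becomes a leaf.
#' @param boost_iterations LogitBoost iterations added at every node
#'   (fast fixed-iteration mode, the default).
#' @param cv_folds if > 0, the per-node iteration count is instead
#'   chosen once at the root by stratified cross-validation over
#'   `1..max_boost_iterations`.
#' @param max_boost_iterations cap for the cross-validated search.
#' @return an object of class `lmt_control`.
#' @export
lmt_control <- function(min_node_size = 15, max_depth = Inf,
                        purity_stop = 1.0, boost_iterations = 30,
                        cv_folds = 0, max_boost_iterations = 200) {
  stopifnot(min_node_size >= 1, purity_stop > 0.5, purity_stop <= 1,
            boost_iterations >= 0, cv_folds >= 0)
  structure(list(min_node_size = min_node_size, max_depth = max_depth,
                 purity_stop = purity_stop,
                 boost_iterations = boost_iterations,
                 cv_folds = cv_folds,
                 max_boost_iterations = max_boost_iterations),
            class = "lmt_control")
}

.entropy2 <- function(n1, n0) {
  n <- n1 + n0
  p <- n1 / n
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# Best axis-aligned split of (X, ystar) by information gain.
# Candidates are midpoints between consecutive distinct sorted values.
# Ties (within 1e-12) break towards the lower feature index, then the
# most balanced child sizes, then the lower threshold.
.best_split <- function(X, ystar) {
  n <- length(ystar)
  base <- .entropy2(sum(ystar), n - sum(ystar))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- ystar[ord]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0) next
    cum1 <- cumsum(ys)
    nl <- distinct                 # left child sizes
    l1 <- cum1[distinct]
    hl <- .entropy2(l1, nl - l1)
    hr <- .entropy2(cum1[n] - l1, (n - nl) - (cum1[n] - l1))
    gain <- base - (nl * hl + (n - nl) * hr) / n
    gmax <- max(gain)
    tie <- which(gain >= gmax - 1e-12)
    bal <- abs(n - 2 * nl[tie])
    tie <- tie[bal == min(bal)]
    k <- tie[1]                    # lowest threshold among remaining
    thr <- (xs[distinct[k]] + xs[distinct[k] + 1]) / 2
    if (is.null(best) || gmax > best$gain + 1e-12)
      best <- list(var = j, threshold = thr, gain = gmax)
  }
  best
}

.leaf_prior_model <- function(y, vocab) {
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  new_logitboost_model(0.5 * log((n1 + 0.5) / (n0 + 0.5)),
                       stats::setNames(numeric(length(vocab)), vocab),
                       iterations = 0L)
}

#' Induce a logistic model tree
#'
#' Recursively splits the instance space with binary axis-aligned
#' splits chosen by information gain on the class labels, stopping at
#' pure nodes, undersized nodes, the depth cap, or when no candidate
#' split exists; every leaf then holds a LogitBoost model warm-started
#' from its parent. Leaf regions partition the feature space (points
#' equal to a split threshold route left).
#'
#' @param X dense numeric matrix or [feature_matrix()] (imputed with
#'   its own column means/zeros when a mask is present).
#' @param y labels, +1/-1 or `"neutral"`/`"pathogenic"`.
#' @param control an [lmt_control()].
#' @return an object of class `lmt_model`.
#' @export
induce_lmt <- function(X, y, control = lmt_control()) {
  if (inherits(X, "feature_matrix"))
    X <- impute_apply(X, impute_fit(X))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- .coerce_pm1(y)
  if (nrow(X) < 2 || length(unique(y)) < 2)
    apogee_error("need >= 2 instances with both classes present",
                 "apogee_degenerate_model_error")
  vocab <- colnames(X)
  it <- control$boost_iterations
  if (control$cv_folds > 0)
    it <- .cv_boost_iterations(X, y, control)
  ystar <- as.numeric(y == 1)
  leaf_id <- 0L
  n_nodes <- 0L
  max_depth_seen <- 0L

  build <- function(idx, depth, parent_model) {
    n_nodes <<- n_nodes + 1L
    max_depth_seen <<- max(max_depth_seen, depth)
    yi <- y[idx]
    n1 <- sum(yi == 1); n0 <- length(yi) - n1
    model <- if (n1 == 0 || n0 == 0) .leaf_prior_model(yi, vocab)
             else fit_logitboost(X[idx, , drop = FALSE], yi,
                                 iterations = it, warm_start = parent_model)
    purity <- max(n1, n0) / length(yi)
    stop_here <- purity >= control$purity_stop ||
      length(idx) < control$min_node_size ||
      depth >= control$max_depth
    split <- if (stop_here) NULL
             else .best_split(X[idx, , drop = FALSE], ystar[idx])
    if (is.null(split)) {
      leaf_id <<- leaf_id + 1L
      return(list(type = "leaf", id = leaf_id, model = model,
                  n = length(idx), depth = depth))
    }
    go_left <- X[idx, split$var] <= split$threshold
    list(type = "split", var = split$var, varname = vocab[split$var],
         threshold = split$threshold, n = length(idx), depth = depth,
         left = build(idx[go_left], depth + 1L, model),
         right = build(idx[!go_left], depth + 1L, model))
  }

  root <- build(seq_len(nrow(X)), 0L, NULL)
  structure(list(root = root, vocab = vocab, control = control,
                 n_nodes = n_nodes, n_leaves = leaf_id,
                 depth = max_depth_seen, boost_iterations = it),
            class = "lmt_model")
}

# stratified k-fold CV at the root to pick the LogitBoost iteration count
.cv_boost_iterations <- function(X, y, control) {
  k <- control$cv_folds
  maxit <- control$max_boost_iterations
  folds <- integer(length(y))
  for (cls in c(-1L, 1L)) {
    idx <- which(y == cls)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  losses <- matrix(NA_real_, k, maxit)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2 || !any(te)) next
    model <- NULL
    ystar_te <- as.numeric(y[te] == 1)
    for (m in seq_len(maxit)) {
      model <- fit_logitboost(X[tr, , drop = FALSE], y[tr],
                              iterations = 1, warm_start = model)
      Fv <- .lb_F(model, X[te, , drop = FALSE])
      losses[f, m] <- .lb_logloss(Fv, ystar_te)
    }
  }
  mean_loss <- colMeans(losses, na.rm = TRUE)
  which.min(mean_loss)
}

.route <- function(node, X, idx, out) {
  if (node$type == "leaf") {
    if (length(idx) > 0)
      out[idx] <- posterior(node$model, X[idx, , drop = FALSE])[, "pathogenic"]
    return(out)
  }
  go_left <- X[idx, node$var] <= node$threshold
  out <- .route(node$left, X, idx[go_left], out)
  .route(node$right, X, idx[!go_left], out)
}

#' Predict pathogenicity probabilities from a logistic model tree
#'
#' Routes each instance to exactly one leaf and evaluates that leaf's
#' logistic model. The hard call is the maximum-posterior class:
#' pathogenic when the probability exceeds 0.5.
#'
#' @param model an [induce_lmt()] result.
#' @param x feature row or matrix over the model's vocabulary.
#' @return numeric vector of P(pathogenic), one per instance.
#' @export
predict_proba <- function(model, x) {
  X <- .as_model_matrix(x, model$vocab)
  .route(model$root, X, seq_len(nrow(X)), numeric(nrow(X)))
}

#' @export
predict.lmt_model <- function(object, newdata, ...) predict_proba(object, newdata)

#' Extract the decision rules of a logistic model tree
#'
#' One rule per leaf: the conjunction of split predicates on the
#' root-to-leaf path plus the leaf model's logistic coefficients.
#' Taken together the rules cover the feature space exactly once.
#'
#' @param model an [induce_lmt()] result.
#' @return data.frame with `leaf`, `n`, `predicate` and `model`
#'   columns.
#' @export
decision_rules <- function(model) {
  rows <- list()
  walk <- function(node, preds) {
    if (node$type == "leaf") {
      beta <- node$model$beta
      sel <- beta[beta != 0]
      coef_txt <- paste0("F_neutral = ", signif(node$model$intercept, 4),
                         if (length(sel) > 0)
                           paste0(" + ", paste(sprintf("%s*%s", signif(sel, 4),
                                                       names(sel)),
                                               collapse = " + ")) else "")
      rows[[length(rows) + 1]] <<- data.frame(
        leaf = node$id, n = node$n,
        predicate = if (length(preds) == 0) "TRUE"
                    else paste(preds, collapse = " & "),
        model = coef_txt, stringsAsFactors = FALSE)
      return(invisible())
    }
    walk(node$left, c(preds, sprintf("%s <= %s", node$varname,
                                     signif(node$threshold, 6))))
    walk(node$right, c(preds, sprintf("%s > %s", node$varname,
                                      signif(node$threshold, 6))))
  }
  walk(model$root, character(0))
  do.call(rbind, rows)
}

#' @export
print.lmt_model <- function(x, ...) {
  cat(sprintf("lmt_model: %d leaves, depth %d, %d LogitBoost iteration(s)/node\n",
              x$n_leaves, x$depth, x$boost_iterations))
  invisible(x)
}

# ---- serialization -------------------------------------------------

.node_to_list <- function(node) {
  if (node$type == "leaf")
    list(type = "leaf", id = node$id, n = node$n, depth = node$depth,
         intercept = node$model$intercept,
         beta = as.list(node$model$beta),
         iterations = node$model$iterations)
  else
    list(type = "split", var = node$var, varname = node$varname,
         threshold = node$threshold, n = node$n, depth = node$depth,
         left = .node_to_list(node$left), right = .node_to_list(node$right))
}

.node_from_list <- function(lst, vocab) {
  if (lst$type == "leaf") {
    beta <- stats::setNames(vapply(lst$beta, as.numeric, numeric(1)),
                            names(lst$beta))
    list(type = "leaf", id = lst$id, n = lst$n, depth = lst$depth,
         model = new_logitboost_model(lst$intercept, beta,
                                      iterations = lst$iterations))
  } else {
    list(type = "split", var = lst$var, varname = lst$varname,
         threshold = lst$threshold, n = lst$n, depth = lst$depth,
         left = .node_from_list(lst$left, vocab),
         right = .node_from_list(lst$right, vocab))
  }
}

#' Serialize a logistic model tree to JSON
#'
#' Versioned JSON document carrying the tree structure, leaf
#' coefficients at 17 significant digits (an exact double round trip),
#' the vocabulary and the control settings.
#'
#' @param model an `lmt_model`.
#' @param path optional file to write.
#' @return the JSON string, invisibly when `path` is given.
#' @export
lmt_to_json <- function(model, path = NULL) {
  doc <- list(format = "apogee-lmt", version = 1L,
              vocab = model$vocab,
              control = unclass(model$control),
              n_nodes = model$n_nodes, n_leaves = model$n_leaves,
              depth = model$depth, boost_iterations = model$boost_iterations,
              tree = .node_to_list(model$root))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "string")
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' Deserialize a logistic model tree from JSON
#'
#' @param json JSON string or path to a file written by
#'   [lmt_to_json()].
#' @return an `lmt_model`.
#' @export
lmt_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyVector = FALSE)
  if (!identical(doc$format, "apogee-lmt"))
    format_error("not an apogee LMT document")
  vocab <- vapply(doc$vocab, as.character, character(1))
  ctl <- doc$control
  control <- lmt_control(ctl$min_node_size,
                         if (is.null(ctl$max_depth)) Inf
                         else as.numeric(ctl$max_depth),
                         ctl$purity_stop, ctl$boost_iterations,
                         ctl$cv_folds, ctl$max_boost_iterations)
  structure(list(root = .node_from_list(doc$tree, vocab), vocab = vocab,
                 control = control, n_nodes = doc$n_nodes,
                 n_leaves = doc$n_leaves, depth = doc$depth,
                 boost_iterations = doc$boost_iterations),
            class = "lmt_model")
}
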