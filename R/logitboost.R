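# Two-class LogitBoost: stagewise fitting of an additive logistic model
# by one-variable weighted least-squares steps, performing implicit
# variable selection. Classes are coded y = +1 (neutral) and y = -1
# (pathogenic). The model stores F(x) for the neutral class; the
# pathogenic class function is its negation, so the two class functions
# sum to zero identically and the posterior is the softmax over them.

.P_CLAMP <- 1e-12

new_logitboost_model <- function(intercept, beta, iterations, trace = numeric(0)) {
  structure(list(intercept = intercept, beta = beta,
                 iterations = iterations, vocab = names(beta),
                 trace = trace),
            class = "logitboost_model")
}

# F_neutral evaluated on a dense matrix
.lb_F <- function(model, X) {
  drop(model$intercept + X %*% model$beta)
}

.lb_logloss <- function(Fv, ystar) {
  p <- 1 / (1 + exp(-2 * Fv))
  p <- pmin(pmax(p, .P_CLAMP), 1 - .P_CLAMP)
  -mean(ystar * log(p) + (1 - ystar) * log(1 - p))
}

#' Fit an additive logistic model by LogitBoost
#'
#' Each boosting iteration computes working responses and case weights
#' from the current class probabilities, fits a one-variable weighted
#' least-squares regression for every candidate feature, and adds the
#' best one (minimum weighted SSE) to the additive model with a factor
#' of 1/2. If a step would increase the training log-loss it is halved
#' until the loss is non-increasing (boosting stops early if no such
#' step exists), so the training log-loss is monotone non-increasing
#' across iterations. The set of features with a nonzero coefficient
#' is the model's selected-variable set.
#'
#' @param X dense numeric matrix (no missing cells; impute upstream).
#' @param y class labels, +1 = neutral, -1 = pathogenic (or the
#'   strings `"neutral"`/`"pathogenic"`).
#' @param iterations number of boosting iterations; 0 returns the
#'   class-prior constant model (or `warm_start` unchanged).
#' @param warm_start an existing model to continue boosting from, as
#'   when a tree leaf refines its parent's model.
#' @return an object of class `logitboost_model` with elements
#'   `intercept`, `beta` (named coefficient vector), `iterations` and
#'   `trace` (training log-loss after each iteration).
#' @export
fit_logitboost <- function(X, y, iterations = 30, warm_start = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) validation_error("X must be dense; impute missing cells first")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- .coerce_pm1(y)
  if (length(y) != nrow(X)) validation_error("length(y) != nrow(X)")
  ystar <- as.numeric(y == 1)
  n1 <- sum(ystar); n0 <- length(ystar) - n1
  if (n1 == 0 || n0 == 0)
    apogee_error("both classes must be present to fit a logistic model",
                 "apogee_degenerate_model_error")
  if (is.null(warm_start)) {
    # prior-only start: P(neutral) equals the empirical class frequency
    model <- new_logitboost_model(0.5 * log(n1 / n0),
                                  stats::setNames(numeric(ncol(X)), colnames(X)),
                                  iterations = 0L)
  } else {
    stopifnot(inherits(warm_start, "logitboost_model"))
    if (!identical(warm_start$vocab, colnames(X)))
      validation_error("warm-start model vocabulary does not match X")
    model <- warm_start
  }
  if (iterations == 0) return(model)

  intercept <- model$intercept
  beta <- model$beta
  Fv <- drop(intercept + X %*% beta)
  loss <- .lb_logloss(Fv, ystar)
  trace <- numeric(iterations)
  done <- 0L
  for (m in seq_len(iterations)) {
    p <- 1 / (1 + exp(-2 * Fv))
    p <- pmin(pmax(p, .P_CLAMP), 1 - .P_CLAMP)
    w <- pmax(p * (1 - p), .P_CLAMP)
    z <- (ystar - p) / w
    # closed-form weighted simple linear regression for every column
    sw <- sum(w)
    swz <- sum(w * z)
    swx <- colSums(w * X)
    swxz <- drop(crossprod(X, w * z))
    swxx <- colSums(w * X * X)
    denom <- swxx - swx^2 / sw
    b <- ifelse(denom > 1e-12, (swxz - swx * swz / sw) / pmax(denom, 1e-12), 0)
    a <- (swz - b * swx) / sw
    szz <- sum(w * z * z)
    sse <- szz - a * swz - b * swxz
    # candidate features in SSE order; half-step, halved further while
    # the training log-loss would rise, falling through to the next
    # feature if no step on this one improves the loss
    accepted <- FALSE
    for (j in order(sse)) {
      step <- 0.5
      repeat {
        F_new <- Fv + step * (a[j] + b[j] * X[, j])
        loss_new <- .lb_logloss(F_new, ystar)
        if (loss_new <= loss + 1e-12 || step < 1e-4) break
        step <- step / 2
      }
      if (loss_new <= loss + 1e-12 && loss_new < loss) {
        intercept <- intercept + step * a[j]
        beta[j] <- beta[j] + step * b[j]
        Fv <- F_new
        loss <- loss_new
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break  # converged: no single-variable step helps
    done <- m
    trace[m] <- loss
  }
  new_logitboost_model(intercept, beta,
                       iterations = model$iterations + done,
                       trace = c(model$trace, trace[seq_len(done)]))
}

.coerce_pm1 <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("pathogenic", "neutral"))
    if (length(bad) > 0)
      validation_error("labels must be 'pathogenic' or 'neutral'")
    return(ifelse(y == "neutral", 1L, -1L))
  }
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L)))
    validation_error("numeric labels must be +1 (neutral) or -1 (pathogenic)")
  y
}

#' Class posterior of an additive logistic model
#'
#' Softmax over the two class functions under the sum-to-zero
#' constraint F_neutral + F_pathogenic = 0:
#' P(neutral | x) = exp(F) / (exp(F) + exp(-F)) with F = F_neutral(x).
#'
#' @param model a `logitboost_model`.
#' @param x feature row (named numeric vector) or dense matrix with
#'   the model's vocabulary as columns.
#' @return matrix with columns `pathogenic` and `neutral`; each row
#'   sums to 1.
#' @export
posterior <- function(model, x) {
  X <- .as_model_matrix(x, model$vocab)
  Fv <- .lb_F(model, X)
  p_neut <- 1 / (1 + exp(-2 * Fv))
  # keep probabilities in the open interval even at saturation
  p_neut <- pmin(pmax(p_neut, .P_CLAMP), 1 - .P_CLAMP)
  cbind(pathogenic = 1 - p_neut, neutral = p_neut)
}

.as_model_matrix <- function(x, vocab) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  X <- as.matrix(x)
  if (ncol(X) != length(vocab))
    validation_error(sprintf("expected %d feature(s), got %d",
                             length(vocab), ncol(X)))
  if (!is.null(colnames(X)) && !identical(colnames(X), vocab)) {
    if (!all(vocab %in% colnames(X)))
      validation_error("feature names do not match the model vocabulary")
    X <- X[, vocab, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}

#' @export
print.logitboost_model <- function(x, ...) {
  sel <- names(x$beta)[x$beta != 0]
  cat(sprintf("logitboost_model: %d iteration(s), %d/%d feature(s) selected\n",
              x$iterations, length(sel), length(x$beta)))
  invisible(x)
}
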