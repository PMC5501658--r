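test_that("posterior is the sum-to-zero softmax", {
  # F_neutral = F_pathogenic = 0 -> (0.5, 0.5)
  m0 <- apogee:::new_logitboost_model(0, stats::setNames(0, "x1"), 0L)
  expect_equal(unname(posterior(m0, cbind(x1 = 0))[1, ]), c(0.5, 0.5))
  # F_neutral = +1, F_pathogenic = -1 -> P(neutral) = e/(e + e^-1)
  m1 <- apogee:::new_logitboost_model(1, stats::setNames(0, "x1"), 0L)
  expect_equal(unname(posterior(m1, cbind(x1 = 0))[1, "neutral"]),
               exp(1) / (exp(1) + exp(-1)), tolerance = 1e-12)
  # probabilities sum to 1 on random inputs
  set.seed(2)
  m <- apogee:::new_logitboost_model(0.3, stats::setNames(c(1.2, -0.7),
                                                          c("a", "b")), 5L)
  X <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  p <- posterior(m, X)
  expect_equal(rowSums(p), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  expect_error(posterior(m, cbind(a = 1)), class = "apogee_validation_error")
})

test_that("LogitBoost separates a 1-D toy set and keeps its invariants", {
  X <- cbind(x1 = c(-1, -0.9, 0.9, 1))
  y <- c(-1L, -1L, 1L, 1L)
  m <- fit_logitboost(X, y, iterations = 30)
  p <- posterior(m, X)[, "pathogenic"]
  expect_equal(mean((p > 0.5) == (y == -1)), 1)
  # decision boundary sign agrees with an independent logistic fit
  glm_fit <- suppressWarnings(glm(I(y == 1) ~ x1, family = binomial,
                                  data = data.frame(x1 = X[, 1], y = y)))
  grid <- cbind(x1 = seq(-2, 2, length.out = 101))
  ours <- posterior(m, grid)[, "neutral"] > 0.5
  theirs <- predict(glm_fit, data.frame(x1 = grid[, 1]),
                    type = "response") > 0.5
  expect_equal(unname(ours), unname(theirs))
  # training log-loss is monotone non-increasing
  expect_true(all(diff(m$trace) <= 1e-12))
  # monotone probability in the feature on separable 1-D data
  expect_true(all(diff(posterior(m, grid)[, "neutral"]) >= 0))
})

test_that("flipping all labels negates the additive model", {
  set.seed(4)
  X <- cbind(x1 = rnorm(60), x2 = rnorm(60))
  y <- ifelse(X[, 1] + rnorm(60, sd = 0.8) > 0, 1L, -1L)
  if (length(unique(y)) < 2) skip("degenerate draw")
  m <- fit_logitboost(X, y, iterations = 20)
  mf <- fit_logitboost(X, -y, iterations = 20)
  expect_equal(mf$beta, -m$beta, tolerance = 1e-6)
  # posteriors mirror
  p <- posterior(m, X)[, "neutral"]
  pf <- posterior(mf, X)[, "neutral"]
  expect_equal(pf, 1 - p, tolerance = 1e-6)
})

test_that("zero iterations yield the class-prior model", {
  X <- cbind(x1 = rnorm(8))
  y <- c(-1L, 1L, 1L, 1L, -1L, 1L, 1L, 1L)
  m <- fit_logitboost(X, y, iterations = 0)
  expect_equal(unname(posterior(m, X)[, "neutral"]), rep(0.75, 8),
               tolerance = 1e-12)
  expect_error(fit_logitboost(X, rep(1L, 8)),
               class = "apogee_degenerate_model_error")
})

test_that("depth-0 LMT agrees with an independent logistic oracle on a grid", {
  d <- make_gaussian_2d(n = 200, seed = 11)
  lmt <- induce_lmt(d$X, d$y, lmt_control(max_depth = 0,
                                          boost_iterations = 200))
  df <- data.frame(f1 = d$X[, 1], f2 = d$X[, 2], y = d$y == 1)
  oracle <- glm(y ~ f1 + f2, family = binomial, data = df)
  grid <- as.matrix(expand.grid(f1 = seq(-3, 4, length.out = 50),
                                f2 = seq(-3, 4, length.out = 50)))
  ours <- predict_proba(lmt, grid) > 0.5
  theirs <- predict(oracle, as.data.frame(grid), type = "response") < 0.5
  expect_gte(mean(ours == theirs), 0.98)
})

test_that("XOR clusters need a split and the tree finds a perfect one", {
  d <- make_xor()
  lmt <- induce_lmt(d$X, d$y)
  acc <- mean((predict_proba(lmt, d$X) > 0.5) == (d$y == -1))
  expect_equal(acc, 1.0)
  expect_gte(lmt$n_leaves, 2)  # at least one split
  flat <- induce_lmt(d$X, d$y, lmt_control(max_depth = 0))
  acc0 <- mean((predict_proba(flat, d$X) > 0.5) == (d$y == -1))
  expect_lte(acc0, 0.75)
})

test_that("pure nodes stop and depth-0 equals plain LogitBoost", {
  X <- cbind(x1 = rnorm(30))
  y <- rep(1L, 30)
  y[1] <- -1L  # keep both classes so fitting is defined
  pure <- induce_lmt(cbind(x1 = rnorm(20)), rep(c(1L, -1L), c(19, 1)),
                     lmt_control(purity_stop = 0.9))
  expect_equal(pure$n_leaves, 1)

  d <- make_gaussian_2d(n = 100, seed = 13)
  flat <- induce_lmt(d$X, d$y, lmt_control(max_depth = 0,
                                           boost_iterations = 25))
  direct <- fit_logitboost(d$X, d$y, iterations = 25)
  expect_equal(predict_proba(flat, d$X),
               posterior(direct, d$X)[, "pathogenic"], tolerance = 1e-12)
})

test_that("a pure all-neutral leaf predicts neutral for every routed input", {
  # left half all neutral, right half mixed: the split isolates a pure
  # neutral region whose leaf must give P(neutral) > 0.5 everywhere
  set.seed(19)
  X <- cbind(x1 = c(rnorm(10, -2, 0.3), rnorm(10, 2, 0.3)))
  y <- c(rep(1L, 10), rep(c(-1L, 1L), 5))
  lmt <- induce_lmt(X, y, lmt_control(min_node_size = 4))
  expect_gte(lmt$n_leaves, 2)
  p_left <- predict_proba(lmt, cbind(x1 = seq(-6, -1, 0.5)))
  expect_true(all(p_left < 0.5))
})

test_that("routing is deterministic: threshold ties go left", {
  # hand-built tree with one split at 0
  leafL <- list(type = "leaf", id = 1L, n = 1L, depth = 1L,
                model = apogee:::new_logitboost_model(
                  3, stats::setNames(0, "x1"), 0L))
  leafR <- list(type = "leaf", id = 2L, n = 1L, depth = 1L,
                model = apogee:::new_logitboost_model(
                  -3, stats::setNames(0, "x1"), 0L))
  tree <- structure(list(root = list(type = "split", var = 1L,
                                     varname = "x1", threshold = 0,
                                     n = 2L, depth = 0L,
                                     left = leafL, right = leafR),
                         vocab = "x1", control = lmt_control(),
                         n_nodes = 3L, n_leaves = 2L, depth = 1L,
                         boost_iterations = 0L),
                    class = "lmt_model")
  p <- predict_proba(tree, cbind(x1 = c(-1, 0, 1)))
  expect_equal(p[2], p[1])      # exactly on the threshold -> left leaf
  expect_true(p[3] != p[1])
  # identical feature rows in the same leaf get identical probabilities
  expect_equal(p[1], predict_proba(tree, cbind(x1 = -1))[1])
})

test_that("prediction is invariant under consistent column permutation", {
  d <- make_gaussian_2d(n = 120, seed = 17)
  lmt <- induce_lmt(d$X, d$y)
  Xp <- d$X[, c("f2", "f1")]
  expect_equal(predict_proba(lmt, Xp), predict_proba(lmt, d$X))
})

test_that("decision rules cover the space with one rule per leaf", {
  d <- make_xor()
  lmt <- induce_lmt(d$X, d$y)
  rules <- decision_rules(lmt)
  expect_equal(nrow(rules), lmt$n_leaves)
  # a 1-split tree yields complementary predicates
  flat <- induce_lmt(d$X, d$y, lmt_control(max_depth = 1))
  r1 <- decision_rules(flat)
  if (nrow(r1) == 2) {
    expect_match(r1$predicate[1], "<=")
    expect_match(r1$predicate[2], ">")
  }
  # depth-0: single rule with the empty predicate
  r0 <- decision_rules(induce_lmt(d$X, d$y, lmt_control(max_depth = 0)))
  expect_equal(nrow(r0), 1)
  expect_equal(r0$predicate, "TRUE")
})

test_that("JSON serialization round-trips models exactly", {
  d <- make_xor()
  lmt <- induce_lmt(d$X, d$y)
  path <- tempfile(fileext = ".json")
  lmt_to_json(lmt, path)
  back <- lmt_from_json(path)
  expect_identical(predict_proba(back, d$X), predict_proba(lmt, d$X))
  expect_equal(back$n_leaves, lmt$n_leaves)
  expect_equal(back$vocab, lmt$vocab)
})

test_that("cross-validated iteration selection runs and is sane", {
  d <- make_gaussian_2d(n = 80, seed = 23)
  lmt <- induce_lmt(d$X, d$y, lmt_control(max_depth = 0, cv_folds = 5,
                                          max_boost_iterations = 40))
  expect_gte(lmt$boost_iterations, 1)
  expect_lte(lmt$boost_iterations, 40)
  acc <- mean((predict_proba(lmt, d$X) > 0.5) == (d$y == -1))
  expect_gte(acc, 0.7)
})
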