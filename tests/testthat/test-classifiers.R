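test_that("entropy matches its closed forms and direct evaluation", {
  expect_equal(entropy(c(5, 5)), 1.0)
  expect_equal(entropy(c(10, 0)), 0.0)
  cc <- c(95, 1534)
  p <- cc / sum(cc)
  expect_equal(entropy(cc), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(entropy(c(0, 0)), "positive total")
  expect_error(entropy(c(-1, 2)), "non-negative")
  # bounds: 0 <= H <= log2(n_classes)
  set.seed(41)
  for (i in 1:20) {
    cc <- rpois(3, 10) + 1
    expect_gte(entropy(cc), 0)
    expect_lte(entropy(cc), log2(3) + 1e-12)
  }
})

test_that("information gain matches the weighted-entropy formula", {
  # perfect separation of (5, 5) gains one full bit
  expect_equal(info_gain(c(5, 5), list(c(5, 0), c(0, 5))), 1.0)
  # children proportional to parent gain nothing
  expect_equal(info_gain(c(6, 4), list(c(3, 2), c(3, 2))), 0.0)
  # random 3-way split vs hand-summed weighted entropies
  parent <- c(40, 60)
  kids <- list(c(10, 5), c(20, 25), c(10, 30))
  hand <- entropy(parent) -
    (15 / 100 * entropy(c(10, 5)) + 45 / 100 * entropy(c(20, 25)) +
       40 / 100 * entropy(c(10, 30)))
  expect_equal(info_gain(parent, kids), hand, tolerance = 1e-12)
  expect_gte(info_gain(parent, kids), 0)
  expect_error(info_gain(c(5, 5), list(c(4, 0), c(0, 5))), "partition")
})

test_that("hoeffding bound has its closed form and monotonicity", {
  expect_equal(hoeffding_bound(1, exp(-2), 1), 1.0)
  expect_lt(hoeffding_bound(1, 1 - 1e-12, 100), 1e-5)  # delta -> 1 => eps -> 0
  for (R in c(0.5, 1, 2)) {
    eps_n <- vapply(c(10, 100, 1000), hoeffding_bound, numeric(1),
                    range = R, delta = 1e-7)
    expect_true(all(diff(eps_n) < 0))
    eps_d <- vapply(c(1e-7, 1e-3, 0.5), hoeffding_bound, numeric(1),
                    range = R, n = 50)
    expect_true(all(diff(eps_d) < 0))
  }
  expect_error(hoeffding_bound(1, 2, 10), "delta")
})

test_that("Poisson(1) bagging weights have the right mean and zero mass", {
  set.seed(42)
  w <- bagging_weights(1e5)
  expect_lt(abs(mean(w) - 1), 0.01)
  expect_lt(abs(mean(w == 0) - exp(-1)), 0.01)
  set.seed(99); w1 <- bagging_weights(100)
  set.seed(99); w2 <- bagging_weights(100)
  expect_identical(w1, w2)
})

test_that("incremental naive Bayes equals the batch fit", {
  set.seed(43)
  n <- 200; d <- 4
  x <- matrix(rnorm(n * d), n, d)
  y <- rbinom(n, 1, 0.4)
  clf <- classifier_nb()
  for (i in seq_len(n)) learn_one(clf, x[i, ], y[i])
  for (k in 0:1) {
    xs <- x[y == k, , drop = FALSE]
    expect_equal(clf$mean[k + 1, ], colMeans(xs), tolerance = 1e-9)
    expect_equal(clf$m2[k + 1, ] / (nrow(xs) - 1), apply(xs, 2, var),
                 tolerance = 1e-9)
  }
  expect_equal(unname(clf$n), c(sum(y == 0), sum(y == 1)))
  # predict is stateless and deterministic
  p1 <- predict_one(clf, x[1, ]); p2 <- predict_one(clf, x[1, ])
  expect_identical(p1, p2)
  # pristine learner warns once and defaults to the negative class
  fresh <- reset(clf)
  expect_warning(p <- predict_one(fresh, x[1, ]), "default class")
  expect_equal(p, 0L)
})

test_that("hoeffding tree learns a separable threshold rule", {
  set.seed(44)
  gen <- function(n) {
    x1 <- runif(n, 0, 20)
    x2 <- rnorm(n)
    cbind(x1, x2)
  }
  X <- gen(2000)
  y <- as.integer(X[, 1] > 10)
  tree <- classifier_hoeffding(grace_period = 200, tie_threshold = 0.05)
  for (i in seq_len(nrow(X))) learn_one(tree, X[i, ], y[i])
  Xh <- gen(500)
  yh <- as.integer(Xh[, 1] > 10)
  preds <- vapply(seq_len(nrow(Xh)), function(i) predict_one(tree, Xh[i, ]),
                  integer(1))
  expect_gt(mean(preds == yh), 0.95)
  expect_false(tree$root$is_leaf)        # it actually split
  expect_equal(tree$root$split_feature, 1L)
})

test_that("degenerate streams never split the tree", {
  # single-class stream: entropy 0 everywhere
  tree <- classifier_hoeffding(grace_period = 50)
  set.seed(45)
  for (i in 1:500) learn_one(tree, rnorm(3), 1L)
  expect_true(tree$root$is_leaf)
  expect_equal(predict_one(tree, rnorm(3)), 1L)

  # constant features, mixed labels: zero gain, majority prediction
  tree2 <- classifier_hoeffding(grace_period = 50)
  labs <- rep(c(0L, 0L, 1L), length.out = 300)
  for (i in seq_along(labs)) learn_one(tree2, c(1, 1), labs[i])
  expect_true(tree2$root$is_leaf)
  expect_equal(predict_one(tree2, c(1, 1)), 0L)
})

test_that("online-bagging ensemble is deterministic and at least tree-grade", {
  set.seed(46)
  X <- cbind(runif(1500, 0, 20), rnorm(1500))
  y <- as.integer(X[, 1] > 10)
  run_model <- function(model) {
    for (i in seq_len(nrow(X))) learn_one(model, X[i, ], y[i])
    vapply(1:300, function(i) predict_one(model, X[i, ]), integer(1))
  }
  e1 <- run_model(classifier_bagging(n_learners = 5, seed = 7))
  e2 <- run_model(classifier_bagging(n_learners = 5, seed = 7))
  expect_identical(e1, e2)               # fixed seed, bit-identical

  tree_preds <- run_model(classifier_hoeffding())
  acc_tree <- mean(tree_preds == y[1:300])
  acc_ens <- mean(e1 == y[1:300])
  expect_gte(acc_ens, acc_tree - 0.05)   # within sampling error of one tree

  # unanimous members -> vote equals that label
  one <- classifier_bagging(n_learners = 3, seed = 1)
  for (i in 1:100) learn_one(one, c(5), 1L)
  expect_equal(predict_one(one, c(5)), 1L)
})

test_that("ensemble RNG use leaves the caller's RNG stream untouched", {
  set.seed(47)
  before <- .Random.seed
  m <- classifier_bagging(n_learners = 3, seed = 5)
  learn_one(m, c(1, 2), 1L)
  expect_identical(.Random.seed, before)
})
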