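# Incremental (streaming) classifiers behind a single learn/predict
# contract. Learners are environments: streaming updates mutate state in
# place, which is the natural fit for one-instance-at-a-time processing.

#' Shannon entropy of a class-count vector
#'
#' `-sum(p_i * log2(p_i))` in bits over the non-zero class proportions,
#' with `0 * log2(0)` defined as 0. This is the impurity measure behind the
#' Hoeffding tree's split scoring.
#'
#' @param class_counts Non-negative counts, at least one non-zero.
#' @return Entropy in bits, in `[0, log2(length(class_counts))]`.
#' @export
#' @examples
#' entropy(c(5, 5))   # 1 bit
#' entropy(c(10, 0))  # pure node
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    abort("class_counts must be non-negative with a positive total")
  }
  p <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(p * log2(p))
}

#' Information gain of a candidate split
#'
#' Entropy of the parent minus the count-weighted mean entropy of the
#' children. The children must partition the parent's counts exactly.
#'
#' @param parent_counts Class counts at the parent node.
#' @param child_counts_list List of class-count vectors, one per child.
#' @return Non-negative gain in bits.
#' @export
info_gain <- function(parent_counts, child_counts_list) {
  tot <- Reduce(`+`, child_counts_list)
  if (!isTRUE(all.equal(as.numeric(tot), as.numeric(parent_counts)))) {
    abort("children must partition the parent counts")
  }
  n <- sum(parent_counts)
  child_term <- sum(vapply(child_counts_list, function(cc) {
    nc <- sum(cc)
    if (nc == 0) 0 else nc / n * entropy(cc)
  }, numeric(1)))
  entropy(parent_counts) - child_term
}

#' Hoeffding bound
#'
#' `eps = sqrt(R^2 * ln(1/delta) / (2n))`: with probability `1 - delta` the
#' true mean of a random variable with range `R` is within `eps` of its
#' empirical mean after `n` observations. A leaf splits once the observed
#' information-gain lead of the best feature exceeds this bound.
#'
#' @param range Value range `R` of the quantity (1 for binary entropy).
#' @param delta Confidence parameter in (0, 1).
#' @param n Number of observations.
#' @return Non-negative bound, decreasing in `n`.
#' @export
hoeffding_bound <- function(range, delta, n) {
  if (range <= 0) abort("range must be positive")
  if (delta <= 0 || delta >= 1) abort("delta must be in (0, 1)")
  if (n < 1) abort("n must be a positive count")
  sqrt(range^2 * log(1 / delta) / (2 * n))
}

#' Poisson(1) online-bagging weights
#'
#' Online bagging simulates bootstrap resampling in a stream by replaying
#' each instance `w` times per ensemble member, with `w ~ Poisson(1)`.
#' Determinism comes from the caller's RNG state.
#'
#' @param n Number of draws.
#' @return Integer vector of non-negative weights with mean 1.
#' @export
bagging_weights <- function(n) {
  rpois(n, lambda = 1)
}

# ---- contract ---------------------------------------------------------------

#' Streaming classifier contract
#'
#' All built-in learners implement three generics: `learn_one(model, x, y)`
#' absorbs a single labelled instance (mutating the model in place and
#' returning it invisibly), `predict_one(model, x)` returns a label in
#' `{0, 1}` without mutating state, and `reset(model)` returns a pristine
#' learner with the same configuration. External incremental learners can be
#' plugged into [prequential_run()] by implementing the same generics.
#'
#' @param model A classifier object.
#' @param x Numeric feature vector.
#' @param y Label 0 or 1.
#' @param ... Passed to methods.
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
learn_one <- function(model, x, y, ...) UseMethod("learn_one")

#' @rdname classifier-contract
#' @export
predict_one <- function(model, x, ...) UseMethod("predict_one")

#' @rdname classifier-contract
#' @export
reset <- function(model, ...) UseMethod("reset")

# ---- Gaussian naive Bayes ---------------------------------------------------

#' Incremental Gaussian naive Bayes
#'
#' Per-class feature means and variances are maintained with Welford's
#' online algorithm, so after `n` single-instance updates the sufficient
#' statistics equal the batch fit on the same `n` instances. Deterministic,
#' which makes it the reference learner for pipeline tests.
#'
#' @param var_floor Lower bound on per-feature variance, guarding against
#'   zero-variance features early in the stream.
#' @return A classifier of class `c("nb_classifier", "stream_classifier")`.
#' @export
#' @examples
#' clf <- classifier_nb()
#' learn_one(clf, c(0, 0), 0); learn_one(clf, c(5, 5), 1)
#' predict_one(clf, c(4.5, 5.2))
classifier_nb <- function(var_floor = 1e-9) {
  e <- new.env(parent = emptyenv())
  e$var_floor <- var_floor
  e$n <- c(`0` = 0, `1` = 0)
  e$mean <- NULL        # 2 x d matrices, rows = classes 0/1
  e$m2 <- NULL
  e$warned <- FALSE
  class(e) <- c("nb_classifier", "stream_classifier")
  e
}

#' @export
learn_one.nb_classifier <- function(model, x, y, ...) {
  k <- as.integer(y) + 1L
  if (is.null(model$mean)) {
    d <- length(x)
    model$mean <- matrix(0, 2, d)
    model$m2 <- matrix(0, 2, d)
  }
  model$n[k] <- model$n[k] + 1
  d1 <- x - model$mean[k, ]
  model$mean[k, ] <- model$mean[k, ] + d1 / model$n[k]
  model$m2[k, ] <- model$m2[k, ] + d1 * (x - model$mean[k, ])
  invisible(model)
}

#' @export
predict_one.nb_classifier <- function(model, x, ...) {
  if (sum(model$n) == 0) {
    if (!model$warned) {
      warn("predict before any learn: returning default class 0")
      model$warned <- TRUE
    }
    return(0L)
  }
  if (any(model$n == 0)) {
    return(as.integer(which.max(model$n)) - 1L)   # only one class seen
  }
  score <- numeric(2)
  for (k in 1:2) {
    v <- pmax(model$m2[k, ] / max(model$n[k] - 1, 1), model$var_floor)
    score[k] <- log(model$n[k] / sum(model$n)) -
      0.5 * sum(log(2 * pi * v) + (x - model$mean[k, ])^2 / v)
  }
  if (score[2] >= score[1]) 1L else 0L
}

#' @export
reset.nb_classifier <- function(model, ...) classifier_nb(model$var_floor)

# ---- Hoeffding tree (VFDT) --------------------------------------------------

.new_leaf <- function() {
  nd <- new.env(parent = emptyenv())
  nd$is_leaf <- TRUE
  nd$counts <- c(0, 0)       # class 0 / class 1
  nd$buf_x <- list()         # buffered rows for split candidates
  nd$buf_y <- integer(0)
  nd$since_attempt <- 0L
  nd
}

#' Minimal Hoeffding tree (VFDT)
#'
#' An incremental decision tree for binary labels. Each leaf accumulates
#' class counts and a capped buffer of recent instances; every
#' `grace_period` instances it scores candidate numeric splits (10 quantile
#' thresholds per feature) by information gain and converts to a decision
#' node when the best feature's gain exceeds the runner-up's by more than
#' the [hoeffding_bound()] at confidence `split_confidence`, or when the
#' bound falls below `tie_threshold`. Prediction returns the majority class
#' of the reached leaf (ties favour the positive class).
#'
#' @param grace_period Instances between split attempts at a leaf
#'   (default 200).
#' @param split_confidence Hoeffding `delta` (default 1e-7).
#' @param tie_threshold Bound below which near-ties split anyway
#'   (default 0.05).
#' @param n_candidates Quantile split candidates per feature (default 10).
#' @param buffer_cap Maximum buffered instances per leaf (default 2000).
#' @return A classifier of class `c("hoeffding_tree", "stream_classifier")`.
#' @export
classifier_hoeffding <- function(grace_period = 200L, split_confidence = 1e-7,
                                 tie_threshold = 0.05, n_candidates = 10L,
                                 buffer_cap = 2000L) {
  e <- new.env(parent = emptyenv())
  e$cfg <- list(grace_period = as.integer(grace_period),
                split_confidence = split_confidence,
                tie_threshold = tie_threshold,
                n_candidates = as.integer(n_candidates),
                buffer_cap = as.integer(buffer_cap))
  e$root <- .new_leaf()
  e$n_learned <- 0L
  e$warned <- FALSE
  class(e) <- c("hoeffding_tree", "stream_classifier")
  e
}

.route <- function(node, x) {
  while (!node$is_leaf) {
    node <- if (x[node$split_feature] <= node$split_threshold)
      node$left else node$right
  }
  node
}

# Score candidate splits at a leaf from its buffer; returns best and
# second-best gains plus the winning (feature, threshold).
.best_splits <- function(X, y, n_candidates) {
  parent <- c(sum(y == 0L), sum(y == 1L))
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  second <- 0
  for (f in seq_len(ncol(X))) {
    xs <- X[, f]
    cand <- unique(quantile(xs, probs = seq_len(n_candidates) /
                              (n_candidates + 1), names = FALSE))
    gains <- vapply(cand, function(th) {
      left <- y[xs <= th]
      if (length(left) == 0L || length(left) == length(y)) return(0)
      info_gain(parent, list(c(sum(left == 0L), sum(left == 1L)),
                             parent - c(sum(left == 0L), sum(left == 1L))))
    }, numeric(1))
    g <- max(gains)
    if (g > best$gain) {
      second <- best$gain
      best <- list(gain = g, feature = f, threshold = cand[which.max(gains)])
    } else if (g > second) {
      second <- g
    }
  }
  list(best = best, second = second)
}

.attempt_split <- function(leaf, cfg) {
  if (length(leaf$buf_y) < 2L || min(leaf$counts) == 0) return(invisible())
  X <- do.call(rbind, leaf$buf_x)
  y <- leaf$buf_y
  sc <- .best_splits(X, y, cfg$n_candidates)
  if (sc$best$gain <= 0) return(invisible())
  eps <- hoeffding_bound(1, cfg$split_confidence, sum(leaf$counts))
  if (sc$best$gain - sc$second > eps || eps < cfg$tie_threshold) {
    leaf$is_leaf <- FALSE
    leaf$split_feature <- sc$best$feature
    leaf$split_threshold <- sc$best$threshold
    leaf$left <- .new_leaf()
    leaf$right <- .new_leaf()
    go_left <- X[, sc$best$feature] <= sc$best$threshold
    for (side in c("left", "right")) {
      sel <- if (side == "left") go_left else !go_left
      ch <- leaf[[side]]
      ch$counts <- c(sum(y[sel] == 0L), sum(y[sel] == 1L))
      ch$buf_x <- leaf$buf_x[sel]
      ch$buf_y <- y[sel]
    }
    leaf$buf_x <- list()
    leaf$buf_y <- integer(0)
  }
  invisible()
}

#' @export
learn_one.hoeffding_tree <- function(model, x, y, ...) {
  leaf <- .route(model$root, x)
  y <- as.integer(y)
  leaf$counts[y + 1L] <- leaf$counts[y + 1L] + 1
  if (length(leaf$buf_y) < model$cfg$buffer_cap) {
    leaf$buf_x[[length(leaf$buf_x) + 1L]] <- x
    leaf$buf_y <- c(leaf$buf_y, y)
  }
  leaf$since_attempt <- leaf$since_attempt + 1L
  if (leaf$since_attempt >= model$cfg$grace_period) {
    leaf$since_attempt <- 0L
    .attempt_split(leaf, model$cfg)
  }
  model$n_learned <- model$n_learned + 1L
  invisible(model)
}

#' @export
predict_one.hoeffding_tree <- function(model, x, ...) {
  if (model$n_learned == 0L) {
    if (!model$warned) {
      warn("predict before any learn: returning default class 0")
      model$warned <- TRUE
    }
    return(0L)
  }
  leaf <- .route(model$root, x)
  if (sum(leaf$counts) == 0) return(0L)
  if (leaf$counts[2] >= leaf$counts[1]) 1L else 0L
}

#' @export
reset.hoeffding_tree <- function(model, ...) {
  do.call(classifier_hoeffding, model$cfg)
}

# ---- online-bagging ensemble ------------------------------------------------

#' Online-bagging ensemble of Hoeffding trees
#'
#' The streaming analogue of a random forest: `n_learners` base trees each
#' see every instance replayed `w ~ Poisson(1)` times ([bagging_weights()]),
#' and prediction is a majority vote with ties resolved toward the positive
#' class (the clinically conservative choice for seizure detection). Drift
#' handling is a pluggable hook (`on_chunk`), a no-op by default; adaptation
#' comes from the trees' continuous leaf updates.
#'
#' @param n_learners Ensemble size M (default 10).
#' @param seed Integer seed for the private Poisson weight stream.
#' @param base Zero-argument function constructing a base learner
#'   (default [classifier_hoeffding()] with its defaults).
#' @param on_chunk Optional `function(model, chunk)` called once per chunk
#'   by [prequential_run()]; the drift-detection hook.
#' @return A classifier of class `c("bagging_ensemble", "stream_classifier")`.
#' @export
classifier_bagging <- function(n_learners = 10L, seed = 1L,
                               base = classifier_hoeffding,
                               on_chunk = NULL) {
  e <- new.env(parent = emptyenv())
  e$n_learners <- as.integer(n_learners)
  if (e$n_learners < 1L) abort("n_learners must be >= 1")
  e$seed <- as.integer(seed)
  e$base <- base
  e$members <- lapply(seq_len(e$n_learners), function(i) base())
  e$rng_state <- rng_state_for_seed(e$seed)
  e$on_chunk <- on_chunk
  class(e) <- c("bagging_ensemble", "stream_classifier")
  e
}

#' @export
learn_one.bagging_ensemble <- function(model, x, y, ...) {
  w <- with_private_rng(model, bagging_weights(model$n_learners))
  for (i in seq_len(model$n_learners)) {
    for (rep in seq_len(w[i])) learn_one(model$members[[i]], x, y)
  }
  invisible(model)
}

#' @export
predict_one.bagging_ensemble <- function(model, x, ...) {
  votes <- vapply(model$members, predict_one, integer(1), x = x)
  if (sum(votes == 1L) * 2L >= length(votes)) 1L else 0L
}

#' @export
reset.bagging_ensemble <- function(model, ...) {
  classifier_bagging(model$n_learners, model$seed, model$base, model$on_chunk)
}
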