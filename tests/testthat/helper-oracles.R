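# Independent reference implementations used as oracles. These deliberately
# use naive algorithms, distinct from the package's code paths.

# Direct O(R^2) evaluation of the DFT magnitude spectrum of one channel.
naive_dft_mag <- function(h, n_bins) {
  R <- length(h)
  vapply(seq_len(n_bins) - 1L, function(k) {
    Mod(sum(h * exp(-2i * pi * (0:(R - 1)) * k / R)))
  }, numeric(1))
}

# Counting oracle for SAW carry-over under the default (uncapped) config:
# the carried set at tick T is exactly the positives that arrived at ticks
# T-ath .. T-1. Implemented by replaying lifetimes, not by running SAW.
oracle_carried_counts <- function(stream, ath) {
  pos_per_tick <- tapply(stream$label, stream$tick, sum)
  ticks <- as.integer(names(pos_per_tick))
  vapply(ticks, function(t) {
    prev <- ticks[ticks >= t - ath & ticks < t]
    sum(pos_per_tick[as.character(prev)])
  }, numeric(1))
}

# Tiny stream builder for hand-constructed chunk sequences.
make_stream <- function(labels_by_chunk, n_features = 2, seed = 42) {
  set.seed(seed)
  rows <- list()
  idx <- 0L
  for (t in seq_along(labels_by_chunk)) {
    lab <- labels_by_chunk[[t]]
    n <- length(lab)
    m <- matrix(rnorm(n * n_features), n, n_features,
                dimnames = list(NULL, paste0("x", seq_len(n_features))))
    df <- tibble::as_tibble(m)
    df$tick <- t
    df$arrival_index <- idx + seq_len(n)
    df$label <- as.integer(lab)
    idx <- idx + n
    rows[[t]] <- df
  }
  dplyr::bind_rows(rows)
}

# Trivial classifiers for evaluation plumbing tests.
classifier_constant <- function(value = 0L) {
  e <- new.env()
  e$value <- as.integer(value)
  class(e) <- c("constant_classifier", "stream_classifier")
  e
}
learn_one.constant_classifier <- function(model, x, y, ...) invisible(model)
predict_one.constant_classifier <- function(model, x, ...) model$value
reset.constant_classifier <- function(model, ...) classifier_constant(model$value)

# "Oracle" classifier that memorizes each feature vector's label before
# being asked (labels are learned after predicting, so it peeks via a
# shared lookup loaded up front).
classifier_lookup <- function(stream) {
  e <- new.env()
  fcols <- setdiff(names(stream), c("tick", "arrival_index", "label"))
  e$keys <- apply(as.matrix(stream[fcols]), 1, paste, collapse = "|")
  e$labels <- stream$label
  class(e) <- c("lookup_classifier", "stream_classifier")
  e
}
learn_one.lookup_classifier <- function(model, x, y, ...) invisible(model)
predict_one.lookup_classifier <- function(model, x, ...) {
  key <- paste(x, collapse = "|")
  model$labels[match(key, model$keys)]
}
reset.lookup_classifier <- function(model, ...) model

isTRUE_vec_test <- function(x) !is.na(x) & x

registerS3method("learn_one", "constant_classifier", learn_one.constant_classifier)
registerS3method("predict_one", "constant_classifier", predict_one.constant_classifier)
registerS3method("reset", "constant_classifier", reset.constant_classifier)
registerS3method("learn_one", "lookup_classifier", learn_one.lookup_classifier)
registerS3method("predict_one", "lookup_classifier", predict_one.lookup_classifier)
registerS3method("reset", "lookup_classifier", reset.lookup_classifier)
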