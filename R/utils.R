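# Internal helpers shared across modules.

# Column names with stream bookkeeping semantics; everything else numeric is a
# feature. Kept in one place so every module slices instances identically.
.reserved_cols <- c(
  "tick", "arrival_index", "label", "pia", "carried", "epoch_start",
  "distance"
)

feature_cols <- function(df) {
  cand <- setdiff(names(df), .reserved_cols)
  cand[vapply(df[cand], is.numeric, logical(1))]
}

as_feature_matrix <- function(df, cols = feature_cols(df)) {
  if (length(cols) == 0L) {
    abort("no feature columns found (all columns are reserved or non-numeric)")
  }
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  m
}

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite %s are not allowed", what))
  }
  invisible(x)
}

# Run `expr` under a private RNG stream held in `state_env$rng_state`,
# leaving the caller's .Random.seed untouched. Streaming learners and the
# skew undersampler use this so results depend only on their own seed.
with_private_rng <- function(state_env, expr) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  assign(".Random.seed", state_env$rng_state, envir = genv)
  on.exit({
    state_env$rng_state <- get(".Random.seed", envir = genv)
    if (is.null(old)) {
      rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  force(expr)
}

# Capture a fresh RNG state for a given integer seed without disturbing the
# caller's stream.
rng_state_for_seed <- function(seed) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  st <- get(".Random.seed", envir = genv)
  if (is.null(old)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", old, envir = genv)
  }
  st
}
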