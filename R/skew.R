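#' Skew rebalancing configuration
#'
#' The skew-style baseline accumulates every positive instance ever seen and
#' randomly undersamples the current chunk's negatives so that the window's
#' positives:negatives ratio approaches `target_ratio`. Unlike SAW, buffered
#' positives never age out, so the window's positive count grows without
#' bound — the behaviour the adaptive-window approach is designed to avoid.
#'
#' @param target_ratio Desired positives:negatives ratio after rebalancing
#'   (default 1, i.e. balanced).
#' @param seed Integer seed driving the undersampling; combined with the
#'   tick so each step is independently reproducible.
#' @return A list of class `skew_config`.
#' @export
skew_config <- function(target_ratio = 1, seed = 1L) {
  if (target_ratio <= 0) abort("target_ratio must be positive")
  structure(list(target_ratio = target_ratio, seed = as.integer(seed)),
            class = "skew_config")
}

#' Fresh skew state
#' @param config A [skew_config()].
#' @return A list of class `skew_state` holding the append-only positive
#'   buffer.
#' @export
skew_state <- function(config = skew_config()) {
  structure(list(buffer = NULL, last_tick = NA_integer_, config = config),
            class = "skew_state")
}

#' One skew rebalancing step
#'
#' The window contains all buffered positives, the chunk's positives, and a
#' uniform random sample (without replacement) of the chunk's negatives
#' sized so positives:negatives is close to `target_ratio` (at least one
#' negative is kept when any exist). The buffer is then extended with the
#' chunk's positives. Sampling depends only on the configured seed and the
#' tick.
#'
#' @param state A `skew_state`.
#' @param chunk Chunk tibble (`tick`, `arrival_index`, `label`, features).
#' @return A list with `window`, `state` and a one-row `trace` tibble.
#' @export
skew_step <- function(state, chunk) {
  tick <- chunk$tick[1]
  pos_chunk <- chunk[chunk$label == 1L, , drop = FALSE]
  neg_chunk <- chunk[chunk$label != 1L, , drop = FALSE]
  positives <- dplyr::bind_rows(state$buffer, pos_chunk)
  n_pos <- nrow(positives)
  n_neg <- nrow(neg_chunk)

  if (n_pos == 0L) {
    window <- chunk                       # nothing to balance against
  } else if (n_neg == 0L) {
    window <- positives
  } else {
    n_keep <- min(n_neg, max(1L, round(n_pos / state$config$target_ratio)))
    rng <- new.env()
    rng$rng_state <- rng_state_for_seed(
      (state$config$seed * 131071L + tick) %% 2147483562L)
    idx <- with_private_rng(rng, sample.int(n_neg, n_keep))
    window <- dplyr::bind_rows(positives, neg_chunk[sort(idx), , drop = FALSE])
  }

  state$buffer <- positives
  state$last_tick <- tick
  trace <- tibble::tibble(
    tick = tick,
    n_native = nrow(chunk),
    n_carried = n_pos - nrow(pos_chunk),   # buffered (non-native) positives
    window_size = nrow(window),
    positive_fraction = sum(window$label == 1L) / nrow(window)
  )
  list(window = window, state = state, trace = trace)
}

#' Run the skew baseline over a chunked stream
#'
#' @inheritParams run_saw
#' @param target_ratio,seed See [skew_config()].
#' @param config Optional [skew_config()].
#' @return An object of class `skew_result` with `windows` and `trace`,
#'   mirroring [run_saw()].
#' @export
run_skew <- function(stream, target_ratio = 1, seed = 1L, config = NULL) {
  cfg <- config %||% skew_config(target_ratio, seed)
  chunks <- split(stream, stream$tick)
  chunks <- chunks[order(as.numeric(names(chunks)))]
  st <- skew_state(cfg)
  windows <- vector("list", length(chunks))
  traces <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    step <- skew_step(st, chunks[[i]])
    st <- step$state
    windows[[i]] <- step$window
    traces[[i]] <- step$trace
  }
  structure(list(windows = windows, trace = dplyr::bind_rows(traces),
                 config = cfg),
            class = "skew_result")
}

#' @exportS3Method generics::tidy
tidy.skew_result <- function(x, ...) x$trace

#' @exportS3Method ggplot2::autoplot
autoplot.skew_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$tick, y = .data$positive_fraction)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = "chunk (tick)", y = "positive-class fraction",
                  title = "Positive-class presence under skew rebalancing") +
    ggplot2::theme_minimal()
}
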