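#' SAW configuration
#'
#' Parameters of the similarity-based adaptive window. `ath` is the
#' positive-instance-age (PIA) threshold: a positive instance is eligible
#' for carrying into later windows only while its PIA is below `ath`, so a
#' positive arriving at tick `T` can appear in windows `T` through
#' `T + ath` — a lifetime of `ath + 1` windows. The PIA constraint is the
#' size control of the balance rare-class set (BRS); `brs_cap`, when set,
#' additionally truncates the BRS to the `brs_cap` instances closest to the
#' current chunk's positive-class centroid.
#'
#' @param ath Positive integer PIA threshold (default 8).
#' @param brs_cap Optional positive integer cap on the BRS size; `NULL`
#'   (default) keeps every age-eligible positive, with the distance sort
#'   determining order only.
#' @param standardize_distances If TRUE, centroid distances are computed on
#'   z-scores using the running per-feature mean/sd of the native stream
#'   seen so far; raw features by default.
#' @return A list of class `saw_config`.
#' @export
saw_config <- function(ath = 8L, brs_cap = NULL, standardize_distances = FALSE) {
  ath <- as.integer(ath)
  if (is.na(ath) || ath < 1L) abort("ath must be a positive integer")
  if (!is.null(brs_cap)) {
    brs_cap <- as.integer(brs_cap)
    if (is.na(brs_cap) || brs_cap < 1L) abort("brs_cap must be positive")
  }
  structure(
    list(ath = ath, brs_cap = brs_cap,
         standardize_distances = isTRUE(standardize_distances)),
    class = "saw_config"
  )
}

#' Fresh SAW state
#'
#' The persistent buffer of carried positive instances (with PIA counters)
#' plus running feature moments for optional distance standardization.
#'
#' @param config A [saw_config()].
#' @return A list of class `saw_state`.
#' @export
saw_state <- function(config = saw_config()) {
  structure(
    list(
      features = NULL,          # matrix, one row per held positive
      arrival_index = integer(0),
      pia = integer(0),
      last_tick = NA_integer_,
      n_seen = 0,               # running moments of the native stream
      run_mean = NULL,
      run_m2 = NULL,
      config = config
    ),
    class = "saw_state"
  )
}

#' Centroid of a set of positive instances
#'
#' The per-feature arithmetic mean. It may coincide with a real data point
#' or be a virtual point between them; either way it is the single
#' representative against which carry-over candidates are ranked, which is
#' what keeps the similarity step cheap.
#'
#' @param positives A data frame of instances (feature columns are detected
#'   automatically) or a numeric matrix with one row per instance.
#' @return Named numeric vector, one value per feature.
#' @export
#' @examples
#' centroid(data.frame(x = c(1, 3), y = c(2, 4)))
centroid <- function(positives) {
  m <- if (is.matrix(positives)) positives else as_feature_matrix(positives)
  if (nrow(m) == 0L) abort("centroid of an empty set is undefined")
  stopifnot_finite(m, "features")
  colMeans(m)
}

#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length with finite values.
#' @return Non-negative scalar `sqrt(sum((a - b)^2))`.
#' @export
#' @examples
#' euclidean(c(0, 0), c(3, 4))
euclidean <- function(a, b) {
  if (length(a) != length(b)) abort("feature arity mismatch")
  stopifnot_finite(c(a, b), "features")
  sqrt(sum((a - b)^2))
}

# Distances of each held-positive row to the centroid, optionally on the
# z-scale of the running stream moments.
.held_distances <- function(state, cvec) {
  f <- state$features
  if (state$config$standardize_distances && state$n_seen > 1) {
    s <- sqrt(state$run_m2 / (state$n_seen - 1))
    s[s < 1e-12] <- 1
    f <- sweep(sweep(f, 2, state$run_mean), 2, s, "/")
    cvec <- (cvec - state$run_mean) / s
  }
  sqrt(rowSums(sweep(f, 2, cvec)^2))
}

#' Select the balance rare-class set (BRS)
#'
#' Returns the held positives eligible for carrying (all have PIA below the
#' threshold by construction of the state). When a centroid is supplied the
#' set is sorted by ascending Euclidean distance to it (ties broken by
#' smaller arrival index, favouring older instances) and truncated to
#' `brs_cap` if configured; with no centroid (the current chunk has no
#' positives) the full set is returned in arrival order.
#'
#' @param state A `saw_state`.
#' @param c Centroid vector from [centroid()], or `NULL`.
#' @return A tibble with columns `arrival_index`, `pia`, `distance` (NA when
#'   no centroid) and the feature values.
#' @export
select_brs <- function(state, c = NULL) {
  eligible <- which(state$pia < state$config$ath)
  if (length(eligible) == 0L) {
    return(tibble::tibble(arrival_index = integer(0), pia = integer(0),
                          distance = numeric(0)))
  }
  if (is.null(c)) {
    ord <- eligible[order(state$arrival_index[eligible])]
    d <- rep(NA_real_, length(state$pia))
  } else {
    d <- .held_distances(state, c)
    ord <- eligible[order(d[eligible], state$arrival_index[eligible])]
  }
  if (!is.null(state$config$brs_cap)) ord <- head(ord, state$config$brs_cap)
  out <- tibble::as_tibble(state$features[ord, , drop = FALSE])
  out$arrival_index <- state$arrival_index[ord]
  out$pia <- state$pia[ord]
  out$distance <- d[ord]
  dplyr::relocate(out, "arrival_index", "pia", "distance")
}

#' One SAW step: adapt the current chunk
#'
#' Applies the similarity-based adaptive window to one arriving chunk.
#' Depending on whether the current chunk and the accumulated state contain
#' positives, the step (1) passes an all-negative chunk through untouched
#' when nothing is held, (2) passes a chunk through when nothing is held but
#' records its positives, (3) merges every age-eligible held positive when
#' the chunk itself has none, or (4) computes the centroid of the chunk's
#' positives, ranks held positives by distance to it, and merges the
#' selected set. In every case native positives enter the state with PIA 0,
#' each carried instance's PIA increments by one, instances reaching the
#' threshold are retired, and no negative is ever dropped or carried.
#'
#' @param state A `saw_state`.
#' @param chunk Tibble with feature columns, `label`, `arrival_index` and a
#'   `tick` column (constant within the chunk, strictly increasing across
#'   calls).
#' @return A list with elements `window` (tibble: the chunk plus carried
#'   instances, with `pia` and `carried` columns), `state` (updated) and
#'   `trace` (one-row tibble: tick, n_native, n_carried, positive_fraction).
#' @export
saw_step <- function(state, chunk) {
  tick <- chunk$tick[1]
  if (!is.na(state$last_tick) && tick <= state$last_tick) {
    abort(sprintf("tick regression: %s after %s", tick, state$last_tick))
  }
  fcols <- feature_cols(chunk)
  x <- as_feature_matrix(chunk, fcols)
  lab <- chunk$label
  pos <- which(lab == 1L)

  # running moments of the native stream (Welford, batched)
  if (state$config$standardize_distances) {
    for (i in seq_len(nrow(x))) {
      state$n_seen <- state$n_seen + 1
      if (is.null(state$run_mean)) {
        state$run_mean <- x[i, ]
        state$run_m2 <- numeric(ncol(x))
      } else {
        d1 <- x[i, ] - state$run_mean
        state$run_mean <- state$run_mean + d1 / state$n_seen
        state$run_m2 <- state$run_m2 + d1 * (x[i, ] - state$run_mean)
      }
    }
  }

  brs <- NULL
  if (length(state$pia) > 0L) {
    cvec <- if (length(pos) > 0L) centroid(x[pos, , drop = FALSE]) else NULL
    brs <- select_brs(state, cvec)
  }
  n_carried <- if (is.null(brs)) 0L else nrow(brs)

  window <- chunk
  window$pia <- ifelse(lab == 1L, 0L, NA_integer_)
  window$carried <- FALSE
  if (n_carried > 0L) {
    carried <- brs[c(fcols, "arrival_index", "pia")]
    carried$pia <- carried$pia + 1L      # ages at carry time
    carried$label <- 1L
    carried$tick <- tick
    carried$carried <- TRUE
    window <- dplyr::bind_rows(window, carried)
  }

  # updated state: carried survivors (pia < ath) + unselected holds + natives
  ath <- state$config$ath
  if (n_carried > 0L) {
    keep_idx <- match(brs$arrival_index, state$arrival_index)
    state$pia[keep_idx] <- state$pia[keep_idx] + 1L
  }
  live <- which(state$pia < ath)
  state$features <- state$features[live, , drop = FALSE]
  state$arrival_index <- state$arrival_index[live]
  state$pia <- state$pia[live]
  if (length(pos) > 0L) {
    new_f <- x[pos, , drop = FALSE]
    state$features <- if (is.null(state$features)) new_f else
      rbind(state$features, new_f)
    state$arrival_index <- c(state$arrival_index, chunk$arrival_index[pos])
    state$pia <- c(state$pia, integer(length(pos)))
  }
  state$last_tick <- tick

  trace <- tibble::tibble(
    tick = tick,
    n_native = nrow(chunk),
    n_carried = n_carried,
    window_size = nrow(window),
    positive_fraction = sum(window$label == 1L) / nrow(window)
  )
  list(window = window, state = state, trace = trace)
}

#' Run SAW over a chunked stream
#'
#' Folds [saw_step()] over the stream from a fresh state and collects the
#' adapted windows and the per-tick trace.
#'
#' @param stream Tibble with `tick`, `arrival_index`, `label` and feature
#'   columns (see [chunk_stream()] and [generate_stream()]).
#' @param ath,brs_cap,standardize_distances See [saw_config()]; ignored when
#'   `config` is given.
#' @param config Optional [saw_config()] overriding the individual arguments.
#' @return An object of class `saw_result`: a list with `windows` (list of
#'   window tibbles, one per tick) and `trace` (tibble). [tidy()] returns the
#'   trace; [autoplot()] plots the positive-class presence per tick.
#' @export
#' @examples
#' stream <- generate_stream(stream_spec(n_chunks = 5, chunk_size = 100,
#'                                       positive_rate = 0.05, seed = 1))
#' res <- run_saw(stream, ath = 4)
#' tidy(res)
run_saw <- function(stream, ath = 8L, brs_cap = NULL,
                    standardize_distances = FALSE, config = NULL) {
  cfg <- config %||% saw_config(ath, brs_cap, standardize_distances)
  chunks <- split(stream, stream$tick)
  chunks <- chunks[order(as.numeric(names(chunks)))]
  st <- saw_state(cfg)
  windows <- vector("list", length(chunks))
  traces <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    step <- saw_step(st, chunks[[i]])
    st <- step$state
    windows[[i]] <- step$window
    traces[[i]] <- step$trace
  }
  structure(
    list(windows = windows, trace = dplyr::bind_rows(traces), config = cfg,
         final_state = st),
    class = "saw_result"
  )
}

#' @exportS3Method generics::tidy
tidy.saw_result <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.saw_result <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_chunks = nrow(tr),
    ath = x$config$ath,
    mean_presence = mean(tr$positive_fraction),
    max_presence = max(tr$positive_fraction),
    mean_carried = mean(tr$n_carried)
  )
}

#' @export
print.saw_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "SAW over %d chunks (ath = %d): mean positive presence %.4f, max %.4f, mean carried %.1f\n",
    g$n_chunks, g$ath, g$mean_presence, g$max_presence, g$mean_carried))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.saw_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$tick, y = .data$positive_fraction)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "chunk (tick)", y = "positive-class fraction",
                  title = "Positive-class presence in SAW-adapted windows") +
    ggplot2::theme_minimal()
}
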