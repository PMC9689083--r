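#' Specification of a synthetic imbalanced stream
#'
#' Defines the seeded generator used throughout testing: a heavily
#' imbalanced binary stream of class-conditional Gaussian feature vectors,
#' chunked for stream processing. Defaults mirror the seizure-detection
#' regime the method targets: 100 chunks of 1600 instances with positive
#' rate 0.008 (the average seizure:normal ratio of the motivating EEG
#' corpus), 10 features, unit variance and a class-mean separation of 2.0 —
#' imbalanced enough that an unaided learner collapses onto the negative
#' class, yet separable enough that rebalancing recovers sensitivity.
#'
#' @param n_chunks Number of chunks (default 100).
#' @param chunk_size Instances per chunk (default 1600).
#' @param positive_rate Long-run positive fraction `p` (default 0.008).
#' @param label_mode `"iid"` (Bernoulli labels) or `"episode"` (contiguous
#'   positive episodes from a two-state Markov chain with the same long-run
#'   rate, mimicking seizures that span consecutive epochs).
#' @param episode_mean_length Mean episode length in instances for
#'   `"episode"` mode (default 93, the mean seizure duration in seconds at
#'   1-second epochs).
#' @param n_features Feature dimension (default 10).
#' @param mean_separation Euclidean distance between the class mean vectors
#'   (default 2.0), spread evenly across features.
#' @param sd Per-feature standard deviation for both classes (default 1).
#' @param drift Optional `function(tick)` returning a length-`n_features`
#'   shift added to both class means at that tick (distribution drift).
#' @param seed Integer seed; the stream is a pure function of the spec.
#' @return A list of class `stream_spec`.
#' @export
stream_spec <- function(n_chunks = 100L, chunk_size = 1600L,
                        positive_rate = 0.008,
                        label_mode = c("iid", "episode"),
                        episode_mean_length = 93,
                        n_features = 10L, mean_separation = 2,
                        sd = 1, drift = NULL, seed = 1L) {
  label_mode <- match.arg(label_mode)
  if (positive_rate <= 0 || positive_rate >= 1) {
    abort("positive_rate must be in (0, 1)")
  }
  if (chunk_size < 1L || n_chunks < 1L) {
    abort("chunk_size and n_chunks must be positive")
  }
  structure(
    list(n_chunks = as.integer(n_chunks), chunk_size = as.integer(chunk_size),
         positive_rate = positive_rate, label_mode = label_mode,
         episode_mean_length = episode_mean_length,
         n_features = as.integer(n_features),
         mean_separation = mean_separation, sd = sd, drift = drift,
         seed = as.integer(seed)),
    class = "stream_spec"
  )
}

#' Generate a chunked synthetic stream
#'
#' Labels are iid Bernoulli(`p`) or episodic with matching long-run rate;
#' features are drawn from the label's Gaussian (`N(0, sd)` for negatives,
#' mean shifted by `mean_separation / sqrt(n_features)` per feature for
#' positives); optional drift shifts both class means per tick. The output
#' is fully determined by the spec, including its seed.
#'
#' @param spec A [stream_spec()].
#' @return A tibble with columns `tick`, `arrival_index`, `label` and
#'   features `x1 ... x<n_features>`.
#' @export
#' @examples
#' stream <- generate_stream(stream_spec(n_chunks = 3, chunk_size = 50,
#'                                       positive_rate = 0.05, seed = 7))
#' dplyr::count(stream, label)
generate_stream <- function(spec) {
  if (!inherits(spec, "stream_spec")) abort("spec must be a stream_spec")
  n <- spec$n_chunks * spec$chunk_size
  d <- spec$n_features
  p <- spec$positive_rate
  rng <- new.env(); rng$rng_state <- rng_state_for_seed(spec$seed)
  with_private_rng(rng, {
    labels <- if (spec$label_mode == "iid") {
      rbinom(n, 1L, p)
    } else {
      .episode_labels(n, p, spec$episode_mean_length)
    }
    mu1 <- spec$mean_separation / sqrt(d)
    x <- matrix(rnorm(n * d, sd = spec$sd), n, d)
    x <- x + outer(as.numeric(labels), rep(mu1, d))
    if (!is.null(spec$drift)) {
      ticks <- rep(seq_len(spec$n_chunks), each = spec$chunk_size)
      for (t in unique(ticks)) {
        rows <- which(ticks == t)
        x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, spec$drift(t), "+")
      }
    }
    colnames(x) <- paste0("x", seq_len(d))
    out <- tibble::as_tibble(x)
    out$tick <- rep(seq_len(spec$n_chunks), each = spec$chunk_size)
    out$arrival_index <- seq_len(n)
    out$label <- as.integer(labels)
    dplyr::relocate(out, "tick", "arrival_index", "label")
  })
}

# Two-state Markov labels: episode (1) lengths geometric with mean L,
# gap (0) lengths geometric with mean L * (1 - p) / p, giving long-run
# positive rate p.
.episode_labels <- function(n, p, mean_len) {
  q10 <- 1 / mean_len                       # leave an episode
  q01 <- p / (mean_len * (1 - p))           # enter an episode
  lab <- integer(n)
  state <- as.integer(runif(1) < p)
  for (i in seq_len(n)) {
    lab[i] <- state
    u <- runif(1)
    state <- if (state == 1L) as.integer(u >= q10) else as.integer(u < q01)
  }
  lab
}

#' Generate a synthetic multichannel signal record
#'
#' Produces a raw-signal stand-in for an annotated EEG record: background
#' channels are AR(1) (pink-ish) noise, and annotated seizure spans add a
#' high-amplitude 5 Hz oscillation plus extra noise, so that featurized
#' epochs are separable by class and labels are recoverable with
#' [label_epochs()]. This is a synthetic surrogate, not a physiological
#' simulation.
#'
#' @param duration Record length in seconds.
#' @param sampling_rate Samples per second (default 128).
#' @param seizure_intervals Data frame with `onset`/`offset` seconds
#'   (non-overlapping), or `NULL` for a seizure-free record.
#' @param n_channels Number of channels (default 4).
#' @param seizure_amplitude Amplitude of the added ictal oscillation
#'   relative to the background sd (default 4).
#' @param seed Integer seed.
#' @return A list with `signal` (matrix samples x channels),
#'   `sampling_rate`, `annotations` and `channel_names`.
#' @export
generate_signal_record <- function(duration, sampling_rate = 128L,
                                   seizure_intervals = NULL, n_channels = 4L,
                                   seizure_amplitude = 4, seed = 1L) {
  if (!is.null(seizure_intervals) && nrow(seizure_intervals) > 0) {
    on <- seizure_intervals$onset; off <- seizure_intervals$offset
    if (any(on < 0) || any(off <= on) || any(off > duration)) {
      abort("seizure intervals must lie within [0, duration]")
    }
    ord <- order(on)
    if (any(on[ord][-1] < off[ord][-length(off)])) {
      abort("seizure intervals must not overlap")
    }
  }
  n <- as.integer(round(duration * sampling_rate))
  t_sec <- (seq_len(n) - 1L) / sampling_rate
  rng <- new.env(); rng$rng_state <- rng_state_for_seed(seed)
  signal <- with_private_rng(rng, {
    sig <- vapply(seq_len(n_channels), function(ch) {
      as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
    }, numeric(n))
    if (!is.null(seizure_intervals) && nrow(seizure_intervals) > 0) {
      in_seizure <- rep(FALSE, n)
      for (k in seq_len(nrow(seizure_intervals))) {
        in_seizure <- in_seizure |
          (t_sec >= seizure_intervals$onset[k] &
             t_sec < seizure_intervals$offset[k])
      }
      bg_sd <- sd(sig)
      ictal <- seizure_amplitude * bg_sd *
        sin(2 * pi * 5 * t_sec[in_seizure]) +
        rnorm(sum(in_seizure), sd = bg_sd)
      sig[in_seizure, ] <- sig[in_seizure, , drop = FALSE] + ictal
    }
    sig
  })
  ch_names <- paste0("ch", seq_len(n_channels))
  colnames(signal) <- ch_names
  list(signal = signal, sampling_rate = sampling_rate,
       annotations = seizure_intervals, channel_names = ch_names)
}

#' Deterministic two-chunk toy example
#'
#' A hand-built pair of 6-instance chunks (2 features, values in
#' `[1, 100]`) with one positive in each and a PIA threshold of 4: running
#' [saw_step()] over them carries exactly one previous positive into the
#' second window, growing it from 6 to 7 instances. Useful for
#' demonstrating and unit-testing the carry mechanism end to end.
#'
#' @return A list with `chunks` (tibble of both chunks) and `ath`.
#' @export
#' @examples
#' toy <- saw_toy_chunks()
#' res <- run_saw(toy$chunks, ath = toy$ath)
#' tidy(res)
saw_toy_chunks <- function() {
  chunks <- tibble::tibble(
    tick = rep(1:2, each = 6L),
    arrival_index = 1:12,
    label = c(0L, 1L, 0L, 0L, 0L, 0L,
              0L, 0L, 1L, 0L, 0L, 0L),
    x1 = c(12, 40, 81, 5, 67, 93,
           28, 74, 44, 9, 88, 60),
    x2 = c(55, 35, 14, 72, 91, 23,
           66, 12, 31, 84, 47, 99)
  )
  list(chunks = chunks, ath = 4L)
}

#' Summary table of an annotated EEG corpus
#'
#' Loads the bundled per-patient class-distribution table of the public
#' Siena Scalp EEG corpus subset (seconds of normal and seizure signal per
#' patient and their ratio), and summarizes it.
#'
#' @return `siena_class_distribution()`: tibble with one row per patient
#'   (`patient_id`, `normal_s`, `seizure_s`, `seizure_ratio`).
#' @export
siena_class_distribution <- function() {
  path <- system.file("extdata", "siena_class_distribution.csv",
                      package = "sawstream", mustWork = TRUE)
  tibble::as_tibble(read.csv(path))
}

#' @param distribution A class-distribution tibble as returned by
#'   [siena_class_distribution()].
#' @return `summarize_class_distribution()`: one-row tibble with totals and
#'   per-patient means (`normal_total`, `seizure_total`, `normal_mean_s`,
#'   `seizure_mean_s`, `ratio_mean`).
#' @rdname siena_class_distribution
#' @export
summarize_class_distribution <- function(distribution = siena_class_distribution()) {
  tibble::tibble(
    n_patients = nrow(distribution),
    normal_total = sum(distribution$normal_s),
    seizure_total = sum(distribution$seizure_s),
    normal_mean_s = mean(distribution$normal_s),
    seizure_mean_s = mean(distribution$seizure_s),
    ratio_mean = mean(distribution$seizure_ratio)
  )
}
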