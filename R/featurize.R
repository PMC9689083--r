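#' Clinical EEG frequency bands
#'
#' The five conventional scalp-EEG bands used as the default feature set:
#' delta 0.5--4 Hz, theta 4--8 Hz, alpha 8--13 Hz, beta 13--30 Hz and
#' gamma 30--45 Hz.
#'
#' @return A named list of `c(low, high)` frequency pairs in Hz.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 13),
    beta  = c(13, 30),
    gamma = c(30, 45)
  )
}

#' Discrete Fourier transform magnitudes of an epoch
#'
#' Computes `|H_k|` for `k = 0, ..., n_bins - 1` per channel, where
#' `H_k = sum_r h_r exp(-2*pi*i*r*k/R)` is the DFT of the `R`-sample signal.
#' The transform is evaluated with the FFT; it is bit-deterministic and has
#' no hidden state.
#'
#' @param epoch Numeric matrix of raw samples, one column per channel (a
#'   plain numeric vector is treated as a single channel).
#' @param n_bins Number of leading frequency bins to return. Defaults to the
#'   one-sided spectrum length `floor(R/2) + 1`.
#' @return A numeric matrix with `n_bins` rows and one column per channel.
#' @export
#' @examples
#' dft_magnitudes(sin(2 * pi * 3 * (0:31) / 32))
dft_magnitudes <- function(epoch, n_bins = NULL) {
  if (is.vector(epoch)) epoch <- matrix(epoch, ncol = 1)
  if (!is.matrix(epoch) || nrow(epoch) == 0L) {
    abort("epoch must be a non-empty numeric matrix (samples x channels)")
  }
  stopifnot_finite(epoch, "samples")
  r <- nrow(epoch)
  max_bins <- floor(r / 2) + 1L
  n_bins <- if (is.null(n_bins)) max_bins else as.integer(n_bins)
  if (n_bins < 1L || n_bins > max_bins) {
    abort(sprintf("n_bins must be in [1, %d] for %d samples", max_bins, r))
  }
  spec <- mvfft(epoch)
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  dimnames(mag) <- list(NULL, colnames(epoch))
  mag
}

#' Band power features from a magnitude spectrum
#'
#' One feature per (channel, band): the sum of squared spectral magnitudes of
#' the bins whose frequency lies in `[low, high)`. Features are ordered
#' channel-major (all bands of channel 1, then channel 2, ...).
#'
#' @param spectrum Magnitude matrix from [dft_magnitudes()] (bins x channels),
#'   assumed to start at DC with bin spacing `sampling_rate / R`.
#' @param sampling_rate Samples per second of the original signal.
#' @param n_samples Number of samples `R` in the original epoch (sets the bin
#'   width); defaults to a one-sided spectrum, `2 * (nrow(spectrum) - 1)`.
#' @param bands Named list of `c(low, high)` pairs in Hz; see [eeg_bands()].
#' @return A named numeric vector of band powers.
#' @export
band_powers <- function(spectrum, sampling_rate, bands = eeg_bands(),
                        n_samples = 2L * (nrow(spectrum) - 1L)) {
  if (is.vector(spectrum)) spectrum <- matrix(spectrum, ncol = 1)
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  nyquist <- sampling_rate / 2
  bad <- vapply(bands, function(b) b[1] < 0 || b[2] > nyquist || b[2] <= b[1],
                logical(1))
  if (any(bad)) {
    abort(sprintf("bands outside the Nyquist range [0, %g]: %s",
                  nyquist, paste(names(bands)[bad], collapse = ", ")))
  }
  freqs <- (seq_len(nrow(spectrum)) - 1L) * sampling_rate / n_samples
  n_ch <- ncol(spectrum)
  ch_names <- colnames(spectrum) %||% paste0("ch", seq_len(n_ch))
  out <- numeric(0)
  for (ch in seq_len(n_ch)) {
    p <- vapply(bands, function(b) {
      sum(spectrum[freqs >= b[1] & freqs < b[2], ch]^2)
    }, numeric(1))
    names(p) <- paste(ch_names[ch], names(bands), sep = "_")
    out <- c(out, p)
  }
  out
}

#' Label epochs from seizure annotation intervals
#'
#' An epoch is labelled positive (1) when the fraction of its duration that
#' overlaps any annotated seizure interval is at least `overlap_threshold`.
#'
#' @param epoch_starts Numeric vector of epoch start times in seconds,
#'   time-ordered.
#' @param epoch_duration Epoch length in seconds (default 1).
#' @param annotations Data frame with numeric columns `onset` and `offset`
#'   (seconds); intervals must not overlap one another. `NULL` or an empty
#'   frame labels everything 0.
#' @param overlap_threshold Minimum overlap fraction in `(0, 1]` for a
#'   positive label (default 0.5: an epoch straddling a seizure boundary
#'   counts as seizure only if at least half of it is inside).
#' @return Integer vector of 0/1 labels, one per epoch.
#' @export
#' @examples
#' label_epochs(0:99, 1, data.frame(onset = 20, offset = 35))
label_epochs <- function(epoch_starts, epoch_duration = 1,
                         annotations = NULL, overlap_threshold = 0.5) {
  if (any(epoch_starts < 0) || epoch_duration <= 0) {
    abort("epoch times must be non-negative and epoch_duration positive")
  }
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    abort("overlap_threshold must be in (0, 1]")
  }
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(integer(length(epoch_starts)))
  }
  on <- annotations$onset
  off <- annotations$offset
  if (any(on < 0) || any(off <= on)) {
    abort("annotation intervals must satisfy 0 <= onset < offset")
  }
  ord <- order(on)
  if (any(on[ord][-1] < off[ord][-length(off)])) {
    abort("annotation intervals must not overlap")
  }
  vapply(epoch_starts, function(s) {
    e <- s + epoch_duration
    ov <- sum(pmax(0, pmin(e, off) - pmax(s, on)))
    as.integer(ov / epoch_duration >= overlap_threshold)
  }, integer(1))
}

#' Featurize a multichannel signal record into a labelled stream
#'
#' Slices the record into consecutive fixed-duration epochs, computes one
#' feature vector per epoch (log band power per channel in the clinical
#' bands by default, or the leading raw spectral magnitudes), and labels
#' each epoch from the seizure annotations. This is the tabular form every
#' downstream module consumes.
#'
#' @param signal Numeric matrix of raw samples (rows) by channels (columns).
#' @param sampling_rate Samples per second.
#' @param annotations Optional data frame of seizure intervals
#'   (`onset`/`offset` seconds); see [label_epochs()].
#' @param epoch_duration Epoch length in seconds (default 1).
#' @param mode `"bandpower"` (default) or `"raw_bins"`.
#' @param bands Band definition for `mode = "bandpower"`.
#' @param n_bins Number of leading magnitude bins for `mode = "raw_bins"`.
#' @param overlap_threshold Passed to [label_epochs()].
#' @param log_power Take `log(power + 1e-12)` of band powers (default TRUE);
#'   spectral power spans orders of magnitude and Gaussian learners behave
#'   far better on the log scale.
#' @return A tibble with columns `epoch_start`, one column per feature and
#'   `label`.
#' @export
featurize_signal <- function(signal, sampling_rate, annotations = NULL,
                             epoch_duration = 1,
                             mode = c("bandpower", "raw_bins"),
                             bands = eeg_bands(), n_bins = 8L,
                             overlap_threshold = 0.5, log_power = TRUE) {
  mode <- match.arg(mode)
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  stopifnot_finite(signal, "samples")
  r <- as.integer(round(sampling_rate * epoch_duration))
  n_epochs <- nrow(signal) %/% r
  if (n_epochs == 0L) abort("signal shorter than one epoch")
  if (is.null(colnames(signal))) {
    colnames(signal) <- paste0("ch", seq_len(ncol(signal)))
  }
  if (mode == "bandpower") {
    fits <- vapply(bands, function(b) b[2] <= sampling_rate / 2, logical(1))
    if (!all(fits)) {
      warn(sprintf("dropping bands beyond the Nyquist frequency: %s",
                   paste(names(bands)[!fits], collapse = ", ")))
      bands <- bands[fits]
    }
    if (length(bands) == 0L) abort("no bands below the Nyquist frequency")
  }
  starts <- (seq_len(n_epochs) - 1L) * epoch_duration
  feats <- lapply(seq_len(n_epochs), function(i) {
    ep <- signal[((i - 1L) * r + 1L):(i * r), , drop = FALSE]
    if (mode == "bandpower") {
      p <- band_powers(dft_magnitudes(ep), sampling_rate, bands, n_samples = r)
      if (log_power) p <- log(p + 1e-12)
      p
    } else {
      m <- dft_magnitudes(ep, n_bins = n_bins)
      setNames(as.vector(m),
               paste(rep(colnames(ep), each = n_bins), "bin",
                     rep(seq_len(n_bins) - 1L, ncol(ep)), sep = "_"))
    }
  })
  out <- tibble::as_tibble(do.call(rbind, feats))
  out$epoch_start <- starts
  out$label <- label_epochs(starts, epoch_duration, annotations,
                            overlap_threshold)
  dplyr::relocate(out, "epoch_start")
}

#' Read / write a labelled feature stream as CSV
#'
#' The on-disk stream format is a plain CSV whose header holds the feature
#' names plus `label` (and, when present, `tick` and `arrival_index`).
#'
#' @param stream A stream tibble.
#' @param path File path.
#' @return `read_stream_csv()` returns a tibble; `write_stream_csv()`
#'   invisibly returns `path`.
#' @export
write_stream_csv <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Chunk a flat labelled stream into fixed-size chunks
#'
#' Adds `tick` (1-based chunk index) and `arrival_index` columns so the
#' stream can be consumed chunkwise; trailing instances that do not fill a
#' complete chunk are dropped.
#'
#' @param stream Tibble with feature columns and `label`.
#' @param chunk_size Instances per chunk.
#' @return The stream tibble with `tick` and `arrival_index` prepended.
#' @export
chunk_stream <- function(stream, chunk_size) {
  n <- nrow(stream) %/% chunk_size * chunk_size
  if (n == 0L) abort("stream shorter than one chunk")
  out <- stream[seq_len(n), , drop = FALSE]
  out$tick <- rep(seq_len(n %/% chunk_size), each = chunk_size)
  out$arrival_index <- seq_len(n)
  dplyr::relocate(tibble::as_tibble(out), "tick", "arrival_index")
}
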