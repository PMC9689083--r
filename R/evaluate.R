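#' Classification metrics from a confusion matrix
#'
#' Computes the seven streaming-evaluation metrics — sensitivity (TPR),
#' specificity (TNR), false positive rate, false negative rate, accuracy,
#' precision and F1 — from TP/TN/FP/FN tallies:
#' `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`, `FPR = FP/(FP+TN)`,
#' `FNR = FN/(FN+TP)`, `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`. Metrics with a zero denominator are reported as
#' `NA` (undefined), never coerced to 0, so early all-negative chunks do not
#' silently deflate averages.
#'
#' @param m A data frame with non-negative integer columns `tp`, `tn`, `fp`,
#'   `fn` (vectorized over rows), or a single named vector/list with those
#'   elements.
#' @return A tibble with one row per input row and columns `tpr`, `tnr`,
#'   `fpr`, `fnr`, `accuracy`, `precision`, `f1`.
#' @export
#' @examples
#' metrics_from_confusion(data.frame(tp = 95, fn = 7, fp = 53, tn = 1534))
metrics_from_confusion <- function(m) {
  if (!is.data.frame(m)) m <- tibble::as_tibble(as.list(m))
  need <- c("tp", "tn", "fp", "fn")
  if (!all(need %in% names(m))) abort("m must contain tp, tn, fp, fn")
  if (any(unlist(m[need]) < 0)) abort("confusion counts must be non-negative")
  tot <- m$tp + m$tn + m$fp + m$fn
  if (any(tot == 0)) abort("empty confusion matrix (total = 0)")
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    tpr = rate(m$tp, m$tp + m$fn),
    tnr = rate(m$tn, m$tn + m$fp),
    fpr = rate(m$fp, m$fp + m$tn),
    fnr = rate(m$fn, m$fn + m$tp),
    accuracy = (m$tp + m$tn) / tot,
    precision = rate(m$tp, m$tp + m$fp),
    f1 = rate(2 * m$tp, 2 * m$tp + m$fp + m$fn)
  )
}

.metric_names <- c("tpr", "tnr", "fpr", "fnr", "accuracy", "precision", "f1")

#' Prequential (test-then-train) evaluation over a chunked stream
#'
#' For each arriving chunk the selected rebalancer produces the evaluation
#' window (`"none"` passes the raw chunk through); each in-scope instance is
#' first predicted — tallying the per-chunk confusion matrix — and then
#' learned, in window order. With `eval_scope = "window"` (default) carried
#' or buffered instances are tested as well as learned, matching chunk
#' totals that exceed the native chunk size; note this re-tests instances
#' the model has already trained on, an optimistic bias. `"native"` tests
#' only the chunk's own instances while still learning the full window.
#'
#' @param stream Chunked stream tibble (`tick`, `arrival_index`, `label`,
#'   features).
#' @param rebalancer One of `"none"`, `"skew"`, `"saw"`.
#' @param classifier A streaming classifier (see [classifier-contract]);
#'   default [classifier_nb()]. A fresh copy is used via [reset()].
#' @param eval_scope `"window"` or `"native"`.
#' @param saw Optional [saw_config()] when `rebalancer = "saw"`.
#' @param skew Optional [skew_config()] when `rebalancer = "skew"`.
#' @return An object of class `prequential_result`: list with `trace` (one
#'   row per chunk: tick, window_size, n_carried, tp/tn/fp/fn and the seven
#'   per-chunk metrics), `method`, `eval_scope`. [tidy()] returns the trace
#'   (per-chunk or cumulative), [glance()] a one-row summary with both
#'   mean-of-chunks and pooled metrics.
#' @export
prequential_run <- function(stream,
                            rebalancer = c("none", "skew", "saw"),
                            classifier = classifier_nb(),
                            eval_scope = c("window", "native"),
                            saw = saw_config(), skew = skew_config()) {
  rebalancer <- match.arg(rebalancer)
  eval_scope <- match.arg(eval_scope)
  clf <- reset(classifier)
  chunks <- split(stream, stream$tick)
  chunks <- chunks[order(as.numeric(names(chunks)))]
  st <- switch(rebalancer,
               none = NULL, skew = skew_state(skew), saw = saw_state(saw))
  fcols <- feature_cols(stream)
  traces <- vector("list", length(chunks))

  for (i in seq_along(chunks)) {
    chunk <- chunks[[i]]
    step <- switch(rebalancer,
      none = list(window = chunk,
                  trace = tibble::tibble(
                    tick = chunk$tick[1], n_native = nrow(chunk),
                    n_carried = 0L, window_size = nrow(chunk),
                    positive_fraction = mean(chunk$label == 1L))),
      skew = skew_step(st, chunk),
      saw = saw_step(st, chunk))
    if (!is.null(step$state)) st <- step$state
    window <- step$window
    x <- as_feature_matrix(window, fcols)
    lab <- as.integer(window$label)
    in_scope <- if (eval_scope == "window") rep(TRUE, nrow(window))
                else !isTRUE_vec(window$carried) & window$tick == chunk$tick[1] &
                     window$arrival_index %in% chunk$arrival_index
    tp <- tn <- fp <- fn <- 0L
    for (j in seq_len(nrow(window))) {
      if (in_scope[j]) {
        pred <- predict_one(clf, x[j, ])
        if (pred == 1L && lab[j] == 1L) tp <- tp + 1L
        else if (pred == 0L && lab[j] == 0L) tn <- tn + 1L
        else if (pred == 1L) fp <- fp + 1L
        else fn <- fn + 1L
      }
      learn_one(clf, x[j, ], lab[j])
    }
    if (!is.null(clf$on_chunk)) clf$on_chunk(clf, chunk)
    cm <- tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn)
    traces[[i]] <- dplyr::bind_cols(step$trace, cm, metrics_from_confusion(cm))
  }

  structure(
    list(trace = dplyr::bind_rows(traces),
         method = rebalancer, eval_scope = eval_scope,
         classifier = class(classifier)[1]),
    class = "prequential_result"
  )
}

# vectorised isTRUE for logical columns that may be absent/NA
isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' @param x A `prequential_result`.
#' @param cumulative If TRUE, return metrics of the running cumulative
#'   confusion matrix instead of per-chunk metrics.
#' @param ... Unused.
#' @rdname prequential_run
#' @exportS3Method generics::tidy
tidy.prequential_result <- function(x, cumulative = FALSE, ...) {
  tr <- x$trace
  if (!cumulative) return(tr)
  cum <- tibble::tibble(
    tp = cumsum(tr$tp), tn = cumsum(tr$tn),
    fp = cumsum(tr$fp), fn = cumsum(tr$fn)
  )
  dplyr::bind_cols(tr[c("tick", "window_size", "n_carried")],
                   cum, metrics_from_confusion(cum))
}

#' @rdname prequential_run
#' @exportS3Method generics::glance
glance.prequential_result <- function(x, ...) {
  tr <- x$trace
  pooled <- metrics_from_confusion(
    tibble::tibble(tp = sum(tr$tp), tn = sum(tr$tn),
                   fp = sum(tr$fp), fn = sum(tr$fn)))
  means <- vapply(tr[.metric_names], mean, numeric(1), na.rm = TRUE)
  out <- tibble::tibble(method = x$method, eval_scope = x$eval_scope,
                        classifier = x$classifier, n_chunks = nrow(tr),
                        n_tested = sum(tr$tp + tr$tn + tr$fp + tr$fn))
  for (m in .metric_names) out[[paste0("mean_", m)]] <- unname(means[m])
  for (m in .metric_names) out[[paste0("pooled_", m)]] <- pooled[[m]]
  out
}

#' Positive-class presence per chunk
#'
#' The fraction of positives in each evaluated window — the quantity that a
#' rebalancer raises from the raw stream's base rate.
#'
#' @param result A `saw_result`, `skew_result` or `prequential_result` (or
#'   the trace tibble itself).
#' @return Tibble with `tick` and `positive_fraction`.
#' @export
presence_trace <- function(result) {
  tr <- if (is.data.frame(result)) result else result$trace
  tibble::tibble(tick = tr$tick, positive_fraction = tr$positive_fraction)
}

#' @export
print.prequential_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Prequential run: rebalancer '%s', %s scope, %d chunks, %d tested\n",
              g$method, g$eval_scope, g$n_chunks, g$n_tested))
  cat(sprintf("  mean-of-chunks: tpr %.4f  tnr %.4f  fpr %.4f  acc %.4f  prec %.4f  f1 %.4f\n",
              g$mean_tpr, g$mean_tnr, g$mean_fpr, g$mean_accuracy,
              g$mean_precision, g$mean_f1))
  cat(sprintf("  pooled:         tpr %.4f  tnr %.4f  fpr %.4f  acc %.4f  prec %.4f  f1 %.4f\n",
              g$pooled_tpr, g$pooled_tnr, g$pooled_fpr, g$pooled_accuracy,
              g$pooled_precision, g$pooled_f1))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.prequential_result <- function(object, metrics = c("tpr", "fpr", "accuracy"), ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(tr[c("tick", metrics)], -"tick",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tick, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "chunk (tick)", y = "metric value",
                  title = sprintf("Prequential metrics (rebalancer: %s)",
                                  object$method)) +
    ggplot2::theme_minimal()
}
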