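#' Run a full, reproducible stream experiment
#'
#' Orchestrates one end-to-end run — stream (synthetic or loaded from CSV)
#' -> rebalancer -> incremental classifier -> prequential traces — and
#' writes every artifact needed to replay it: per-chunk and cumulative trace
#' CSVs, a presence trace, a summary JSON with both mean-of-chunks and
#' pooled metrics, and a manifest echoing the full configuration and seeds.
#' Runs with a deterministic classifier replay byte-identically from the
#' manifest.
#'
#' @param stream A chunked stream tibble, or `NULL` to generate one from
#'   `spec`.
#' @param spec A [stream_spec()] used when `stream` is `NULL`.
#' @param rebalancer `"none"`, `"skew"` or `"saw"`.
#' @param classifier `"nb"`, `"hoeffding"`, `"bagging"`, or a ready
#'   classifier object.
#' @param ath,brs_cap SAW parameters (see [saw_config()]).
#' @param target_ratio Skew undersampling target (see [skew_config()]).
#' @param eval_scope `"window"` or `"native"` (see [prequential_run()]).
#' @param seed Global seed: drives stream generation (when simulated), skew
#'   undersampling and stochastic classifiers.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @return The `prequential_result`, invisibly augmented with
#'   `out_dir`.
#' @export
run_experiment <- function(stream = NULL, spec = stream_spec(),
                           rebalancer = c("none", "skew", "saw"),
                           classifier = "nb",
                           ath = 8L, brs_cap = NULL, target_ratio = 1,
                           eval_scope = c("window", "native"),
                           seed = 1L, out_dir = NULL) {
  rebalancer <- match.arg(rebalancer)
  eval_scope <- match.arg(eval_scope)
  if (is.null(stream)) {
    spec$seed <- as.integer(seed)
    stream <- generate_stream(spec)
  }
  clf <- if (is.character(classifier)) {
    switch(match.arg(classifier, c("nb", "hoeffding", "bagging")),
           nb = classifier_nb(),
           hoeffding = classifier_hoeffding(),
           bagging = classifier_bagging(seed = seed))
  } else classifier
  res <- prequential_run(stream, rebalancer, clf, eval_scope,
                         saw = saw_config(ath, brs_cap),
                         skew = skew_config(target_ratio, seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tidy(res), file.path(out_dir, "trace_per_chunk.csv"),
              row.names = FALSE, na = "")
    write.csv(tidy(res, cumulative = TRUE),
              file.path(out_dir, "trace_cumulative.csv"),
              row.names = FALSE, na = "")
    write.csv(presence_trace(res), file.path(out_dir, "presence.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.list(glance(res)),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("sawstream")),
      rebalancer = rebalancer,
      classifier = if (is.character(classifier)) classifier else class(clf)[1],
      ath = ath, brs_cap = brs_cap, target_ratio = target_ratio,
      eval_scope = eval_scope, seed = seed,
      stream = if (inherits(spec, "stream_spec"))
        spec[setdiff(names(spec), "drift")] else "external"
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    res$out_dir <- out_dir
  }
  invisible(res)
}

#' Compare rebalancing methods on one shared stream
#'
#' Runs the same stream and classifier under several rebalancers and
#' returns a side-by-side table of the seven mean metrics (mean-of-chunks,
#' with pooled variants alongside). The shared stream guarantees a paired
#' comparison.
#'
#' @param stream Chunked stream tibble (shared across methods).
#' @param methods Character vector of rebalancers to compare.
#' @param classifier As in [run_experiment()]; a fresh [reset()] copy is
#'   used per method.
#' @param ... Passed to [prequential_run()] configs via [run_experiment()]
#'   arguments `ath`, `brs_cap`, `target_ratio`, `eval_scope`, `seed`.
#' @return A tibble with one row per method (the [glance()] rows).
#' @export
compare_methods <- function(stream, methods = c("none", "skew", "saw"),
                            classifier = "nb", ...) {
  rows <- lapply(methods, function(m) {
    glance(run_experiment(stream = stream, rebalancer = m,
                          classifier = classifier, ...))
  })
  dplyr::bind_rows(rows)
}
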