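#' Construct a metrics report
#'
#' Binary contingency counts with the derived metrics: precision
#' `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1 `2PR/(P+R)`; each defined as 0
#' when its denominator is 0 (logged convention for degenerate runs).
#'
#' @param tp,fp,fn,tn Contingency counts (positive class = relation
#'   present).
#' @param parse_failures Number of predictions whose raw output could not
#'   be parsed (these enter the contingency as the default negative
#'   label and are tallied here separately).
#' @param run_id Optional run identifier.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(tp, fp, fn, tn, parse_failures = 0L, run_id = NA) {
  for (x in list(tp, fp, fn, tn, parse_failures)) {
    if (!is_count(x)) abort("counts must be non-negative integers")
  }
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 precision = precision, recall = recall, f1 = f1,
                 parse_failures = as.integer(parse_failures), run_id = run_id),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> P=%.4f R=%.4f F1=%.4f (tp=%d fp=%d fn=%d tn=%d, %d parse failure(s))\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn,
              x$parse_failures))
  invisible(x)
}

#' Construct a prediction for an instance
#'
#' @param instance The [relation_instance()] predicted for.
#' @param predicted `"yes"` or `"no"`.
#' @param parse_status `"parsed"` or `"unparseable"`. Unparseable outputs
#'   must carry the configured default label (`"no"` by default).
#' @param raw Optional raw generation text (opaque; kept for audit).
#' @return An object of class `re_prediction`.
#' @export
prediction <- function(instance, predicted, parse_status = "parsed", raw = NULL) {
  predicted <- match.arg(predicted, c("yes", "no"))
  parse_status <- match.arg(parse_status, c("parsed", "unparseable"))
  structure(list(doc_id = instance$doc_id,
                 head = instance$head$entity_id,
                 tail = instance$tail$entity_id,
                 predicted = predicted, parse_status = parse_status, raw = raw),
            class = "re_prediction")
}

#' Score predictions against gold instances
#'
#' Computes the binary contingency table (positive class = relation
#' present) and the precision/recall/F1 metrics for one run. Predictions
#' must align one-to-one with the instances, in order and on the same
#' (document, head, tail) keys.
#'
#' @param predictions List of [prediction()] objects.
#' @param instances List of [relation_instance()] objects.
#' @param run_id Optional run identifier carried into the report.
#' @return A [metrics_report()].
#' @export
score_predictions <- function(predictions, instances, run_id = NA) {
  if (length(predictions) != length(instances)) {
    abort(sprintf("%d prediction(s) for %d instance(s)",
                  length(predictions), length(instances)))
  }
  tp <- fp <- fn <- tn <- 0L
  parse_failures <- 0L
  for (i in seq_along(instances)) {
    pred <- predictions[[i]]
    inst <- instances[[i]]
    key_p <- paste(pred$doc_id, pred$head, pred$tail, sep = "|")
    if (!identical(key_p, instance_key(inst))) {
      abort(sprintf("prediction %d (%s) does not match instance (%s)",
                    i, key_p, instance_key(inst)))
    }
    if (pred$parse_status == "unparseable") parse_failures <- parse_failures + 1L
    pos_pred <- pred$predicted == "yes"
    pos_gold <- inst$gold == "positive"
    if (pos_pred && pos_gold) tp <- tp + 1L
    else if (pos_pred && !pos_gold) fp <- fp + 1L
    else if (!pos_pred && pos_gold) fn <- fn + 1L
    else tn <- tn + 1L
  }
  metrics_report(tp, fp, fn, tn, parse_failures, run_id)
}

#' Aggregate metric reports over repeated runs
#'
#' Mean and sample standard deviation (n - 1 denominator; 0 for a single
#' run) of precision, recall and F1 across runs — the mean +/- std
#' presentation convention for repeated zero-shot experiments.
#'
#' @param reports Non-empty list of [metrics_report()] objects.
#' @return An object of class `run_aggregate`: a list with `n` and
#'   `metrics` (data frame `metric`, `mean`, `sd`).
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) == 0L) abort("`reports` must be non-empty")
  ok <- vapply(reports, inherits, logical(1), what = "metrics_report")
  if (!all(ok)) abort("`reports` must all be metrics_report objects")
  one <- function(field) {
    vals <- vapply(reports, function(r) r[[field]], numeric(1))
    c(mean = mean(vals),
      sd = if (length(vals) == 1L) 0 else stats::sd(vals))
  }
  m <- rbind(precision = one("precision"), recall = one("recall"),
             f1 = one("f1"))
  structure(list(n = length(reports),
                 metrics = data.frame(metric = rownames(m),
                                      mean = m[, "mean"], sd = m[, "sd"],
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "run_aggregate")
}

aggregate_metric <- function(agg, metric, what = "mean") {
  agg$metrics[[what]][agg$metrics$metric == metric]
}

#' @export
print.run_aggregate <- function(x, ...) {
  cat(sprintf("<run_aggregate> over %d run(s):\n", x$n))
  for (i in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", x$metrics$metric[[i]],
                x$metrics$mean[[i]], x$metrics$sd[[i]]))
  }
  invisible(x)
}
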