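#' Confusion counts for binary calls
#'
#' TP: predicted binding, observed binding. FP: predicted binding, observed
#' non-binding. TN/FN analogously. Works on any pair of equal-length 0/1
#' vectors (a single class column or the binary reduction).
#'
#' @param calls integer 0/1 vector of predictions.
#' @param labels integer 0/1 vector of observations.
#' @return named list TP, FP, TN, FN (non-negative integers summing to the
#'   number of scored residues).
#' @export
confusion <- function(calls, labels) {
  assert_that(length(calls) == length(labels), "calls/labels length mismatch")
  list(TP = sum(calls == 1 & labels == 1),
       FP = sum(calls == 1 & labels == 0),
       TN = sum(calls == 0 & labels == 0),
       FN = sum(calls == 0 & labels == 1))
}

#' Per-class and binary confusion counts
#'
#' @param calls L x 3 call matrix.
#' @param labels L x 3 label matrix.
#' @return named list with one confusion per ligand class plus `binary`
#'   (any-class reduction on both sides).
#' @export
confusion_by_class <- function(calls, labels) {
  out <- lapply(1:3, function(c) confusion(calls[, c], labels[, c]))
  names(out) <- LIGAND_CLASSES
  out$binary <- confusion(to_binary(calls), as.integer(rowSums(labels) > 0))
  out
}

#' Confusion-derived performance metrics
#'
#' Computes MCC, precision, recall, accuracy and F1 from a confusion table.
#' Degenerate denominators return 0 rather than an error (MCC with any zero
#' marginal, precision with no predicted positives, recall with no observed
#' positives, F1 with precision + recall = 0), keeping every metric total.
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts list with TP, FP, TN, FN.
#' @return named list: mcc, precision, recall, accuracy, f1.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fn * fp) / denom
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  total <- tp + tn + fp + fn
  accuracy <- if (total == 0) 0 else (tp + tn) / total
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(mcc = mcc, precision = precision, recall = recall,
       accuracy = accuracy, f1 = f1)
}

#' Mean and symmetric 95 % confidence interval over per-protein values
#'
#' Performance is summarized by computing each metric per protein, then
#' reporting the mean and `1.96 * SD / sqrt(n)` (normal approximation).
#' `NA` values -- proteins where the metric is undefined, e.g. no observed
#' and no predicted positives for a class -- are excluded from the
#' aggregation and counted in `n_undefined`. A single defined value gets a
#' half-width of 0 with `single = TRUE` flagged.
#'
#' @param values numeric vector of per-protein metric values (may contain NA).
#' @return list: mean, ci_halfwidth, n, n_undefined, single.
#' @export
per_protein_ci <- function(values) {
  defined <- values[!is.na(values)]
  n <- length(defined)
  if (n == 0) {
    return(list(mean = NA_real_, ci_halfwidth = NA_real_, n = 0L,
                n_undefined = length(values), single = FALSE))
  }
  half <- if (n == 1) 0 else 1.96 * stats::sd(defined) / sqrt(n)
  list(mean = mean(defined), ci_halfwidth = half, n = n,
       n_undefined = length(values) - n, single = n == 1)
}

## Per-protein metric value with the undefined-metric convention: for
## precision/recall/F1/MCC a protein with neither observed nor predicted
## positives carries no information about that class -> NA (excluded from
## aggregation, the default) or zero-filled when exclude_undefined = FALSE.
per_protein_metric <- function(counts, metric, exclude_undefined = TRUE) {
  undefined <- counts$TP + counts$FN + counts$FP == 0 && metric != "accuracy"
  if (undefined) {
    if (exclude_undefined) return(NA_real_) else return(0)
  }
  metrics(counts)[[metric]]
}

#' Evaluate predictions against labels, per class and binary
#'
#' Applies the call threshold, accumulates per-protein confusion counts and
#' reports, for every ligand class and the binary reduction: micro counts
#' (summed over proteins, equal to confusion on the concatenated residues)
#' with their metrics, and per-protein mean +/- 95 % CI for each metric.
#'
#' @param probs named list of L x 3 probability matrices.
#' @param labels named list of L x 3 label matrices (same names).
#' @param threshold call threshold (default 0.5).
#' @param exclude_undefined exclude proteins where a metric is undefined
#'   from that metric's CI aggregation (default), instead of zero-filling.
#' @return a `metric_set`: per task (metal/nucleic/small/binary) the micro
#'   counts + metrics and per-metric `list(mean, ci_halfwidth, n, ...)`.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5,
                                 exclude_undefined = TRUE) {
  assert_that(length(probs) == length(labels), "probs/labels length mismatch")
  ids <- names(probs) %||% seq_along(probs)
  per_prot <- lapply(seq_along(probs), function(i) {
    confusion_by_class(call_binding(probs[[i]], threshold), labels[[i]])
  })
  metric_names <- c("mcc", "precision", "recall", "accuracy", "f1")
  tasks <- c(LIGAND_CLASSES, "binary")
  out <- lapply(tasks, function(task) {
    counts <- lapply(per_prot, `[[`, task)
    micro <- list(TP = sum(vapply(counts, `[[`, numeric(1), "TP")),
                  FP = sum(vapply(counts, `[[`, numeric(1), "FP")),
                  TN = sum(vapply(counts, `[[`, numeric(1), "TN")),
                  FN = sum(vapply(counts, `[[`, numeric(1), "FN")))
    agg <- lapply(metric_names, function(mn) {
      vals <- vapply(counts, per_protein_metric, numeric(1),
                     metric = mn, exclude_undefined = exclude_undefined)
      per_protein_ci(vals)
    })
    names(agg) <- metric_names
    list(micro_counts = micro, micro_metrics = metrics(micro), per_protein = agg)
  })
  names(out) <- tasks
  structure(out, class = "metric_set", n_proteins = length(probs))
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("metric_set over %d proteins\n", attr(x, "n_proteins")))
  for (task in names(x)) {
    pp <- x[[task]]$per_protein
    cat(sprintf("  %-8s F1 %.3f +/- %.3f | MCC %.3f +/- %.3f | prec %.3f | rec %.3f (n=%d)\n",
                task, pp$f1$mean, pp$f1$ci_halfwidth, pp$mcc$mean,
                pp$mcc$ci_halfwidth, pp$precision$mean, pp$recall$mean,
                pp$f1$n))
  }
  invisible(x)
}

#' Precision-recall and ROC sweep over call thresholds
#'
#' Binary task: a residue's score is its maximum class probability, its
#' observed state the any-class label. For each threshold the calls are
#' `score >= t`; the table reports precision, recall (= TPR) and FPR.
#' Trapezoidal areas under ROC (FPR vs TPR) and PR (recall vs precision)
#' are attached as attributes `auroc` / `aupr`.
#'
#' @param probs named list of L x 3 probability matrices (or one matrix).
#' @param labels matching list of L x 3 label matrices.
#' @param thresholds numeric vector of thresholds (default 0 to 1 by 0.01).
#' @return data.frame: threshold, TP, FP, TN, FN, precision, recall, fpr.
#' @export
pr_roc_sweep <- function(probs, labels, thresholds = seq(0, 1, by = 0.01)) {
  if (is.matrix(probs)) probs <- list(probs)
  if (is.matrix(labels)) labels <- list(labels)
  score <- unlist(lapply(probs, reliability))
  truth <- unlist(lapply(labels, function(l) as.integer(rowSums(l) > 0)))
  rows <- lapply(thresholds, function(t) {
    cc <- confusion(as.integer(score >= t), truth)
    m <- metrics(cc)
    data.frame(threshold = t, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               precision = m$precision, recall = m$recall,
               fpr = if (cc$FP + cc$TN == 0) 0 else cc$FP / (cc$FP + cc$TN))
  })
  df <- do.call(rbind, rows)
  trapz <- function(x, y) {
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  # FPR and TPR are monotone in the threshold, so walking thresholds from
  # high to low traces the ROC curve left to right
  o <- order(df$threshold, decreasing = TRUE)
  attr(df, "auroc") <- trapz(c(0, df$fpr[o], 1), c(0, df$recall[o], 1))
  attr(df, "aupr") <- abs(trapz(df$recall[o], df$precision[o]))
  df
}

#' Reliability table: coverage and precision above score cutoffs
#'
#' For each reliability cutoff t (strictly greater-than): coverage is the
#' fraction of observed binding residues whose score exceeds t; precision
#' is the fraction of residues with score > t that are observed binding.
#' Stronger predictions being more often correct shows up as precision
#' rising with t.
#'
#' @param probs named list of L x 3 probability matrices (or one matrix).
#' @param labels matching list of L x 3 label matrices.
#' @param thresholds score cutoffs (default 0.5 to 0.95 by 0.05).
#' @return data.frame: threshold, n_above, coverage, precision.
#' @export
reliability_table <- function(probs, labels,
                              thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.matrix(probs)) probs <- list(probs)
  if (is.matrix(labels)) labels <- list(labels)
  score <- unlist(lapply(probs, reliability))
  truth <- unlist(lapply(labels, function(l) as.integer(rowSums(l) > 0)))
  n_bind <- sum(truth == 1)
  rows <- lapply(thresholds, function(t) {
    above <- score > t
    data.frame(threshold = t, n_above = sum(above),
               coverage = if (n_bind == 0) NA_real_ else
                 sum(above & truth == 1) / n_bind,
               precision = if (!any(above)) NA_real_ else
                 sum(above & truth == 1) / sum(above))
  })
  do.call(rbind, rows)
}

#' Pearson correlation between structure confidence and predicted binding
#'
#' Correlates per-residue pLDDT with the predicted binding probability
#' (maximum class probability), concatenated over proteins. A constant
#' vector has no defined correlation: returns `NA` with a warning.
#'
#' @param plddt list of per-protein pLDDT vectors (or one vector).
#' @param probs matching list of L x 3 probability matrices (or one matrix).
#' @return scalar Pearson r (possibly NA).
#' @export
plddt_correlation <- function(plddt, probs) {
  if (is.numeric(plddt)) plddt <- list(plddt)
  if (is.matrix(probs)) probs <- list(probs)
  x <- unlist(plddt)
  y <- unlist(lapply(probs, reliability))
  assert_that(length(x) == length(y), "plddt/probability length mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Null interval for binary F1 under label permutation
#'
#' Empirical 95 % interval of the binary F1 obtained when the calls are
#' randomly permuted against the labels -- the distribution a predictor
#' with the same call rate but no signal would produce. Used to check that
#' a model trained on signal-free data performs at chance.
#'
#' @param calls binary call vector.
#' @param labels binary label vector.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list: lower, upper (2.5/97.5 percentiles), f1_values.
#' @export
permutation_f1_interval <- function(calls, labels, n_perm = 1000, seed = 1) {
  set.seed(seed)
  f1s <- vapply(seq_len(n_perm), function(i) {
    metrics(confusion(sample(calls), labels))$f1
  }, numeric(1))
  q <- stats::quantile(f1s, c(0.025, 0.975), names = FALSE)
  list(lower = q[1], upper = q[2], f1_values = f1s)
}
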