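# Evaluation protocol: one-vs-all metrics, macro averaging, balanced
# repeated-holdout cross-validation, the metric-by-k parameter sweep, and
# the rank-of-true-group distribution.

#' One-vs-all metrics from confusion counts
#'
#' Sensitivity TPR = tp / P, specificity SPC = tn / N, precision
#' PPV = tp / (tp + fp) with the 0/0 case defined as 0 (a never-predicted
#' class scores zero precision), accuracy ACC = (tp + tn) / (P + N), where
#' P = tp + fn and N = tn + fp.
#'
#' @param tp,tn,fp,fn Non-negative integer counts for one class.
#' @param class Optional class name used in error messages.
#' @return Named numeric vector `c(TPR, SPC, PPV, ACC)`.
#' @export
#' @examples
#' one_vs_all_metrics(9, 95, 1, 1)
one_vs_all_metrics <- function(tp, tn, fp, fn, class = "?") {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  P <- tp + fn; N <- tn + fp
  if (P == 0) stop("TPR undefined for class ", class, ": no positives",
                   call. = FALSE)
  if (N == 0) stop("SPC undefined for class ", class, ": no negatives",
                   call. = FALSE)
  c(TPR = tp / P, SPC = tn / N,
    PPV = if (tp + fp == 0) 0 else tp / (tp + fp),
    ACC = (tp + tn) / (P + N))
}

#' Per-class one-vs-all confusion counts
#'
#' Binarizes a multiclass prediction set class by class.
#'
#' @param truth,predicted Character vectors of equal length (canonical
#'   labels).
#' @param labels Class inventory (default: all 14).
#' @return data.frame with columns `label`, `tp`, `tn`, `fp`, `fn`; each
#'   row sums to `length(truth)`.
#' @export
confusion_counts <- function(truth, predicted,
                             labels = heart_state_labels()) {
  stopifnot(length(truth) == length(predicted))
  n <- length(truth)
  rows <- lapply(labels, function(lb) {
    tp <- sum(truth == lb & predicted == lb)
    fp <- sum(truth != lb & predicted == lb)
    fn <- sum(truth == lb & predicted != lb)
    data.frame(label = lb, tp = tp, tn = n - tp - fp - fn, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Macro average accuracy over classes
#'
#' The mean over classes of the one-vs-all accuracies
#' (tp + tn) / (tp + tn + fp + fn).
#'
#' @param counts data.frame as from [confusion_counts()].
#' @return A single number in \[0, 1\].
#' @export
macro_average_accuracy <- function(counts) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1,
            all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  acc <- with(counts, (tp + tn) / (tp + tn + fp + fn))
  mean(acc)
}

#' Published clinical per-group metrics
#'
#' The per-group accuracy, precision, sensitivity and specificity of the
#' two-stage classifier on the original clinical cohort, packaged as a
#' worked example for macro averaging (the clinical maps are not public).
#'
#' @return data.frame with columns `group`, `accuracy`, `precision`,
#'   `sensitivity`, `specificity` (14 rows).
#' @export
clinical_group_metrics <- function() {
  path <- system.file("extdata", "clinical_group_metrics.tsv",
                      package = "cddmcascade", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Macro averages of a per-group metric table
#'
#' Column means of the four rate columns of a per-group table in the layout
#' of [clinical_group_metrics()].
#'
#' @param per_group data.frame with columns `accuracy`, `precision`,
#'   `sensitivity`, `specificity`.
#' @return Named numeric vector of the four macro averages.
#' @export
macro_metric_summary <- function(per_group) {
  cols <- c("accuracy", "precision", "sensitivity", "specificity")
  stopifnot(all(cols %in% names(per_group)))
  vapply(per_group[cols], mean, 0)
}

#' Rank-of-true-group distribution
#'
#' For a set of classified maps with known labels, the fraction whose true
#' label sits at rank r of the stage-1 ranking, r = 1..14. The cumulative
#' top-3 fraction is the quantity that motivates restricting stage 2 to the
#' three highest-correlation groups.
#'
#' @param traces List of `cddm_trace` objects with true labels.
#' @return Numeric vector of 14 fractions summing to 1, with attribute
#'   `top3` (cumulative fraction at ranks 1-3).
#' @export
rank_distribution <- function(traces) {
  stopifnot(length(traces) >= 1)
  ranks <- vapply(traces, function(tr) {
    if (is.na(tr$true_label))
      stop("trace '", tr$map_id, "' has no true label", call. = FALSE)
    match(tr$true_label, tr$ranked$label)
  }, 0L)
  dist <- tabulate(ranks, nbins = 14) / length(ranks)
  names(dist) <- paste0("rank", 1:14)
  attr(dist, "top3") <- sum(dist[1:3])
  dist
}

# Internal: balanced disjoint draw of reference/experimental map ids.
.draw_sets <- function(cohort, per_group) {
  ref <- character(0); exp <- character(0)
  for (lb in heart_state_labels()) {
    ids <- cohort$groups[[lb]]
    if (is.null(ids) || length(ids) < 2 * per_group)
      stop("label ", lb, " has ", length(ids), " maps; need at least ",
           2 * per_group, call. = FALSE)
    pick <- sample(ids, 2 * per_group)
    ref <- c(ref, pick[seq_len(per_group)])
    exp <- c(exp, pick[per_group + seq_len(per_group)])
  }
  list(reference = ref, experimental = exp)
}

# Internal: cohort subset by map ids.
.subset_cohort <- function(cohort, ids) as_cohort(cohort$maps[ids])

#' Balanced repeated-holdout cross-validation of the two-stage classifier
#'
#' Per iteration, draws a balanced reference set (`per_group` maps per label;
#' 280 at the defaults) and a disjoint balanced experimental set of the same
#' size, classifies the experimental maps with the two-stage cascade against
#' that reference, and accumulates one-vs-all counts. Rates are averaged
#' over iterations at the rate level; the confusion matrix and the rank
#' distribution pool all iterations.
#'
#' @param cohort A labelled `cddm_cohort` with at least `2 * per_group` maps
#'   per label.
#' @param iterations Number of iterations (default 20).
#' @param per_group Maps per label in each of the two sets (default 20).
#' @param m Stage-1 top-m parameter.
#' @param tables,registry Rule tables and pair registry.
#' @param seed Integer seed for the draws.
#' @param two_stage If FALSE, stage-1 labels are evaluated without the k-NN
#'   refinement (the one-stage baseline).
#' @return Object of class `cddm_eval_report`: list with `per_class`
#'   (label, accuracy, precision, sensitivity, specificity), `macro`,
#'   `confusion` (14 x 14 matrix, rows = truth), `rank_distribution`,
#'   `escalation_rate`, `n_iterations`, `per_group`.
#' @export
cross_validate <- function(cohort, iterations = 20L, per_group = 20L,
                           m = 3L, tables = escalation_tables(),
                           registry = pair_registry(), seed = 1L,
                           two_stage = TRUE) {
  stopifnot(inherits(cohort, "cddm_cohort"), iterations >= 1, per_group >= 1)
  set.seed(as.integer(seed))
  cache <- .cohort_cache(cohort)
  idx_of <- setNames(seq_along(cache$map_ids), cache$map_ids)
  labels <- heart_state_labels()
  rate_sum <- matrix(0, 14, 4,
                     dimnames = list(labels,
                                     c("TPR", "SPC", "PPV", "ACC")))
  confusion <- matrix(0L, 14, 14, dimnames = list(labels, labels))
  all_traces <- list()
  n_escalated <- 0L; n_total <- 0L
  for (it in seq_len(iterations)) {
    sets <- .draw_sets(cohort, per_group)
    ri <- idx_of[sets$reference]; qi <- idx_of[sets$experimental]
    ref <- list(mag = cache$mag[, ri, drop = FALSE],
                ang = cache$ang[, ri, drop = FALSE],
                features = cache$features[ri, , drop = FALSE],
                labels = cache$labels[ri], map_ids = cache$map_ids[ri])
    traces <- .classify_core(cache$map_ids[qi], cache$labels[qi],
                             cache$mag[, qi, drop = FALSE],
                             cache$ang[, qi, drop = FALSE],
                             cache$features[qi, , drop = FALSE],
                             ref, tables, registry, m)
    truth <- vapply(traces, function(tr) tr$true_label, "")
    pred <- vapply(traces, function(tr)
      if (two_stage) tr$final_label else tr$stage1_label, "")
    counts <- confusion_counts(truth, pred, labels)
    for (i in seq_len(14))
      rate_sum[i, ] <- rate_sum[i, ] +
        one_vs_all_metrics(counts$tp[i], counts$tn[i], counts$fp[i],
                           counts$fn[i], class = counts$label[i])
    for (j in seq_along(truth))
      confusion[truth[j], pred[j]] <- confusion[truth[j], pred[j]] + 1L
    n_escalated <- n_escalated +
      sum(vapply(traces, function(tr) tr$decision$escalate, TRUE))
    n_total <- n_total + length(traces)
    all_traces <- c(all_traces, traces)
  }
  rates <- rate_sum / iterations
  per_class <- data.frame(label = labels,
                          accuracy = rates[, "ACC"],
                          precision = rates[, "PPV"],
                          sensitivity = rates[, "TPR"],
                          specificity = rates[, "SPC"],
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_class = per_class,
                 macro = macro_metric_summary(per_class),
                 confusion = confusion,
                 rank_distribution = rank_distribution(all_traces),
                 escalation_rate = n_escalated / n_total,
                 n_iterations = as.integer(iterations),
                 per_group = as.integer(per_group)),
            class = "cddm_eval_report")
}

#' @export
print.cddm_eval_report <- function(x, ...) {
  cat(sprintf("<evaluation: %d iterations, %d maps/group>\n",
              x$n_iterations, x$per_group))
  print(transform(x$per_class,
                  accuracy = round(accuracy, 3),
                  precision = round(precision, 3),
                  sensitivity = round(sensitivity, 3),
                  specificity = round(specificity, 3)))
  cat("macro:", paste(names(x$macro), round(x$macro, 3), sep = "=",
                      collapse = "  "), "\n")
  cat(sprintf("escalation rate: %.3f | top-3 rank fraction: %.3f\n",
              x$escalation_rate, attr(x$rank_distribution, "top3")))
  invisible(x)
}

#' Metric-by-k parameter sweep for one class pair
#'
#' Repeated balanced holdout restricted to the two classes of the pair:
#' per iteration a disjoint reference/experimental draw is made, and binary
#' k-NN accuracy is measured for every metric and every k in `k_range`. The
#' best cell (ties: smaller k, then cityblock before euclidean before
#' chebyshev) becomes the recommended pair parameters.
#'
#' @param cohort A labelled `cddm_cohort`.
#' @param pair Two heart-state labels.
#' @param k_range Neighbor counts to scan (default 1:15).
#' @param metrics Metrics to scan (default all three).
#' @param iterations,per_group,seed As in [cross_validate()].
#' @return List with `best` (pair, metric, k) and `table` (data.frame
#'   metric x k with mean accuracy; 45 rows at defaults).
#' @export
sweep_pair_params <- function(cohort, pair, k_range = 1:15,
                              metrics = c("cityblock", "euclidean",
                                          "chebyshev"),
                              iterations = 20L, per_group = 20L, seed = 1L) {
  stopifnot(inherits(cohort, "cddm_cohort"), length(pair) == 2)
  pair <- as_heart_state(pair)
  metrics <- .normalize_metric(metrics)
  set.seed(as.integer(seed))
  acc <- matrix(0, length(metrics), length(k_range),
                dimnames = list(metrics, k_range))
  for (it in seq_len(iterations)) {
    ref_ids <- character(0); exp_ids <- character(0)
    for (lb in pair) {
      ids <- cohort$groups[[lb]]
      if (is.null(ids) || length(ids) < 2 * per_group)
        stop("label ", lb, " has too few maps for the sweep", call. = FALSE)
      pick <- sample(ids, 2 * per_group)
      ref_ids <- c(ref_ids, pick[seq_len(per_group)])
      exp_ids <- c(exp_ids, pick[per_group + seq_len(per_group)])
    }
    train <- t(vapply(cohort$maps[ref_ids], extract_features, numeric(32)))
    train_lab <- vapply(cohort$maps[ref_ids], function(m) m$label, "")
    test <- t(vapply(cohort$maps[exp_ids], extract_features, numeric(32)))
    test_lab <- vapply(cohort$maps[exp_ids], function(m) m$label, "")
    for (mt in metrics) {
      # one distance ranking per query serves every k
      ords <- lapply(seq_len(nrow(test)), function(i)
        order(.distances_to(test[i, ], train, mt)))
      for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        pred <- vapply(seq_len(nrow(test)), function(i) {
          top <- train_lab[ords[[i]][seq_len(k)]]
          tab <- table(top)
          if (length(tab) == 2 && tab[1] == tab[2]) top[1]
          else names(tab)[which.max(tab)]
        }, "")
        acc[mt, ki] <- acc[mt, ki] + mean(pred == test_lab)
      }
    }
  }
  acc <- acc / iterations
  tab <- data.frame(metric = rep(rownames(acc), times = ncol(acc)),
                    k = rep(k_range, each = nrow(acc)),
                    accuracy = as.vector(acc), stringsAsFactors = FALSE)
  # tie-break: highest accuracy, then smaller k, then fixed metric order
  mrank <- match(tab$metric, c("cityblock", "euclidean", "chebyshev"))
  best <- tab[order(-tab$accuracy, tab$k, mrank), ][1, ]
  list(best = list(pair = sort(pair), metric = best$metric,
                   k = as.integer(best$k)),
       table = tab)
}
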