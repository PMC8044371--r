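#' Confusion counts
#'
#' @param labels binary truth vector (0/1).
#' @param calls binary predictions (0/1), same length.
#' @return A list of class `mt_confusion` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(labels, calls) {
  if (length(labels) != length(calls)) stop("labels and calls differ in length")
  if (length(labels) < 1L) stop("empty input")
  if (!all(labels %in% c(0, 1)) || !all(calls %in% c(0, 1))) {
    stop("labels and calls must be 0/1")
  }
  structure(list(TP = sum(labels == 1 & calls == 1),
                 TN = sum(labels == 0 & calls == 0),
                 FP = sum(labels == 0 & calls == 1),
                 FN = sum(labels == 1 & calls == 0)),
            class = "mt_confusion")
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/total, and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)). A zero
#' factor in the MCC denominator yields MCC = 0, and a zero SN/SP
#' denominator yields 0, both flagged in `degenerate`.
#'
#' @param counts an `mt_confusion` (or list with TP/TN/FP/FN).
#' @return A list with `SN`, `SP`, `ACC`, `MCC`, `counts`, `degenerate`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total < 1L) stop("no evaluated samples")
  degenerate <- character(0)
  sn <- if (TP + FN > 0) TP / (TP + FN) else {
    degenerate <- c(degenerate, "SN"); 0
  }
  sp <- if (TN + FP > 0) TN / (TN + FP) else {
    degenerate <- c(degenerate, "SP"); 0
  }
  acc <- (TP + TN) / total
  den <- as.numeric(TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  mcc <- if (den > 0) {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  } else {
    degenerate <- c(degenerate, "MCC"); 0
  }
  list(SN = sn, SP = sp, ACC = acc, MCC = mcc, counts = counts,
       degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' AUC is computed as the tie-aware rank (Mann-Whitney) statistic: the
#' probability that a random positive scores above a random negative, ties
#' counting one half. ROC points come from a threshold sweep over the
#' unique scores.
#'
#' @param labels binary truth vector containing both classes.
#' @param scores numeric scores (higher = more positive).
#' @return A list with `auc` and `roc` (data.frame threshold/FPR/TPR).
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes in the labels")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- do.call(rbind, lapply(thr, function(th) {
    calls <- as.integer(scores >= th)
    data.frame(threshold = th,
               FPR = sum(calls == 1 & labels == 0) / n_neg,
               TPR = sum(calls == 1 & labels == 1) / n_pos)
  }))
  list(auc = auc, roc = roc)
}

#' Evaluate a model on a registry split
#'
#' Runs eval-mode predictions for every task and computes the full metrics
#' report (SN/SP/ACC/MCC as proportions, AUC, confusion counts).
#'
#' @param model a trained `mt_model`.
#' @param registry an `mt_registry`; only tasks with a head are evaluated.
#' @param split `"test"` (default) or `"train"`.
#' @param threshold hard-call threshold (default 0.5).
#' @return data.frame with one row per task: task, n, TP/TN/FP/FN, SN, SP,
#'   ACC, MCC, AUC.
#' @export
evaluate_model <- function(model, registry, split = c("test", "train"),
                           threshold = 0.5) {
  split <- match.arg(split)
  tasks <- intersect(names(registry$tasks), names(model$heads))
  if (length(tasks) == 0L) stop("no registry task has a model head")
  out <- do.call(rbind, lapply(tasks, function(tn) {
    d <- registry$tasks[[tn]][[split]]
    pr <- predict_sites(model, d$seq, tn, threshold = threshold)
    cc <- confusion_counts(d$label, pr$call)
    m <- classification_metrics(cc)
    auc <- roc_auc(d$label, pr$p)$auc
    data.frame(task = tn, n = nrow(d), TP = cc$TP, TN = cc$TN, FP = cc$FP,
               FN = cc$FN, SN = m$SN, SP = m$SP, ACC = m$ACC, MCC = m$MCC,
               AUC = auc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Multi-task vs single-task comparison table
#'
#' Renders the ablation comparison: per task, Single and Multi rows with
#' SN/SP/ACC (as percentages), MCC and AUC, the better value flagged, plus
#' delta columns (Multi - Single).
#'
#' @param multi,single data.frames as returned by [evaluate_model()], over
#'   the same task set.
#' @return A list with `table` (long form, one row per task x model) and
#'   `delta` (per-task metric differences).
#' @export
ablation_report <- function(multi, single) {
  if (!setequal(multi$task, single$task)) {
    stop("multi and single reports cover different task sets")
  }
  single <- single[match(multi$task, single$task), , drop = FALSE]
  metrics <- c("SN", "SP", "ACC", "MCC", "AUC")
  rows <- list()
  for (i in seq_len(nrow(multi))) {
    for (model in c("Single", "Multi")) {
      src <- if (model == "Single") single else multi
      other <- if (model == "Single") multi else single
      vals <- unlist(src[i, metrics])
      flags <- vals > unlist(other[i, metrics])
      rows[[length(rows) + 1L]] <- data.frame(
        task = multi$task[i], model = model,
        SN_pct = 100 * vals["SN"], SP_pct = 100 * vals["SP"],
        ACC_pct = 100 * vals["ACC"], MCC = vals["MCC"], AUC = vals["AUC"],
        best = paste(metrics[flags], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  delta <- data.frame(task = multi$task,
                      as.data.frame(as.matrix(multi[, metrics]) -
                                      as.matrix(single[, metrics])))
  list(table = table, delta = delta)
}

#' @export
format.mt_confusion <- function(x, ...) {
  sprintf("TP=%d TN=%d FP=%d FN=%d", x$TP, x$TN, x$FP, x$FN)
}

#' @export
print.mt_confusion <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Render an ablation table for reading
#'
#' Percentages are printed to 2 decimals.
#'
#' @param report result of [ablation_report()].
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_ablation <- function(report) {
  t <- report$table
  lines <- c(sprintf("%-24s %-7s %8s %8s %8s %8s %8s  %s",
                     "task", "model", "SN(%)", "SP(%)", "ACC(%)", "MCC",
                     "AUC", "best"),
             sprintf("%-24s %-7s %8.2f %8.2f %8.2f %8.4f %8.4f  %s",
                     t$task, t$model, t$SN_pct, t$SP_pct, t$ACC_pct, t$MCC,
                     t$AUC, t$best))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write / read a predictions TSV
#'
#' Columns: `id  task  label  score  call`.
#'
#' @param pred data.frame with those columns.
#' @param path TSV path.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred[, c("id", "task", "label", "score", "call")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
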