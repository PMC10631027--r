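#' Individual cancer risk score (RS)
#'
#' The fraction of an individual's total predicted tumor-probability mass
#' carried by confident ctDNA reads:
#' \deqn{RS = \sum_{p_i > t} p_i / \sum_i p_i}
#' where `p_i` is the predicted probability that read `i` is tumor-derived
#' and `t` the ctDNA probability threshold (a read with `p > t` counts as
#' ctDNA). RS lies in `[0, 1]`.
#'
#' @param probs per-read probabilities in `[0, 1]`.
#' @param t ctDNA probability threshold.
#' @return the risk score.
#' @export
risk_score <- function(probs, t) {
  if (length(probs) == 0L) stop("risk score needs at least one read", call. = FALSE)
  stopifnot(all(probs >= 0 & probs <= 1), t >= 0, t <= 1)
  denom <- sum(probs)
  if (denom == 0) {
    warning("all read probabilities are zero; RS set to 0")
    return(0)
  }
  sum(probs[probs > t]) / denom
}

#' Stratified fold assignment
#'
#' Randomly splits individuals into `k` roughly equal folds, stratified by
#' class label so each fold carries both classes; fold sizes within a
#' stratum differ by at most one.
#'
#' @param labels named 0/1 vector (names = sample ids).
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return named integer vector of fold ids (1..k).
#' @export
assign_folds <- function(labels, k = 4, seed = 1) {
  with_seed(seed, {
    fold <- integer(length(labels))
    names(fold) <- names(labels)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Search the ctDNA probability and risk-score thresholds
#'
#' Exhaustive grid search on a tuning set: for every `t` in `t_grid`,
#' per-individual risk scores are computed and candidate RS cutoffs are
#' placed at midpoints between consecutive sorted observed scores (plus 0
#' and 1). The pair maximising the criterion (Youden's J = sensitivity +
#' specificity - 1) is returned, ties broken by smallest `t` then smallest
#' RS cutoff.
#'
#' @param probs_by_sample named list of per-read probability vectors.
#' @param labels named 0/1 vector over the same samples (1 = cancer).
#' @param t_grid candidate ctDNA thresholds (default `seq(0.50, 0.99, 0.01)`).
#' @param criterion only `"youden"` is implemented.
#' @return list with `t`, `rs_threshold`, `criterion_value`.
#' @export
search_thresholds <- function(probs_by_sample, labels,
                              t_grid = seq(0.50, 0.99, by = 0.01),
                              criterion = "youden") {
  stopifnot(criterion == "youden")
  labels <- labels[names(probs_by_sample)]
  if (length(unique(labels)) < 2L)
    stop("threshold search requires both classes in the tuning fold", call. = FALSE)
  best <- list(t = NA_real_, rs_threshold = NA_real_, criterion_value = -Inf)
  for (t in t_grid) {
    rs <- vapply(probs_by_sample, risk_score, 0, t = t)
    cand <- sort(unique(rs))
    cuts <- unique(c(0, (head(cand, -1) + tail(cand, -1)) / 2, cand, 1))
    for (cut in sort(cuts)) {
      call_pos <- rs >= cut
      sens <- mean(call_pos[labels == 1])
      spec <- mean(!call_pos[labels == 0])
      j <- sens + spec - 1
      if (j > best$criterion_value + 1e-12)
        best <- list(t = t, rs_threshold = cut, criterion_value = j)
    }
  }
  best
}

#' Confusion-matrix classification metrics
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1 (harmonic mean of precision
#' and recall) and the Matthews correlation coefficient. Metrics whose
#' denominator is zero are reported as `NA`, never silently 0.
#'
#' @param tp,tn,fp,fn confusion-matrix counts.
#' @return named list of metrics plus the counts.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
       accuracy = (tp + tn) / n, precision = precision, recall = recall,
       sensitivity = recall, specificity = div(tn, tn + fp), f1 = f1,
       mcc = mcc)
}

#' Area under the ROC curve (trapezoidal)
#'
#' Builds the empirical ROC over all score cutoffs and integrates by the
#' trapezoidal rule; equivalent to pairwise concordance with ties counted
#' one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct cutoff
  tpr <- c(0, tp[keep] / pos); fpr <- c(0, fp[keep] / neg)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (trapezoidal)
#'
#' @inheritParams roc_auc
#' @return AUPR, or `NA` when no positives exist.
#' @export
pr_auc <- function(scores, labels) {
  pos <- sum(labels == 1)
  if (pos == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  recall <- tp[keep] / pos
  precision <- tp[keep] / (tp[keep] + fp[keep])
  r <- c(0, recall); p <- c(precision[1], precision)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

# Read-level evaluation bundle used by finetune()'s held-out report.
read_level_metrics <- function(p, labels, cutoff = 0.5) {
  pred <- as.integer(p >= cutoff)
  cm <- classification_metrics(sum(pred == 1 & labels == 1),
                               sum(pred == 0 & labels == 0),
                               sum(pred == 1 & labels == 0),
                               sum(pred == 0 & labels == 1))
  c(cm, list(auc = roc_auc(p, labels), aupr = pr_auc(p, labels)))
}

#' Four-fold individual-level evaluation with per-round threshold search
#'
#' Individuals are split into four folds. In each of four rounds, one fold
#' serves as the tuning set on which [search_thresholds] picks the ctDNA
#' probability threshold `t*` and the RS cutoff; the other three folds are
#' then scored with those frozen thresholds and classified. Per-round
#' metrics are summarised as mean with a normal-approximation 95% CI
#' (`mean +/- 1.96 SE`) across rounds; rounds lacking a class report
#' class-dependent metrics as `NA`.
#'
#' @param probs_by_sample named list of per-read probability vectors, one
#'   entry per individual.
#' @param labels named 0/1 vector (1 = cancer-positive).
#' @param folds number of folds (default 4).
#' @param seed fold-assignment seed.
#' @param t_grid candidate ctDNA thresholds.
#' @return list with `rounds` (per-round metrics data.table), `summary`
#'   (mean / CI per metric), `calls` (per-individual RS and calls from the
#'   round in which the individual was validated) and `fold_assignment`.
#' @export
crossfold_evaluate <- function(probs_by_sample, labels, folds = 4, seed = 1,
                               t_grid = seq(0.50, 0.99, by = 0.01)) {
  labels <- labels[names(probs_by_sample)]
  fold <- assign_folds(labels, k = folds, seed = seed)
  round_rows <- list(); call_rows <- list()
  for (r in seq_len(folds)) {
    tune_ids <- names(fold)[fold == r]
    val_ids <- names(fold)[fold != r]
    th <- search_thresholds(probs_by_sample[tune_ids], labels[tune_ids],
                            t_grid = t_grid)
    rs <- vapply(probs_by_sample[val_ids], risk_score, 0, t = th$t)
    call_pos <- rs >= th$rs_threshold
    y <- labels[val_ids]
    cm <- classification_metrics(sum(call_pos & y == 1), sum(!call_pos & y == 0),
                                 sum(call_pos & y == 0), sum(!call_pos & y == 1))
    round_rows[[r]] <- data.table(round = r, t = th$t,
                                  rs_threshold = th$rs_threshold,
                                  accuracy = cm$accuracy,
                                  sensitivity = cm$sensitivity,
                                  specificity = cm$specificity,
                                  precision = cm$precision, f1 = cm$f1,
                                  mcc = cm$mcc,
                                  auc = roc_auc(rs, y), aupr = pr_auc(rs, y))
    call_rows[[r]] <- data.table(sample_id = val_ids, round = r, rs = rs,
                                 t_used = th$t,
                                 rs_threshold_used = th$rs_threshold,
                                 call = ifelse(call_pos, "positive", "negative"),
                                 label = y)
  }
  rounds <- rbindlist(round_rows)
  met_cols <- setdiff(names(rounds), "round")
  vals <- as.data.frame(rounds)[met_cols]
  m <- vapply(vals, mean, 0, na.rm = TRUE)
  se <- vapply(vals, function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))), 0)
  summary <- data.table(metric = met_cols, mean = m,
                        ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  list(rounds = rounds, summary = summary, calls = rbindlist(call_rows),
       fold_assignment = fold)
}
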