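# Threshold-sweep classification metrics against a labeled target network:
# ROC/AUC (rank-based, ties counted one half) and precision-recall/AUPR
# (average precision with tied scores grouped by level).

#' Build the labeled evaluation universe for a split
#'
#' Positives are the hidden positive edges (`mode = "hidden"`) or every
#' target-present edge missing from the input (`mode = "all"`); negatives are
#' the target's labeled absent edges. Pairs carrying no target label are
#' excluded — the universe size is returned so users can see how much of the
#' network is actually evaluated. Input-present edges never enter the
#' universe.
#'
#' @param split a `split_result` from [mask_positives()] or
#'   [generate_planted()].
#' @param scored data.frame with columns `left`, `right`, `score` covering
#'   the universe (e.g. from [score_all_unobserved()]).
#' @param mode `"hidden"` or `"all"`.
#' @return data.frame with columns `left`, `right`, `label` (1/0), `score`.
#' @export
evaluation_universe <- function(split, scored, mode = c("hidden", "all")) {
  mode <- match.arg(mode)
  pos <- if (mode == "hidden") {
    split$hidden
  } else {
    tgt <- split$target$present
    tgt[!(pair_key(tgt$left, tgt$right) %in% present_keys(split$input)), , drop = FALSE]
  }
  neg <- split$target$absent
  if (!nrow(pos) && !nrow(neg)) stop("empty universe: no hidden positives and no labeled absents")
  uni <- rbind(cbind(as_edge_df(pos), label = 1L),
               cbind(as_edge_df(neg), label = 0L))
  sk <- pair_key(scored$left, scored$right)
  idx <- match(pair_key(uni$left, uni$right), sk)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("missing score for universe pair (%s, %s)",
                 uni$left[miss], uni$right[miss]))
  }
  uni$score <- scored$score[idx]
  rownames(uni) <- NULL
  uni
}

# per-score-level positive/negative counts, best score first
level_sweep <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  list(tp_lev = as.vector(rowsum(as.numeric(l == 1), grp)),
       fp_lev = as.vector(rowsum(as.numeric(l == 0), grp)))
}

#' Rank-based ROC AUC with full threshold sweep
#'
#' The AUC equals the Mann-Whitney statistic with tied comparisons counted
#' one half; `roc_points` traces the (FPR, TPR) curve over score levels
#' (tied scores grouped, so tie blocks appear as diagonal segments whose
#' trapezoidal area equals the rank statistic).
#'
#' @param labels 0/1 vector (at least one of each class).
#' @param scores numeric score vector.
#' @return list with `auc` and `roc_points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("degenerate universe: need >= 1 positive and >= 1 negative")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  sw <- level_sweep(labels, scores)
  pts <- data.frame(fpr = c(0, cumsum(sw$fp_lev) / n_neg),
                    tpr = c(0, cumsum(sw$tp_lev) / n_pos))
  list(auc = auc, roc_points = pts)
}

#' Average-precision AUPR with tied scores grouped
#'
#' Sweeps score levels from best to worst; each level contributes
#' `(delta recall) * precision-at-level`, which reduces to precision summed
#' at each positive's rank when scores are distinct, equals prevalence under
#' a constant score, and equals 1 for a perfect ranking.
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores numeric score vector.
#' @return list with `aupr` and `pr_points` (data.frame `recall`,
#'   `precision`).
#' @export
pr_aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positives in evaluation universe")
  sw <- level_sweep(labels, scores)
  tp <- cumsum(sw$tp_lev)
  tot <- cumsum(sw$tp_lev + sw$fp_lev)
  recall <- tp / n_pos
  precision <- tp / tot
  aupr <- sum(diff(c(0, recall)) * precision)
  list(aupr = aupr,
       pr_points = data.frame(recall = recall, precision = precision))
}

#' Evaluate scored pairs against a split's target labels
#'
#' @inheritParams evaluation_universe
#' @return object of class `eval_result`: list with `auc`, `aupr`,
#'   `roc_points`, `pr_points`, `n_pos`, `n_neg`, `universe_size`.
#' @export
evaluate_scores <- function(split, scored, mode = c("hidden", "all")) {
  uni <- evaluation_universe(split, scored, mode)
  roc <- roc_auc(uni$label, uni$score)
  pr <- pr_aupr(uni$label, uni$score)
  structure(list(auc = roc$auc, aupr = pr$aupr,
                 roc_points = roc$roc_points, pr_points = pr$pr_points,
                 n_pos = sum(uni$label == 1), n_neg = sum(uni$label == 0),
                 universe_size = nrow(uni)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: AUC %.4f, AUPR %.4f (%d pos / %d neg, universe %d)\n",
              x$auc, x$aupr, x$n_pos, x$n_neg, x$universe_size))
  invisible(x)
}
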