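# End-to-end prediction runs and the sample-rate benchmark grid.

#' Run one link-prediction method on an input network
#'
#' `"mf-nss"` is the full pipeline: mark structural-hole pairs, select
#' negatives from the unmarked unobserved pairs, train biased MF, score all
#' unobserved pairs. `"mf"` is the raw comparator (every unobserved pair is a
#' value-0 sample). The remaining methods are the unsupervised baselines.
#'
#' @param net the input [bipartite_network()] (present links only).
#' @param method one of `"mf-nss"`, `"mf"`, `"cn"`, `"jc"`, `"aa"`, `"pa"`,
#'   `"rwr"`.
#' @param nss an [nss_params()] (used by `"mf-nss"`).
#' @param mf an [mf_params()] (used by `"mf-nss"` and `"mf"`).
#' @param rwr an [rwr_params()] (used by `"rwr"`).
#' @return list with `scores` (data.frame `left`, `right`, `score` over all
#'   unobserved pairs) and `info` (counts: marked pairs, pool size, negatives
#'   drawn).
#' @export
run_prediction <- function(net, method = c("mf-nss", "mf", "cn", "jc", "aa", "pa", "rwr"),
                           nss = nss_params(), mf = mf_params(),
                           rwr = rwr_params()) {
  method <- match.arg(method)
  info <- list(method = method)
  if (method == "mf-nss") {
    marked <- collect_marked_pairs(to_context(net), nss)
    negs <- select_negatives(net, marked, nss)
    info$n_marked <- nrow(marked)
    info$pool_size <- nrow(unobserved_pairs(net, marked))
    info$n_negatives <- nrow(negs)
    model <- train_mf(training_set(net, negs), mf)
    scores <- score_all_unobserved(model, net)
  } else if (method == "mf") {
    ts <- raw_training_set(net)
    info$n_negatives <- sum(ts$a == 0)
    model <- train_mf(ts, mf)
    scores <- score_all_unobserved(model, net)
  } else {
    scores <- baseline_scores(net, method, rwr = rwr)
  }
  list(scores = scores, info = info)
}

#' Sample-rate benchmark on planted networks
#'
#' For every seed, generates a planted network, then runs the MF pipeline
#' under each negative-selection mode and sample rate, and evaluates AUC and
#' AUPR on the target labels. Selection modes: `"fca"` draws negatives from
#' the unmarked pool (structural-hole marking), `"random"` draws from all
#' unobserved pairs, `"none"` is raw MF (rate ignored). Marked pairs are
#' computed once per seed and reused across rates.
#'
#' @param cfg a [planted_config()]; its seed field is replaced by each entry
#'   of `seeds`.
#' @param rates numeric vector of sample rates in `[0, 1]`.
#' @param seeds integer vector of simulation seeds.
#' @param selections subset of `c("fca", "random", "none")`.
#' @param nss an [nss_params()] (alpha/rho for the marking stage).
#' @param mf an [mf_params()].
#' @param eval_mode `"hidden"` or `"all"` (see [evaluation_universe()]).
#' @return data.frame with one row per (selection, rate, seed):
#'   `selection`, `rate`, `seed`, `auc`, `aupr`, `n_marked`, `n_negatives`.
#' @export
benchmark_planted <- function(cfg, rates = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              seeds = 1:5,
                              selections = c("fca", "random", "none"),
                              nss = nss_params(), mf = mf_params(),
                              eval_mode = "hidden") {
  selections <- match.arg(selections, c("fca", "random", "none"), several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    cfg_s <- cfg; cfg_s$seed <- as.integer(seed)
    sim <- generate_planted(cfg_s)
    net <- sim$input
    marked <- if ("fca" %in% selections) {
      collect_marked_pairs(to_context(net), nss)
    } else edge_df()
    raw_eval <- NULL
    for (sel in selections) {
      for (rate in (if (sel == "none") rates[1] else rates)) {
        nss_run <- nss
        nss_run$sample_rate <- rate
        nss_run$seed <- as.integer(seed * 1000L + round(rate * 100))
        mf_run <- mf
        mf_run$seed <- as.integer(seed)
        if (sel == "none") {
          model <- train_mf(raw_training_set(net), mf_run)
          negs <- NULL
        } else {
          negs <- if (sel == "fca") select_negatives(net, marked, nss_run)
                  else select_negatives_random(net, nss_run)
          model <- train_mf(training_set(net, negs), mf_run)
        }
        ev <- evaluate_scores(sim$truth, score_all_unobserved(model, net),
                              mode = eval_mode)
        res <- data.frame(selection = sel, rate = rate, seed = seed,
                          auc = ev$auc, aupr = ev$aupr,
                          n_marked = if (sel == "fca") nrow(marked) else 0L,
                          n_negatives = if (is.null(negs))
                            n_left(net) * n_right(net) - nrow(net$present)
                          else nrow(negs),
                          stringsAsFactors = FALSE)
        if (sel == "none") raw_eval <- res
        rows[[length(rows) + 1L]] <- res
      }
    }
    # raw MF is rate-independent: replicate its row across the rate grid
    if ("none" %in% selections && length(rates) > 1 && !is.null(raw_eval)) {
      for (rate in rates[-1]) {
        r2 <- raw_eval; r2$rate <- rate
        rows[[length(rows) + 1L]] <- r2
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a benchmark table into per-cell means and standard deviations
#' @param bench output of [benchmark_planted()].
#' @return data.frame with one row per (selection, rate).
#' @export
summarize_benchmark <- function(bench) {
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  key <- interaction(bench$selection, bench$rate, drop = TRUE)
  out <- do.call(rbind, lapply(split(bench, key), function(d) {
    data.frame(selection = d$selection[1], rate = d$rate[1], n = nrow(d),
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               aupr_mean = mean(d$aupr), aupr_sd = stats::sd(d$aupr),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$selection, out$rate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
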