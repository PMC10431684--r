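# Negative sample selection: find non-trivially overlapping comparable
# maximal bi-cliques, mark the node pairs in their structural holes as "do
# not use as negatives", and draw negative training samples uniformly from
# the unmarked unobserved pairs.

#' Parameters for negative sample selection
#'
#' @param alpha integer component-size threshold: both sides of both
#'   bi-cliques in an overlapping pair must have at least `alpha` nodes
#'   (comparisons use `>=`, following the pseudocode convention).
#' @param rho overlap-rate threshold in `[0, 1]`: both overlap rates of the
#'   pair must be at least `rho`.
#' @param sample_rate fraction in `[0, 1]` of the unmarked unobserved pairs
#'   to draw as negatives.
#' @param seed integer seed for the uniform draw.
#' @export
nss_params <- function(alpha = 2L, rho = 0.3, sample_rate = 0.5, seed = 1L) {
  alpha <- as.integer(alpha)
  stopifnot(alpha >= 1L, rho >= 0, rho <= 1)
  if (sample_rate < 0 || sample_rate > 1) stop("sample_rate must be in [0, 1]")
  structure(list(alpha = alpha, rho = rho, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "nss_params")
}

#' Overlap rates of two comparable concepts
#'
#' For comparable concepts (one extent containing the other),
#' `sigma1 = min(|A1|,|A2|) / max(|A1|,|A2|)` on extents and `sigma2`
#' likewise on intents. Symmetric in its arguments. A zero-sized component on
#' the max side yields a rate of 0 (the pair is maximally dissimilar there).
#'
#' @param c1,c2 [concept()]s, comparable under the lattice order.
#' @return named numeric vector `c(sigma1, sigma2)`.
#' @export
overlap_rates <- function(c1, c2) {
  check_comparable(c1, c2)
  rate <- function(a, b) {
    mx <- max(a, b)
    if (mx == 0) 0 else min(a, b) / mx
  }
  c(sigma1 = rate(length(c1$extent), length(c2$extent)),
    sigma2 = rate(length(c1$intent), length(c2$intent)))
}

check_comparable <- function(c1, c2) {
  e12 <- all(c1$extent %in% c2$extent)
  e21 <- all(c2$extent %in% c1$extent)
  if (!e12 && !e21) stop("concepts are not comparable (neither extent contains the other)")
  invisible(if (e21) list(lower = c1, upper = c2) else list(lower = c2, upper = c1))
}

#' Record of an overlapping comparable concept pair
#'
#' `lower` is the chain-wise higher-extent concept (`lower$extent` contains
#' `upper$extent`). Carries the component sizes, both overlap rates, and the
#' structural hole.
#'
#' @param lower,upper [concept()]s with `lower` below `upper` in intent order.
#' @return object of class `overlap_record`.
#' @export
overlap_record <- function(lower, upper) {
  if (!all(upper$extent %in% lower$extent) || !all(lower$intent %in% upper$intent)) {
    stop("lower must precede upper (extent contains, intent contained)")
  }
  sig <- overlap_rates(lower, upper)
  structure(list(
    lower = lower, upper = upper,
    s1_lower = length(lower$extent), s1_upper = length(upper$extent),
    s2_lower = length(lower$intent), s2_upper = length(upper$intent),
    sigma1 = unname(sig["sigma1"]), sigma2 = unname(sig["sigma2"]),
    hole = structure_hole(lower, upper)
  ), class = "overlap_record")
}

#' Non-triviality test for an overlapping pair
#'
#' TRUE iff all four component sizes are `>= alpha` and both overlap rates
#' are `>= rho`.
#'
#' @param rec an [overlap_record()].
#' @param params an [nss_params()].
#' @export
is_nontrivial <- function(rec, params) {
  min(rec$s1_lower, rec$s1_upper, rec$s2_lower, rec$s2_upper) >= params$alpha &&
    min(rec$sigma1, rec$sigma2) >= params$rho
}

#' Structural hole of a comparable concept pair
#'
#' The Cartesian product of the exclusive extent and exclusive intent:
#' `(lower$extent - upper$extent) x (upper$intent - lower$intent)`. These are
#' the node pairs the structural-hole argument expects to become links, hence
#' the pairs that must not be used as negative training samples. For a chain
#' c1 <= c2 <= c3 the hole of the extremes contains the holes of all inner
#' pairs (it is a strict superset in general: pairs combining a c1-exclusive
#' object with a c3-beyond-c2 attribute belong to no inner hole), which is
#' why the marking stage records each concept against its farthest
#' qualifying ancestor.
#'
#' @param lower,upper [concept()]s with `lower` preceding `upper`.
#' @return data.frame with integer columns `object`, `attribute`.
#' @export
structure_hole <- function(lower, upper) {
  if (!all(upper$extent %in% lower$extent) || !all(lower$intent %in% upper$intent)) {
    stop("concepts not ordered lower before upper")
  }
  objs <- setdiff(lower$extent, upper$extent)
  attrs <- setdiff(upper$intent, lower$intent)
  expand.grid(object = as.integer(objs), attribute = as.integer(attrs),
              KEEP.OUT.ATTRS = FALSE)
}

# One chain-clustering DFS pass over a context: for every concept with both
# components >= alpha, record the farthest DFS ancestor whose extent overlap
# rate with it is still >= rho. Because sigma1 is multiplicative along
# chains, an ancestor that has fallen below rho can never re-qualify deeper,
# so the farthest qualifying ancestor is found by scanning the ancestor path
# from the root end.
chain_pass <- function(ctx, params) {
  path <- vector("list", length(ctx$attributes) + 2L)
  recorded <- list()
  visitor <- function(cpt, depth) {
    path[[depth]] <<- cpt
    if (depth > 1L &&
        length(cpt$extent) >= params$alpha &&
        length(cpt$intent) >= params$alpha) {
      sz <- length(cpt$extent)
      for (d in seq_len(depth - 1L)) {
        anc <- path[[d]]
        if (sz >= params$rho * length(anc$extent)) {
          recorded[[length(recorded) + 1L]] <<- list(lower = anc, upper = cpt)
          break
        }
      }
    }
  }
  enumerate_concepts(ctx, min_extent = params$alpha, visitor = visitor)
  recorded
}

#' Mark node pairs inside structural holes of non-trivial overlapping
#' bi-cliques
#'
#' Runs the chain-clustering DFS on the context and on its transpose (the
#' second pass catches pairs whose chain is only visible from the attribute
#' side), re-checks the full non-triviality condition on every recorded
#' (concept, farthest-qualifying-ancestor) pair, collects their structural
#' holes, normalizes orientation back to (left node, right node), and removes
#' any pair that is a present link of the context. The result is the set of
#' unobserved pairs considered unsafe as negative training samples.
#'
#' @param ctx a [formal_context()] (objects = left nodes).
#' @param params an [nss_params()].
#' @return data.frame with character columns `left`, `right`.
#' @export
collect_marked_pairs <- function(ctx, params) {
  emit <- function(recs, transposed) {
    out <- list()
    for (r in recs) {
      rec <- overlap_record(r$lower, r$upper)
      if (!is_nontrivial(rec, params)) next
      h <- rec$hole
      if (!nrow(h)) next
      out[[length(out) + 1L]] <- if (transposed) {
        data.frame(left = ctx$objects[h$attribute], right = ctx$attributes[h$object],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(left = ctx$objects[h$object], right = ctx$attributes[h$attribute],
                   stringsAsFactors = FALSE)
      }
    }
    out
  }
  pairs <- c(emit(chain_pass(ctx, params), FALSE),
             emit(chain_pass(context_transpose(ctx), params), TRUE))
  if (!length(pairs)) return(edge_df())
  marked <- do.call(rbind, pairs)
  marked <- marked[!duplicated(pair_key(marked$left, marked$right)), , drop = FALSE]
  # a hole of a non-adjacent lattice pair can contain an incidence pair;
  # present links are never marked
  idx <- which(ctx$mat, arr.ind = TRUE)
  inc_keys <- pair_key(ctx$objects[idx[, 1]], ctx$attributes[idx[, 2]])
  marked <- marked[!(pair_key(marked$left, marked$right) %in% inc_keys), , drop = FALSE]
  rownames(marked) <- NULL
  marked
}

#' Select negative training samples from the unmarked unobserved pairs
#'
#' The candidate pool is `(V1 x V2) - present_edges - marked`; exactly
#' `floor(sample_rate * |pool|)` pairs are drawn uniformly without
#' replacement, deterministically per seed. The result is disjoint from
#' present edges and marked pairs by construction.
#'
#' @param net a [bipartite_network()].
#' @param marked data.frame of marked pairs (`left`, `right`), e.g. from
#'   [collect_marked_pairs()]; present edges in it are ignored.
#' @param params an [nss_params()].
#' @return data.frame with columns `left`, `right`.
#' @export
select_negatives <- function(net, marked, params) {
  if (params$sample_rate < 0 || params$sample_rate > 1) {
    stop("sample_rate must be in [0, 1]")
  }
  pool <- unobserved_pairs(net, exclude = marked)
  k <- floor(params$sample_rate * nrow(pool))
  idx <- with_seed(params$seed, sample.int(nrow(pool), k))
  out <- pool[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname select_negatives
#' @description `select_negatives_random()` is the fully random comparator:
#'   the same draw with no marked pairs at all.
#' @export
select_negatives_random <- function(net, params) {
  select_negatives(net, edge_df(), params)
}
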