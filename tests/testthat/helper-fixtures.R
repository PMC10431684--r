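# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive (brute force / O(n^2)) and never reuse the code paths
# they certify.

# incidence Y = {(g1,m1),(g1,m2),(g2,m2),(g3,m3)} (1-based)
toy_context <- function() {
  formal_context(paste0("g", 1:3), paste0("m", 1:3),
                 rbind(c(TRUE, TRUE, FALSE),
                       c(FALSE, TRUE, FALSE),
                       c(FALSE, FALSE, TRUE)))
}

identity_context <- function(n = 3) {
  formal_context(paste0("g", 1:n), paste0("m", 1:n), diag(n) == 1)
}

random_context <- function(n, m, density) {
  formal_context(paste0("g", 1:n), paste0("m", 1:m),
                 matrix(stats::runif(n * m) < density, n, m))
}

# two fully-linked 4x4 blocks sharing a 2x2 core
two_block_network <- function() {
  blk <- rbind(
    expand.grid(left = paste0("g", 0:3), right = paste0("m", 0:3),
                stringsAsFactors = FALSE),
    expand.grid(left = paste0("g", 2:5), right = paste0("m", 2:5),
                stringsAsFactors = FALSE))
  bipartite_network(paste0("g", 0:5), paste0("m", 0:5), blk)
}

net_from_matrix <- function(mat, left = paste0("a", seq_len(nrow(mat))),
                            right = paste0("b", seq_len(ncol(mat)))) {
  idx <- which(mat != 0, arr.ind = TRUE)
  bipartite_network(left, right,
                    data.frame(left = left[idx[, 1]], right = right[idx[, 2]],
                               stringsAsFactors = FALSE))
}

pair_strings <- function(df) sort(paste(df$left, df$right))

concept_strings <- function(concepts) {
  sort(vapply(concepts, function(x)
    paste(paste(x$extent, collapse = ","), paste(x$intent, collapse = ","),
          sep = "|"), ""))
}

# zero-initialized bias-only (k = 0) factor model
new_factor_model_for_test <- function(n, m) {
  structure(list(P = matrix(0, n, 0), Q = matrix(0, 0, m),
                 b_row = numeric(n), b_col = numeric(m), mu = 0,
                 params = NULL),
            class = "factor_model")
}

# O(pos x neg) Mann-Whitney AUC with tied comparisons counted one half
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# average precision by explicit ranking (assumes distinct scores)
ap_oracle <- function(labels, scores) {
  stopifnot(!anyDuplicated(scores))
  l <- labels[order(scores, decreasing = TRUE)]
  ranks <- which(l == 1)
  mean(vapply(ranks, function(r) sum(l[seq_len(r)]) / r, 0))
}

# union of structural holes over ALL comparable non-trivial concept pairs,
# computed from the brute-force lattice, minus incidence pairs
marked_oracle <- function(ctx, params) {
  cps <- enumerate_concepts_bruteforce(ctx)
  out <- list()
  for (a in cps) for (b in cps) {
    if (identical(a, b)) next
    if (all(b$extent %in% a$extent) && all(a$intent %in% b$intent)) {
      rec <- overlap_record(a, b)
      if (is_nontrivial(rec, params) && nrow(rec$hole)) {
        out[[length(out) + 1L]] <- data.frame(
          left = ctx$objects[rec$hole$object],
          right = ctx$attributes[rec$hole$attribute],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(left = character(), right = character()))
  res <- unique(do.call(rbind, out))
  idx <- which(ctx$mat, arr.ind = TRUE)
  inc <- paste(ctx$objects[idx[, 1]], ctx$attributes[idx[, 2]])
  res[!(paste(res$left, res$right) %in% inc), , drop = FALSE]
}

# all root-to-leaf chains of the DFS tree as lists of concepts
dfs_chains <- function(ctx, min_extent = 0L) {
  path <- list(); chains <- list(); maxdepth <- 0L
  enumerate_concepts(ctx, min_extent, function(cpt, depth) {
    if (depth <= maxdepth) chains[[length(chains) + 1L]] <<- path[seq_len(maxdepth)]
    path[[depth]] <<- cpt
    maxdepth <<- depth
  })
  if (maxdepth > 0L) chains[[length(chains) + 1L]] <- path[seq_len(maxdepth)]
  chains
}
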