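# Seeded generator of planted-structure bipartite networks: a chain of full
# bi-cliques in which consecutive blocks share a fixed fraction of nodes on
# each side, so the network contains genuine, analytically known structural
# holes. Emulates the regimes the method targets: a fraction of positives is
# hidden from the input, and the input carries no absent ground truth.

#' Configuration for the planted-bi-clique generator
#'
#' Defaults describe the package's standard benchmark world: a 60 x 80
#' network with 6 planted blocks of 10-12 nodes per side, 40% node sharing
#' between consecutive blocks, 2% background noise, 20% of positives hidden,
#' and 30% of non-edges labeled absent in the target.
#'
#' @param n_left,n_right node counts of the two sides.
#' @param n_blocks number of planted bi-cliques.
#' @param block_size_range integer `(min, max)`; each block's size per side
#'   is drawn uniformly from this range.
#' @param overlap_fraction fraction of a block's nodes (per side) shared with
#'   the previous block in the chain; 0 plants disjoint blocks.
#' @param noise_rate probability of a background edge outside the blocks.
#' @param hole_link_rate fraction of the analytic structural-hole pairs that
#'   are genuine missing links: present in the target, never observable in
#'   the input. This is the structural-hole premise made literal — pairs in
#'   the hole of two overlapping clusters are the ones likely to be links —
#'   and emulates a curated/inferred split: the input holds the observed
#'   cluster structure, the target additionally holds the links that
#'   structure implies.
#' @param hide_fraction fraction of the observed (block + noise) links masked
#'   from the input, round half-up (see [mask_positives()]).
#' @param absent_label_rate fraction of target non-edges labeled as
#'   ground-truth absent.
#' @param clean_holes if TRUE, background noise is never inserted inside the
#'   analytically known planted holes, so hole-recovery tests are exact.
#' @param seed integer seed; generation is fully deterministic.
#' @export
planted_config <- function(n_left = 60L, n_right = 80L, n_blocks = 6L,
                           block_size_range = c(10L, 12L),
                           overlap_fraction = 0.4, noise_rate = 0.02,
                           hole_link_rate = 0.5,
                           hide_fraction = 0.2, absent_label_rate = 0.3,
                           clean_holes = FALSE, seed = 1L) {
  stopifnot(n_left >= 1, n_right >= 1, n_blocks >= 1,
            length(block_size_range) == 2, block_size_range[1] >= 1,
            block_size_range[1] <= block_size_range[2],
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1,
            hole_link_rate >= 0, hole_link_rate <= 1,
            hide_fraction >= 0, hide_fraction < 1,
            absent_label_rate >= 0, absent_label_rate <= 1)
  structure(list(n_left = as.integer(n_left), n_right = as.integer(n_right),
                 n_blocks = as.integer(n_blocks),
                 block_size_range = as.integer(block_size_range),
                 overlap_fraction = overlap_fraction, noise_rate = noise_rate,
                 hole_link_rate = hole_link_rate,
                 hide_fraction = hide_fraction,
                 absent_label_rate = absent_label_rate,
                 clean_holes = isTRUE(clean_holes), seed = as.integer(seed)),
            class = "planted_config")
}

# lay one side out as an overlapping chain; returns list of index vectors
chain_layout <- function(sizes, overlap_fraction, n_nodes, side) {
  starts <- integer(length(sizes))
  starts[1] <- 1L
  if (length(sizes) > 1) {
    for (t in 2:length(sizes)) {
      shared <- floor(overlap_fraction * min(sizes[t - 1], sizes[t]))
      starts[t] <- starts[t - 1] + sizes[t - 1] - shared
    }
  }
  if (starts[length(sizes)] + sizes[length(sizes)] - 1L > n_nodes) {
    stop("infeasible block sizes: planted chain needs ",
         starts[length(sizes)] + sizes[length(sizes)] - 1L,
         " nodes on the ", side, " side, have ", n_nodes)
  }
  lapply(seq_along(sizes), function(t) seq.int(starts[t], length.out = sizes[t]))
}

#' Generate a planted-structure bipartite network
#'
#' Plants `n_blocks` full bi-cliques with consecutive-block node sharing and
#' adds background noise edges; these form the observable links. A
#' `hole_link_rate` fraction of the analytic structural-hole pairs between
#' consecutive blocks become genuine missing links (target-present, never in
#' the input), and a further `hide_fraction` of the observable links is
#' masked from the input. A fraction of the target's non-edges is labeled
#' absent; the input carries no absent labels at all. Fully deterministic
#' per seed.
#'
#' @param cfg a [planted_config()].
#' @return object of class `planted_sim`: list with `target`, `input`
#'   ([bipartite_network()]s), `truth` (a `split_result`; its `hidden` set is
#'   the masked links plus the hole links), `blocks` (per block, the planted
#'   left/right node names) and `config`.
#' @export
generate_planted <- function(cfg) {
  left_names <- sprintf("u%03d", seq_len(cfg$n_left))
  right_names <- sprintf("v%03d", seq_len(cfg$n_right))
  sim <- with_seed(cfg$seed, {
    sizes_avail <- seq(cfg$block_size_range[1], cfg$block_size_range[2])
    # sample() treats a length-1 vector as 1:n; index explicitly
    sz <- function(n) sizes_avail[sample.int(length(sizes_avail), n, replace = TRUE)]
    lsizes <- sz(cfg$n_blocks); rsizes <- sz(cfg$n_blocks)
    lidx <- chain_layout(lsizes, cfg$overlap_fraction, cfg$n_left, "left")
    ridx <- chain_layout(rsizes, cfg$overlap_fraction, cfg$n_right, "right")
    mat <- matrix(FALSE, cfg$n_left, cfg$n_right)   # observable links
    for (t in seq_len(cfg$n_blocks)) mat[lidx[[t]], ridx[[t]]] <- TRUE
    blocks <- lapply(seq_len(cfg$n_blocks), function(t)
      list(left = left_names[lidx[[t]]], right = right_names[ridx[[t]]]))
    holes <- analytic_holes(lidx, ridx)
    if (cfg$noise_rate > 0) {
      cand <- !mat
      if (cfg$clean_holes && nrow(holes)) cand[as.matrix(holes)] <- FALSE
      cells <- which(cand)
      noisy <- cells[stats::runif(length(cells)) < cfg$noise_rate]
      mat[noisy] <- TRUE
    }
    # structural-hole pairs that become true missing links (target only)
    hole_cells <- setdiff((holes$col - 1L) * nrow(mat) + holes$row, which(mat))
    n_hl <- floor(cfg$hole_link_rate * length(hole_cells))
    hl_cells <- sort(sample(hole_cells, n_hl))
    # uniform masking of observable links
    obs_cells <- which(mat)
    k <- round_half_up(cfg$hide_fraction * length(obs_cells))
    masked <- sort(sample(obs_cells, k))
    tgt_mat <- mat
    tgt_mat[hl_cells] <- TRUE
    non_edges <- which(!tgt_mat)
    n_abs <- floor(cfg$absent_label_rate * length(non_edges))
    abs_cells <- sort(sample(non_edges, n_abs))
    list(mat = mat, blocks = blocks, masked = masked, hl_cells = hl_cells,
         abs_cells = abs_cells)
  })
  cell_edges <- function(cells) {
    ai <- arrayInd(cells, c(cfg$n_left, cfg$n_right))
    edge_df(left_names[ai[, 1]], right_names[ai[, 2]])
  }
  obs <- which(sim$mat)
  target <- bipartite_network(left_names, right_names,
                              cell_edges(sort(c(obs, sim$hl_cells))),
                              cell_edges(sim$abs_cells))
  input <- bipartite_network(left_names, right_names,
                             cell_edges(setdiff(obs, sim$masked)))
  truth <- structure(list(input = input, target = target,
                          hidden = cell_edges(sort(c(sim$masked, sim$hl_cells)))),
                     class = "split_result")
  structure(list(target = target, input = input, truth = truth,
                 blocks = sim$blocks, config = cfg),
            class = "planted_sim")
}

#' @export
print.planted_sim <- function(x, ...) {
  cat(sprintf("planted_sim: %d x %d, %d blocks, %d target present (%d hidden)\n",
              length(x$target$left), length(x$target$right),
              length(x$blocks), nrow(x$target$present), nrow(x$truth$hidden)))
  invisible(x)
}

# hole index pairs between consecutive blocks (index-space helper)
analytic_holes <- function(lidx, ridx) {
  out <- list()
  for (t in seq_len(length(lidx) - 1L)) {
    if (!length(intersect(lidx[[t]], lidx[[t + 1]])) ||
        !length(intersect(ridx[[t]], ridx[[t + 1]]))) next
    a <- expand.grid(row = setdiff(lidx[[t]], lidx[[t + 1]]),
                     col = setdiff(ridx[[t + 1]], ridx[[t]]))
    b <- expand.grid(row = setdiff(lidx[[t + 1]], lidx[[t]]),
                     col = setdiff(ridx[[t]], ridx[[t + 1]]))
    out[[length(out) + 1L]] <- rbind(a, b)
  }
  if (!length(out)) return(data.frame(row = integer(), col = integer()))
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$row, res$col)), , drop = FALSE]
}

#' Analytically known structural-hole pairs of a clean planted network
#'
#' For each pair of consecutive overlapping blocks, the hole is the union of
#' (exclusive left of one block) x (exclusive right of the other), in both
#' orientations — exactly the pairs the marking stage must recover at
#' thresholds matching the construction. Only defined for noise-free
#' simulations: with background noise the holes are no longer analytic.
#'
#' @param sim a `planted_sim` generated with `noise_rate = 0`.
#' @return data.frame with character columns `left`, `right`.
#' @export
known_hole_pairs <- function(sim) {
  if (sim$config$noise_rate > 0) {
    stop("known_hole_pairs requires noise_rate = 0 (holes are not analytic under noise)")
  }
  out <- list()
  blocks <- sim$blocks
  for (t in seq_len(length(blocks) - 1L)) {
    L1 <- blocks[[t]]$left; L2 <- blocks[[t + 1]]$left
    R1 <- blocks[[t]]$right; R2 <- blocks[[t + 1]]$right
    if (!length(intersect(L1, L2)) || !length(intersect(R1, R2))) next
    a <- expand.grid(left = setdiff(L1, L2), right = setdiff(R2, R1),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    b <- expand.grid(left = setdiff(L2, L1), right = setdiff(R1, R2),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- rbind(a, b)
  }
  if (!length(out)) return(edge_df())
  res <- do.call(rbind, out)
  res <- res[!duplicated(pair_key(res$left, res$right)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
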