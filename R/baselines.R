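# Unsupervised comparators adapted to bipartite networks. In a bipartite
# graph a left node and a right node share no direct common neighbours, so
# the local measures compare the left node's attribute set S = G(u) with the
# attribute set T reachable from the right node in two hops.

#' Random-walk-with-restart parameters
#'
#' @param restart_prob restart probability c in (0, 1].
#' @param tol convergence tolerance on the L1 change of the distribution.
#' @param max_steps iteration cap; non-convergence yields a warning and the
#'   best iterate.
#' @export
rwr_params <- function(restart_prob = 0.15, tol = 1e-10, max_steps = 1000L) {
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_steps >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_steps = as.integer(max_steps)),
            class = "rwr_params")
}

#' Preferential-attachment score of a pair
#'
#' Degree product `deg(u) * deg(v)` on the bipartite graph.
#'
#' @param net a [bipartite_network()].
#' @param u a left-node identifier.
#' @param v a right-node identifier.
#' @export
pa_score <- function(net, u, v) {
  if (!(u %in% net$left)) stop("unknown left node: ", u)
  if (!(v %in% net$right)) stop("unknown right node: ", v)
  sum(net$present$left == u) * sum(net$present$right == v)
}

#' Two-hop local similarity scores (common neighbours, Jaccard, Adamic-Adar)
#'
#' For a pair (u, v), let `S = G(u)` be u's attribute neighbours and
#' `T = union of G(w) over w in G(v)` the attributes reachable from v in two
#' hops. Then `cn = |S n T|`, `jc = |S n T| / |S u T|` (0 when both are
#' empty), and `aa = sum over x in S n T of 1 / log(deg(x))`, dropping terms
#' with attribute degree below 2.
#'
#' @param net a [bipartite_network()].
#' @param kind one of `"cn"`, `"jc"`, `"aa"`.
#' @return numeric matrix (left x right) of scores for all pairs; use
#'   [baseline_scores()] for the unobserved-pairs data.frame.
#' @export
hop2_scores <- function(net, kind = c("cn", "jc", "aa")) {
  kind <- match.arg(kind)
  A <- biadjacency_matrix(net)                  # N x M
  Tmat <- (crossprod(A) > 0) * 1                # M x M: T membership per right node
  cn <- A %*% Tmat                              # |S n T|
  if (kind == "cn") return(cn)
  if (kind == "jc") {
    degL <- rowSums(A)
    Tsize <- colSums(Tmat)
    un <- outer(degL, Tsize, "+") - cn          # |S u T|
    jc <- ifelse(un > 0, cn / un, 0)
    dimnames(jc) <- dimnames(cn)
    return(jc)
  }
  degR <- colSums(A)
  w <- ifelse(degR >= 2, 1 / log(degR), 0)
  A %*% (Tmat * w)
}

#' Stationary random-walk-with-restart distribution from one left node
#'
#' Power-iterates `r <- (1 - c) W r + (c + (1 - c) * dangling_mass) e_u` on
#' the full bipartite adjacency, where `W` is the column-normalized walk
#' matrix and mass on dangling (degree-0) nodes is redistributed to the
#' restart vector, so the distribution always sums to 1.
#'
#' @param net a [bipartite_network()].
#' @param u a left-node identifier.
#' @param params an [rwr_params()].
#' @return named numeric vector of length `N + M` (left nodes then right
#'   nodes) summing to 1.
#' @export
rwr_stationary <- function(net, u, params = rwr_params()) {
  n <- n_left(net); m <- n_right(net)
  if (n + m == 0) stop("empty network")
  ui <- match(u, net$left)
  if (is.na(ui)) stop("unknown left node: ", u)
  A <- biadjacency_matrix(net)
  adj <- rbind(cbind(matrix(0, n, n), A), cbind(t(A), matrix(0, m, m)))
  deg <- colSums(adj)
  dangling <- deg == 0
  W <- sweep(adj, 2, pmax(deg, 1), "/")
  W[, dangling] <- 0
  cc <- params$restart_prob
  r <- numeric(n + m); r[ui] <- 1
  converged <- FALSE
  for (step in seq_len(params$max_steps)) {
    leak <- sum(r[dangling])
    r_new <- (1 - cc) * as.vector(W %*% r)
    r_new[ui] <- r_new[ui] + cc + (1 - cc) * leak
    if (sum(abs(r_new - r)) < params$tol) {
      r <- r_new; converged <- TRUE; break
    }
    r <- r_new
  }
  if (!converged) warning("RWR did not converge within max_steps; returning best iterate")
  names(r) <- c(net$left, net$right)
  r
}

#' Random-walk-with-restart scores for all (left, right) pairs
#'
#' @param net a [bipartite_network()].
#' @param params an [rwr_params()].
#' @return numeric matrix (left x right): stationary mass on each right node
#'   for a walk restarting at each left node.
#' @export
rwr_scores <- function(net, params = rwr_params()) {
  n <- n_left(net); m <- n_right(net)
  out <- matrix(0, n, m, dimnames = list(net$left, net$right))
  for (u in net$left) {
    out[u, ] <- rwr_stationary(net, u, params)[n + seq_len(m)]
  }
  out
}

#' Baseline scores over the unobserved pairs of a network
#'
#' @param net a [bipartite_network()].
#' @param method one of `"cn"`, `"jc"`, `"aa"`, `"pa"`, `"rwr"`.
#' @param rwr an [rwr_params()] (used by `method = "rwr"`).
#' @return data.frame with columns `left`, `right`, `score`.
#' @export
baseline_scores <- function(net, method = c("cn", "jc", "aa", "pa", "rwr"),
                            rwr = rwr_params()) {
  method <- match.arg(method)
  S <- switch(method,
    cn = hop2_scores(net, "cn"),
    jc = hop2_scores(net, "jc"),
    aa = hop2_scores(net, "aa"),
    pa = {
      A <- biadjacency_matrix(net)
      outer(rowSums(A), colSums(A))
    },
    rwr = rwr_scores(net, rwr))
  pairs <- unobserved_pairs(net)
  pairs$score <- S[cbind(match(pairs$left, net$left), match(pairs$right, net$right))]
  pairs
}
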