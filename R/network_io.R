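# Data model for bipartite networks / formal contexts, file formats, and the
# positive-link masking split used by the evaluation protocol.

pair_key <- function(left, right) paste(left, right, sep = "\x1f")

edge_df <- function(left = character(), right = character()) {
  data.frame(left = as.character(left), right = as.character(right),
             stringsAsFactors = FALSE)
}

as_edge_df <- function(x) {
  if (is.null(x)) return(edge_df())
  if (is.matrix(x)) x <- data.frame(left = x[, 1], right = x[, 2],
                                    stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  out <- edge_df(x[[1]], x[[2]])
  out[!duplicated(pair_key(out$left, out$right)), , drop = FALSE]
}

#' Construct a bipartite network
#'
#' A bipartite network G = (V1, V2, E) with an optional set of ground-truth
#' absent links. Most real inputs carry no absent ground truth: an unlinked
#' pair usually means "unobserved", not "absent", which is the premise behind
#' negative sample selection.
#'
#' @param left_nodes character vector of unique left-side (V1) identifiers.
#' @param right_nodes character vector of unique right-side (V2) identifiers.
#' @param present_edges two-column data.frame/matrix of present links (E).
#' @param absent_edges optional two-column data.frame/matrix of links known to
#'   be absent. Empty by default.
#' @return an object of class `bipartite_network` with fields `left`, `right`,
#'   `present`, `absent`.
#' @export
bipartite_network <- function(left_nodes, right_nodes, present_edges = NULL,
                              absent_edges = NULL) {
  left <- as.character(left_nodes)
  right <- as.character(right_nodes)
  if (anyDuplicated(left)) stop("duplicate left node identifiers")
  if (anyDuplicated(right)) stop("duplicate right node identifiers")
  present <- as_edge_df(present_edges)
  absent <- as_edge_df(absent_edges)
  for (e in list(present, absent)) {
    if (nrow(e) == 0) next
    bad <- !(e$left %in% left) | !(e$right %in% right)
    if (any(bad)) {
      stop("edge endpoint not in node lists: ",
           paste(e$left[bad][1], e$right[bad][1]))
    }
  }
  if (nrow(present) && nrow(absent) &&
      length(intersect(pair_key(present$left, present$right),
                       pair_key(absent$left, absent$right)))) {
    stop("present_edges and absent_edges overlap")
  }
  structure(list(left = left, right = right, present = present,
                 absent = absent),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d x %d nodes, %d present edges, %d labeled absent\n",
              length(x$left), length(x$right), nrow(x$present), nrow(x$absent)))
  invisible(x)
}

n_left <- function(net) length(net$left)
n_right <- function(net) length(net$right)

# present-edge membership keys, used throughout
present_keys <- function(net) pair_key(net$present$left, net$present$right)

#' Read a bipartite network from a tab-separated edge list
#'
#' Two columns give present edges only; a third column labels each row
#' (1 = present, 0 = absent). Lines starting with `#` and blank lines are
#' skipped. Nodes are collected in first-appearance order; duplicate rows are
#' collapsed.
#'
#' @param path file path.
#' @param has_labels `NA` (default) auto-detects from the first data row;
#'   otherwise TRUE/FALSE forces 3- or 2-column parsing.
#' @return a [bipartite_network()].
#' @export
read_edgelist <- function(path, has_labels = NA) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) {
    return(bipartite_network(character(), character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (is.na(has_labels)) has_labels <- ncols[1] >= 3
  want <- if (has_labels) 3L else 2L
  bad <- which(ncols < want)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected %d tab-separated fields",
                 keep[bad[1]], want))
  }
  left <- vapply(fields, `[[`, "", 1L)
  right <- vapply(fields, `[[`, "", 2L)
  if (has_labels) {
    lab <- vapply(fields, `[[`, "", 3L)
    if (!all(lab %in% c("0", "1"))) {
      stop(sprintf("bad label at line %d: must be 0 or 1",
                   keep[which(!lab %in% c("0", "1"))[1]]))
    }
    key <- pair_key(left, right)
    dup <- !duplicated(key)
    conflict <- tapply(lab, key, function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      k <- names(conflict)[conflict][1]
      pr <- strsplit(k, "\x1f", fixed = TRUE)[[1]]
      stop(sprintf("pair (%s, %s) labeled both present and absent", pr[1], pr[2]))
    }
    left <- left[dup]; right <- right[dup]; lab <- lab[dup]
    pres <- lab == "1"
    bipartite_network(unique(left), unique(right),
                      edge_df(left[pres], right[pres]),
                      edge_df(left[!pres], right[!pres]))
  } else {
    bipartite_network(unique(left), unique(right), edge_df(left, right))
  }
}

#' Write a bipartite network as a tab-separated edge list
#'
#' @param net a [bipartite_network()].
#' @param path file path.
#' @param labels write a third 0/1 label column (required to preserve labeled
#'   absent edges on round trip).
#' @export
write_edgelist <- function(net, path, labels = nrow(net$absent) > 0) {
  if (labels) {
    rows <- c(sprintf("%s\t%s\t1", net$present$left, net$present$right),
              sprintf("%s\t%s\t0", net$absent$left, net$absent$right))
  } else {
    rows <- sprintf("%s\t%s", net$present$left, net$present$right)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Construct a formal context
#'
#' The FCA view of a bipartite network: ordered objects, ordered attributes
#' and a binary incidence relation. Attribute order defines the canonical
#' enumeration order of [enumerate_concepts()].
#'
#' @param objects character vector of object names.
#' @param attributes character vector of attribute names.
#' @param incidence logical matrix, `length(objects)` x `length(attributes)`,
#'   or a two-column data.frame of (object, attribute) pairs.
#' @return an object of class `formal_context` with fields `objects`,
#'   `attributes`, `mat` (logical incidence matrix).
#' @export
formal_context <- function(objects, attributes, incidence) {
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  n <- length(objects); m <- length(attributes)
  if (is.data.frame(incidence) || (is.matrix(incidence) && !is.logical(incidence) &&
                                   !is.numeric(incidence))) {
    inc <- as_edge_df(incidence)
    mat <- matrix(FALSE, n, m, dimnames = list(objects, attributes))
    if (nrow(inc)) {
      oi <- match(inc$left, objects); ai <- match(inc$right, attributes)
      if (anyNA(oi) || anyNA(ai)) stop("incidence pair outside objects/attributes")
      mat[cbind(oi, ai)] <- TRUE
    }
  } else {
    mat <- matrix(as.logical(incidence), n, m, dimnames = list(objects, attributes))
    stopifnot(nrow(mat) == n, ncol(mat) == m)
  }
  structure(list(objects = objects, attributes = attributes, mat = mat),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("formal_context: %d objects x %d attributes, %d incidences\n",
              length(x$objects), length(x$attributes), sum(x$mat)))
  invisible(x)
}

#' Transpose a formal context (swap objects and attributes)
#' @param ctx a [formal_context()].
#' @export
context_transpose <- function(ctx) {
  formal_context(ctx$attributes, ctx$objects, t(ctx$mat))
}

#' Convert a bipartite network to a formal context
#'
#' @param net a [bipartite_network()].
#' @param orientation `"left-as-objects"` maps V1 to objects and V2 to
#'   attributes; `"right-as-objects"` is the transpose (used by the second
#'   enumeration pass of the marking algorithm).
#' @export
to_context <- function(net, orientation = c("left-as-objects", "right-as-objects")) {
  orientation <- match.arg(orientation)
  ctx <- formal_context(net$left, net$right, net$present)
  if (orientation == "right-as-objects") ctx <- context_transpose(ctx)
  ctx
}

#' View a formal context as a bipartite network
#'
#' Objects become left nodes, attributes right nodes, incidences present edges.
#' @param ctx a [formal_context()].
#' @export
context_as_network <- function(ctx) {
  idx <- which(ctx$mat, arr.ind = TRUE)
  bipartite_network(ctx$objects, ctx$attributes,
                    edge_df(ctx$objects[idx[, 1]], ctx$attributes[idx[, 2]]))
}

#' Read / write a Burmeister CXT formal-context file
#'
#' The classic plain-text FCA exchange format: a `B` header, object and
#' attribute counts, names, then one `.`/`X` row per object.
#'
#' @param path file path.
#' @return [read_cxt()]: a [formal_context()].
#' @export
read_cxt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (!length(lines) || trimws(lines[1]) != "B") stop("not a Burmeister CXT file (missing 'B' header)")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- as.integer(body[1]); m <- as.integer(body[2])
  if (is.na(n) || is.na(m)) stop("bad CXT object/attribute counts")
  objects <- body[3:(2 + n)]
  attributes <- if (m > 0) body[(3 + n):(2 + n + m)] else character()
  rows <- if (n > 0) body[(3 + n + m):(2 + n + m + n)] else character()
  mat <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    ch <- strsplit(rows[i], "")[[1]]
    if (length(ch) != m) stop(sprintf("CXT row %d has %d cells, expected %d", i, length(ch), m))
    mat[i, ] <- ch %in% c("X", "x")
  }
  formal_context(objects, attributes, mat)
}

#' @rdname read_cxt
#' @param ctx a [formal_context()] to write.
#' @export
write_cxt <- function(ctx, path) {
  n <- length(ctx$objects); m <- length(ctx$attributes)
  rows <- vapply(seq_len(n), function(i)
    paste(ifelse(ctx$mat[i, ], "X", "."), collapse = ""), "")
  writeLines(c("B", "", n, m, "", ctx$objects, ctx$attributes, rows), path)
  invisible(path)
}

#' Read / write a dense 0/1 bi-adjacency CSV with row and column headers
#' @param path file path.
#' @export
read_biadjacency <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  mat <- as.matrix(df) != 0
  idx <- which(mat, arr.ind = TRUE)
  bipartite_network(rownames(mat), colnames(mat),
                    edge_df(rownames(mat)[idx[, 1]], colnames(mat)[idx[, 2]]))
}

#' @rdname read_biadjacency
#' @param net a [bipartite_network()] to write.
#' @export
write_biadjacency <- function(net, path) {
  mat <- biadjacency_matrix(net)
  utils::write.csv(mat * 1L, path, row.names = TRUE)
  invisible(path)
}

#' Dense 0/1 bi-adjacency matrix of a network (rows = left nodes)
#' @param net a [bipartite_network()].
#' @export
biadjacency_matrix <- function(net) {
  mat <- matrix(0L, n_left(net), n_right(net),
                dimnames = list(net$left, net$right))
  if (nrow(net$present)) {
    mat[cbind(match(net$present$left, net$left),
              match(net$present$right, net$right))] <- 1L
  }
  mat
}

round_half_up <- function(x) floor(x + 0.5)

#' Hide a fraction of present links to create an input/target split
#'
#' Emulates the standard protocol for evaluating link prediction when no
#' absent ground truth exists: `round(hide_fraction * |E|)` present links
#' (round half-up) are removed uniformly at random from the input copy, and
#' the input's absent-edge labels are emptied, so the predictor sees presence
#' only. The full target network keeps all labels.
#'
#' @param net a [bipartite_network()] with at least one present edge.
#' @param hide_fraction proportion in `[0, 1)` of present links to hide.
#' @param seed integer seed; the draw is deterministic per seed.
#' @return an object of class `split_result`: list with `input`, `target`,
#'   `hidden` (data.frame of hidden positive edges).
#' @export
mask_positives <- function(net, hide_fraction, seed) {
  if (hide_fraction < 0 || hide_fraction >= 1) {
    stop("hide_fraction must be in [0, 1)")
  }
  np <- nrow(net$present)
  if (np < 1) stop("network has no present edges")
  k <- round_half_up(hide_fraction * np)
  hide <- with_seed(seed, sample.int(np, k))
  input <- bipartite_network(net$left, net$right,
                             net$present[setdiff(seq_len(np), hide), , drop = FALSE])
  structure(list(input = input, target = net,
                 hidden = net$present[sort(hide), , drop = FALSE]),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %d input / %d target present edges, %d hidden\n",
              nrow(x$input$present), nrow(x$target$present), nrow(x$hidden)))
  invisible(x)
}

#' Write scored pairs as a TSV, best first
#'
#' Rows are sorted by descending score with ties broken by (left, right)
#' identifier so output is reproducible bit-for-bit.
#'
#' @param scores data.frame with columns `left`, `right`, `score`.
#' @param path file path.
#' @export
write_predictions <- function(scores, path) {
  stopifnot(is.data.frame(scores), all(c("left", "right", "score") %in% names(scores)))
  if (nrow(scores) && any(!is.finite(scores$score))) stop("non-finite score in predictions")
  ord <- order(-scores$score, scores$left, scores$right)
  scores <- scores[ord, c("left", "right", "score"), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("left\tright\tscore", con)
  if (nrow(scores)) {
    writeLines(sprintf("%s\t%s\t%.10g", scores$left, scores$right, scores$score), con)
  }
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#' @param path file path.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character", "numeric"))
  names(df) <- c("left", "right", "score")
  df
}

# run expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' All unobserved (non-present) pairs of a network
#'
#' @param net a [bipartite_network()].
#' @param exclude optional data.frame of pairs to drop as well.
#' @return data.frame with columns `left`, `right`.
#' @export
unobserved_pairs <- function(net, exclude = NULL) {
  all <- expand.grid(left = net$left, right = net$right,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  drop <- present_keys(net)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- c(drop, pair_key(exclude$left, exclude$right))
  }
  all[!(pair_key(all$left, all$right) %in% drop), , drop = FALSE]
}
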