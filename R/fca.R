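# Formal-concept (maximal bi-clique) enumeration by depth-first canonical
# extension. A concept (A, B) of a context K = (G, M, Y) is a maximal
# bi-clique of the bipartite graph underlying K; all concepts are produced
# exactly once by a close-by-one style DFS whose children are generated with
# the augmentation operator and filtered by a prefix-preserving canonicity
# test on attribute IDs.

#' Create a concept (extent/intent pair)
#'
#' @param extent integer vector of object positions (1-based), sorted.
#' @param intent integer vector of attribute positions (1-based), sorted.
#' @return object of class `concept`.
#' @export
concept <- function(extent, intent) {
  structure(list(extent = unname(sort(as.integer(extent))),
                 intent = unname(sort(as.integer(intent)))),
            class = "concept")
}

#' @export
print.concept <- function(x, ...) {
  cat(sprintf("concept: extent {%s} | intent {%s}\n",
              paste(x$extent, collapse = ","), paste(x$intent, collapse = ",")))
  invisible(x)
}

concept_key <- function(cpt) paste(cpt$intent, collapse = ",")

#' Derivation operators
#'
#' `derive_objects(attrs, ctx)` returns the objects incident to every
#' attribute in `attrs` (all objects for the empty set); `derive_attrs` is the
#' dual. Applying both yields a closed concept.
#'
#' @param attrs integer vector of attribute positions.
#' @param objs integer vector of object positions.
#' @param ctx a [formal_context()].
#' @return sorted integer vector.
#' @export
derive_objects <- function(attrs, ctx) {
  attrs <- as.integer(attrs)
  m <- ncol(ctx$mat)
  if (length(attrs) && (anyNA(attrs) || any(attrs < 1L | attrs > m))) {
    stop("unknown attribute ID")
  }
  if (!length(attrs)) return(seq_len(nrow(ctx$mat)))
  unname(which(rowSums(ctx$mat[, attrs, drop = FALSE]) == length(attrs)))
}

#' @rdname derive_objects
#' @export
derive_attrs <- function(objs, ctx) {
  objs <- as.integer(objs)
  n <- nrow(ctx$mat)
  if (length(objs) && (anyNA(objs) || any(objs < 1L | objs > n))) {
    stop("unknown object ID")
  }
  if (!length(objs)) return(seq_len(ncol(ctx$mat)))
  unname(which(colSums(ctx$mat[objs, , drop = FALSE]) == length(objs)))
}

#' Closure of an attribute set
#'
#' Returns the concept generated from any attribute subset:
#' `(derive_objects(attrs), derive_attrs(derive_objects(attrs)))`. The result
#' is closed and its intent contains `attrs`; the map is idempotent.
#'
#' @inheritParams derive_objects
#' @return a [concept()].
#' @export
closure_of <- function(attrs, ctx) {
  ext <- derive_objects(attrs, ctx)
  concept(ext, derive_attrs(ext, ctx))
}

#' Augmentation operator
#'
#' Generates the concept obtained by adding attribute `b` to the intent of
#' `cpt` and closing: `closure_of(union(cpt$intent, b))`. The result lies
#' below `cpt` in the lattice order (extent shrinks or stays, intent grows).
#'
#' @param cpt a [concept()].
#' @param b an attribute position not in `cpt$intent`.
#' @param ctx a [formal_context()].
#' @export
augment <- function(cpt, b, ctx) {
  b <- as.integer(b)
  if (b %in% cpt$intent) stop("augmentation attribute already in intent")
  closure_of(c(cpt$intent, b), ctx)
}

#' Canonicity (predecessor) test on intents
#'
#' TRUE iff the smallest attribute ID added in `child_intent` relative to
#' `parent_intent` exceeds the largest ID in `parent_intent` (vacuously true
#' for an empty parent). This is the predecessor condition on a lattice edge;
#' the enumerator uses the strictly stronger prefix-preserving form (see
#' [enumerate_concepts()]) which is what guarantees exactly-once visits.
#'
#' @param parent_intent,child_intent sorted integer vectors with
#'   `parent_intent` a proper subset of `child_intent`.
#' @export
is_canonical <- function(parent_intent, child_intent) {
  added <- setdiff(child_intent, parent_intent)
  if (!length(added)) stop("child intent must strictly contain parent intent")
  !length(parent_intent) || min(added) > max(parent_intent)
}

#' Enumerate all formal concepts of a context exactly once
#'
#' Depth-first enumeration from the top concept `closure_of(integer(0))`.
#' Children of a concept generated by augmentation attribute `y` are tried
#' for every attribute `b > y` outside the intent; the augmented concept is
#' accepted iff it adds no attribute with ID below `b` (prefix-preserving
#' canonicity). Every root-to-node path of the recursion tree is a chain in
#' the lattice order, which the overlap-marking pass relies on. The DFS is
#' run on an explicit stack so deep lattices cannot exhaust C-stack limits.
#'
#' @param ctx a [formal_context()].
#' @param min_extent prune (do not visit or expand) concepts whose extent is
#'   smaller than this; sound because extents only shrink downward.
#' @param visitor optional `function(concept, depth)` called exactly once per
#'   visited concept, in DFS preorder (root depth 1). Must not mutate `ctx`.
#' @return the number of visited concepts.
#' @export
enumerate_concepts <- function(ctx, min_extent = 0L, visitor = NULL) {
  mat <- ctx$mat
  n <- nrow(mat); m <- ncol(mat)
  root_ext <- seq_len(n)
  root_int <- unname(which(colSums(mat) == n))   # attrs common to all objects
  if (length(root_ext) < min_extent) return(0L)
  count <- 0L
  # stack of nodes to visit: extent, intent, generator attribute y, depth
  stack <- list(list(ext = root_ext, int = root_int, y = 0L, depth = 1L))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    count <- count + 1L
    if (!is.null(visitor)) visitor(concept(node$ext, node$int), node$depth)
    if (node$y >= m) next
    intent_mask <- logical(m)
    intent_mask[node$int] <- TRUE
    children <- list()
    for (b in seq.int(node$y + 1L, m)) {
      if (intent_mask[b]) next
      child_ext <- node$ext[mat[node$ext, b]]
      if (length(child_ext) < min_extent) next
      child_int <- unname(which(colSums(mat[child_ext, , drop = FALSE]) == length(child_ext)))
      added <- child_int[!intent_mask[child_int]]
      if (added[1] < b) next    # a smaller new attribute: not canonical here
      children[[length(children) + 1L]] <-
        list(ext = child_ext, int = child_int, y = b, depth = node$depth + 1L)
    }
    # reverse so the smallest augmentation attribute is explored first
    if (length(children)) stack <- c(stack, rev(children))
  }
  count
}

#' Brute-force concept enumeration (test oracle)
#'
#' Closes all `2^|M|` attribute subsets and deduplicates. Independent of the
#' DFS path: used to certify [enumerate_concepts()] on small contexts.
#'
#' @param ctx a [formal_context()] with at most 15 attributes.
#' @return list of [concept()]s, sorted by intent key.
#' @export
enumerate_concepts_bruteforce <- function(ctx) {
  m <- ncol(ctx$mat); n <- nrow(ctx$mat)
  if (m > 15) stop("context too large for brute force (", m, " attributes)")
  pow <- as.integer(2^(seq_len(m) - 1L))
  rowbits <- as.integer(ctx$mat %*% pow)
  full <- as.integer(2^m - 1)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (s in 0:full) {
    ext <- which(bitwAnd(rowbits, s) == s)
    int_bits <- Reduce(bitwAnd, rowbits[ext], init = full)
    key <- as.character(int_bits)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    int <- which(bitwAnd(int_bits, pow) > 0L)
    out[[length(out) + 1L]] <- concept(ext, int)
  }
  out[order(vapply(out, concept_key, ""))]
}
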