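#' Degree-weighted adjacency matrix of one metaedge
#'
#' Builds the sparse matrix whose entry (u, v) is
#' \eqn{d(u)^{-w} \, d(v)^{-w}} when an edge of the metaedge joins u to v
#' (in the traversal direction) and 0 otherwise, where \eqn{d} is the
#' node's degree for that metaedge at its end of the traversal and `w` is
#' the damping exponent. With `w = 0` this is the plain 0/1 adjacency.
#' Rows are the nodes of the traversal's source type and columns those of
#' its target type, in a canonical ordering shared by all matrices built
#' from the same network, so chained products are conformable. Nodes of
#' degree zero yield all-zero rows/columns (0^-w is never evaluated).
#'
#' @param net A [hetnet()].
#' @param metaedge Metaedge label.
#' @param direction `"forward"` (with the arrow) or `"backward"` (against
#'   it); for undirected metaedges the two coincide.
#' @param w Damping exponent, >= 0.
#' @return A sparse `dgCMatrix` with node-id dimnames.
#' @export
weighted_adjacency <- function(net, metaedge, direction = c("forward", "backward"), w = 0.4) {
  direction <- match.arg(direction)
  me <- metaedge_row(net$metagraph, metaedge)
  if (!is_scalar_number(w) || w < 0) abort_config("damping exponent w must be >= 0")
  d_src <- degree_vector(net, metaedge, "source")
  d_tgt <- degree_vector(net, metaedge, "target")
  e <- net$edges[net$edges$metaedge == metaedge, ]
  # weight of an edge is independent of traversal direction
  wt <- function(u, v) {
    if (w == 0) rep(1, length(u)) else (d_src[u] * d_tgt[v])^(-w)
  }
  if (!me$directed) {
    ids <- names(d_src) # source and target types coincide
    i <- c(match(e$source, ids), match(e$target, ids))
    j <- c(match(e$target, ids), match(e$source, ids))
    x <- rep(wt(e$source, e$target), 2L)
    m <- Matrix::sparseMatrix(
      i = i, j = j, x = x, dims = c(length(ids), length(ids)),
      dimnames = list(ids, ids)
    )
  } else {
    rows <- names(d_src)
    cols <- names(d_tgt)
    m <- Matrix::sparseMatrix(
      i = match(e$source, rows), j = match(e$target, cols),
      x = wt(e$source, e$target),
      dims = c(length(rows), length(cols)), dimnames = list(rows, cols)
    )
    if (direction == "backward") m <- Matrix::t(m)
  }
  methods::as(m, "CsparseMatrix")
}

#' Degree-weighted path counts for all source-target pairs of a metapath
#'
#' The DWPC between nodes s and t along a metapath is the sum over
#' node-distinct paths conforming to the metapath of the product over path
#' steps of \eqn{(d_{\mathrm{prev}} \, d_{\mathrm{next}})^{-w}}. It is
#' computed by chaining the degree-weighted adjacency matrices of the
#' steps and analytically subtracting walk contributions that revisit a
#' node. For metapaths of up to three steps the correction is exact
#' (repeats can only arise between positions of equal node type:
#' inclusion-exclusion over the two possible non-adjacent repeats plus
#' zeroing the diagonal when source and target types coincide). Longer
#' metapaths fall back to the exhaustive path-enumeration oracle per pair.
#'
#' @param net A [hetnet()].
#' @param mp A `metapath` (see [new_metapath()], [enumerate_metapaths()]).
#' @param w Damping exponent.
#' @return Dense base matrix of DWPC values, rows = source-type nodes,
#'   columns = target-type nodes (canonical ordering, id dimnames).
#' @export
dwpc_matrix <- function(net, mp, w = 0.4) {
  stopifnot(inherits(mp, "metapath"))
  types <- c(mp$steps$from_type, mp$target_type)
  bad <- setdiff(unique(types), net$metagraph$node_types$type)
  if (length(bad) > 0 || !all(mp$steps$metaedge %in% net$metagraph$metaedges$label)) {
    abort_schema("metapath is not enumerable on this network's metagraph")
  }
  L <- mp$length
  if (L > 3L) {
    return(dwpc_matrix_oracle(net, mp, w))
  }
  W <- lapply(seq_len(L), function(i) {
    weighted_adjacency(net, mp$steps$metaedge[i], mp$steps$direction[i], w)
  })
  P <- Reduce(`%*%`, W)
  if (L == 3L) {
    same02 <- types[1] == types[3]
    same13 <- types[2] == types[4]
    if (same02) {
      d1 <- Matrix::diag(W[[1]] %*% W[[2]])
      P <- P - Matrix::Diagonal(x = d1) %*% W[[3]]
    }
    if (same13) {
      d2 <- Matrix::diag(W[[2]] %*% W[[3]])
      P <- P - W[[1]] %*% Matrix::Diagonal(x = d2)
    }
    if (same02 && same13) {
      P <- P + W[[1]] * Matrix::t(W[[2]]) * W[[3]]
    }
  }
  P <- as.matrix(P)
  if (types[1] == types[length(types)]) diag(P) <- 0
  # tiny negatives can arise from floating cancellation in the corrections
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- list(nodes_of_type(net, mp$source_type), nodes_of_type(net, mp$target_type))
  P
}

dwpc_matrix_oracle <- function(net, mp, w) {
  rows <- nodes_of_type(net, mp$source_type)
  cols <- nodes_of_type(net, mp$target_type)
  P <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (s in rows) {
    for (t in cols) {
      P[s, t] <- dwpc_oracle(net, s, t, mp, w)
    }
  }
  P
}

#' Exhaustive DWPC oracle for a single node pair
#'
#' Depth-first enumeration of all node-distinct paths conforming to the
#' metapath, summing the degree-product weights directly. Exact by
#' construction and independent of the matrix engine; intended as a
#' verification reference on small networks.
#'
#' @inheritParams dwpc_matrix
#' @param source,target Node ids.
#' @param max_paths Enumeration budget; exceeding it raises a budget error.
#' @return A single DWPC value.
#' @export
dwpc_oracle <- function(net, source, target, mp, w = 0.4, max_paths = 1e4) {
  stopifnot(inherits(mp, "metapath"))
  i <- match(c(source, target), net$nodes$id)
  if (anyNA(i)) abort_identifier("unknown source or target node id")
  L <- mp$length
  # neighbor lists and per-end degrees for each step
  steps <- vector("list", L)
  for (k in seq_len(L)) {
    melab <- mp$steps$metaedge[k]
    me <- metaedge_row(net$metagraph, melab)
    e <- net$edges[net$edges$metaedge == melab, ]
    fwd <- mp$steps$direction[k] == "forward"
    if (!me$directed) {
      adj <- split(c(e$target, e$source), c(e$source, e$target))
      d_from <- d_to <- degree_vector(net, melab, "source")
    } else if (fwd) {
      adj <- split(e$target, e$source)
      d_from <- degree_vector(net, melab, "source")
      d_to <- degree_vector(net, melab, "target")
    } else {
      adj <- split(e$source, e$target)
      d_from <- degree_vector(net, melab, "target")
      d_to <- degree_vector(net, melab, "source")
    }
    steps[[k]] <- list(adj = adj, d_from = d_from, d_to = d_to)
  }
  n_paths <- 0L
  total <- 0
  recurse <- function(node, k, visited, weight) {
    if (k > L) {
      n_paths <<- n_paths + 1L
      if (n_paths > max_paths) abort_budget("path enumeration budget exceeded")
      total <<- total + weight
      return(invisible())
    }
    st <- steps[[k]]
    nbrs <- st$adj[[node]]
    if (is.null(nbrs)) {
      return(invisible())
    }
    for (v in nbrs) {
      if (v %in% visited) next
      if (k < L && v == target) next # target may only appear at the final position
      if (k == L && v != target) next
      stepw <- if (w == 0) 1 else (st$d_from[[node]] * st$d_to[[v]])^(-w)
      recurse(v, k + 1L, c(visited, v), weight * stepw)
    }
  }
  recurse(source, 1L, source, 1)
  total
}

#' Feature extraction configuration
#'
#' @param source_type,target_type Node types of the pair endpoints (drug
#'   and disease types).
#' @param w Damping exponent in `[0, 1]` down-weighting paths through
#'   high-degree nodes (`0` = raw path counts).
#' @param max_length Maximum metapath length (default 3).
#' @return A `feature_config` list.
#' @export
feature_config <- function(source_type, target_type, w = 0.4, max_length = 3) {
  if (!is_scalar_number(w) || w < 0) abort_config("w must be >= 0")
  if (!is_scalar_number(max_length) || max_length < 1) abort_config("max_length must be >= 1")
  structure(
    list(
      source_type = source_type, target_type = target_type,
      w = w, max_length = as.integer(max_length)
    ),
    class = "feature_config"
  )
}

# degree-feature column plan for one endpoint role ("drug" or "disease"):
# one column per (metaedge, end) at which the role's node type appears.
degree_column_plan <- function(mg, type, role) {
  me <- mg$metaedges
  plan <- list()
  for (i in seq_len(nrow(me))) {
    if (me$source[i] == type) {
      suffix <- if (me$directed[i] && me$source[i] == me$target[i]) "_out" else ""
      plan[[length(plan) + 1L]] <- list(
        metaedge = me$label[i], end = "source",
        column = paste0("degree_", role, "_", me$label[i], suffix)
      )
    }
    if (me$target[i] == type && me$directed[i]) {
      suffix <- if (me$source[i] == me$target[i]) "_in" else ""
      plan[[length(plan) + 1L]] <- list(
        metaedge = me$label[i], end = "target",
        column = paste0("degree_", role, "_", me$label[i], suffix)
      )
    }
  }
  plan
}

#' Extract DWPC and degree features for drug-disease pairs
#'
#' Computes one row per pair with a `dwpc_<metapath label>` column for
#' every metapath enumerated under the configuration (source type to
#' target type, length up to `max_length`) and a
#' `degree_<role>_<metaedge>` column for each metaedge end at which the
#' drug or disease node type appears. Column order is deterministic:
#' metapaths by length then label, degree columns drug-first in metagraph
#' order.
#'
#' @param net A [hetnet()].
#' @param pairs Data frame with columns `drug`, `disease` (node ids).
#' @param config A [feature_config()].
#' @return Tibble of features keyed by (`drug`, `disease`).
#' @export
extract_features <- function(net, pairs, config) {
  stopifnot(inherits(config, "feature_config"))
  pairs <- tibble::as_tibble(pairs)[, c("drug", "disease")]
  node_type <- stats::setNames(net$nodes$type, net$nodes$id)
  ok <- !is.na(node_type[pairs$drug]) & node_type[pairs$drug] == config$source_type &
    !is.na(node_type[pairs$disease]) & node_type[pairs$disease] == config$target_type
  if (any(!ok)) {
    bad <- pairs[!ok, ]
    abort_identifier(paste0(
      "pairs with endpoints missing from the network (or of the wrong type): ",
      paste(utils::head(paste0(bad$drug, "/", bad$disease), 5), collapse = ", ")
    ))
  }
  mps <- enumerate_metapaths(net$metagraph, config$source_type, config$target_type,
    max_length = config$max_length
  )
  out <- pairs
  for (k in seq_len(nrow(mps))) {
    P <- dwpc_matrix(net, mps$metapath[[k]], config$w)
    out[[paste0("dwpc_", mps$label[k])]] <- P[cbind(pairs$drug, pairs$disease)]
  }
  for (role in c("drug", "disease")) {
    type <- if (role == "drug") config$source_type else config$target_type
    ids <- pairs[[role]]
    for (p in degree_column_plan(net$metagraph, type, role)) {
      d <- degree_vector(net, p$metaedge, p$end)
      out[[p$column]] <- as.integer(d[ids])
    }
  }
  out
}

feature_columns <- function(features) {
  grep("^(dwpc|degree)_", names(features), value = TRUE)
}
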