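#' Construct a heterogeneous network (hetnet)
#'
#' A hetnet holds typed node instances and typed edge instances under a
#' [metagraph()] schema. Each edge carries the set of publication ids
#' (PMIDs) supporting it and, once dated, the earliest publication year.
#' Undirected edges are stored once, with endpoints in lexicographic order;
#' self-loops (identical subject and object) are rejected because a
#' text-mined assertion relating a concept to itself carries no path
#' information.
#'
#' @param nodes Data frame with columns `id`, `name`, `type` (`name` may be
#'   omitted; it defaults to the id).
#' @param edges Data frame with columns `source`, `target`, `metaedge`
#'   (metaedge label), and optionally `pmids` (list of character vectors, or
#'   a pipe-joined character column) and `year` (integer, `NA` = undated).
#' @param mg The [metagraph()] schema.
#' @return An object of class `hetnet`: list with tibbles `nodes`, `edges`
#'   and the `metagraph`.
#' @export
hetnet <- function(nodes, edges, mg) {
  stopifnot(inherits(mg, "metagraph"))
  nodes <- tibble::as_tibble(nodes)
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  nodes <- nodes[, c("id", "name", "type")]
  if (anyDuplicated(nodes$id)) abort_schema("node ids must be unique")
  bad_type <- setdiff(nodes$type, mg$node_types$type)
  if (length(bad_type) > 0) {
    abort_schema(paste0("undeclared node types: ", paste(bad_type, collapse = ", ")))
  }
  edges <- tibble::as_tibble(edges)
  if (!"pmids" %in% names(edges)) edges$pmids <- replicate(nrow(edges), character(), simplify = FALSE)
  if (is.character(edges$pmids)) {
    edges$pmids <- lapply(edges$pmids, function(p) {
      if (is.na(p) || p == "") character() else strsplit(p, "|", fixed = TRUE)[[1]]
    })
  }
  edges$pmids <- lapply(edges$pmids, function(p) sort_c(unique(as.character(p))))
  if (!"year" %in% names(edges)) edges$year <- NA_integer_
  edges$year <- as.integer(edges$year)
  edges <- edges[, c("source", "target", "metaedge", "pmids", "year")]

  if (nrow(edges) > 0) {
    merows <- metaedge_row(mg, edges$metaedge) # errors on unknown metaedge
    if (any(edges$source == edges$target)) {
      bad <- which(edges$source == edges$target)
      abort_schema(paste0(
        "self-loop edges are not allowed (rows ",
        paste(utils::head(bad, 5), collapse = ", "), ")"
      ))
    }
    node_type <- stats::setNames(nodes$type, nodes$id)
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing) > 0) {
      abort_integrity(paste0(
        "edges reference absent nodes: ",
        paste(utils::head(sort_c(missing), 5), collapse = ", ")
      ))
    }
    # canonical ordering for undirected edges: lexicographically smaller id first
    undir <- !merows$directed
    swap <- undir & edges$source > edges$target
    if (any(swap)) {
      tmp <- edges$source[swap]
      edges$source[swap] <- edges$target[swap]
      edges$target[swap] <- tmp
    }
    st <- node_type[edges$source]
    tt <- node_type[edges$target]
    ok <- (st == merows$source & tt == merows$target) |
      (undir & st == merows$target & tt == merows$source)
    if (any(!ok)) {
      bad <- which(!ok)
      abort_schema(paste0(
        "edge endpoint types contradict the metaedge (rows ",
        paste(utils::head(bad, 5), collapse = ", "), ")"
      ))
    }
    key <- paste(edges$source, edges$target, edges$metaedge, sep = "\r")
    if (anyDuplicated(key)) {
      abort_schema(paste0(
        "duplicate (source, target, metaedge) edges (rows ",
        paste(utils::head(which(duplicated(key)), 5), collapse = ", "), ")"
      ))
    }
    edges <- edges[order_c(edges$metaedge, edges$source, edges$target), ]
  }
  nodes <- nodes[order_c(nodes$id), ]
  structure(list(nodes = nodes, edges = edges, metagraph = mg), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("<hetnet>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tc <- table(x$nodes$type)
  cat("node types:", paste0(names(tc), " (", tc, ")", collapse = ", "), "\n")
  ec <- table(factor(x$edges$metaedge, levels = x$metagraph$metaedges$label))
  cat("metaedges:", paste0(names(ec), " (", ec, ")", collapse = ", "), "\n")
  n_dated <- sum(!is.na(x$edges$year))
  if (n_dated > 0) {
    cat("dated edges:", n_dated, "spanning", min(x$edges$year, na.rm = TRUE), "-",
      max(x$edges$year, na.rm = TRUE), "\n")
  }
  invisible(x)
}

#' Node ids of one type, in canonical order
#'
#' The canonical (byte-order sorted) id ordering is shared by every
#' adjacency and DWPC matrix built from the same hetnet, so chained matrix
#' products stay conformable.
#'
#' @param net A [hetnet()].
#' @param type A declared node type.
#' @return Character vector of node ids.
#' @export
nodes_of_type <- function(net, type) {
  sort_c(net$nodes$id[net$nodes$type == type])
}

#' Typed degree of nodes
#'
#' Counts the edges of one metaedge incident to each queried node at the
#' requested end. For undirected metaedges the two ends are equivalent and
#' incidences at either endpoint are counted.
#'
#' @param net A [hetnet()].
#' @param node Character vector of node ids.
#' @param metaedge A metaedge label.
#' @param end `"source"` or `"target"`: which end of the metaedge the node
#'   occupies.
#' @return Integer vector of counts, one per queried node.
#' @export
node_degree <- function(net, node, metaedge, end = c("source", "target")) {
  end <- match.arg(end)
  me <- metaedge_row(net$metagraph, metaedge)
  i <- match(node, net$nodes$id)
  if (anyNA(i)) {
    abort_identifier(paste0("unknown node ids: ", paste(node[is.na(i)], collapse = ", ")))
  }
  want_type <- if (end == "source") me$source else me$target
  if (any(net$nodes$type[i] != want_type)) {
    abort_identifier(paste0("node type does not match the ", end, " of ", metaedge))
  }
  e <- net$edges[net$edges$metaedge == metaedge, ]
  if (!me$directed) {
    counts <- table(c(e$source, e$target))
  } else if (end == "source") {
    counts <- table(e$source)
  } else {
    counts <- table(e$target)
  }
  out <- as.integer(counts[node])
  out[is.na(out)] <- 0L
  out
}

# named degree vector over all nodes of the relevant type for one metaedge end
degree_vector <- function(net, metaedge, end) {
  me <- metaedge_row(net$metagraph, metaedge)
  type <- if (end == "source") me$source else me$target
  ids <- nodes_of_type(net, type)
  e <- net$edges[net$edges$metaedge == metaedge, ]
  incident <- if (!me$directed) c(e$source, e$target) else if (end == "source") e$source else e$target
  d <- tabulate(match(incident, ids), nbins = length(ids))
  stats::setNames(d, ids)
}

#' Total degree of every node
#'
#' Sum of incident edge counts over all metaedges and both ends, used e.g.
#' to identify hub nodes.
#'
#' @param net A [hetnet()].
#' @return Tibble with columns `id`, `degree`, sorted by decreasing degree
#'   then id.
#' @export
total_degree <- function(net) {
  counts <- table(factor(c(net$edges$source, net$edges$target), levels = net$nodes$id))
  out <- tibble::tibble(id = names(counts), degree = as.integer(counts))
  out[order_c(-out$degree, out$id), ]
}

# drop edges of `metaedge` connecting the given (source, target) pairs;
# for undirected metaedges either orientation matches.
remove_edges <- function(net, metaedge, pairs) {
  me <- metaedge_row(net$metagraph, metaedge)
  e <- net$edges
  key <- paste(e$source, e$target, sep = "\r")
  hit <- e$metaedge == metaedge & key %in% paste(pairs[[1]], pairs[[2]], sep = "\r")
  if (!me$directed) {
    hit <- hit | (e$metaedge == metaedge & key %in% paste(pairs[[2]], pairs[[1]], sep = "\r"))
  }
  net$edges <- e[!hit, ]
  net
}

# drop nodes with zero incident edges, and metaedges with zero edges
prune_network <- function(net, drop_isolated = TRUE, drop_empty_metaedges = FALSE) {
  if (drop_isolated) {
    used <- unique(c(net$edges$source, net$edges$target))
    net$nodes <- net$nodes[net$nodes$id %in% used, ]
  }
  if (drop_empty_metaedges) {
    keep <- net$metagraph$metaedges$label %in% unique(net$edges$metaedge)
    net$metagraph$metaedges <- net$metagraph$metaedges[keep, ]
  }
  net
}
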