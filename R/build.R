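#' Normalize a triple table to publication-id sets
#'
#' Collapses a raw one-pmid-per-row triple table to one row per distinct
#' (subject, predicate, object) class, with the supporting publication ids
#' gathered into a set-valued `pmids` list-column. Tables already carrying
#' a `pmids` list-column pass through (re-unioned). All downstream cleaning
#' operations work on this normalized form.
#'
#' @param triples Tibble with columns `subject`, `subject_type`,
#'   `predicate`, `object`, `object_type` and either `pmid` (character) or
#'   `pmids` (list of character vectors).
#' @return Normalized tibble with a `pmids` list-column.
#' @export
normalize_triples <- function(triples) {
  t <- tibble::as_tibble(triples)
  if (!"pmids" %in% names(t)) {
    if (!"pmid" %in% names(t)) abort_schema("triple table needs a pmid or pmids column")
    t$pmids <- as.list(as.character(t$pmid))
    t$pmid <- NULL
  }
  t |>
    dplyr::group_by(.data$subject, .data$subject_type, .data$predicate, .data$object, .data$object_type) |>
    dplyr::summarise(pmids = list(sort_c(unique(unlist(pmids)))), .groups = "drop") |>
    dplyr::arrange(.data$subject, .data$predicate, .data$object)
}

#' Remap concept identifiers
#'
#' Replaces raw subject/object identifiers by canonical identifiers,
#' merging granular concepts into more general ones (the typical use is
#' mapping concept ids to a more general vocabulary so that, e.g., several
#' rhinitis variants collapse into a single allergic-rhinitis concept).
#' Identifiers absent from the map pass through unchanged and are counted
#' in the report. Triples made identical by the mapping are merged with
#' their publication-id sets unioned; triples whose subject equals their
#' object after mapping are dropped.
#'
#' @param triples A triple table (see [normalize_triples()]).
#' @param concept_map Data frame with columns `raw_id`, `canonical_id` and
#'   optionally `canonical_name`; many raw ids may share one canonical id.
#' @return Normalized triple table; attribute `"report"` holds counts of
#'   unmapped identifiers, merges and dropped self-loops. The canonical
#'   id -> name map (for node naming) is kept in attribute `"concept_names"`.
#' @export
remap_concepts <- function(triples, concept_map) {
  t <- normalize_triples(triples)
  cm <- tibble::as_tibble(concept_map)
  if (nrow(cm) > 0 && anyDuplicated(cm$raw_id)) {
    abort_schema("concept map raw ids must be unique")
  }
  lookup <- stats::setNames(as.character(cm$canonical_id), as.character(cm$raw_id))
  map_ids <- function(x) {
    y <- unname(lookup[x])
    ifelse(is.na(y), x, y)
  }
  n_unmapped <- sum(!unique(c(t$subject, t$object)) %in% names(lookup))
  t$subject <- map_ids(t$subject)
  t$object <- map_ids(t$object)
  n_self <- sum(t$subject == t$object)
  t <- t[t$subject != t$object, ]
  n_before <- nrow(t)
  out <- normalize_triples(t)
  names_map <- if ("canonical_name" %in% names(cm)) {
    dplyr::distinct(cm[, c("canonical_id", "canonical_name")])
  } else {
    NULL
  }
  attr(out, "report") <- list(
    n_unmapped_ids = n_unmapped,
    n_merged_triples = n_before - nrow(out),
    n_selfloops_dropped = n_self
  )
  attr(out, "concept_names") <- names_map
  out
}

#' Condense edge types of similar meaning
#'
#' Rewrites predicates class-by-class according to a condensation map keyed
#' on (source type, predicate, target type); for instance `PREVENTS`,
#' `DISRUPTS` and `INHIBITS` edges between drugs and disorders may all be
#' merged into `TREATS`. Classes mapped to `DROP` (or `NA`) are removed.
#' Triples merged by the rewrite have their publication sets unioned.
#'
#' @param triples A triple table.
#' @param condense_map Data frame with columns `source_type`, `predicate`,
#'   `target_type`, `replacement` (`"DROP"` or `NA` removes the class).
#'   Classes not listed pass through unchanged.
#' @return Normalized triple table.
#' @export
condense_edge_types <- function(triples, condense_map) {
  t <- normalize_triples(triples)
  cm <- tibble::as_tibble(condense_map)
  key <- paste(t$subject_type, t$predicate, t$object_type, sep = "\r")
  ckey <- paste(cm$source_type, cm$predicate, cm$target_type, sep = "\r")
  if (anyDuplicated(ckey)) abort_schema("condensation map classes must be unique")
  i <- match(key, ckey)
  repl <- as.character(cm$replacement)[i]
  drop <- !is.na(i) & (is.na(repl) | repl == "DROP")
  t <- t[!drop, ]
  repl <- repl[!drop]
  i <- i[!drop]
  t$predicate <- ifelse(is.na(i), t$predicate, repl)
  normalize_triples(t)
}

#' Assemble a hetnet from a cleaned triple table
#'
#' Aggregates triples into typed edges (one edge per source, target,
#' metaedge, with publication sets unioned), resolving undirected
#' metaedges to a canonical endpoint ordering and merging reversed
#' duplicates. Self-loops are dropped and counted in the report.
#'
#' @param triples A triple table.
#' @param mg Optional [metagraph()]; inferred with [infer_metagraph()] when
#'   omitted.
#' @param node_names Optional data frame `canonical_id`, `canonical_name`
#'   used to name nodes (e.g. the `"concept_names"` attribute of
#'   [remap_concepts()]).
#' @param ... Passed to [infer_metagraph()].
#' @return A [hetnet()] (edges undated; see [assign_edge_years()]).
#' @export
triples_to_hetnet <- function(triples, mg = NULL, node_names = NULL, ...) {
  t <- normalize_triples(triples)
  if (is.null(mg)) mg <- infer_metagraph(t, ...)
  class_key <- paste(t$subject_type, t$predicate, t$object_type, sep = "\r")
  me <- mg$metaedges
  me_key <- paste(me$source, me$predicate, me$target, sep = "\r")
  i <- match(class_key, me_key)
  if (anyNA(i)) {
    abort_schema(paste0(
      "triple classes not present in the metagraph: ",
      paste(utils::head(unique(class_key[is.na(i)]), 5), collapse = "; ")
    ))
  }
  t$metaedge <- me$label[i]
  directed <- me$directed[i]
  n_self <- sum(t$subject == t$object)
  keep <- t$subject != t$object
  t <- t[keep, ]
  directed <- directed[keep]
  swap <- !directed & t$subject > t$object
  s <- ifelse(swap, t$object, t$subject)
  o <- ifelse(swap, t$subject, t$object)
  edges <- tibble::tibble(source = s, target = o, metaedge = t$metaedge, pmids = t$pmids) |>
    dplyr::group_by(.data$source, .data$target, .data$metaedge) |>
    dplyr::summarise(pmids = list(sort_c(unique(unlist(pmids)))), .groups = "drop")
  ids <- tibble::tibble(
    id = c(t$subject, t$object),
    type = c(t$subject_type, t$object_type)
  ) |> dplyr::distinct()
  if (anyDuplicated(ids$id)) {
    abort_schema("some concept ids occur under more than one node type")
  }
  ids$name <- ids$id
  if (!is.null(node_names)) {
    j <- match(ids$id, node_names$canonical_id)
    ids$name <- ifelse(is.na(j), ids$id, node_names$canonical_name[j])
  }
  net <- hetnet(ids, edges, mg)
  attr(net, "report") <- list(n_selfloops_dropped = n_self)
  net
}

#' Remove sparsely populated edge types
#'
#' Deletes every metaedge whose share of the network's edges is strictly
#' below `min_fraction` (default 0.1%), together with all its edges, and
#' updates the metagraph.
#'
#' @param net A [hetnet()].
#' @param min_fraction Fraction threshold in `[0, 1)`; strict inequality.
#' @return Filtered hetnet.
#' @export
filter_sparse_edge_types <- function(net, min_fraction = 0.001) {
  if (!is_scalar_number(min_fraction) || min_fraction < 0 || min_fraction >= 1) {
    abort_config("min_fraction must lie in [0, 1)")
  }
  total <- nrow(net$edges)
  counts <- table(factor(net$edges$metaedge, levels = net$metagraph$metaedges$label))
  frac <- as.numeric(counts) / total
  drop <- names(counts)[frac < min_fraction]
  if (length(drop) == nrow(net$metagraph$metaedges)) {
    abort_empty("sparse-type filter would remove every metaedge")
  }
  net$edges <- net$edges[!net$edges$metaedge %in% drop, ]
  net$metagraph$metaedges <- net$metagraph$metaedges[
    !net$metagraph$metaedges$label %in% drop,
  ]
  net
}

#' Remove the highest-degree hub nodes
#'
#' Deletes the `n_top` nodes with the greatest total degree (incident edge
#' count summed over all metaedges and both ends) along with their incident
#' edges, eliminating extremely general concepts. Ties at the cutoff are
#' broken by lexicographic node id, so the operation is deterministic.
#'
#' @param net A [hetnet()].
#' @param n_top Number of nodes to remove (0 = identity).
#' @return Filtered hetnet.
#' @export
remove_hub_nodes <- function(net, n_top = 100) {
  if (!is_scalar_number(n_top) || n_top < 0) abort_config("n_top must be >= 0")
  if (n_top == 0) {
    return(net)
  }
  if (n_top >= nrow(net$nodes)) {
    abort_empty("hub removal would delete every node")
  }
  hubs <- total_degree(net)$id[seq_len(n_top)]
  net$nodes <- net$nodes[!net$nodes$id %in% hubs, ]
  net$edges <- net$edges[!(net$edges$source %in% hubs | net$edges$target %in% hubs), ]
  net
}

#' Remove weakly supported edges
#'
#' Drops edges supported by fewer than `min_pmids` publications (default 2,
#' suppressing one-off text-mining noise), then removes nodes left with no
#' edges.
#'
#' @param net A [hetnet()].
#' @param min_pmids Minimum publication-set size (>= 1; 1 = identity).
#' @return Filtered hetnet.
#' @export
filter_low_support_edges <- function(net, min_pmids = 2) {
  if (!is_scalar_number(min_pmids) || min_pmids < 1) abort_config("min_pmids must be >= 1")
  n_support <- lengths(net$edges$pmids)
  net$edges <- net$edges[n_support >= min_pmids, ]
  prune_network(net, drop_isolated = TRUE)
}

#' Full cleaning pipeline from raw triples to a hetnet
#'
#' Applies, in order: concept remapping, edge-type condensation, hetnet
#' assembly, sparse-edge-type filtering, hub removal, and the low-support
#' edge filter. The order is fixed and logged in the report so identical
#' inputs always give identical outputs.
#'
#' @param triples Raw triple table.
#' @param concept_map,condense_map Optional cleaning maps (see
#'   [remap_concepts()], [condense_edge_types()]).
#' @param sparse_fraction,hub_top,min_support Parameters of the three
#'   filters.
#' @param mg Optional explicit [metagraph()].
#' @param year_map Optional publication-year map; when given, edges are
#'   dated with [assign_edge_years()] as a final step.
#' @param ... Passed to [infer_metagraph()].
#' @return A cleaned [hetnet()]; attribute `"report"` records per-stage
#'   node/edge counts.
#' @export
build_hetnet <- function(triples, concept_map = NULL, condense_map = NULL,
                         sparse_fraction = 0.001, hub_top = 100, min_support = 2,
                         mg = NULL, year_map = NULL, ...) {
  report <- list()
  t <- normalize_triples(triples)
  node_names <- NULL
  if (!is.null(concept_map)) {
    t <- remap_concepts(t, concept_map)
    node_names <- attr(t, "concept_names")
    report$remap <- attr(t, "report")
  }
  if (!is.null(condense_map)) t <- condense_edge_types(t, condense_map)
  net <- triples_to_hetnet(t, mg = mg, node_names = node_names, ...)
  stage_counts <- function(net) c(nodes = nrow(net$nodes), edges = nrow(net$edges))
  report$assembled <- stage_counts(net)
  net <- filter_sparse_edge_types(net, sparse_fraction)
  report$after_sparse_filter <- stage_counts(net)
  net <- remove_hub_nodes(net, hub_top)
  report$after_hub_removal <- stage_counts(net)
  net <- filter_low_support_edges(net, min_support)
  report$after_support_filter <- stage_counts(net)
  if (!is.null(year_map)) net <- assign_edge_years(net, year_map)
  attr(net, "report") <- report
  net
}
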