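#' Construct a metagraph (hetnet schema)
#'
#' A metagraph declares the node types and typed edges (metaedges) of a
#' heterogeneous network. Each node type carries a short uppercase
#' abbreviation (e.g. `"Chemicals & Drugs"` -> `"CD"`) and each metaedge a
#' lowercase predicate abbreviation (e.g. `TREATS` -> `"t"`). The full
#' metaedge label concatenates the three: `CDtDO`. Directed metaedges
#' between a type and itself are disambiguated with an arrow marker
#' (`CDreg>CD`), matching the labelling convention of text-mined biomedical
#' hetnets.
#'
#' @param node_types Data frame with columns `type` and `abbrev`
#'   (uppercase, unique).
#' @param metaedges Data frame with columns `source`, `predicate`, `target`,
#'   `abbrev` (lowercase predicate abbreviation) and `directed` (logical).
#'   Undirected metaedges must connect a type to itself.
#'
#' @return An object of class `metagraph`: a list with tibbles `node_types`
#'   and `metaedges`, the latter gaining a `label` column with the full
#'   unique metaedge label.
#' @examples
#' mg <- metagraph(
#'   node_types = data.frame(type = c("Drug", "Disease"), abbrev = c("CD", "DO")),
#'   metaedges = data.frame(
#'     source = "Drug", predicate = "TREATS", target = "Disease",
#'     abbrev = "t", directed = TRUE
#'   )
#' )
#' mg$metaedges$label
#' @export
metagraph <- function(node_types, metaedges) {
  node_types <- tibble::as_tibble(node_types)[, c("type", "abbrev")]
  metaedges <- tibble::as_tibble(metaedges)[, c("source", "predicate", "target", "abbrev", "directed")]
  if (anyDuplicated(node_types$type) || anyDuplicated(node_types$abbrev)) {
    abort_schema("node types and node-type abbreviations must be unique")
  }
  if (!all(grepl("^[A-Z]+$", node_types$abbrev))) {
    abort_schema("node-type abbreviations must be uppercase letters")
  }
  if (!all(grepl("^[a-z]+$", metaedges$abbrev))) {
    abort_schema("metaedge predicate abbreviations must be lowercase letters")
  }
  bad <- setdiff(c(metaedges$source, metaedges$target), node_types$type)
  if (length(bad) > 0) {
    abort_schema(paste0("metaedge endpoint types not declared: ", paste(bad, collapse = ", ")))
  }
  if (any(!metaedges$directed & metaedges$source != metaedges$target)) {
    abort_schema("undirected metaedges must connect a node type to itself")
  }
  ab <- stats::setNames(node_types$abbrev, node_types$type)
  marker <- ifelse(metaedges$directed & metaedges$source == metaedges$target,
    paste0(metaedges$abbrev, ">"), metaedges$abbrev
  )
  metaedges$label <- paste0(ab[metaedges$source], marker, ab[metaedges$target])
  if (anyDuplicated(metaedges$label)) {
    abort_schema("metaedge labels must be unique across the metagraph")
  }
  structure(list(node_types = node_types, metaedges = metaedges), class = "metagraph")
}

#' @export
print.metagraph <- function(x, ...) {
  cat("<metagraph>", nrow(x$node_types), "node types,", nrow(x$metaedges), "metaedges\n")
  cat("node types:", paste0(x$node_types$type, " (", x$node_types$abbrev, ")", collapse = ", "), "\n")
  print(x$metaedges, n = Inf)
  invisible(x)
}

type_abbrev <- function(mg, type) {
  i <- match(type, mg$node_types$type)
  if (anyNA(i)) abort_identifier(paste0("unknown node type: ", paste(type[is.na(i)], collapse = ", ")))
  mg$node_types$abbrev[i]
}

metaedge_row <- function(mg, label) {
  i <- match(label, mg$metaedges$label)
  if (anyNA(i)) {
    abort_identifier(paste0("unknown metaedge: ", paste(label[is.na(i)], collapse = ", ")))
  }
  mg$metaedges[i, , drop = FALSE]
}

#' Derive unique predicate abbreviations
#'
#' Lowercases the initial letters of each underscore- or space-separated word
#' of a predicate (e.g. `RELATED_TO` -> `rt`, `ASSOCIATED_WITH` -> `aw`) and
#' extends single-word abbreviations letter by letter until all requested
#' predicates are distinct.
#'
#' @param predicates Character vector of predicate names.
#' @return Named character vector of lowercase abbreviations.
#' @examples
#' abbreviate_predicates(c("TREATS", "RELATED_TO", "REGULATES"))
#' @export
abbreviate_predicates <- function(predicates) {
  predicates <- unique(predicates)
  words <- strsplit(predicates, "[_ ]+")
  base <- vapply(words, function(w) tolower(paste0(substr(w, 1, 1), collapse = "")), "")
  out <- base
  k <- 1L
  while (anyDuplicated(out)) {
    k <- k + 1L
    dup <- out %in% out[duplicated(out)]
    out[dup] <- vapply(which(dup), function(i) {
      w <- words[[i]]
      if (length(w) == 1L) tolower(substr(w, 1, k)) else tolower(paste0(substr(w, 1, k), collapse = ""))
    }, "")
    if (k > 12L) abort_schema("could not derive unique predicate abbreviations")
  }
  stats::setNames(out, predicates)
}

#' Derive a metagraph from a triple table
#'
#' Builds a [metagraph()] whose node types are the distinct subject/object
#' types of a triple table and whose metaedges are the distinct
#' (source type, predicate, target type) classes. Node-type abbreviations
#' are the uppercase initials of each type (extended until unique);
#' predicate abbreviations come from [abbreviate_predicates()].
#'
#' @param triples Triple table (see [remap_concepts()] for the layout).
#' @param undirected_predicates Predicates treated as undirected when they
#'   connect a node type to itself.
#' @return A `metagraph`.
#' @export
infer_metagraph <- function(triples,
                            undirected_predicates = c(
                              "RELATED_TO", "ASSOCIATED_WITH",
                              "INTERACTS_WITH", "COEXISTS_WITH"
                            )) {
  triples <- normalize_triples(triples)
  types <- sort_c(unique(c(triples$subject_type, triples$object_type)))
  ab <- toupper(vapply(strsplit(types, "[_ &]+"), function(w) paste0(substr(w, 1, 1), collapse = ""), ""))
  k <- 1L
  while (anyDuplicated(ab)) {
    k <- k + 1L
    dup <- ab %in% ab[duplicated(ab)]
    ab[dup] <- toupper(substr(gsub("[_ &]+", "", types[dup]), 1, k))
  }
  classes <- dplyr::distinct(triples, source = .data$subject_type, predicate = .data$predicate,
    target = .data$object_type
  )
  classes <- classes[order_c(classes$source, classes$predicate, classes$target), ]
  pred_ab <- abbreviate_predicates(classes$predicate)
  classes$abbrev <- unname(pred_ab[classes$predicate])
  classes$directed <- !(classes$source == classes$target &
    classes$predicate %in% undirected_predicates)
  metagraph(tibble::tibble(type = types, abbrev = ab), classes)
}

#' Read or write a metagraph as YAML
#'
#' The on-disk form is a structured text file with a `node_types` mapping
#' (type -> abbreviation) and a `metaedges` list of
#' `{source, predicate, target, abbrev, directed}` entries.
#'
#' @param path File path.
#' @param mg A `metagraph`.
#' @return `read_metagraph()` returns a `metagraph`; `write_metagraph()`
#'   returns `path` invisibly.
#' @export
read_metagraph <- function(path) {
  y <- yaml::read_yaml(path)
  nt <- tibble::tibble(type = names(y$node_types), abbrev = unlist(y$node_types, use.names = FALSE))
  me <- dplyr::bind_rows(lapply(y$metaedges, tibble::as_tibble))
  metagraph(nt, me)
}

#' @rdname read_metagraph
#' @export
write_metagraph <- function(mg, path) {
  y <- list(
    node_types = as.list(stats::setNames(mg$node_types$abbrev, mg$node_types$type)),
    metaedges = lapply(seq_len(nrow(mg$metaedges)), function(i) {
      r <- mg$metaedges[i, ]
      list(
        source = r$source, predicate = r$predicate, target = r$target,
        abbrev = r$abbrev, directed = r$directed
      )
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
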