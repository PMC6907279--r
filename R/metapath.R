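#' Metapaths: typed path templates through a metagraph
#'
#' A metapath is an ordered chain of metaedge traversals from a source node
#' type to a target node type. Undirected metaedges may be traversed in
#' either sense; directed metaedges may be traversed forward or backward,
#' and a backward traversal is a distinct step (the well-known drug-drug
#' co-localisation template `CDloAloCDtDO`, for instance, traverses an
#' `Anatomy-LOCATION_OF->Chemicals & Drugs` metaedge against its arrow).
#'
#' `new_metapath()` assembles a metapath from explicit steps;
#' `metapath_label()` returns its label; `parse_metapath()` inverts the
#' label back into steps.
#'
#' @param mg A [metagraph()].
#' @param metaedges Character vector of metaedge labels, one per step.
#' @param directions Character vector, `"forward"` or `"backward"` per step.
#' @return A `metapath` object: list with `steps` (tibble of `metaedge`,
#'   `direction`, `from_type`, `to_type`), `source_type`, `target_type`,
#'   `length` and `label`.
#' @export
new_metapath <- function(mg, metaedges, directions = rep("forward", length(metaedges))) {
  stopifnot(length(metaedges) == length(directions), length(metaedges) >= 1L)
  rows <- metaedge_row(mg, metaedges)
  from <- ifelse(directions == "forward", rows$source, rows$target)
  to <- ifelse(directions == "forward", rows$target, rows$source)
  if (length(metaedges) > 1L && any(to[-length(to)] != from[-1L])) {
    abort_schema("metapath steps do not chain: target type of each step must equal source type of the next")
  }
  steps <- tibble::tibble(
    metaedge = metaedges, direction = directions,
    from_type = from, to_type = to
  )
  mp <- structure(
    list(
      steps = steps, source_type = from[1L], target_type = to[length(to)],
      length = nrow(steps), label = NA_character_
    ),
    class = "metapath"
  )
  mp$label <- build_metapath_label(mg, mp)
  mp
}

build_metapath_label <- function(mg, mp) {
  rows <- metaedge_row(mg, mp$steps$metaedge)
  segs <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$directed && r$source == r$target) {
      segs[i] <- if (mp$steps$direction[i] == "forward") paste0(r$abbrev, ">") else paste0("<", r$abbrev)
    } else {
      segs[i] <- r$abbrev
    }
  }
  nodes <- type_abbrev(mg, c(mp$steps$from_type, mp$target_type))
  paste0(nodes[1L], paste0(segs, nodes[-1L], collapse = ""))
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath>", x$label, " (", x$source_type, "->", x$target_type,
    ", length ", x$length, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname new_metapath
#' @param label A metapath label such as `"CDrtCDtDO"`.
#' @export
parse_metapath <- function(mg, label) {
  toks <- stringr::str_extract_all(label, "[A-Z]+|[a-z<>]+")[[1]]
  if (paste0(toks, collapse = "") != label || length(toks) < 3L || length(toks) %% 2L != 1L) {
    abort_schema(paste0("cannot tokenize metapath label: ", label))
  }
  node_toks <- toks[seq(1L, length(toks), by = 2L)]
  edge_toks <- toks[seq(2L, length(toks), by = 2L)]
  ti <- match(node_toks, mg$node_types$abbrev)
  if (anyNA(ti)) abort_schema(paste0("unknown node-type abbreviation in label: ", label))
  types <- mg$node_types$type[ti]
  me <- mg$metaedges
  metaedges <- character(length(edge_toks))
  directions <- character(length(edge_toks))
  for (i in seq_along(edge_toks)) {
    tok <- edge_toks[i]
    a <- types[i]
    b <- types[i + 1L]
    if (grepl(">", tok, fixed = TRUE)) { # directed self-type, forward
      core <- sub(">", "", tok, fixed = TRUE)
      hit <- which(me$source == a & me$target == b & me$abbrev == core & me$directed)
      dir <- "forward"
    } else if (grepl("<", tok, fixed = TRUE)) { # directed self-type, backward
      core <- sub("<", "", tok, fixed = TRUE)
      hit <- which(me$source == b & me$target == a & me$abbrev == core & me$directed)
      dir <- "backward"
    } else {
      fwd <- which(me$source == a & me$target == b & me$abbrev == tok &
        !(me$directed & me$source == me$target))
      bwd <- which(me$source == b & me$target == a & me$abbrev == tok & me$directed & b != a)
      if (length(fwd) > 0 && length(bwd) > 0) {
        abort_schema(paste0("ambiguous step '", tok, "' between ", a, " and ", b, " in ", label))
      }
      hit <- c(fwd, bwd)
      dir <- if (length(bwd) > 0) "backward" else "forward"
    }
    if (length(hit) != 1L) {
      abort_schema(paste0("no metaedge matches step '", tok, "' between ", a, " and ", b, " in ", label))
    }
    metaedges[i] <- me$label[hit]
    directions[i] <- dir
  }
  new_metapath(mg, metaedges, directions)
}

#' Enumerate metapaths between two node types
#'
#' Lists every metapath of length at most `max_length` from `source_type` to
#' `target_type`. Undirected metaedges are traversed in one canonical sense
#' (their two orientations are the same step); directed metaedges are
#' traversed forward or backward, each a distinct step direction.
#'
#' @param mg A [metagraph()].
#' @param source_type,target_type Declared node types.
#' @param max_length Maximum number of steps (>= 1).
#' @return A tibble with columns `label`, `length` and a list-column
#'   `metapath` of `metapath` objects, ordered by length then label.
#' @examples
#' mg <- metagraph(
#'   data.frame(type = c("Drug", "Disease"), abbrev = c("CD", "DO")),
#'   data.frame(
#'     source = c("Drug", "Drug", "Disease"),
#'     predicate = c("TREATS", "RELATED_TO", "ASSOCIATED_WITH"),
#'     target = c("Disease", "Drug", "Disease"),
#'     abbrev = c("t", "rt", "aw"), directed = c(TRUE, FALSE, FALSE)
#'   )
#' )
#' enumerate_metapaths(mg, "Drug", "Disease", max_length = 2)$label
#' @export
enumerate_metapaths <- function(mg, source_type, target_type, max_length) {
  if (!is_scalar_number(max_length) || max_length < 1) {
    abort_config("max_length must be a number >= 1")
  }
  type_abbrev(mg, c(source_type, target_type)) # validates
  me <- mg$metaedges
  # steps available from a given node type
  steps_from <- function(type) {
    fwd <- which(me$source == type)
    bwd <- which(me$target == type & me$directed)
    tibble::tibble(
      idx = c(fwd, bwd),
      direction = c(rep("forward", length(fwd)), rep("backward", length(bwd))),
      to = c(me$target[fwd], me$source[bwd])
    )
  }
  out <- list()
  recurse <- function(cur_type, mes, dirs) {
    if (length(mes) >= 1L && cur_type == target_type) {
      out[[length(out) + 1L]] <<- new_metapath(mg, mes, dirs)
    }
    if (length(mes) == max_length) {
      return(invisible())
    }
    st <- steps_from(cur_type)
    for (j in seq_len(nrow(st))) {
      recurse(st$to[j], c(mes, me$label[st$idx[j]]), c(dirs, st$direction[j]))
    }
  }
  recurse(source_type, character(), character())
  labs <- vapply(out, function(m) m$label, "")
  lens <- vapply(out, function(m) m$length, 1L)
  o <- order_c(lens, labs)
  tibble::tibble(label = labs[o], length = lens[o], metapath = out[o])
}
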