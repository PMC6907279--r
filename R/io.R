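#' Read and write hetnets as tab-separated tables
#'
#' The on-disk form is two UTF-8 TSV tables: a node table with columns
#' `id`, `name`, `type`, and an edge table with columns `source`, `target`,
#' `metaedge`, `pmids` (pipe-joined publication ids, may be empty) and
#' `year` (empty when undated). Reading after writing reproduces the same
#' hetnet up to row order; malformed rows are reported with their line
#' numbers.
#'
#' @param node_path,edge_path Paths of the node and edge tables.
#' @param mg A [metagraph()] or the path of a YAML metagraph file.
#' @param net A [hetnet()].
#' @return `read_hetnet()` returns a `hetnet`; `write_hetnet()` returns the
#'   paths invisibly.
#' @export
read_hetnet <- function(node_path, edge_path, mg) {
  if (is.character(mg)) mg <- read_metagraph(mg)
  nodes <- readr::read_tsv(node_path,
    col_types = readr::cols(
      id = readr::col_character(), name = readr::col_character(),
      type = readr::col_character()
    ), progress = FALSE
  )
  edges <- readr::read_tsv(edge_path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      metaedge = readr::col_character(), pmids = readr::col_character(),
      year = readr::col_integer()
    ), progress = FALSE, na = ""
  )
  need_n <- c("id", "type")
  if (!all(need_n %in% names(nodes))) abort_schema("node table must have columns id, name, type")
  need_e <- c("source", "target", "metaedge")
  if (!all(need_e %in% names(edges))) {
    abort_schema("edge table must have columns source, target, metaedge, pmids, year")
  }
  bad <- which(is.na(edges$source) | is.na(edges$target) | is.na(edges$metaedge))
  if (length(bad) > 0) {
    abort_schema(paste0(
      "malformed edge rows (missing fields) at lines ",
      paste(bad + 1L, collapse = ", ") # +1 for the header line
    ))
  }
  missing <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
  if (any(missing)) {
    abort_integrity(paste0(
      "edge rows reference absent nodes at lines ",
      paste(utils::head(which(missing), 10) + 1L, collapse = ", ")
    ))
  }
  unknown_me <- !(edges$metaedge %in% mg$metaedges$label)
  if (any(unknown_me)) {
    abort_schema(paste0(
      "edge rows with unknown metaedge at lines ",
      paste(utils::head(which(unknown_me), 10) + 1L, collapse = ", ")
    ))
  }
  tryCatch(
    hetnet(nodes, edges, mg),
    hetpath_schema_error = function(e) {
      abort_schema(paste0("edge table invalid: ", conditionMessage(e)))
    }
  )
}

#' @rdname read_hetnet
#' @param metagraph_path Optional path for the YAML metagraph (omit to skip).
#' @export
write_hetnet <- function(net, node_path, edge_path, metagraph_path = NULL) {
  readr::write_tsv(net$nodes, node_path, progress = FALSE)
  e <- net$edges
  out <- tibble::tibble(
    source = e$source, target = e$target, metaedge = e$metaedge,
    pmids = vapply(e$pmids, paste, "", collapse = "|"),
    year = e$year
  )
  readr::write_tsv(out, edge_path, na = "", progress = FALSE)
  if (!is.null(metagraph_path)) write_metagraph(net$metagraph, metagraph_path)
  invisible(c(node_path, edge_path))
}

#' Read a raw triple table
#'
#' Accepts tab- or comma-separated text with columns `subject`,
#' `subject_type`, `predicate`, `object`, `object_type`, `pmid` (one
#' subject-predicate-object assertion per row, each supported by one
#' publication id).
#'
#' @param path File path (`.tsv`/`.txt` read as TSV, `.csv` as CSV).
#' @return A tibble of triples.
#' @export
read_triples <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  t <- reader(path, col_types = readr::cols(.default = readr::col_character()), progress = FALSE)
  need <- c("subject", "subject_type", "predicate", "object", "object_type", "pmid")
  if (!all(need %in% names(t))) {
    abort_schema(paste0("triple table must have columns: ", paste(need, collapse = ", ")))
  }
  bad <- which(is.na(t$pmid) | t$pmid == "")
  if (length(bad) > 0) {
    warn(paste0(
      length(bad), " triple rows without a publication id dropped (lines ",
      paste(utils::head(bad, 10) + 1L, collapse = ", "), ")"
    ))
    t <- t[-bad, ]
  }
  t[need]
}

#' Read a publication-year map
#'
#' Two-column TSV `pmid`, `year` mapping publication ids to 4-digit years.
#'
#' @param path File path.
#' @return Tibble with columns `pmid` (character) and `year` (integer).
#' @export
read_year_map <- function(path) {
  ym <- readr::read_tsv(path,
    col_types = readr::cols(pmid = readr::col_character(), year = readr::col_integer()),
    progress = FALSE
  )
  validate_year_map(ym)
}

validate_year_map <- function(ym) {
  ym <- tibble::as_tibble(ym)[, c("pmid", "year")]
  ym$pmid <- as.character(ym$pmid)
  ym$year <- as.integer(ym$year)
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad <- !is.na(ym$year) & (ym$year < 1900L | ym$year > this_year)
  if (any(bad)) {
    abort_schema(paste0(sum(bad), " publication years outside [1900, ", this_year, "]"))
  }
  dplyr::distinct(ym, .data$pmid, .keep_all = TRUE)
}

#' Read a gold-standard indication table
#'
#' TSV with columns `drug`, `disease`, `approval_year` (first worldwide
#' approval year of the drug for that indication, used as the indication's
#' date proxy).
#'
#' @param path File path.
#' @return Tibble of positive indications.
#' @export
read_indications <- function(path) {
  ind <- readr::read_tsv(path,
    col_types = readr::cols(
      drug = readr::col_character(), disease = readr::col_character(),
      approval_year = readr::col_integer()
    ), progress = FALSE
  )
  if (anyDuplicated(paste(ind$drug, ind$disease))) {
    abort_schema("(drug, disease) pairs must be unique in the indication table")
  }
  ind
}
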