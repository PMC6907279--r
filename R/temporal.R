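#' Date edges by their earliest supporting publication
#'
#' Sets each edge's `year` to the minimum publication year among its
#' supporting publication ids found in the year map. Edges none of whose
#' publication ids can be mapped remain undated (`NA`): they are kept in
#' the full network but excluded from every time slice, since an assertion
#' that cannot be dated cannot be placed in a past state of knowledge.
#'
#' @param net A [hetnet()].
#' @param year_map Data frame `pmid`, `year` (see [read_year_map()]).
#' @return The dated hetnet; attribute `"report"` counts undated edges.
#' @export
assign_edge_years <- function(net, year_map) {
  ym <- validate_year_map(year_map)
  lookup <- stats::setNames(ym$year, ym$pmid)
  yrs <- vapply(net$edges$pmids, function(p) {
    v <- lookup[p]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_integer_ else min(v)
  }, integer(1))
  net$edges$year <- yrs
  attr(net, "report") <- list(n_undated = sum(is.na(yrs)), n_dated = sum(!is.na(yrs)))
  net
}

#' Time slice of a dated hetnet
#'
#' Retains only edges whose earliest supporting publication year is less
#' than or equal to `year`, approximating the state of knowledge at that
#' year. Undated edges are excluded; nodes left with no edges and
#' metaedges left with no instances are removed from the slice.
#'
#' @param net A dated [hetnet()].
#' @param year Integer slice year.
#' @return The sliced hetnet.
#' @export
slice_network <- function(net, year) {
  if (!is_scalar_number(year)) abort_config("year must be a single number")
  net$edges <- net$edges[!is.na(net$edges$year) & net$edges$year <= year, ]
  prune_network(net, drop_isolated = TRUE, drop_empty_metaedges = TRUE)
}

#' Default slice-year grid
#'
#' @param from,to,by Year range and interval; the default follows the
#'   5-year grid from 1950 to 2015.
#' @return Integer vector of slice years.
#' @export
slice_grid <- function(from = 1950, to = 2015, by = 5) {
  seq(as.integer(from), as.integer(to), by = as.integer(by))
}

#' Split indications into past (train) and future (test) sets
#'
#' Positives approved in years up to and including the network year go to
#' the training split; those approved after it form the test split. Any
#' positive whose drug or disease is no longer connected to the sliced
#' network is dropped from both.
#'
#' @param indications Tibble `drug`, `disease`, `approval_year` of positive
#'   indications.
#' @param net_slice The [slice_network()] output for `year`.
#' @param year The slice year.
#' @return The indication tibble with an added `split` column in
#'   `c("train", "test", "dropped")`.
#' @export
split_indications <- function(indications, net_slice, year) {
  ind <- tibble::as_tibble(indications)
  present <- ind$drug %in% net_slice$nodes$id & ind$disease %in% net_slice$nodes$id
  ind$split <- dplyr::case_when(
    !present ~ "dropped",
    ind$approval_year <= year ~ "train",
    TRUE ~ "test"
  )
  ind
}
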