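#' Configuration of the synthetic study generator
#'
#' Describes a small dated hetnet with drug-like and disease-like node
#' types and a gold standard of planted indications, so the whole
#' pipeline — build, slicing, DWPC extraction, learning, time-split
#' evaluation and ablations — can be exercised end-to-end with recoverable
#' signal.
#'
#' The signal is planted at the path level: each positive indication gets
#' `effect_size` supporting paths per planted metapath (default the
#' drug-drug-similarity template `CDrtCDtDO` and the
#' disease-disease-similarity template `CDtDOawDO`), whose edges are dated
#' within `signal_lead` years before the approval year. Effect size 0
#' produces pure-noise positives. The fractional part of `effect_size` is
#' the probability of one extra path, so integer values plant
#' deterministically many paths.
#'
#' @param seed Integer seed; the whole generator is a deterministic
#'   function of the configuration.
#' @param n_drugs,n_diseases,n_anatomy,n_phenomena Node counts per type.
#' @param mean_degree Target mean degree per metaedge for the background
#'   edges: a single number or a vector named by metaedge label.
#' @param years Two-element year range of the literature.
#' @param growth_rate Per-year multiplicative growth of edge arrivals;
#'   later years are denser, so cumulative edge counts grow superlinearly.
#' @param n_positives Number of planted gold-standard indications.
#' @param planted_metapaths Metapath labels along which support paths are
#'   planted.
#' @param effect_size Expected number of support paths per planted
#'   metapath and positive (0 = pure noise).
#' @param signal_lead Maximum number of years before approval at which a
#'   support path appears in the literature.
#' @param undated_fraction Fraction of background edges whose publication
#'   ids are withheld from the year map (undated edges).
#' @param pmid_lambda Poisson rate of extra publications per edge (sizes
#'   are `1 + Poisson(pmid_lambda)`).
#' @param approval_range Two-element range of approval years.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 42,
                         n_drugs = 60, n_diseases = 40,
                         n_anatomy = 12, n_phenomena = 12,
                         mean_degree = 2.5,
                         years = c(1950, 2015), growth_rate = 0.05,
                         n_positives = 40,
                         planted_metapaths = c("CDrtCDtDO", "CDtDOawDO"),
                         effect_size = 2,
                         signal_lead = 8,
                         undated_fraction = 0.02,
                         pmid_lambda = 1.5,
                         approval_range = c(1960, 2010)) {
  if (any(c(n_drugs, n_diseases, n_anatomy, n_phenomena, n_positives) <= 0)) {
    abort_config("all counts must be positive")
  }
  if (!is.numeric(effect_size) || effect_size < 0) abort_config("effect_size must be >= 0")
  structure(
    list(
      seed = as.integer(seed), n_drugs = n_drugs, n_diseases = n_diseases,
      n_anatomy = n_anatomy, n_phenomena = n_phenomena,
      mean_degree = mean_degree, years = as.integer(years),
      growth_rate = growth_rate, n_positives = n_positives,
      planted_metapaths = planted_metapaths, effect_size = effect_size,
      signal_lead = as.integer(signal_lead),
      undated_fraction = undated_fraction, pmid_lambda = pmid_lambda,
      approval_range = as.integer(approval_range)
    ),
    class = "synth_config"
  )
}

#' Metagraph of the synthetic study
#'
#' Four node types (drug-like `Chemicals & Drugs`, disease-like
#' `Disorders`, `Anatomy`, `Phenomena`) and six metaedges, including
#' analogues of the treatment edge (`CDtDO`), the drug-drug similarity
#' edge (`CDrtCD`, undirected) and the disease-disease similarity edge
#' (`DOawDO`, undirected).
#'
#' @return A [metagraph()].
#' @export
synth_metagraph <- function() {
  metagraph(
    node_types = tibble::tibble(
      type = c("Chemicals & Drugs", "Disorders", "Anatomy", "Phenomena"),
      abbrev = c("CD", "DO", "A", "PH")
    ),
    metaedges = tibble::tibble(
      source = c("Chemicals & Drugs", "Chemicals & Drugs", "Disorders", "Anatomy", "Anatomy", "Chemicals & Drugs"),
      predicate = c("TREATS", "RELATED_TO", "ASSOCIATED_WITH", "LOCATION_OF", "LOCATION_OF", "AFFECTS"),
      target = c("Disorders", "Chemicals & Drugs", "Disorders", "Chemicals & Drugs", "Disorders", "Phenomena"),
      abbrev = c("t", "rt", "aw", "lo", "lo", "af"),
      directed = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
    )
  )
}

# sample n years from the range with arrival weight (1+g)^(y - y0):
# an exponential-growth model of the literature, so cumulative counts rise
# superlinearly and later slices are markedly denser
sample_years <- function(n, years, growth_rate) {
  span <- years[1]:years[2]
  w <- (1 + growth_rate)^(span - years[1])
  sample(span, n, replace = TRUE, prob = w)
}

# internal edge-record accumulator; pmids are materialized at the end
new_record <- function(source, target, metaedge, year, n_pmids) {
  tibble::tibble(
    source = source, target = target, metaedge = metaedge,
    year = as.integer(year), n_pmids = as.integer(n_pmids)
  )
}

# turn records into a pmid-carrying edge table and year map; records of the
# same (source, target, metaedge) merge with publication sets unioned
materialize_records <- function(records, mg, cfg, pmid_start = 1L, undated_fraction = 0) {
  undir <- mg$metaedges$label[!mg$metaedges$directed]
  swap <- records$metaedge %in% undir & records$source > records$target
  s <- ifelse(swap, records$target, records$source)
  records$target <- ifelse(swap, records$source, records$target)
  records$source <- s
  records <- records[order_c(records$metaedge, records$source, records$target, records$year), ]
  n_pm <- records$n_pmids
  pmid_ids <- sprintf("PM%06d", seq(pmid_start, length.out = sum(n_pm)))
  rec_of_pmid <- rep(seq_len(nrow(records)), n_pm)
  first_of_rec <- !duplicated(rec_of_pmid)
  extra_years <- sample(0:15, sum(n_pm), replace = TRUE)
  pmid_years <- records$year[rec_of_pmid] + ifelse(first_of_rec, 0L, extra_years)
  pmid_years <- pmin(pmid_years, max(cfg$years))
  records$pmids <- split(pmid_ids, rec_of_pmid)[as.character(seq_len(nrow(records)))]
  edges <- records |>
    dplyr::group_by(.data$source, .data$target, .data$metaedge) |>
    dplyr::summarise(pmids = list(sort_c(unique(unlist(pmids)))), .groups = "drop")
  year_map <- tibble::tibble(pmid = pmid_ids, year = as.integer(pmid_years))
  if (undated_fraction > 0) {
    n_hide <- floor(undated_fraction * nrow(edges))
    if (n_hide > 0) {
      hide <- sample.int(nrow(edges), n_hide)
      hidden_pmids <- unlist(edges$pmids[hide])
      year_map <- year_map[!year_map$pmid %in% hidden_pmids, ]
    }
  }
  list(edges = edges, year_map = year_map)
}

#' Generate a dated synthetic hetnet
#'
#' Draws background edges for every metaedge of [synth_metagraph()] with
#' endpoint pairs sampled uniformly (no self-loops, no duplicates), years
#' drawn from an exponentially growing arrival process, and per-edge
#' publication sets of size `1 + Poisson(pmid_lambda)` whose earliest
#' member dates the edge. A configurable fraction of edges is left
#' undated.
#'
#' @param cfg A [synth_config()].
#' @return List with the dated `net` ([hetnet()]) and the `year_map`
#'   tibble.
#' @export
generate_temporal_hetnet <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  mg <- synth_metagraph()
  nodes <- tibble::tibble(
    id = c(
      sprintf("C%03d", seq_len(cfg$n_drugs)),
      sprintf("D%03d", seq_len(cfg$n_diseases)),
      sprintf("A%03d", seq_len(cfg$n_anatomy)),
      sprintf("P%03d", seq_len(cfg$n_phenomena))
    ),
    type = rep(
      c("Chemicals & Drugs", "Disorders", "Anatomy", "Phenomena"),
      c(cfg$n_drugs, cfg$n_diseases, cfg$n_anatomy, cfg$n_phenomena)
    )
  )
  nodes$name <- nodes$id
  type_ids <- split(nodes$id, nodes$type)
  with_seed(cfg$seed, {
    records <- purrr::map_dfr(seq_len(nrow(mg$metaedges)), function(i) {
      me <- mg$metaedges[i, ]
      src_ids <- type_ids[[me$source]]
      tgt_ids <- type_ids[[me$target]]
      d <- if (length(cfg$mean_degree) > 1) cfg$mean_degree[[me$label]] else cfg$mean_degree
      same <- me$source == me$target
      n_edges <- if (same && !me$directed) {
        round(d * length(src_ids) / 2)
      } else {
        round(d * length(src_ids))
      }
      n_pairs <- if (same) length(src_ids) * (length(src_ids) - 1L) else length(src_ids) * length(tgt_ids)
      if (!me$directed) n_pairs <- n_pairs / 2
      if (n_edges > n_pairs) {
        abort_config(paste0("infeasible degree target for metaedge ", me$label))
      }
      # rejection-free draw: sample pair indices without replacement
      pool <- tidyr::expand_grid(source = src_ids, target = tgt_ids)
      pool <- pool[pool$source != pool$target, ]
      if (!me$directed) pool <- pool[pool$source < pool$target, ]
      take <- pool[sample.int(nrow(pool), n_edges), ]
      new_record(
        take$source, take$target, me$label,
        sample_years(n_edges, cfg$years, cfg$growth_rate),
        1L + stats::rpois(n_edges, cfg$pmid_lambda)
      )
    })
    mat <- materialize_records(records, mg, cfg, undated_fraction = cfg$undated_fraction)
    net <- hetnet(nodes, mat$edges, mg)
    net <- assign_edge_years(net, mat$year_map)
    list(net = net, year_map = mat$year_map)
  })
}

#' Plant a gold standard of indications into a synthetic hetnet
#'
#' Samples distinct drug-disease pairs with approval years spread across
#' the configured range and plants their supporting structure: for each
#' planted metapath, `effect_size` support paths through fresh helper
#' nodes (a related drug that already treats the disease; a treated
#' disease associated with the target disease), dated within
#' `signal_lead` years before approval, plus the indication's own
#' treatment edge dated shortly *after* approval. With `effect_size = 0`
#' the positives are uniform random pairs with no planted structure.
#'
#' @param net The hetnet from [generate_temporal_hetnet()].
#' @param cfg The same [synth_config()].
#' @param year_map The generator's year map (extended with the planted
#'   publications).
#' @return List with `indications` (tibble `drug`, `disease`,
#'   `approval_year`, `label`), the augmented `net`, and the extended
#'   `year_map`.
#' @export
generate_gold_standard <- function(net, cfg, year_map) {
  stopifnot(inherits(cfg, "synth_config"))
  drugs <- nodes_of_type(net, "Chemicals & Drugs")
  diseases <- nodes_of_type(net, "Disorders")
  if (cfg$n_positives > length(drugs) * length(diseases) / 2) {
    abort_config("not enough eligible drug-disease pairs for the requested positives")
  }
  with_seed(cfg$seed + 1L, {
    pool <- tidyr::expand_grid(drug = drugs, disease = diseases)
    ind <- pool[sample.int(nrow(pool), cfg$n_positives), ]
    ind$approval_year <- sample(
      cfg$approval_range[1]:cfg$approval_range[2],
      cfg$n_positives,
      replace = TRUE
    )
    ind$label <- "positive"
    records <- list()
    n_paths <- function() {
      floor(cfg$effect_size) +
        stats::rbinom(1L, 1L, cfg$effect_size - floor(cfg$effect_size))
    }
    if (cfg$effect_size > 0) {
      for (i in seq_len(nrow(ind))) {
        d <- ind$drug[i]
        e <- ind$disease[i]
        ay <- ind$approval_year[i]
        for (mp_label in cfg$planted_metapaths) {
          for (j in seq_len(n_paths())) {
            lead <- sample.int(cfg$signal_lead, 1L)
            yr <- max(cfg$years[1], ay - lead)
            if (mp_label == "CDrtCDtDO") {
              helper <- sample(setdiff(drugs, d), 1L)
              records[[length(records) + 1L]] <-
                new_record(d, helper, "CDrtCD", yr, 2L)
              records[[length(records) + 1L]] <-
                new_record(helper, e, "CDtDO", yr, 2L)
            } else if (mp_label == "CDtDOawDO") {
              helper <- sample(setdiff(diseases, e), 1L)
              records[[length(records) + 1L]] <-
                new_record(d, helper, "CDtDO", yr, 2L)
              records[[length(records) + 1L]] <-
                new_record(helper, e, "DOawDO", yr, 2L)
            } else {
              abort_config(paste0("no planting rule for metapath ", mp_label))
            }
          }
        }
        # the indication's own treatment edge enters the literature after approval
        records[[length(records) + 1L]] <-
          new_record(d, e, "CDtDO", min(cfg$years[2], ay + sample.int(3L, 1L)), 2L)
      }
    }
    if (length(records) > 0) {
      existing_max <- max(c(0L, as.integer(sub("^PM", "", unlist(net$edges$pmids)))))
      mat <- materialize_records(
        dplyr::bind_rows(records), net$metagraph, cfg,
        pmid_start = existing_max + 1L, undated_fraction = 0
      )
      year_map <- dplyr::bind_rows(year_map, mat$year_map)
      merged <- dplyr::bind_rows(net$edges[, c("source", "target", "metaedge", "pmids")], mat$edges) |>
        dplyr::group_by(.data$source, .data$target, .data$metaedge) |>
        dplyr::summarise(pmids = list(sort_c(unique(unlist(pmids)))), .groups = "drop")
      net <- hetnet(net$nodes, merged, net$metagraph)
      net <- assign_edge_years(net, year_map)
    }
    list(indications = ind[, c("drug", "disease", "approval_year", "label")], net = net, year_map = year_map)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_temporal_hetnet()] and
#' [generate_gold_standard()].
#'
#' @param cfg A [synth_config()].
#' @return List with `net`, `year_map`, `indications`, and the `config`.
#' @export
generate_synthetic_study <- function(cfg = synth_config()) {
  g <- generate_temporal_hetnet(cfg)
  gs <- generate_gold_standard(g$net, cfg, g$year_map)
  list(net = gs$net, year_map = gs$year_map, indications = gs$indications, config = cfg)
}
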