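#' Randomly drop edges of one metaedge
#'
#' Removes a uniformly sampled `floor(rate/100 * n)` of the metaedge's
#' edge instances (without replacement, reproducible under `seed`); all
#' other metaedges are untouched. Degrees and features downstream are
#' recomputed from the perturbed network.
#'
#' @param net A [hetnet()].
#' @param metaedge Metaedge label.
#' @param rate Dropout percentage in `(0, 100]`.
#' @param seed Integer seed.
#' @return The perturbed hetnet.
#' @export
dropout_edges <- function(net, metaedge, rate, seed = 1) {
  metaedge_row(net$metagraph, metaedge)
  if (!is_scalar_number(rate) || rate <= 0 || rate > 100) {
    abort_config("dropout rate must lie in (0, 100]")
  }
  idx <- which(net$edges$metaedge == metaedge)
  n_remove <- floor(rate / 100 * length(idx))
  if (n_remove > 0) {
    drop <- with_seed(seed, sample(idx, n_remove))
    net$edges <- net$edges[-drop, ]
  }
  net
}

#' Replace one edge type with another year's version
#'
#' Deletes the base network's edges of the metaedge and inserts the
#' donor's, restricted to endpoint pairs whose nodes exist in the base
#' network (the node set is held constant so that only the edge
#' information changes). All other edges are untouched.
#'
#' @param base,donor Two [hetnet()]s, typically time slices of the same
#'   underlying network at different years.
#' @param metaedge Metaedge label (must exist in at least one of the two
#'   metagraphs).
#' @return The modified base hetnet; attribute `"report"` counts donor
#'   edges skipped for missing endpoints.
#' @export
replace_edge_type <- function(base, donor, metaedge) {
  in_base <- metaedge %in% base$metagraph$metaedges$label
  in_donor <- metaedge %in% donor$metagraph$metaedges$label
  if (!in_base && !in_donor) {
    abort_identifier(paste0("metaedge absent from both networks: ", metaedge))
  }
  if (!in_base) {
    i <- match(metaedge, donor$metagraph$metaedges$label)
    base$metagraph$metaedges <- dplyr::bind_rows(
      base$metagraph$metaedges, donor$metagraph$metaedges[i, ]
    )
  }
  incoming <- donor$edges[donor$edges$metaedge == metaedge, ]
  keep <- incoming$source %in% base$nodes$id & incoming$target %in% base$nodes$id
  base$edges <- dplyr::bind_rows(
    base$edges[base$edges$metaedge != metaedge, ],
    incoming[keep, ]
  )
  base$edges <- base$edges[order_c(base$edges$metaedge, base$edges$source, base$edges$target), ]
  attr(base, "report") <- list(n_donor_skipped = sum(!keep), n_donor_inserted = sum(keep))
  base
}

#' Perturbation experiment plan
#'
#' @param base_year Network year of the baseline slice.
#' @param metaedges Metaedge labels to perturb.
#' @param mode `"dropout"` or `"replace"`.
#' @param rates Dropout percentages (default 25, 50, 75, 100).
#' @param replicate_seeds Seeds for dropout replicates (default 5
#'   replicates).
#' @param donor_years Donor slice years for replacement mode.
#' @return A `perturbation_plan` list.
#' @export
perturbation_plan <- function(base_year, metaedges, mode = c("dropout", "replace"),
                              rates = c(25, 50, 75, 100), replicate_seeds = 1:5,
                              donor_years = NULL) {
  mode <- match.arg(mode)
  if (any(rates <= 0 | rates > 100)) abort_config("dropout rates must lie in (0, 100]")
  if (length(replicate_seeds) < 1) abort_config("at least one replicate seed is required")
  if (mode == "replace" && length(donor_years) == 0) {
    abort_config("replacement mode needs donor_years")
  }
  structure(
    list(
      base_year = as.integer(base_year), metaedges = metaedges, mode = mode,
      rates = rates, replicate_seeds = as.integer(replicate_seeds),
      donor_years = donor_years
    ),
    class = "perturbation_plan"
  )
}

#' Run an edge-perturbation suite
#'
#' Trains a baseline time-split model on the base-year slice, then, for
#' every plan condition (metaedge x dropout rate x replicate, or metaedge
#' x donor year), perturbs the slice, re-extracts the features, retrains
#' with the same seeds and train/test split as the baseline, and records
#' the change in AUROC / AUPRC on the frozen test set (future positives
#' plus the held-out negatives), so the deltas reflect the perturbation
#' only. A condition that fails to train is recorded as a failed row and
#' the suite continues.
#'
#' @param net A dated [hetnet()] (full network; slices are taken
#'   internally).
#' @param plan A [perturbation_plan()].
#' @param indications Positives with `approval_year`.
#' @param config A [model_config()].
#' @param source_type,target_type Drug and disease node types.
#' @return A `perturbation_result`: list with `results` (one row per
#'   condition x replicate, including `delta_auroc`), `baseline`
#'   (metrics), and the plan. `tidy()` returns per-row results; use
#'   [summarize_perturbations()] for per-condition means with 95%
#'   confidence intervals.
#' @export
run_perturbation_suite <- function(net, plan, indications, config,
                                   source_type = "Chemicals & Drugs",
                                   target_type = "Disorders") {
  stopifnot(inherits(plan, "perturbation_plan"))
  ind <- tibble::as_tibble(indications)
  fcfg <- feature_config(source_type, target_type, w = config$w, max_length = config$max_length)
  base <- slice_network(net, plan$base_year)
  spl <- split_indications(ind, base, plan$base_year)
  train_pos <- spl[spl$split == "train", c("drug", "disease")]
  test_pos <- spl[spl$split == "test", c("drug", "disease")]
  if (nrow(train_pos) < 2L || nrow(test_pos) < 1L) {
    abort_config("baseline year must have training and future positives")
  }
  universe <- negative_universe(base, ind[, c("drug", "disease")], source_type, target_type)
  negatives <- sample_negatives(spl[spl$split != "dropped", c("drug", "disease")],
    universe,
    ratio = config$ratio, seed = config$seed + plan$base_year
  )
  n_train_neg <- floor(0.8 * nrow(negatives))
  idx <- with_seed(config$seed + plan$base_year + 1L, sample.int(nrow(negatives)))
  neg_train <- negatives[idx[seq_len(n_train_neg)], ]
  neg_test <- negatives[idx[-seq_len(n_train_neg)], ]
  train_rows <- dplyr::bind_rows(dplyr::mutate(train_pos, label = 1L), neg_train)
  test_rows <- dplyr::bind_rows(dplyr::mutate(test_pos, label = 1L), neg_test)

  eval_on <- function(network) {
    feats_train <- extract_features(network, train_rows, fcfg)
    model <- fit_treats_model(feats_train, train_rows$label, config)
    scored <- predict(model, extract_features(network, test_rows, fcfg))
    c(
      auroc = auroc(scored$probability, test_rows$label),
      auprc = auprc(scored$probability, test_rows$label)
    )
  }
  base_metrics <- eval_on(base)
  conditions <- if (plan$mode == "dropout") {
    tidyr::expand_grid(
      metaedge = plan$metaedges, condition = plan$rates,
      replicate = seq_along(plan$replicate_seeds)
    )
  } else {
    tidyr::expand_grid(metaedge = plan$metaedges, condition = plan$donor_years, replicate = 1L)
  }
  results <- purrr::pmap_dfr(conditions, function(metaedge, condition, replicate) {
    row <- tibble::tibble(
      metaedge = metaedge, mode = plan$mode, condition = condition,
      replicate = replicate, auroc = NA_real_, auprc = NA_real_,
      delta_auroc = NA_real_, delta_auprc = NA_real_, failed = FALSE
    )
    m <- tryCatch(
      {
        perturbed <- if (plan$mode == "dropout") {
          dropout_edges(base, metaedge, condition,
            seed = plan$replicate_seeds[replicate]
          )
        } else {
          replace_edge_type(base, slice_network(net, condition), metaedge)
        }
        eval_on(perturbed)
      },
      error = function(e) NULL
    )
    if (is.null(m)) {
      row$failed <- TRUE
    } else {
      row$auroc <- m[["auroc"]]
      row$auprc <- m[["auprc"]]
      row$delta_auroc <- m[["auroc"]] - base_metrics[["auroc"]]
      row$delta_auprc <- m[["auprc"]] - base_metrics[["auprc"]]
    }
    row
  })
  structure(
    list(
      results = results,
      baseline = tibble::tibble(
        network_year = plan$base_year,
        auroc = base_metrics[["auroc"]], auprc = base_metrics[["auprc"]],
        n_train_pos = nrow(train_pos), n_test_pos = nrow(test_pos)
      ),
      plan = plan, config = config
    ),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(
    "<perturbation_result>", x$plan$mode, "on", length(x$plan$metaedges),
    "metaedges; baseline AUROC", round(x$baseline$auroc, 3), "\n"
  )
  print(summarize_perturbations(x), n = Inf)
  invisible(x)
}

#' @method tidy perturbation_result
#' @export
tidy.perturbation_result <- function(x, ...) x$results

#' Per-condition summary of a perturbation suite
#'
#' Mean delta over replicates with the normal-approximation 95% confidence
#' interval `mean +/- 1.96 * sd / sqrt(n)`.
#'
#' @param x A `perturbation_result`.
#' @return Tibble with one row per (metaedge, condition).
#' @export
summarize_perturbations <- function(x) {
  x$results |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$metaedge, .data$mode, .data$condition) |>
    dplyr::summarise(
      mean_delta_auroc = mean(.data$delta_auroc),
      sd_delta_auroc = stats::sd(.data$delta_auroc),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      se = dplyr::coalesce(.data$sd_delta_auroc, 0) / sqrt(.data$n),
      ci_lo = .data$mean_delta_auroc - 1.96 * .data$se,
      ci_hi = .data$mean_delta_auroc + 1.96 * .data$se
    )
}
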