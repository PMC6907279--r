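#' Area under the ROC curve
#'
#' Computed as the normalized Wilcoxon rank-sum statistic with midranks
#' for ties: the probability that a random positive is scored above a
#' random negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (`0`/`1` or logical).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) abort_config("scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort_metric("AUROC undefined: both classes must be present")
  }
  r <- rank(scores) # midrank ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of precision over recall: candidates are taken in
#' decreasing score order (ties processed as one block) and each recall
#' increment contributes the precision attained after its block.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L) {
    abort_metric("AUPRC undefined: both classes must be present")
  }
  o <- order(-scores)
  s <- scores[o]
  y <- labels[o]
  block <- cumsum(!duplicated(s)) # tie blocks in descending score order
  tp_block <- tapply(y, block, sum)
  n_block <- tapply(y, block, length)
  tp <- cumsum(tp_block)
  n_seen <- cumsum(n_block)
  precision <- tp / n_seen
  d_tp <- diff(c(0, tp))
  sum(d_tp * precision) / n_pos
}

#' Ranks of held-out positives within their candidate slates
#'
#' For every query drug with at least one positive among the scored
#' predictions, ranks that drug's true diseases among all diseases scored
#' for it (rank 1 = best; ties get the average rank), and symmetrically
#' for query diseases. A drug treating several diseases contributes every
#' rank.
#'
#' @param predictions Tibble with columns `drug`, `disease`, a score
#'   column and `label`.
#' @param score_col Name of the score column (default `"probability"`).
#' @return Tibble with columns `direction` (`"disease_given_drug"` /
#'   `"drug_given_disease"`), `query`, `positive`, `rank`, `slate_size`;
#'   attribute `"summary"` holds the median rank and slate size per
#'   direction.
#' @export
rank_holdouts <- function(predictions, score_col = "probability") {
  p <- tibble::as_tibble(predictions)
  one_direction <- function(query_col, cand_col, direction) {
    p |>
      dplyr::group_by(query = .data[[query_col]]) |>
      dplyr::filter(sum(.data$label == 1L) > 0) |>
      dplyr::mutate(rank = rank(-.data[[score_col]]), slate_size = dplyr::n()) |>
      dplyr::filter(.data$label == 1L) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        direction = direction, query = .data$query,
        positive = .data[[cand_col]], rank = .data$rank, slate_size = .data$slate_size
      )
  }
  out <- dplyr::bind_rows(
    one_direction("drug", "disease", "disease_given_drug"),
    one_direction("disease", "drug", "drug_given_disease")
  )
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      median_rank = stats::median(.data$rank),
      slate_size = max(.data$slate_size), n_ranks = dplyr::n(), .groups = "drop"
    )
  out
}

#' Standardize prediction probabilities per model
#'
#' Converts each model's probabilities to z-scores over all pairs it
#' scored (population standard deviation), making predictions comparable
#' across models trained on different network years. Models with fewer
#' than two scored pairs or zero variance are flagged and excluded.
#'
#' @param predictions Tibble of predictions from several models.
#' @param model_col Column identifying the model (default
#'   `"network_year"`).
#' @param score_col Probability column (default `"probability"`).
#' @return The input with an added `zscore` column, rows of excluded
#'   models removed; attribute `"excluded"` lists them.
#' @export
standardize_probabilities <- function(predictions, model_col = "network_year",
                                      score_col = "probability") {
  p <- tibble::as_tibble(predictions)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  p <- p |>
    dplyr::group_by(.data[[model_col]]) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .sd = sd_pop(.data[[score_col]]),
      zscore = (.data[[score_col]] - mean(.data[[score_col]])) / .data$.sd
    ) |>
    dplyr::ungroup()
  bad <- p$.n < 2L | p$.sd == 0
  excluded <- unique(p[[model_col]][bad])
  out <- p[!bad, setdiff(names(p), c(".n", ".sd"))]
  attr(out, "excluded") <- excluded
  out
}

#' Performance by relative approval year
#'
#' Pools standardized predictions from all network-year models, groups
#' the gold-standard positives by the offset between the drug's approval
#' year and the network year, and computes AUROC / AUPRC per offset
#' against a common pool of negatives sampled once at `ratio` per
#' positive across all models. Offsets without positives are absent from
#' the result (never reported as zero). A centered 5-year rolling mean
#' (shrinking at the edges) is attached for both metrics.
#'
#' @param predictions Standardized predictions (see
#'   [standardize_probabilities()]) with columns `network_year`, `label`,
#'   `zscore`, and `approval_year` on positive rows.
#' @param ratio Negatives per positive in the pooled sample.
#' @param seed Seed for the one-off negative draw.
#' @param offsets Offset window (inclusive), default -20..20 years.
#' @param window Rolling-mean window width in years.
#' @return A `relative_year_curve` tibble: `offset`, `auroc`, `auprc`,
#'   `n_pos`, `auroc_smooth`, `auprc_smooth`.
#' @export
relative_year_curve <- function(predictions, ratio = 10, seed = 1,
                                offsets = c(-20L, 20L), window = 5L) {
  p <- tibble::as_tibble(predictions)
  pos <- p[p$label == 1L & !is.na(p$approval_year), ]
  pos$offset <- as.integer(pos$approval_year - pos$network_year)
  pos <- pos[pos$offset >= offsets[1] & pos$offset <= offsets[2], ]
  if (nrow(pos) == 0) abort_metric("no positives within the offset window")
  neg_pool <- p[p$label == 0L, ]
  n_draw <- min(nrow(neg_pool), floor(ratio * nrow(pos)))
  if (n_draw == 0) abort_metric("no negatives available for the pooled sample")
  neg <- with_seed(seed, neg_pool[sample.int(nrow(neg_pool), n_draw), ])
  curve <- pos |>
    dplyr::group_by(offset = .data$offset) |>
    dplyr::group_modify(function(rows, key) {
      sc <- c(rows$zscore, neg$zscore)
      lb <- c(rep(1L, nrow(rows)), rep(0L, nrow(neg)))
      tibble::tibble(auroc = auroc(sc, lb), auprc = auprc(sc, lb), n_pos = nrow(rows))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$offset)
  half <- (window - 1) / 2
  roll <- function(v) {
    vapply(curve$offset, function(o) {
      mean(v[curve$offset >= o - half & curve$offset <= o + half])
    }, numeric(1))
  }
  curve$auroc_smooth <- roll(curve$auroc)
  curve$auprc_smooth <- roll(curve$auprc)
  class(curve) <- c("relative_year_curve", class(curve))
  curve
}
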