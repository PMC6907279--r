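#' Model configuration
#'
#' Bundles the hyperparameters of the DWPC + ElasticNet learning pipeline.
#' The mixing parameter `alpha` and damping exponent `w` are tuned once
#' (see `alpha_grid` / `w_grid` and [tune_hyperparameters()]) and then held
#' constant across all runs; the regularization strength is chosen on
#' glmnet's internal path by cross-validated deviance.
#'
#' @param alpha ElasticNet mixing parameter in `[0, 1]` (1 = lasso).
#' @param w DWPC damping exponent (shared with [feature_config()]).
#' @param ratio Negative:positive sampling ratio (default 10).
#' @param k Cross-validation fold count (default 5).
#' @param repeats Number of repeated random partitionings (default 10).
#' @param seed Integer seed from which all randomness derives.
#' @param max_length Maximum metapath length for feature extraction.
#' @param nlambda Length of glmnet's regularization path.
#' @param alpha_grid,w_grid Candidate grids for one-off tuning.
#' @param transform `"asinh"` (mean-scale, asinh, z-score) or
#'   `"zscore"` (plain standardization).
#' @param treats_metaedge Label of the drug-treats-disease metaedge whose
#'   held-out instances are removed before feature extraction; `NULL` =
#'   resolve automatically (the unique `TREATS`-predicate metaedge from
#'   source to target type).
#' @return A `model_config` list.
#' @export
model_config <- function(alpha = 0.5, w = 0.4, ratio = 10, k = 5, repeats = 10,
                         seed = 1, max_length = 3, nlambda = 50,
                         alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                         w_grid = c(0.2, 0.4, 0.6),
                         transform = c("asinh", "zscore"),
                         treats_metaedge = NULL) {
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) abort_config("alpha must lie in [0, 1]")
  if (!is_scalar_number(ratio) || ratio <= 0) abort_config("ratio must be > 0")
  if (!is_scalar_number(k) || k < 2) abort_config("fold count k must be >= 2")
  if (length(alpha_grid) == 0 || length(w_grid) == 0) abort_config("tuning grids must be nonempty")
  structure(
    list(
      alpha = alpha, w = w, ratio = ratio, k = as.integer(k),
      repeats = as.integer(repeats), seed = as.integer(seed),
      max_length = as.integer(max_length), nlambda = as.integer(nlambda),
      alpha_grid = alpha_grid, w_grid = w_grid,
      transform = match.arg(transform), treats_metaedge = treats_metaedge
    ),
    class = "model_config"
  )
}

resolve_treats <- function(net, config, source_type, target_type) {
  if (!is.null(config$treats_metaedge)) {
    return(config$treats_metaedge)
  }
  me <- net$metagraph$metaedges
  hit <- me$label[me$source == source_type & me$target == target_type & me$predicate == "TREATS"]
  if (length(hit) != 1L) {
    hit <- me$label[me$source == source_type & me$target == target_type]
    if (length(hit) != 1L) {
      abort_config("cannot resolve the TREATS metaedge automatically; set treats_metaedge")
    }
  }
  hit
}

#' Scale and standardize extracted features
#'
#' The default transformation divides each DWPC column by its training
#' mean, applies the inverse hyperbolic sine, and z-scores the result
#' (sample standard deviation); degree columns skip the mean scaling. The
#' transformation parameters are captured from the training rows at fit
#' time and, when supplied via `params`, reapplied verbatim so that
#' prediction-time features go through the identical map. Zero-variance or
#' all-zero columns map to all-zeros.
#'
#' @param features A feature tibble from [extract_features()].
#' @param params Frozen parameters from a previous call (`NULL` = fit).
#' @param method `"asinh"` or `"zscore"` (ignored when `params` given).
#' @return Transformed tibble; attribute `"transform_params"` carries the
#'   fitted parameter tibble (`column`, `scale_mean`, `center`, `sd`).
#' @export
transform_features <- function(features, params = NULL, method = c("asinh", "zscore")) {
  method <- match.arg(method)
  cols <- feature_columns(features)
  out <- features
  if (is.null(params)) {
    params <- tibble::tibble(
      column = cols, method = method,
      scale_mean = NA_real_, center = NA_real_, sd = NA_real_
    )
    for (i in seq_along(cols)) {
      x <- as.numeric(features[[cols[i]]])
      if (method == "asinh") {
        m <- if (startsWith(cols[i], "dwpc_")) mean(x) else 1
        if (is.na(m) || m == 0) m <- 1 # all-zero column: skip scaling
        x <- asinh(x / m)
        params$scale_mean[i] <- m
      } else {
        params$scale_mean[i] <- 1
      }
      mu <- mean(x)
      s <- stats::sd(x)
      params$center[i] <- mu
      params$sd[i] <- s
      out[[cols[i]]] <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mu) / s
    }
  } else {
    if (!setequal(params$column, cols)) {
      abort_schema("feature columns do not match the frozen transformation parameters")
    }
    for (i in seq_len(nrow(params))) {
      cname <- params$column[i]
      x <- as.numeric(features[[cname]])
      if (params$method[i] == "asinh") x <- asinh(x / params$scale_mean[i])
      out[[cname]] <- if (is.na(params$sd[i]) || params$sd[i] == 0) {
        rep(0, length(x))
      } else {
        (x - params$center[i]) / params$sd[i]
      }
    }
  }
  attr(out, "transform_params") <- params
  out
}

#' All candidate drug-disease pairs not in the gold standard
#'
#' @param net A [hetnet()].
#' @param indications Positive indications (`drug`, `disease`) — past and
#'   future — to exclude.
#' @param source_type,target_type Drug and disease node types.
#' @return Tibble of non-positive (`drug`, `disease`) pairs.
#' @export
negative_universe <- function(net, indications, source_type, target_type) {
  u <- tidyr::expand_grid(
    drug = nodes_of_type(net, source_type),
    disease = nodes_of_type(net, target_type)
  )
  dplyr::anti_join(u, tibble::as_tibble(indications), by = c("drug", "disease"))
}

#' Sample negative training examples
#'
#' Uniform sample without replacement of `floor(ratio * n_positives)`
#' pairs from the non-positive universe; reproducible under `seed`. Any
#' pair also present in `positives` is excluded defensively.
#'
#' @param positives Positive pairs (`drug`, `disease`).
#' @param universe Candidate pairs (see [negative_universe()]).
#' @param ratio Negatives per positive (default 10).
#' @param seed Integer seed.
#' @return Tibble of sampled pairs labelled `label = 0`.
#' @export
sample_negatives <- function(positives, universe, ratio = 10, seed = 1) {
  universe <- dplyr::anti_join(
    tibble::as_tibble(universe)[, c("drug", "disease")],
    tibble::as_tibble(positives), by = c("drug", "disease")
  )
  n <- floor(ratio * nrow(tibble::as_tibble(positives)))
  if (n > nrow(universe)) {
    abort_sampling(paste0("negative universe too small: need ", n, ", have ", nrow(universe)))
  }
  with_seed(seed, {
    out <- universe[sample.int(nrow(universe), n), ]
  })
  out$label <- 0L
  out
}

# shared fitting core: transform, build model matrix, run glmnet with an
# internal cross-validated deviance path, freeze everything needed to predict
fit_treats_model <- function(train_features, labels, config) {
  trans <- transform_features(train_features, method = config$transform)
  params <- attr(trans, "transform_params")
  x <- as.matrix(trans[, params$column])
  y <- as.integer(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos < 3L || n_neg < 3L) {
    abort_config("need at least 3 examples of each class to fit the model")
  }
  nfolds <- min(5L, n_pos, n_neg)
  # stratified fold assignment so every internal fold sees both classes
  foldid <- integer(length(y))
  foldid[y == 1L] <- with_seed(config$seed, sample(rep_len(seq_len(nfolds), n_pos)))
  foldid[y == 0L] <- with_seed(config$seed + 1L, sample(rep_len(seq_len(nfolds), n_neg)))
  # glmnet warns about small class counts on the deliberately small fits
  # used in tests; class sizes are validated above
  cvfit <- suppressWarnings(glmnet::cv.glmnet(x, y,
    family = "binomial", alpha = config$alpha,
    nlambda = config$nlambda, foldid = foldid, standardize = FALSE
  ))
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  structure(
    list(
      cvfit = cvfit, lambda = cvfit$lambda.min, alpha = config$alpha,
      coefficients = tibble::tibble(term = rownames(co), estimate = co[, 1]),
      transform_params = params, config = config, n_train = length(y),
      n_positive = sum(y == 1L)
    ),
    class = "dwpc_model"
  )
}

#' @export
print.dwpc_model <- function(x, ...) {
  nz <- sum(x$coefficients$estimate != 0 & x$coefficients$term != "(Intercept)")
  cat(
    "<dwpc_model> ElasticNet logistic regression: alpha =", x$alpha,
    "lambda =", signif(x$lambda, 4), "\n ", nz, "of", nrow(x$coefficients) - 1L,
    "features selected;", x$n_train, "training rows (", x$n_positive, "positives)\n"
  )
  invisible(x)
}

#' Predict treatment probabilities
#'
#' @param object A fitted `dwpc_model`.
#' @param features Feature tibble for the pairs to score (untransformed;
#'   the model's frozen transformation parameters are applied).
#' @param ... Unused.
#' @return The pair columns plus a `probability` column.
#' @export
predict.dwpc_model <- function(object, features, ...) {
  trans <- transform_features(features, params = object$transform_params)
  x <- as.matrix(trans[, object$transform_params$column])
  p <- as.numeric(stats::predict(object$cvfit, newx = x, s = "lambda.min", type = "response"))
  out <- tibble::as_tibble(features)[, c("drug", "disease")]
  out$probability <- p
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy dwpc_model
#' @export
tidy.dwpc_model <- function(x, ...) x$coefficients

#' @method glance dwpc_model
#' @export
glance.dwpc_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, lambda = x$lambda,
    n_features = nrow(x$coefficients) - 1L,
    n_selected = sum(x$coefficients$estimate != 0 & x$coefficients$term != "(Intercept)"),
    n_train = x$n_train, n_positive = x$n_positive
  )
}

#' Repeated k-fold cross-validation of the repositioning model
#'
#' Partitions the positive indications into `k` folds (repeated
#' `repeats` times with different random partitionings), samples
#' negatives at `ratio` per positive, and, within each fold, removes the
#' held-out positives' TREATS edges from the network *before* feature
#' extraction so the model cannot read the answer off the direct edge.
#' Each fold's model is fit on the remaining positives plus that fold's
#' complement of negatives and evaluated on the held-out rows.
#'
#' @param net A [hetnet()].
#' @param indications Positive indications (`drug`, `disease`, ...).
#' @param config A [model_config()].
#' @param source_type,target_type Drug and disease node types.
#' @return A `cv_result`: list with `metrics` (per repeat x fold AUROC /
#'   AUPRC), `predictions`, and the last fold's fitted model. `tidy()`
#'   returns the per-fold metrics, `glance()` their means.
#' @export
cv_run <- function(net, indications, config,
                   source_type = "Chemicals & Drugs", target_type = "Disorders") {
  positives <- tibble::as_tibble(indications)[, c("drug", "disease")]
  if (nrow(positives) < config$k) abort_config("fewer positives than folds")
  treats <- resolve_treats(net, config, source_type, target_type)
  fcfg <- feature_config(source_type, target_type, w = config$w, max_length = config$max_length)
  universe <- negative_universe(net, positives, source_type, target_type)
  metrics <- list()
  preds <- list()
  model <- NULL
  for (r in seq_len(config$repeats)) {
    seed_r <- config$seed + 1000L * r
    fold_pos <- with_seed(seed_r, sample(rep_len(seq_len(config$k), nrow(positives))))
    negatives <- sample_negatives(positives, universe, config$ratio, seed = seed_r)
    fold_neg <- with_seed(seed_r + 1L, sample(rep_len(seq_len(config$k), nrow(negatives))))
    if (min(table(fold_pos)) == 0) abort_config("a fold received zero positives")
    for (f in seq_len(config$k)) {
      hold_pos <- positives[fold_pos == f, ]
      net_f <- remove_edges(net, treats, hold_pos)
      all_pairs <- dplyr::bind_rows(
        dplyr::mutate(positives, label = 1L),
        negatives
      )
      feats <- extract_features(net_f, all_pairs, fcfg)
      is_hold <- c(fold_pos == f, fold_neg == f)
      model <- fit_treats_model(feats[!is_hold, ], all_pairs$label[!is_hold], config)
      scored <- predict(model, feats[is_hold, ])
      scored$label <- all_pairs$label[is_hold]
      scored$repeat_id <- r
      scored$fold <- f
      preds[[length(preds) + 1L]] <- scored
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        repeat_id = r, fold = f,
        auroc = auroc(scored$probability, scored$label),
        auprc = auprc(scored$probability, scored$label),
        n_pos = sum(scored$label == 1L), n_neg = sum(scored$label == 0L)
      )
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(metrics),
      predictions = dplyr::bind_rows(preds),
      last_model = model, config = config
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(
    "<cv_result>", max(x$metrics$repeat_id), "repeats x", max(x$metrics$fold),
    "folds; mean AUROC", round(g$mean_auroc, 3), "mean AUPRC", round(g$mean_auprc, 3), "\n"
  )
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mean_auroc = mean(x$metrics$auroc), mean_auprc = mean(x$metrics$auprc),
    sd_auroc = stats::sd(x$metrics$auroc), n_folds = nrow(x$metrics)
  )
}

#' Time-resolved training and prospective evaluation
#'
#' For each network year: slice the dated network, split the gold standard
#' at the year (approval up to and including the year = training
#' positives; later = test positives; disconnected = dropped), sample
#' negatives at `ratio` per *total* (past + future) positive, split the
#' negatives 80:20 into training and validation shares, train on past
#' positives plus the 80% share, and evaluate on future positives plus the
#' 20% share. Years with no future positives are recorded with absent
#' (`NA`) metrics rather than zero.
#'
#' @param net A dated [hetnet()] (the full, contemporary network).
#' @param indications Positives with `approval_year`.
#' @param years Slice years (see [slice_grid()]).
#' @param config A [model_config()].
#' @param source_type,target_type Drug and disease node types.
#' @return A `timesplit_result`: list with per-year `metrics`,
#'   `predictions` (train and test rows with `network_year`), and
#'   `models`.
#' @export
timesplit_run <- function(net, indications, years, config,
                          source_type = "Chemicals & Drugs", target_type = "Disorders") {
  ind <- tibble::as_tibble(indications)
  fcfg <- feature_config(source_type, target_type, w = config$w, max_length = config$max_length)
  metrics <- list()
  preds <- list()
  models <- list()
  for (y in years) {
    sl <- slice_network(net, y)
    if (!source_type %in% sl$nodes$type || !target_type %in% sl$nodes$type) next
    spl <- split_indications(ind, sl, y)
    train_pos <- spl[spl$split == "train", c("drug", "disease")]
    test_pos <- spl[spl$split == "test", c("drug", "disease")]
    if (nrow(train_pos) < 5L) next # too few past approvals to fit a model
    universe <- negative_universe(sl, ind[, c("drug", "disease")], source_type, target_type)
    # 10:1 of the total (past + future) positives mappable to this slice
    negatives <- sample_negatives(
      spl[spl$split != "dropped", c("drug", "disease")],
      universe,
      ratio = config$ratio,
      seed = config$seed + y
    )
    n_train_neg <- floor(0.8 * nrow(negatives))
    idx <- with_seed(config$seed + y + 1L, sample.int(nrow(negatives)))
    neg_train <- negatives[idx[seq_len(n_train_neg)], ]
    neg_test <- negatives[idx[-seq_len(n_train_neg)], ]
    train_rows <- dplyr::bind_rows(dplyr::mutate(train_pos, label = 1L), neg_train)
    feats_train <- extract_features(sl, train_rows, fcfg)
    model <- fit_treats_model(feats_train, train_rows$label, config)
    models[[as.character(y)]] <- model
    test_rows <- dplyr::bind_rows(dplyr::mutate(test_pos, label = 1L), neg_test)
    year_preds <- list()
    if (nrow(test_rows) > 0) {
      feats_test <- extract_features(sl, test_rows, fcfg)
      scored <- predict(model, feats_test)
      scored$label <- test_rows$label
      scored$set <- "test"
      year_preds$test <- scored
    }
    scored_train <- predict(model, feats_train)
    scored_train$label <- train_rows$label
    scored_train$set <- "train"
    year_preds$train <- scored_train
    yp <- dplyr::bind_rows(year_preds)
    yp$network_year <- y
    preds[[as.character(y)]] <- yp
    test_scored <- yp[yp$set == "test", ]
    has_both <- nrow(test_pos) > 0 && nrow(neg_test) > 0
    metrics[[as.character(y)]] <- tibble::tibble(
      network_year = y,
      n_train_pos = nrow(train_pos), n_test_pos = nrow(test_pos),
      n_dropped = sum(spl$split == "dropped"),
      auroc = if (has_both) auroc(test_scored$probability, test_scored$label) else NA_real_,
      auprc = if (has_both) auprc(test_scored$probability, test_scored$label) else NA_real_
    )
  }
  structure(
    list(
      metrics = dplyr::bind_rows(metrics), predictions = dplyr::bind_rows(preds),
      models = models, config = config, years = years
    ),
    class = "timesplit_result"
  )
}

#' @export
print.timesplit_result <- function(x, ...) {
  cat("<timesplit_result>", nrow(x$metrics), "network years\n")
  print(x$metrics, n = Inf)
  invisible(x)
}

#' @method tidy timesplit_result
#' @export
tidy.timesplit_result <- function(x, ...) x$metrics

#' @method glance timesplit_result
#' @export
glance.timesplit_result <- function(x, ...) {
  ok <- !is.na(x$metrics$auroc)
  tibble::tibble(
    n_years = nrow(x$metrics),
    peak_auroc = if (any(ok)) max(x$metrics$auroc[ok]) else NA_real_,
    peak_auroc_year = if (any(ok)) x$metrics$network_year[ok][which.max(x$metrics$auroc[ok])] else NA_integer_,
    peak_auprc = if (any(ok)) max(x$metrics$auprc[ok], na.rm = TRUE) else NA_real_
  )
}

#' One-off hyperparameter tuning
#'
#' Grid search over the ElasticNet mixing parameter and the DWPC damping
#' exponent by mean cross-validated AUROC on one network; the chosen pair
#' is intended to be frozen into the [model_config()] for all subsequent
#' runs.
#'
#' @inheritParams cv_run
#' @param repeats CV repeats per grid point (default 1 to keep the search
#'   cheap).
#' @return Tibble of grid results sorted by decreasing AUROC, with the
#'   chosen `(alpha, w)` in attribute `"best"`.
#' @export
tune_hyperparameters <- function(net, indications, config,
                                 source_type = "Chemicals & Drugs",
                                 target_type = "Disorders", repeats = 1) {
  grid <- tidyr::expand_grid(alpha = config$alpha_grid, w = config$w_grid)
  res <- purrr::pmap_dfr(grid, function(alpha, w) {
    cfg <- config
    cfg$alpha <- alpha
    cfg$w <- w
    cfg$repeats <- as.integer(repeats)
    cv <- cv_run(net, indications, cfg, source_type, target_type)
    tibble::tibble(alpha = alpha, w = w, mean_auroc = mean(cv$metrics$auroc))
  })
  res <- res[order(-res$mean_auroc), ]
  attr(res, "best") <- res[1, c("alpha", "w")]
  res
}
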