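test_that("the feature transform follows the mean-scale, asinh, z-score chain", {
  ft <- tibble::tibble(
    drug = c("C1", "C2"), disease = "D1",
    dwpc_CDtDO = c(1, 3), degree_drug_CDtDO = c(0L, 0L)
  )
  out <- transform_features(ft)
  # column [1, 3]: mean 2 -> [0.5, 1.5] -> asinh -> z-score
  asinh_vals <- asinh(c(0.5, 1.5))
  expected <- (asinh_vals - mean(asinh_vals)) / stats::sd(asinh_vals)
  expect_equal(out$dwpc_CDtDO, expected, tolerance = 1e-6)
  expect_equal(round(expected, 4), c(-0.7071, 0.7071))
  # all-zero column maps to zeros, with the degenerate case in the params
  expect_equal(out$degree_drug_CDtDO, c(0, 0))
  params <- attr(out, "transform_params")
  expect_equal(params$sd[params$column == "degree_drug_CDtDO"], 0)
  # frozen params reproduce the fitted transform bit for bit
  again <- transform_features(ft, params = params)
  expect_identical(again$dwpc_CDtDO, out$dwpc_CDtDO)
  # column mismatch at predict time is a schema error
  expect_error(
    transform_features(dplyr::rename(ft, dwpc_other = "dwpc_CDtDO"), params = params),
    class = "hetpath_schema_error"
  )
})

test_that("negative sampling is sized, reproducible, and disjoint from positives", {
  study <- generate_synthetic_study(synth_config(
    seed = 11, n_drugs = 20, n_diseases = 15,
    n_positives = 5
  ))
  pos <- study$indications[, c("drug", "disease")]
  uni <- negative_universe(study$net, pos, cd, do)
  neg <- sample_negatives(pos, uni, ratio = 10, seed = 1)
  expect_equal(nrow(neg), 50L)
  expect_identical(neg, sample_negatives(pos, uni, ratio = 10, seed = 1))
  expect_false(identical(neg, sample_negatives(pos, uni, ratio = 10, seed = 2)))
  for (s in 1:25) {
    n <- sample_negatives(pos, uni, ratio = 3, seed = s)
    expect_equal(nrow(dplyr::inner_join(n, pos, by = c("drug", "disease"))), 0L)
  }
  expect_error(sample_negatives(pos, uni[1:10, ], ratio = 10, seed = 1),
    class = "hetpath_sampling_error"
  )
})

test_that("removing holdout TREATS edges changes the feature matrix", {
  study <- generate_synthetic_study(synth_config(seed = 12, n_positives = 20))
  pos <- study$indications[, c("drug", "disease")]
  fcfg <- feature_config(cd, do, w = 0.4, max_length = 2)
  before <- extract_features(study$net, pos, fcfg)
  held <- remove_edges(study$net, "CDtDO", pos[1:4, ])
  after <- extract_features(held, pos, fcfg)
  expect_false(identical(before$dwpc_CDtDO, after$dwpc_CDtDO))
  # only metapaths through the treatment edge can change
  expect_true(any(before$dwpc_CDrtCDtDO != after$dwpc_CDrtCDtDO) ||
    identical(before$dwpc_CDrtCDtDO, after$dwpc_CDrtCDtDO))
  expect_identical(before$dwpc_CDloAloDO, after$dwpc_CDloAloDO)
})

test_that("cross-validation recovers planted signal and is deterministic", {
  study <- generate_synthetic_study(synth_config(
    seed = 13, n_drugs = 30, n_diseases = 20,
    n_anatomy = 8, n_phenomena = 8, n_positives = 20
  ))
  cfg <- model_config(repeats = 1, seed = 7)
  cv1 <- cv_run(study$net, study$indications, cfg)
  expect_equal(nrow(cv1$metrics), 5L)
  # well above the ~0.5 of a pure-noise study (full-size recovery is
  # exercised in the acceptance suite)
  expect_gt(mean(cv1$metrics$auroc), 0.65)
  expect_true(all(cv1$metrics$n_pos > 0))
  cv2 <- cv_run(study$net, study$indications, cfg)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$metrics, cv2$metrics)
  # tidy/glance accessors
  expect_equal(nrow(tidy(cv1)), 5L)
  expect_equal(glance(cv1)$mean_auroc, mean(cv1$metrics$auroc))
  m <- cv1$last_model
  expect_s3_class(m, "dwpc_model")
  expect_true(all(c("term", "estimate") %in% names(tidy(m))))
  expect_lte(glance(m)$n_selected, glance(m)$n_features)
})

test_that("stronger regularization weakly decreases the number of selected features", {
  study <- generate_synthetic_study(synth_config(
    seed = 14, n_drugs = 30, n_diseases = 20,
    n_anatomy = 8, n_phenomena = 8, n_positives = 15
  ))
  pos <- dplyr::mutate(study$indications[, c("drug", "disease")], label = 1L)
  uni <- negative_universe(study$net, pos, cd, do)
  neg <- sample_negatives(pos, uni, ratio = 10, seed = 3)
  rows <- dplyr::bind_rows(pos, neg)
  feats <- extract_features(study$net, rows, feature_config(cd, do))
  model <- fit_treats_model(feats, rows$label, model_config(alpha = 1, seed = 2, repeats = 1))
  fit <- model$cvfit$glmnet.fit
  nz <- fit$df # nonzero coefficients along the decreasing-lambda path
  expect_lte(nz[1], nz[length(nz)]) # strongest penalty selects the fewest
  expect_lte(max(nz), ncol(feats) - 2L)
  expect_gte(min(nz), 0L)
})

test_that("time-split training evaluates on future indications only", {
  study <- generate_synthetic_study(synth_config(seed = 15))
  cfg <- model_config(repeats = 1, seed = 5)
  ts <- timesplit_run(study$net, study$indications, c(1980, 1995), cfg)
  expect_true(all(c("network_year", "auroc", "n_test_pos") %in% names(ts$metrics)))
  for (y in ts$metrics$network_year) {
    preds <- ts$predictions[ts$predictions$network_year == y, ]
    sl <- slice_network(study$net, y)
    # a drug absent from the slice never appears in train or test rows
    expect_true(all(preds$drug %in% sl$nodes$id))
    spl <- split_indications(study$indications, sl, y)
    test_pos <- preds[preds$set == "test" & preds$label == 1L, ]
    expect_setequal(
      paste(test_pos$drug, test_pos$disease),
      paste(spl$drug[spl$split == "test"], spl$disease[spl$split == "test"])
    )
    # negatives total 10x the (past + future) positives, split 80:20
    n_pos_total <- sum(spl$split != "dropped")
    n_neg <- sum(preds$label == 0L)
    expect_equal(n_neg, 10L * n_pos_total)
    expect_equal(sum(preds$label == 0L & preds$set == "train"), floor(0.8 * n_neg))
  }
})
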