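test_that("weighted adjacency damps entries by endpoint degrees", {
  mg <- toy_metagraph()
  # adjacency [[1,1],[0,1]]: C1 treats D1 and D2, C2 treats D2
  net <- hetnet(
    tibble::tibble(id = c("C1", "C2", "D1", "D2"), type = c(cd, cd, do, do)),
    tibble::tibble(
      source = c("C1", "C1", "C2"), target = c("D1", "D2", "D2"),
      metaedge = "CDtDO"
    ),
    mg
  )
  W0 <- weighted_adjacency(net, "CDtDO", "forward", w = 0)
  expect_equal(as.matrix(W0), matrix(c(1, 0, 1, 1), 2, 2,
    dimnames = list(c("C1", "C2"), c("D1", "D2"))
  ))
  # source degrees (2, 1), target degrees (1, 2): entries d_u^-1 * d_v^-1
  W1 <- weighted_adjacency(net, "CDtDO", "forward", w = 1)
  expect_equal(as.matrix(W1), matrix(c(0.5, 0, 0.25, 0.5), 2, 2,
    dimnames = list(c("C1", "C2"), c("D1", "D2"))
  ))
  # backward traversal is the transpose
  expect_equal(as.matrix(weighted_adjacency(net, "CDtDO", "backward", w = 1)), t(as.matrix(W1)))
  # an isolated source node contributes an all-zero row
  net2 <- hetnet(
    tibble::tibble(id = c("C1", "C2", "D1"), type = c(cd, cd, do)),
    tibble::tibble(source = "C1", target = "D1", metaedge = "CDtDO"),
    mg
  )
  expect_equal(sum(weighted_adjacency(net2, "CDtDO", "forward", 0.4)["C2", ]), 0)
  expect_error(weighted_adjacency(net2, "XX", "forward", 0.4), class = "hetpath_identifier_error")
})

test_that("the worked 3-node DWPC cell equals 2^-0.4 in both engines", {
  # C1-rt-C2, C2-t->D1, C1-t->D1: single conforming path C1-C2->D1 with
  # step degree products (1*1) and (1*2)
  net <- toy_net()
  mp <- parse_metapath(net$metagraph, "CDrtCDtDO")
  expected <- 2^-0.4
  P <- dwpc_matrix(net, mp, w = 0.4)
  expect_equal(P["C1", "D1"], expected, tolerance = 1e-10)
  expect_equal(dwpc_oracle(net, "C1", "D1", mp, w = 0.4), expected, tolerance = 1e-10)
  expect_lt(abs(P["C1", "D1"] - dwpc_oracle(net, "C1", "D1", mp, w = 0.4)), 1e-10)
})

test_that("node-distinctness zeroes backtracking walks", {
  mg <- toy_metagraph()
  net <- hetnet(
    tibble::tibble(id = c("C1", "C2"), type = cd),
    tibble::tibble(source = "C1", target = "C2", metaedge = "CDrtCD"),
    mg
  )
  mp <- new_metapath(mg, c("CDrtCD", "CDrtCD"))
  P <- dwpc_matrix(net, mp, w = 0.4)
  expect_equal(P["C1", "C1"], 0) # the only walk revisits C1
  expect_equal(dwpc_oracle(net, "C1", "C1", mp, w = 0.4), 0)
})

test_that("matrix engine equals the path-enumeration oracle elementwise", {
  for (s in 1:2) {
    net <- small_random_net(s)
    mps <- enumerate_metapaths(net$metagraph, cd, do, max_length = 3)
    for (k in seq_len(nrow(mps))) {
      mp <- mps$metapath[[k]]
      P <- dwpc_matrix(net, mp, w = 0.4)
      P0 <- dwpc_matrix(net, mp, w = 0)
      # spot-check full agreement on a deterministic subset of cells
      rows <- rownames(P)[seq(1, nrow(P), by = 3)]
      cols <- colnames(P)[seq(1, ncol(P), by = 2)]
      for (i in rows) {
        for (j in cols) {
          expect_lt(abs(P[i, j] - dwpc_oracle(net, i, j, mp, w = 0.4)), 1e-10)
        }
      }
      # damping off recovers integer node-distinct path counts
      expect_true(all(abs(P0 - round(P0)) < 1e-9), info = mp$label)
    }
  }
})

test_that("DWPC is non-increasing in the damping exponent", {
  net <- small_random_net(5)
  mp <- parse_metapath(net$metagraph, "CDrtCDtDO")
  ws <- c(0, 0.2, 0.4, 0.6, 1)
  Ps <- lapply(ws, function(w) dwpc_matrix(net, mp, w))
  for (k in 2:length(ws)) {
    expect_true(all(Ps[[k]] <= Ps[[k - 1]] + 1e-12))
  }
})

test_that("removing a metaedge zeroes exactly the metapaths that contain it", {
  net <- small_random_net(2)
  cfg <- feature_config(cd, do, w = 0.4, max_length = 3)
  pairs <- tidyr::expand_grid(
    drug = nodes_of_type(net, cd)[1:6],
    disease = nodes_of_type(net, do)[1:4]
  )
  before <- extract_features(net, pairs, cfg)
  gone <- net
  gone$edges <- gone$edges[gone$edges$metaedge != "CDtDO", ]
  after <- extract_features(gone, pairs, cfg)
  mps <- enumerate_metapaths(net$metagraph, cd, do, 3)
  for (k in seq_len(nrow(mps))) {
    colname <- paste0("dwpc_", mps$label[k])
    contains <- "CDtDO" %in% mps$metapath[[k]]$steps$metaedge
    if (contains) {
      expect_true(all(after[[colname]] == 0), info = colname)
    } else {
      expect_equal(after[[colname]], before[[colname]], info = colname)
    }
  }
})

test_that("feature tables have deterministic columns and oracle-exact cells", {
  net <- toy_net()
  cfg <- feature_config(cd, do, w = 0.4, max_length = 2)
  pairs <- tibble::tibble(drug = c("C1", "C2"), disease = "D1")
  ft <- extract_features(net, pairs, cfg)
  expect_equal(
    names(ft),
    c(
      "drug", "disease", "dwpc_CDtDO", "dwpc_CDrtCDtDO", "dwpc_CDtDOawDO",
      "degree_drug_CDtDO", "degree_drug_CDrtCD",
      "degree_disease_CDtDO", "degree_disease_DOawDO"
    )
  )
  mps <- enumerate_metapaths(net$metagraph, cd, do, 2)
  for (k in seq_len(nrow(mps))) {
    for (r in seq_len(nrow(pairs))) {
      expect_equal(
        ft[[paste0("dwpc_", mps$label[k])]][r],
        dwpc_oracle(net, pairs$drug[r], pairs$disease[r], mps$metapath[[k]], 0.4),
        tolerance = 1e-12
      )
    }
  }
  expect_equal(ft$degree_drug_CDtDO, c(1L, 1L))
  expect_equal(ft$degree_disease_CDtDO, c(2L, 2L))
  # a pair with a disconnected endpoint scores zero everywhere
  net2 <- net
  net2$edges <- net2$edges[net2$edges$source != "C2" & net2$edges$target != "C2", ]
  ft2 <- extract_features(net2, tibble::tibble(drug = "C2", disease = "D1"), cfg)
  expect_true(all(ft2$dwpc_CDtDO == 0, ft2$degree_drug_CDtDO == 0))
  # missing endpoints raise an identifier error listing the pair
  err <- expect_error(
    extract_features(net, tibble::tibble(drug = "C9", disease = "D1"), cfg),
    class = "hetpath_identifier_error"
  )
  expect_match(conditionMessage(err), "C9")
})

test_that("the oracle enforces its enumeration budget", {
  net <- toy_net()
  mp <- parse_metapath(net$metagraph, "CDrtCDtDO")
  expect_equal(dwpc_oracle(net, "C2", "D1", new_metapath(net$metagraph, "CDrtCD"), 0.4), 0)
  expect_error(
    dwpc_oracle(net, "C1", "D1", mp, w = 0.4, max_paths = 0),
    class = "hetpath_budget_error"
  )
})
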