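test_that("concept remapping merges triples and unions publication sets", {
  t <- dplyr::bind_rows(
    triple_row("A", cd, "TREATS", "B", do, "pmid1"),
    triple_row("A2", cd, "TREATS", "B", do, "pmid2")
  )
  cm <- tibble::tibble(raw_id = c("A", "A2"), canonical_id = "A_general")
  out <- remap_concepts(t, cm)
  expect_equal(nrow(out), 1L)
  expect_equal(out$subject, "A_general")
  expect_equal(out$pmids[[1]], c("pmid1", "pmid2"))
  expect_equal(attr(out, "report")$n_merged_triples, 1L)

  # an empty map is the identity (up to normalized form)
  expect_equal(remap_concepts(t, tibble::tibble(raw_id = character(), canonical_id = character()))[1:6],
    normalize_triples(t)[1:6],
    ignore_attr = TRUE
  )

  # granular variants all collapse to one downstream node
  rhin <- dplyr::bind_rows(lapply(paste0("rhinitis_", 1:4), function(id) {
    triple_row("drugX", cd, "TREATS", id, do, paste0("p", id))
  }))
  cm2 <- tibble::tibble(
    raw_id = paste0("rhinitis_", 1:4),
    canonical_id = "allergic_rhinitis", canonical_name = "Allergic rhinitis"
  )
  out2 <- remap_concepts(rhin, cm2)
  expect_equal(nrow(out2), 1L)
  expect_equal(length(out2$pmids[[1]]), 4L)
  net <- triples_to_hetnet(out2, node_names = attr(out2, "concept_names"))
  expect_equal(sum(net$nodes$type == do), 1L)
  expect_equal(net$nodes$name[net$nodes$id == "allergic_rhinitis"], "Allergic rhinitis")

  # a mapping that makes subject equal object drops the triple
  self <- triple_row("A", cd, "RELATED_TO", "A2", cd, "p1")
  out3 <- remap_concepts(self, cm)
  expect_equal(nrow(out3), 0L)
  expect_equal(attr(out3, "report")$n_selfloops_dropped, 1L)
})

test_that("edge-type condensation rewrites predicates and merges duplicates", {
  t <- dplyr::bind_rows(
    triple_row("A", cd, "TREATS", "B", do, "p1"),
    triple_row("A", cd, "PREVENTS", "B", do, "p2"),
    triple_row("A", cd, "CAUSES", "B", do, "p3")
  )
  cmap <- tibble::tibble(
    source_type = cd, predicate = c("PREVENTS", "CAUSES"),
    target_type = do, replacement = c("TREATS", "DROP")
  )
  out <- condense_edge_types(t, cmap)
  expect_equal(nrow(out), 1L)
  expect_equal(out$predicate, "TREATS")
  expect_equal(out$pmids[[1]], c("p1", "p2"))

  # identity map leaves the table unchanged
  out2 <- condense_edge_types(t, tibble::tibble(
    source_type = character(), predicate = character(),
    target_type = character(), replacement = character()
  ))
  expect_equal(out2, normalize_triples(t), ignore_attr = TRUE)
})

test_that("sparse edge types are removed under a strict-inequality threshold", {
  # 999 TREATS + 1 RELATED_TO: 1/1000 = 0.001 is NOT < 0.001, so it stays
  mg <- toy_metagraph()
  nodes <- tibble::tibble(
    id = c(sprintf("C%03d", 1:500), sprintf("D%03d", 1:500), "CX", "CY"),
    type = c(rep(cd, 500), rep(do, 500), cd, cd)
  )
  edges <- dplyr::bind_rows(
    tibble::tibble(
      source = rep(sprintf("C%03d", 1:500), length.out = 999),
      target = rep(sprintf("D%03d", 1:500), each = 2)[1:999],
      metaedge = "CDtDO"
    ),
    tibble::tibble(source = "CX", target = "CY", metaedge = "CDrtCD")
  )
  net <- hetnet(nodes, edges, mg)
  kept <- filter_sparse_edge_types(net, 0.001)
  expect_true("CDrtCD" %in% kept$metagraph$metaedges$label)

  # 9999 + 1: 1/10000 < 0.001, removed together with its metaedge
  edges2 <- dplyr::bind_rows(
    tidyr::expand_grid(source = sprintf("C%03d", 1:500), target = sprintf("D%03d", 1:20)) |>
      dplyr::slice(1:9999) |>
      dplyr::mutate(metaedge = "CDtDO"),
    tibble::tibble(source = "CX", target = "CY", metaedge = "CDrtCD")
  )
  net2 <- hetnet(nodes, edges2, mg)
  cut <- filter_sparse_edge_types(net2, 0.001)
  expect_false("CDrtCD" %in% cut$metagraph$metaedges$label)
  expect_false(any(cut$edges$metaedge == "CDrtCD"))

  # threshold 0 is the identity
  expect_equal(filter_sparse_edge_types(net, 0)$edges, net$edges)
})

test_that("hub removal deletes top-degree nodes with a lexicographic tie-break", {
  mg <- toy_metagraph()
  # star: C1 connected to D1..D4
  star <- hetnet(
    tibble::tibble(id = c("C1", paste0("D", 1:4)), type = c(cd, rep(do, 4))),
    tibble::tibble(source = "C1", target = paste0("D", 1:4), metaedge = "CDtDO"),
    mg
  )
  out <- remove_hub_nodes(star, 1)
  expect_false("C1" %in% out$nodes$id)
  expect_equal(nrow(out$edges), 0L)
  expect_equal(remove_hub_nodes(star, 0)$edges, star$edges)
  expect_error(remove_hub_nodes(star, 5), class = "hetpath_empty_network_error")

  # degrees 3, 2, 2, 1: with n_top = 2 the degree-3 node goes, and of the
  # two degree-2 nodes the lexicographically smaller id goes
  net <- hetnet(
    tibble::tibble(id = c("Ca", "Cb", "Cc", "Cd"), type = cd),
    tibble::tibble(
      source = c("Ca", "Ca", "Cb", "Cb"),
      target = c("Cb", "Cc", "Cc", "Cd"),
      metaedge = "CDrtCD"
    ),
    mg
  ) # degrees: Ca 2, Cb 3, Cc 2, Cd 1
  out2 <- remove_hub_nodes(net, 2)
  expect_equal(sort(out2$nodes$id), c("Cc", "Cd"))
})

test_that("weakly supported edges are filtered and isolated nodes dropped", {
  mg <- toy_metagraph()
  net <- hetnet(
    tibble::tibble(id = c("C1", "C2", "D1", "D2"), type = c(cd, cd, do, do)),
    tibble::tibble(
      source = c("C1", "C1", "C2"), target = c("D1", "D2", "D1"),
      metaedge = "CDtDO",
      pmids = c("p1", "p1|p2", "p1|p2|p3|p4|p5")
    ),
    mg
  )
  out <- filter_low_support_edges(net, 2)
  expect_equal(nrow(out$edges), 2L) # publication-set sizes 1, 2, 5 -> 2 survive
  expect_setequal(out$nodes$id, c("C1", "C2", "D1", "D2"))
  out3 <- filter_low_support_edges(net, 3)
  expect_setequal(out3$nodes$id, c("C2", "D1")) # C1 and D2 isolated and removed
  expect_equal(filter_low_support_edges(net, 1)$edges, net$edges)
})

test_that("the full build pipeline is deterministic", {
  t <- dplyr::bind_rows(
    triple_row("A", cd, "TREATS", "B", do, "p1"),
    triple_row("A", cd, "TREATS", "B", do, "p2"),
    triple_row("A", cd, "PREVENTS", "B", do, "p3"),
    triple_row("C", cd, "TREATS", "B", do, "p4"),
    triple_row("C", cd, "TREATS", "B", do, "p5"),
    triple_row("A", cd, "RELATED_TO", "C", cd, "p6"),
    triple_row("A", cd, "RELATED_TO", "C", cd, "p7")
  )
  build_once <- function() {
    net <- build_hetnet(t,
      condense_map = tibble::tibble(
        source_type = cd, predicate = "PREVENTS", target_type = do, replacement = "TREATS"
      ),
      sparse_fraction = 0, hub_top = 0, min_support = 2
    )
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_hetnet(net, f1, f2)
    list(net = net, bytes = c(readLines(f1), readLines(f2)))
  }
  a <- build_once()
  b <- build_once()
  expect_identical(a$bytes, b$bytes)
  me <- a$net$metagraph$metaedges
  treats <- me$label[me$predicate == "TREATS"]
  expect_equal(
    a$net$edges$pmids[[which(a$net$edges$metaedge == treats & a$net$edges$source == "A")]],
    c("p1", "p2", "p3") # condensation folded the PREVENTS support into TREATS
  )
})
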