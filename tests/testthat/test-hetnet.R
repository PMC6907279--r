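test_that("typed degree counts edges at the requested end", {
  net <- toy_net()
  expect_equal(node_degree(net, "C1", "CDtDO", "source"), 1L)
  expect_equal(node_degree(net, "D1", "CDtDO", "target"), 2L)
  # node with no edges of the metaedge
  net2 <- toy_net()
  net2$edges <- net2$edges[net2$edges$metaedge != "CDrtCD", ]
  expect_equal(node_degree(net2, "C1", "CDrtCD", "source"), 0L)
  # C1-TREATS->D1, C1-TREATS->D2
  mg <- toy_metagraph()
  net3 <- hetnet(
    tibble::tibble(id = c("C1", "D1", "D2"), type = c(cd, do, do)),
    tibble::tibble(source = c("C1", "C1"), target = c("D1", "D2"), metaedge = "CDtDO"),
    mg
  )
  expect_equal(node_degree(net3, "C1", "CDtDO", "source"), 2L)
  # undirected chain C1-C2-C3: middle node has degree 2 regardless of orientation
  net4 <- hetnet(
    tibble::tibble(id = c("C1", "C2", "C3"), type = cd),
    tibble::tibble(source = c("C1", "C2"), target = c("C2", "C3"), metaedge = "CDrtCD"),
    mg
  )
  expect_equal(node_degree(net4, "C2", "CDrtCD", "source"), 2L)
  expect_equal(node_degree(net4, c("C1", "C3"), "CDrtCD", "target"), c(1L, 1L))
})

test_that("degrees sum to edge counts (2x for undirected self-type metaedges)", {
  net <- small_random_net(7)
  for (i in seq_len(nrow(net$metagraph$metaedges))) {
    me <- net$metagraph$metaedges[i, ]
    ids <- net$nodes$id[net$nodes$type == me$source]
    dsum <- sum(node_degree(net, ids, me$label, "source"))
    n_me <- sum(net$edges$metaedge == me$label)
    expect_equal(dsum, if (me$directed) n_me else 2L * n_me, info = me$label)
  }
})

test_that("degree queries on unknown identifiers fail", {
  net <- toy_net()
  expect_error(node_degree(net, "C9", "CDtDO", "source"), class = "hetpath_identifier_error")
  expect_error(node_degree(net, "C1", "XXX", "source"), class = "hetpath_identifier_error")
  # type mismatch: D1 cannot sit at the source of TREATS
  expect_error(node_degree(net, "D1", "CDtDO", "source"), class = "hetpath_identifier_error")
})

test_that("hetnet enforces referential and schema invariants", {
  mg <- toy_metagraph()
  nodes <- tibble::tibble(id = c("C1", "C2", "D1"), type = c(cd, cd, do))
  expect_error(
    hetnet(nodes, tibble::tibble(source = "C1", target = "D9", metaedge = "CDtDO"), mg),
    class = "hetpath_integrity_error"
  )
  expect_error(
    hetnet(nodes, tibble::tibble(source = "C1", target = "C1", metaedge = "CDrtCD"), mg),
    class = "hetpath_schema_error"
  )
  expect_error(
    hetnet(nodes, tibble::tibble(source = "D1", target = "C1", metaedge = "CDtDO"), mg),
    class = "hetpath_schema_error"
  )
  expect_error(
    hetnet(
      nodes,
      tibble::tibble(source = c("C1", "C1"), target = c("D1", "D1"), metaedge = "CDtDO"),
      mg
    ),
    class = "hetpath_schema_error"
  )
})

test_that("undirected edges are stored under the lexicographic endpoint order", {
  mg <- toy_metagraph()
  net <- hetnet(
    tibble::tibble(id = c("C1", "C2"), type = cd),
    tibble::tibble(source = "C2", target = "C1", metaedge = "CDrtCD"),
    mg
  )
  expect_equal(net$edges$source, "C1")
  expect_equal(net$edges$target, "C2")
})

test_that("hetnet tables round-trip through TSV", {
  net <- toy_net()
  net$edges$pmids <- list(c("p1", "p2"), character(), "p3")
  net$edges$year <- c(1989L, NA, 2001L)
  nodef <- withr::local_tempfile(fileext = ".tsv")
  edgef <- withr::local_tempfile(fileext = ".tsv")
  mgf <- withr::local_tempfile(fileext = ".yaml")
  write_hetnet(net, nodef, edgef, mgf)
  net2 <- read_hetnet(nodef, edgef, mgf)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$metagraph$metaedges, net$metagraph$metaedges)
})

test_that("reading reports malformed rows with their line numbers", {
  net <- toy_net()
  nodef <- withr::local_tempfile(fileext = ".tsv")
  edgef <- withr::local_tempfile(fileext = ".tsv")
  write_hetnet(net, nodef, edgef)
  # edge referencing an absent node (data line 2 = file line 3)
  bad <- readLines(edgef)
  bad[3] <- "C9\tD1\tCDtDO\t\t"
  writeLines(bad, edgef)
  err <- expect_error(read_hetnet(nodef, edgef, toy_metagraph()),
    class = "hetpath_integrity_error"
  )
  expect_match(conditionMessage(err), "3")
  # unknown metaedge
  bad[3] <- "C1\tD1\tXXyDO\t\t"
  writeLines(bad, edgef)
  expect_error(read_hetnet(nodef, edgef, toy_metagraph()), class = "hetpath_schema_error")
})

test_that("an empty pmid field reads as an empty publication set, year absent", {
  net <- toy_net() # pmids default to empty sets, year to NA
  nodef <- withr::local_tempfile(fileext = ".tsv")
  edgef <- withr::local_tempfile(fileext = ".tsv")
  write_hetnet(net, nodef, edgef)
  net2 <- read_hetnet(nodef, edgef, toy_metagraph())
  expect_true(all(lengths(net2$edges$pmids) == 0))
  expect_true(all(is.na(net2$edges$year)))
})
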