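test_that("expression TSV round-trips and enforces its invariants", {
  m <- matrix(round(rnorm(12), 6), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  f <- tempfile(fileext = ".tsv")
  writeExpression(m, f)
  se <- readExpression(f, "gene")
  expect_equal(dim(se), c(3L, 4L))
  expect_equal(SummarizedExperiment::assay(se, "exprs"), m, tolerance = 1e-12)
  expect_identical(S4Vectors::metadata(se)$featureKind, "gene")
})

test_that("duplicate feature rows are collapsed by mean with a warning", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2",
               "g1\t1\t2",
               "g1\t3\t4",
               "g2\t5\t6"), f)
  expect_warning(se <- readExpression(f, "gene"), "collapsed by mean")
  expect_equal(nrow(se), 2L)
  expect_equal(unname(SummarizedExperiment::assay(se)["g1", ]), c(2, 3))
})

test_that("rows with missing values are dropped; garbage cells are errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2",
               "g1\t1\tNA",
               "g2\t5\t6"), f)
  expect_message(se <- readExpression(f, "gene"), "missing values dropped")
  expect_identical(rownames(se), "g2")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "g1\t1\tabc"), f2)
  expect_error(readExpression(f2, "gene"), "non-numeric value 'abc'.*g1.*s2")

  f3 <- tempfile(fileext = ".tsv")
  file.create(f3)
  expect_error(readExpression(f3, "gene"), "empty")
})

test_that("target table rows merge per (miRNA, gene) pair", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id\tsource\texperimental",
               "m1\tg1\tPicTar\t0",
               "m1\tg1\tTargetScan\t0",
               "m1\tg2\tTarbase\t1",
               "m2\tg1\tmiRanda\t0"), f)
  tab <- readTargetTable(f)
  expect_equal(nrow(tab), 3L)
  row <- tab[tab$mirna_id == "m1" & tab$gene_id == "g1", ]
  expect_identical(row$sources, "PicTar;TargetScan")
  expect_identical(row$n_sources, 2L)
  expect_false(row$experimental)
  expect_true(tab$experimental[tab$gene_id == "g2"])

  f2 <- tempfile(fileext = ".tsv")
  writeLines("mirna_id\tgene_id\tsource\texperimental", f2)
  expect_equal(nrow(readTargetTable(f2)), 0L)

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id\tsource", "m1\tg1\tPicTar"), f3)
  expect_error(readTargetTable(f3), "missing column")
})

test_that("sample labels and TF lists read with validation", {
  f <- tempfile(); writeLines(c("sample_id\tgroup", "s1\tcase",
                                "s2\tcontrol"), f)
  lab <- readSampleLabels(f)
  expect_identical(as.character(lab[c("s1", "s2")]), c("case", "control"))
  f2 <- tempfile(); writeLines(c("sample_id\tgroup", "s1\tsick"), f2)
  expect_error(readSampleLabels(f2), "case")
  f3 <- tempfile(); writeLines(c("TP53", " GATA3 ", "", "TP53"), f3)
  expect_identical(readTFList(f3), c("TP53", "GATA3"))
})

test_that("networks round-trip through GraphML and TSV with attributes", {
  edges <- data.frame(gene1 = c("a", "b", "c"), gene2 = c("b", "c", "a"),
                      weight = c(0.91234567890123, 0.8, 0.7654321),
                      p = c(1e-6, 0.002, 0.03))
  net <- makeNetwork(edges)
  for (fmt in c("graphml", "tsv")) {
    f <- tempfile()
    writeNetwork(net, f, fmt)
    g2 <- readNetwork(f, fmt)
    expect_true(igraph::isomorphic(networkGraph(net), g2))
    e1 <- networkEdges(net)
    el <- igraph::as_edgelist(g2)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(e1$gene1, e1$gene2), key(el[, 1], el[, 2]))
    expect_equal(igraph::E(g2)$weight[m], e1$weight, tolerance = 1e-12)
  }
})

test_that("empty and typed graphs survive a GraphML round trip", {
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  f <- tempfile()
  writeNetwork(g0, f, "graphml")
  expect_equal(igraph::ecount(readNetwork(f, "graphml")), 0L)

  g <- igraph::graph_from_data_frame(
    data.frame(from = c("mirX", "tfY"), to = c("g1", "g1")),
    directed = FALSE,
    vertices = data.frame(name = c("mirX", "tfY", "g1"),
                          type = c("mirna", "tf", "gene")))
  writeNetwork(g, f, "graphml")
  g2 <- readNetwork(f, "graphml")
  expect_identical(
    igraph::V(g2)$type[match(c("mirX", "tfY", "g1"), igraph::V(g2)$name)],
    c("mirna", "tf", "gene"))
})

test_that("loading is order-insensitive up to feature reordering", {
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  f1 <- tempfile(); writeExpression(m, f1)
  f2 <- tempfile(); writeExpression(m[5:1, ], f2)
  se1 <- readExpression(f1, "gene"); se2 <- readExpression(f2, "gene")
  expect_equal(SummarizedExperiment::assay(se1),
               SummarizedExperiment::assay(se2)[rownames(se1), ],
               tolerance = 1e-12)
})
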