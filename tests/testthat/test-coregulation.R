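coregFixture <- function() {
  # module M1 = 4-clique with TF "g2"; module M2 = triangle with no miRNA
  cl <- function(v, w = 0.9) { cmb <- t(combn(v, 2))
    data.frame(gene1 = cmb[, 1], gene2 = cmb[, 2], weight = w) }
  m1 <- sprintf("g%d", 1:4); m2 <- sprintf("h%d", 1:3)
  net <- makeNetwork(rbind(cl(m1), cl(m2)))
  ms <- new("ModuleSet", modules = list(M1 = m1, M2 = m2),
            stats = data.frame(module_id = c("M1", "M2"),
                               size = c(4L, 3L)),
            params = list())
  ev <- do.call(rbind, lapply(c("g1", "g3"), function(g)
    data.frame(mirna_id = "mir1", gene_id = g, sources = "PicTar;TargetScan",
               n_sources = 2L, experimental = FALSE)))
  tm <- buildConsensusTargets(ev)
  asn <- list(
    mirna = data.frame(module_id = "M1", mirna_id = "mir1", k = 2L, K = 2L,
                       n = 4L, N = 7L, p_value = 0.005),
    tf = data.frame(module_id = c("M1", "M2"), tf_id = c("g2", "h1"),
                    module_degree = c(3L, 2L)),
    coregulated = c(M1 = TRUE, M2 = FALSE))
  list(net = net, ms = ms, tm = tm, asn = asn)
}

test_that("assembly keeps exactly the modules with both regulator kinds", {
  fx <- coregFixture()
  coreg <- buildCoregulationNetwork(fx$ms, fx$asn, fx$tm, fx$net)
  summ <- moduleSummary(coreg)
  expect_identical(summ$module_id, "M1")     # M2 has a TF but no miRNA
  expect_equal(summ$n_nodes, 4L)
  expect_equal(summ$n_edges, 6L)
  expect_identical(summ$mirnas, "mir1")
  expect_identical(summ$tfs, "g2")
  v <- igraph::V(coreg@graph)
  expect_identical(sort(v$name[v$type == "tf"]), "g2")
  expect_identical(sort(v$name[v$type == "mirna"]), "mir1")
  # every targeting edge exists in the consensus map and inside the module
  te <- coreg@targetEdges
  expect_true(all(te$gene_id %in% targetsOf(fx$tm, "mir1")))
  expect_true(all(te$gene_id %in% moduleGenes(fx$ms)$M1))
})

test_that("zero coregulated modules yields an empty network with warning", {
  fx <- coregFixture()
  asn <- fx$asn
  asn$coregulated[] <- FALSE
  expect_warning(coreg <- buildCoregulationNetwork(fx$ms, asn, fx$tm,
                                                   fx$net),
                 "no coregulated modules")
  expect_equal(nrow(moduleSummary(coreg)), 0L)
  expect_equal(igraph::vcount(networkGraph(coreg)), 0L)
})

test_that("anticorrelation report separates negation from duplication", {
  lab <- caseControlLabels(7, 7)
  withr::with_seed(5, base <- matrix(rnorm(3 * 14), 3, 14))
  gm <- base
  dimnames(gm) <- list(c("g1", "g2", "g3"), names(lab))
  # mirNeg is the exact negation (about the mean) of every target profile;
  # use a single shared profile so all correlations are exactly -1
  shared <- gm["g1", ]
  gm["g2", ] <- shared * 1.5 + 2
  gm["g3", ] <- shared * 0.5 - 1
  mm <- rbind(mirNeg = -shared, mirPos = shared)
  te <- rbind(
    data.frame(module_id = "M1", mirna_id = "mirNeg",
               gene_id = c("g1", "g2", "g3")),
    data.frame(module_id = "M1", mirna_id = "mirPos",
               gene_id = c("g1", "g2", "g3")))
  coreg <- makeCoregFromEdges(te, c("mirNeg", "mirPos"), "g1")
  rep <- mirnaTargetAnticorrelation(mm, gm, coreg)
  expect_equal(rep$pairs$r[rep$pairs$mirna_id == "mirNeg"], rep(-1, 3),
               tolerance = 1e-12)
  summ <- rep$summary
  expect_identical(summ$direction[summ$mirna_id == "mirNeg"], "negative")
  expect_identical(summ$direction[summ$mirna_id == "mirPos"], "non-negative")
  # fewer than 3 shared samples is an input error
  expect_error(mirnaTargetAnticorrelation(mm[, 1:2], gm[, 3:4], coreg),
               "at least 3 shared samples")
})

test_that("pipeline runs end to end on files and reports sane counts", {
  cfg <- simConfig(n_genes = 150, n_mirnas = 15,
                   modules = list(list(size = 18, lambda = 0.95)),
                   seed = 77)
  sim <- simulateDataset(cfg)
  dir <- file.path(tempdir(), "pipe-smoke")
  unlink(dir, recursive = TRUE)
  paths <- writeDataset(sim, file.path(dir, "in"))
  config <- pipelineConfig(paths$gene_expr, paths$mirna_expr, paths$labels,
                           paths$targets, paths$tfs,
                           out_dir = file.path(dir, "out"))
  res <- suppressMessages(runPipeline(config))
  expected <- c("degs.tsv", "demirs.tsv", "net.graphml", "modules.tsv",
                "modules_merged.tsv", "enrich.tsv", "regulators.tsv",
                "coregulation.graphml", "target_edges.tsv",
                "anticorrelation.tsv", "report.json", "run.log")
  expect_true(all(file.exists(file.path(dir, "out", expected))))
  counts <- res$report$counts
  # stage-count monotonicity along the filtering cascade
  expect_lte(counts$n_modules_after_merge, counts$n_modules_detected)
  expect_lte(counts$n_deg_enriched, counts$n_modules_after_merge)
  expect_lte(counts$n_coregulated, counts$n_deg_enriched)
  expect_equal(counts$n_genes, 150L)
  expect_equal(counts$n_samples, 14L)
})

test_that("an impossible DE threshold degrades gracefully", {
  cfg <- simConfig(n_genes = 80, n_mirnas = 8,
                   modules = list(list(size = 10, lambda = 0.9)),
                   de_effect = 0, de_fraction_background = 0, seed = 5)
  sim <- simulateDataset(cfg)
  dir <- file.path(tempdir(), "pipe-null")
  unlink(dir, recursive = TRUE)
  paths <- writeDataset(sim, file.path(dir, "in"))
  config <- pipelineConfig(paths$gene_expr, paths$mirna_expr, paths$labels,
                           paths$targets, paths$tfs,
                           out_dir = file.path(dir, "out"),
                           alpha_de = 1e-9)
  res <- suppressMessages(suppressWarnings(runPipeline(config)))
  expect_equal(res$report$counts$n_degs, 0L)
  expect_equal(res$report$counts$n_coregulated, 0L)
  expect_equal(nrow(moduleSummary(res$coregulation)), 0L)
})
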