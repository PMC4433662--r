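test_that("generation is fully reproducible from the seed", {
  cfg <- simConfig(n_genes = 100, n_mirnas = 10,
                   modules = list(list(size = 12, lambda = 0.9)), seed = 9)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(s1$geneExpr),
                   SummarizedExperiment::assay(s2$geneExpr))
  expect_identical(SummarizedExperiment::assay(s1$mirnaExpr),
                   SummarizedExperiment::assay(s2$mirnaExpr))
  expect_identical(s1$evidence, s2$evidence)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateDataset(simConfig(n_genes = 100, n_mirnas = 10,
                                  modules = list(list(size = 12,
                                                      lambda = 0.9)),
                                  seed = 10))
  expect_false(identical(SummarizedExperiment::assay(s1$geneExpr),
                         SummarizedExperiment::assay(s3$geneExpr)))
})

test_that("lambda = 1 gives perfectly correlated module genes", {
  cfg <- simConfig(n_genes = 30, n_mirnas = 5,
                   modules = list(list(size = 6, lambda = 1)),
                   de_effect = 0, seed = 2)
  sim <- simulateDataset(cfg)
  m <- SummarizedExperiment::assay(sim$geneExpr)[sim$truth$modules$T1, ]
  R <- cor(t(m))
  expect_equal(unname(R[upper.tri(R)]), rep(1, sum(upper.tri(R))),
               tolerance = 1e-12)
})

test_that("within-module correlation converges to lambda^2", {
  # one big module, many samples: the empirical mean pairwise correlation
  # must approach the single-factor population value lambda^2 = 0.81
  cfg <- simConfig(n_case = 500L, n_control = 2L, n_genes = 50,
                   n_mirnas = 5, modules = list(list(size = 46,
                                                     lambda = 0.9)),
                   de_effect = 0, seed = 3)
  sim <- simulateDataset(cfg)
  m <- SummarizedExperiment::assay(sim$geneExpr)[sim$truth$modules$T1,
                                                 1:500]
  R <- cor(t(m))
  pairwise <- R[upper.tri(R)]           # 1035 pairs
  expect_equal(mean(pairwise), 0.81, tolerance = 0.02)
  # cross-module (module vs background) correlation converges to 0
  bg <- setdiff(rownames(sim$geneExpr), sim$truth$modules$T1)[1:4]
  cross <- cor(t(SummarizedExperiment::assay(sim$geneExpr)[bg, 1:500]),
               t(m))
  expect_lt(max(abs(cross)), 0.2)
})

test_that("repressor miRNA anticorrelates with its module at lambda*rho", {
  cfg <- simConfig(n_case = 800L, n_control = 2L, n_genes = 40, n_mirnas = 5,
                   modules = list(list(size = 20, lambda = 0.9)),
                   de_effect = 0, repressor_loading = -0.89, seed = 4)
  sim <- simulateDataset(cfg)
  rep_id <- names(sim$truth$regulators)[1]
  mi <- SummarizedExperiment::assay(sim$mirnaExpr)[rep_id, 1:800]
  ge <- SummarizedExperiment::assay(sim$geneExpr)[sim$truth$modules$T1,
                                                  1:800]
  r <- apply(ge, 1L, cor, y = mi)
  expect_equal(mean(r), 0.9 * -0.89, tolerance = 0.02)
})

test_that("evidence table calibration matches stated sensitivity and fpr", {
  # one source with known rates over ~10,000 candidate pairs
  cfg <- simConfig(n_genes = 500, n_mirnas = 20,
                   modules = list(list(size = 10, lambda = 0.9)),
                   background_target_rate = 0.3,
                   source_sensitivity = c(ToolA = 0.6, ToolB = 0.2),
                   source_fpr = c(ToolA = 0.05, ToolB = 0.01),
                   experimental_sensitivity = 0, seed = 6)
  sim <- simulateDataset(cfg)
  truth <- sim$truth$target_matrix
  ev <- sim$evidence
  key <- paste(ev$mirna_id, ev$gene_id)
  hasA <- grepl("ToolA", ev$sources, fixed = TRUE)
  allkey <- paste(rep(rownames(truth), times = ncol(truth)),
                  rep(colnames(truth), each = nrow(truth)))
  istrue <- as.vector(truth)
  n_true <- sum(istrue); n_false <- sum(!istrue)
  tp <- sum(key[hasA] %in% allkey[istrue])
  fp <- sum(hasA) - tp
  # 99% binomial bands
  expect_lt(abs(tp / n_true - 0.6), 2.58 * sqrt(0.6 * 0.4 / n_true))
  expect_lt(abs(fp / n_false - 0.05), 2.58 * sqrt(0.05 * 0.95 / n_false))
})

test_that("recovery scoring handles identity, misses and half-overlap", {
  cfg <- simConfig(n_genes = 60, n_mirnas = 6,
                   modules = list(list(size = 10, lambda = 0.9),
                                  list(size = 8, lambda = 0.9)), seed = 8)
  sim <- simulateDataset(cfg)
  tr <- sim$truth
  # inferred == truth
  perfect <- scoreRecovery(tr, modules = tr$modules,
                           regulators = data.frame(
                             module_id = unname(tr$regulators),
                             mirna_id = names(tr$regulators)))
  expect_equal(unname(perfect$module_jaccard), c(1, 1))
  expect_equal(perfect$regulator$precision, 1)
  expect_equal(perfect$regulator$recall, 1)
  # empty inference
  empty <- scoreRecovery(tr, modules = list())
  expect_equal(unname(empty$module_jaccard), c(0, 0))
  # exactly half of each planted module, no extras
  halves <- lapply(tr$modules, function(g) g[seq_len(length(g) / 2)])
  half <- scoreRecovery(tr, modules = halves)
  expect_equal(unname(half$module_jaccard), c(0.5, 0.5))
  # foreign namespace is rejected
  expect_error(scoreRecovery(tr, modules = list(c("XX1", "XX2"))),
               "namespace")
})

test_that("DE calling scores against planted truth are computed", {
  cfg <- simConfig(n_genes = 200, n_mirnas = 20,
                   modules = list(list(size = 20, lambda = 0.9)),
                   de_effect = 3, seed = 12)
  sim <- simulateDataset(cfg)
  de <- callDifferential(sim$geneExpr, sim$labels)
  sc <- scoreRecovery(sim$truth, degs = de$feature_id[de$significant])
  expect_gt(sc$de$gene_sensitivity, 0.6)
  expect_gt(sc$de$gene_specificity, 0.85)
})
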