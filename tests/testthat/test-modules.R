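# unit-weight triangle used by several cohesiveness examples
triangleNet <- function() makeNetwork(
  data.frame(gene1 = c("a", "b", "c"), gene2 = c("b", "c", "a"), weight = 1))

# two unit-weight 4-cliques joined by a single bridge edge
twoCliqueBridge <- function() {
  cl <- function(v) { cmb <- t(combn(v, 2)); data.frame(gene1 = cmb[, 1],
                                                        gene2 = cmb[, 2],
                                                        weight = 1) }
  makeNetwork(rbind(cl(c("a1", "a2", "a3", "a4")),
                    cl(c("b1", "b2", "b3", "b4")),
                    data.frame(gene1 = "a4", gene2 = "b1", weight = 1)))
}

test_that("cohesiveness matches direct formula evaluation", {
  net <- triangleNet()
  expect_equal(cohesiveness(net, c("a", "b", "c"), penalty = 0), 1)
  expect_equal(cohesiveness(net, c("a", "b"), penalty = 0), 1 / 3)
  expect_equal(cohesiveness(net, c("a", "b"), penalty = 2), 1 / 7)
  expect_error(cohesiveness(net, c("a", "zzz")), "not in network")
})

test_that("greedy growth recovers a clique behind a bridge", {
  net <- twoCliqueBridge()
  got <- growCluster(net, "a1", detectionParams(penalty = 0))
  expect_identical(got, c("a1", "a2", "a3", "a4"))
  # the naive full-rescan oracle follows the same trajectory
  expect_identical(got, naiveGrow(net, "a1", penalty = 0))
  # and the result is a verified local optimum
  expect_true(isLocalOptimum(net, got, penalty = 0))
  # an isolated edge closes on itself with f = 1
  net2 <- makeNetwork(data.frame(gene1 = "x", gene2 = "y", weight = 1))
  expect_identical(growCluster(net2, "x", detectionParams(penalty = 0)),
                   c("x", "y"))
  expect_equal(cohesiveness(net2, c("x", "y"), penalty = 0), 1)
})

test_that("growth trajectories equal the naive oracle on random graphs", {
  for (seed in 1:8) {
    net <- randomSmallNetwork(n = 9, p = 0.45, seed = seed)
    for (pen in c(0, 1, 2)) {
      seeds <- networkNodes(net)[c(1L, 4L)]
      for (s in seeds) {
        got <- growCluster(net, s, detectionParams(penalty = pen))
        expect_identical(got, naiveGrow(net, s, pen),
                         info = sprintf("seed=%d penalty=%g start=%s",
                                        seed, pen, s))
      }
    }
  }
})

test_that("detectModules separates disjoint cliques and honours filters", {
  cl <- function(v) { cmb <- t(combn(v, 2)); data.frame(gene1 = cmb[, 1],
                                                        gene2 = cmb[, 2],
                                                        weight = 1) }
  a <- sprintf("a%d", 1:5); b <- sprintf("b%d", 1:5)
  net <- makeNetwork(rbind(cl(a), cl(b)))
  ms <- detectModules(net)
  expect_equal(length(ms), 2L)
  expect_setequal(lapply(moduleGenes(ms), sort), list(a, b))
  st <- moduleStats(ms)
  expect_equal(st$density, c(1, 1))
  # empty network -> zero modules
  empty <- new("CoexpressionNetwork",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               nSamples = 7L, alpha = 0.05)
  expect_equal(length(detectModules(empty)), 0L)
})

test_that("match-coefficient merging follows the omega formula", {
  A <- letters[1:6]; B <- letters[2:7]   # overlap 5: omega = 25/36 ~ 0.694
  expect_equal(comireg:::.matchCoefficient(A, B), 25 / 36)
  expect_length(comireg:::.omegaMerge(list(A, B), 0.8), 2L)   # below 0.8
  expect_length(comireg:::.omegaMerge(list(A, B), 0.69), 1L)  # above 0.69
  # transitive closure: A~B and B~C union all three
  C <- letters[3:8]
  expect_length(comireg:::.omegaMerge(list(A, B, C), 0.69), 1L)
})

test_that("one-third overlap merge applies the strict boundary rule", {
  big <- letters[1:9]
  exact_third <- c("a", "x", "y")       # overlap 1 = exactly 1/3 of 3
  above_third <- c("a", "b", "z")       # overlap 2 > 1
  edges <- do.call(rbind, lapply(list(big, exact_third, above_third),
    function(v) { cmb <- t(combn(v, 2))
      data.frame(gene1 = cmb[, 1], gene2 = cmb[, 2], weight = 0.9) }))
  edges <- edges[!duplicated(paste(pmin(edges$gene1, edges$gene2),
                                   pmax(edges$gene1, edges$gene2))), ]
  net <- makeNetwork(edges)
  mk <- function(sets) new("ModuleSet",
    modules = stats::setNames(sets, paste0("M", seq_along(sets))),
    stats = data.frame(module_id = paste0("M", seq_along(sets)),
                       size = lengths(sets)),
    params = unclass(detectionParams()))

  # boundary case: exactly one third is NOT merged
  out <- mergeModulesByOverlap(mk(list(big, exact_third)), net)
  expect_equal(length(out), 2L)

  # strictly above one third merges into the union
  out2 <- mergeModulesByOverlap(mk(list(big, above_third)), net)
  expect_equal(length(out2), 1L)
  expect_setequal(moduleGenes(out2)[[1]], union(big, above_third))

  # disjoint modules are a no-op and input order does not matter
  d1 <- list(c("a", "b", "c"), c("x", "y", "z"), c("q", "r", "s"))
  alledges <- do.call(rbind, lapply(d1, function(v) {
    cmb <- t(combn(v, 2))
    data.frame(gene1 = cmb[, 1], gene2 = cmb[, 2], weight = 0.8) }))
  net2 <- makeNetwork(alledges)
  o1 <- mergeModulesByOverlap(mk(d1), net2)
  o2 <- mergeModulesByOverlap(mk(rev(d1)), net2)
  expect_identical(moduleGenes(o1), moduleGenes(o2))
  expect_equal(length(o1), 3L)
})

test_that("one-third merge output is a fixed point with bounded overlaps", {
  withr::with_seed(99, {
    pool <- sprintf("g%02d", 1:30)
    sets <- replicate(6, sample(pool, sample(4:10, 1)), simplify = FALSE)
  })
  cmb <- t(combn(pool, 2))
  net <- makeNetwork(data.frame(gene1 = cmb[, 1], gene2 = cmb[, 2],
                                weight = 0.8))
  ms <- new("ModuleSet",
            modules = stats::setNames(sets, paste0("M", seq_along(sets))),
            stats = data.frame(module_id = paste0("M", seq_along(sets)),
                               size = lengths(sets)),
            params = unclass(detectionParams()))
  out <- mergeModulesByOverlap(ms, net)
  again <- mergeModulesByOverlap(out, net)
  expect_identical(moduleGenes(out), moduleGenes(again))
  gs <- moduleGenes(out)
  if (length(gs) >= 2L)
    for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
      ov <- length(intersect(gs[[i]], gs[[j]]))
      expect_lte(3 * ov, min(length(gs[[i]]), length(gs[[j]])))
    }
})

test_that("returned modules are brute-force-verified local optima", {
  for (seed in 11:16) {
    net <- randomSmallNetwork(n = 10, p = 0.5, seed = seed)
    ms <- detectModules(net, detectionParams(minSize = 2L, minDensity = 0))
    st <- moduleStats(ms)
    for (id in names(moduleGenes(ms))) {
      genes <- moduleGenes(ms)[[id]]
      f_pkg <- st$cohesiveness[st$module_id == id]
      expect_equal(f_pkg, naiveCohesiveness(net, genes, 2), tolerance = 1e-12)
      expect_true(igraph::is_connected(
        igraph::induced_subgraph(networkGraph(net), genes)))
    }
  }
})

test_that("detection is deterministic", {
  net <- randomSmallNetwork(n = 12, p = 0.4, seed = 77)
  m1 <- detectModules(net)
  m2 <- detectModules(net)
  expect_identical(moduleGenes(m1), moduleGenes(m2))
  expect_identical(moduleStats(m1), moduleStats(m2))
})
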