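# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths: enrichment is
# checked against exact combinatorial enumeration, cohesiveness against a
# from-scratch edge-table recomputation, and greedy growth against a naive
# re-simulation that rescans the whole graph at every step.

# exact hypergeometric upper tail by direct enumeration; choose() is exact
# for the N <= 50 tables used in tests (all values < 2^53)
bruteHyperTail <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# cohesiveness recomputed from the network's edge table only
naiveCohesiveness <- function(net, genes, penalty) {
  ed <- networkEdges(net)
  in1 <- ed$gene1 %in% genes
  in2 <- ed$gene2 %in% genes
  w_in <- sum(ed$weight[in1 & in2])
  w_bound <- sum(ed$weight[xor(in1, in2)])
  den <- w_in + w_bound + penalty * length(genes)
  if (den > 0) w_in / den else 0
}

# naive greedy growth: full rescan each step, same move rule as the package
# (single best strictly-improving add/remove, ties by smallest gene id,
# removals keeping the set connected)
naiveGrow <- function(net, seed, penalty) {
  g <- networkGraph(net)
  nodes <- igraph::V(g)$name
  V <- seed
  f <- naiveCohesiveness(net, V, penalty)
  repeat {
    nb <- setdiff(unique(unlist(lapply(V, function(v)
      igraph::V(g)$name[igraph::neighbors(g, v)]))), V)
    cand <- list()
    for (u in nb)
      cand[[length(cand) + 1L]] <-
        list(set = c(V, u), f = naiveCohesiveness(net, c(V, u), penalty),
             id = u)
    if (length(V) > 1L) for (v in V) {
      rest <- setdiff(V, v)
      sub <- igraph::induced_subgraph(g, rest)
      if (!igraph::is_connected(sub)) next
      cand[[length(cand) + 1L]] <-
        list(set = rest, f = naiveCohesiveness(net, rest, penalty), id = v)
    }
    if (!length(cand)) break
    fs <- vapply(cand, `[[`, 0, "f")
    ids <- vapply(cand, `[[`, "", "id")
    ok <- fs > f + 1e-12
    if (!any(ok)) break
    o <- order(-fs, match(ids, sort(unique(ids), method = "radix")))
    o <- o[ok[o]][1L]
    V <- cand[[o]]$set
    f <- cand[[o]]$f
  }
  sort(V)
}

# verify a set is a cohesiveness local optimum by exhausting single moves
isLocalOptimum <- function(net, genes, penalty) {
  g <- networkGraph(net)
  f <- naiveCohesiveness(net, genes, penalty)
  nb <- setdiff(unique(unlist(lapply(genes, function(v)
    igraph::V(g)$name[igraph::neighbors(g, v)]))), genes)
  for (u in nb)
    if (naiveCohesiveness(net, c(genes, u), penalty) > f + 1e-12)
      return(FALSE)
  if (length(genes) > 1L) for (v in genes) {
    rest <- setdiff(genes, v)
    if (!igraph::is_connected(igraph::induced_subgraph(g, rest))) next
    if (naiveCohesiveness(net, rest, penalty) > f + 1e-12) return(FALSE)
  }
  TRUE
}

# build a CoexpressionNetwork from an explicit edge table
makeNetwork <- function(edges, nSamples = 7L, alpha = 0.05) {
  stopifnot(all(c("gene1", "gene2", "weight") %in% colnames(edges)))
  if (is.null(edges$p)) edges$p <- 0.01
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new("CoexpressionNetwork", graph = g, nSamples = as.integer(nSamples),
      alpha = alpha)
}

# k planted cliques plus sparse random inter-clique edges
plantedCliqueNetwork <- function(sizes, interDensity = 0.02, seed = 1) {
  withr::with_seed(seed, {
    nodes <- split(sprintf("n%03d", seq_len(sum(sizes))),
                   rep(seq_along(sizes), sizes))
    edges <- do.call(rbind, lapply(nodes, function(v) {
      cmb <- t(combn(v, 2L))
      data.frame(gene1 = cmb[, 1L], gene2 = cmb[, 2L],
                 weight = runif(nrow(cmb), 0.76, 1))
    }))
    for (i in seq_along(nodes)[-length(nodes)])
      for (j in (i + 1L):length(nodes)) {
        pairs <- expand.grid(gene1 = nodes[[i]], gene2 = nodes[[j]],
                             stringsAsFactors = FALSE)
        take <- runif(nrow(pairs)) < interDensity
        if (any(take))
          edges <- rbind(edges, data.frame(pairs[take, ],
                                           weight = runif(sum(take),
                                                          0.76, 1)))
      }
    list(network = makeNetwork(edges), truth = nodes)
  })
}

# random small weighted graph for oracle-equivalence checks
randomSmallNetwork <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    cmb <- t(combn(sprintf("v%02d", seq_len(n)), 2L))
    take <- runif(nrow(cmb)) < p
    if (sum(take) == 0L) take[1L] <- TRUE
    makeNetwork(data.frame(gene1 = cmb[take, 1L], gene2 = cmb[take, 2L],
                           weight = runif(sum(take), 0.1, 1)))
  })
}

# expression SummarizedExperiment from a matrix + auto labels
makeExprSE <- function(m, kind = "gene") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m))
  S4Vectors::metadata(se)$featureKind <- kind
  se
}

caseControlLabels <- function(nCase, nControl,
                              ids = c(sprintf("case%02d", seq_len(nCase)),
                                      sprintf("ctrl%02d", seq_len(nControl)))) {
  stats::setNames(factor(rep(c("case", "control"), c(nCase, nControl)),
                         levels = c("case", "control")), ids)
}

# construct a pair of vectors with an exact sample correlation r
vectorsWithCorrelation <- function(r, n, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(rnorm(n))[, 1L]
    z <- rnorm(n)
    z <- scale(z - x * sum(x * z) / sum(x * x))[, 1L]
    y <- r * x + sqrt(1 - r^2) * z
    list(x = x, y = y)
  })
}

# minimal CoregulationNetwork wrapper around explicit target edges, for
# testing the anticorrelation report in isolation
makeCoregFromEdges <- function(targetEdges, mirnas, tfs) {
  summ <- data.frame(module_id = unique(targetEdges$module_id),
                     n_nodes = NA_integer_, n_edges = NA_integer_,
                     mirnas = paste(mirnas, collapse = ","),
                     tfs = paste(tfs, collapse = ","))
  g <- igraph::graph_from_data_frame(
    targetEdges[, c("mirna_id", "gene_id")], directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% mirnas, "mirna", "gene")
  igraph::V(g)$module_id <- targetEdges$module_id[1L]
  new("CoregulationNetwork", graph = g, summary = summ,
      mirnaAssignments = data.frame(), tfAssignments = data.frame(),
      targetEdges = targetEdges)
}
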