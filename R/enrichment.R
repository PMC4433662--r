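#' One-sided Fisher's exact enrichment of a gene set in a module
#'
#' Tests whether a module contains more members of a query set than expected
#' under hypergeometric sampling from the universe.  The p-value is the
#' exact upper tail \eqn{P(X \ge k)} for \eqn{X \sim}
#' Hypergeometric(\eqn{N, K, n}), with \eqn{N} the universe size, \eqn{K}
#' the query-set size inside the universe, \eqn{n} the module size and
#' \eqn{k} the overlap; this equals the one-sided (greater) Fisher's exact
#' test on the 2x2 table.  Computed in log space via [stats::phyper()], so
#' it is exact and stable for any table.
#'
#' @param moduleGenes character vector, must be a subset of \code{universe}.
#' @param querySet character vector; intersected with the universe first.
#' @param universe character vector of all genes eligible to be drawn
#'   (typically the coexpression-network node set).
#' @param alpha significance threshold (default 0.01, strict inequality).
#' @return one-row \code{data.frame}: \code{k, K, n, N, odds_ratio, p_value,
#'   significant}.
#' @examples
#' u <- paste0("g", 1:10)
#' fisherEnrichment(u[1:5], u[1:5], u)  # p = 1/choose(10,5)
#' @export
fisherEnrichment <- function(moduleGenes, querySet, universe, alpha = 0.01) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("input error: empty universe")
  moduleGenes <- unique(moduleGenes)
  if (!all(moduleGenes %in% universe))
    stop("input error: module genes must be a subset of the universe")
  query <- intersect(unique(querySet), universe)
  N <- length(universe)
  K <- length(query)
  n <- length(moduleGenes)
  k <- length(intersect(moduleGenes, query))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  num <- k * (N - K - n + k)
  den <- (K - k) * (n - k)
  odds <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  data.frame(k = k, K = K, n = n, N = N, odds_ratio = odds, p_value = p,
             significant = p < alpha)
}

#' Filter modules by enrichment of differentially expressed genes
#'
#' A module is considered disease-related (and retained) when it is
#' significantly enriched with differentially expressed genes at
#' \code{alpha} (strict), tested by [fisherEnrichment()] against the given
#' universe.  The full per-module enrichment table is returned for all
#' modules, retained or not.
#'
#' @param modules a [ModuleSet-class].
#' @param degs character vector of differentially expressed gene ids.
#' @param universe character vector; defaults in the pipeline to the
#'   coexpression-network node set.
#' @param alpha significance threshold (default 0.01).
#' @return list with \code{retained} (a [ModuleSet-class]) and \code{table}
#'   (per-module \code{data.frame} with the enrichment fields).
#' @export
filterModulesByDEG <- function(modules, degs, universe, alpha = 0.01) {
  sets <- moduleGenes(modules)
  tab <- do.call(rbind, lapply(names(sets), function(id) {
    cbind(data.frame(module_id = id, stringsAsFactors = FALSE),
          fisherEnrichment(sets[[id]], degs, universe, alpha))
  }))
  if (is.null(tab))
    tab <- data.frame(module_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      p_value = numeric(), significant = logical())
  keep <- tab$module_id[tab$significant]
  list(retained = modules[keep], table = tab)
}
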