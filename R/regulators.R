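#' Build the consensus miRNA target map
#'
#' Applies the consensus filter to a merged evidence table (see
#' [readTargetTable()]): a (miRNA, gene) interaction is retained when it is
#' predicted by at least \code{minSources} tools or is experimentally
#' validated.  miRNAs left without any retained target are dropped from the
#' map.
#'
#' @param evidence \code{data.frame} with columns \code{mirna_id},
#'   \code{gene_id}, \code{n_sources} and \code{experimental}.
#' @param minSources prediction-source support threshold (default 2).
#' @return a [TargetMap-class].
#' @export
buildConsensusTargets <- function(evidence, minSources = 2L) {
  need <- c("mirna_id", "gene_id", "n_sources", "experimental")
  miss <- setdiff(need, colnames(evidence))
  if (length(miss))
    stop("input error: evidence table missing column(s): ",
         paste(miss, collapse = ", "))
  keep <- evidence$n_sources >= minSources | evidence$experimental
  ev <- evidence[keep, , drop = FALSE]
  targets <- lapply(split(ev$gene_id, ev$mirna_id), function(g)
    sort(unique(g), method = "radix"))
  targets <- targets[order(names(targets), method = "radix")]
  new("TargetMap", targets = targets, minSources = as.integer(minSources))
}

#' Assign miRNA regulators to a module
#'
#' A differentially expressed miRNA (DemiR) regulates a module when its
#' consensus targets are significantly enriched among the module genes
#' (one-sided Fisher's exact test against the universe at \code{alpha},
#' strict).  Only DemiRs are candidates; miRNAs with no targets inside the
#' universe are skipped with a message.  Results are sorted by ascending
#' p-value (ties by miRNA id).
#'
#' @param moduleGenes character vector of module gene ids (subset of
#'   \code{universe}).
#' @param demirs character vector of differentially expressed miRNA ids.
#' @param targets a [TargetMap-class].
#' @param universe character vector of eligible genes (network node set in
#'   the pipeline).
#' @param alpha significance threshold (default 0.01).
#' @return \code{data.frame} with columns \code{mirna_id}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p_value} for the assigned
#'   regulators.
#' @export
assignMirnaRegulators <- function(moduleGenes, demirs, targets, universe,
                                  alpha = 0.01) {
  stopifnot(is(targets, "TargetMap"))
  cand <- intersect(names(targets), demirs)
  cand <- cand[order(cand, method = "radix")]
  rows <- lapply(cand, function(m) {
    tg <- intersect(targetsOf(targets, m), universe)
    if (length(tg) == 0L) {
      message("miRNA ", m, " has no targets in the universe; skipped")
      return(NULL)
    }
    e <- fisherEnrichment(moduleGenes, tg, universe, alpha)
    if (!e$significant) return(NULL)
    data.frame(mirna_id = m, k = e$k, K = e$K, n = e$n, N = e$N,
               p_value = e$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric())
  out[order(out$p_value, .radixRank(out$mirna_id)), , drop = FALSE]
}

#' Assign TF regulators to a module
#'
#' A transcription factor regulates a module when it belongs to the module
#' and coexpresses with other module genes, operationalized as having at
#' least \code{minModuleEdges} significant coexpression edges to other
#' module members.  Results are sorted by descending within-module degree
#' (ties by gene id).
#'
#' @param moduleGenes character vector of module gene ids.
#' @param tfs character vector of gene ids annotated as transcription
#'   factors.
#' @param network the [CoexpressionNetwork-class].
#' @param minModuleEdges minimum within-module degree (default 1).
#' @return \code{data.frame} with columns \code{tf_id},
#'   \code{module_degree}.
#' @export
assignTfRegulators <- function(moduleGenes, tfs, network,
                               minModuleEdges = 1L) {
  g <- network@graph
  nodes <- igraph::V(g)$name
  if (!all(moduleGenes %in% nodes))
    stop("input error: module genes must all be network nodes")
  tf_in <- intersect(moduleGenes, tfs)
  if (length(tf_in) == 0L)
    return(data.frame(tf_id = character(), module_degree = integer()))
  sub <- igraph::induced_subgraph(g, moduleGenes)
  deg <- igraph::degree(sub)
  d <- deg[tf_in]
  keep <- d >= minModuleEdges
  out <- data.frame(tf_id = tf_in[keep],
                    module_degree = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$module_degree, .radixRank(out$tf_id)), , drop = FALSE]
}

#' Assign miRNA and TF regulators to every module
#'
#' Convenience wrapper running [assignMirnaRegulators()] and
#' [assignTfRegulators()] over a [ModuleSet-class]; a module is coregulated
#' when it receives at least one regulator of each kind.
#'
#' @inheritParams assignMirnaRegulators
#' @inheritParams assignTfRegulators
#' @param modules a [ModuleSet-class].
#' @return list with \code{mirna} (data.frame module_id, mirna_id, ...,
#'   p_value), \code{tf} (data.frame module_id, tf_id, module_degree) and
#'   \code{coregulated} (named logical per module).
#' @export
assignRegulators <- function(modules, demirs, targets, tfs, network,
                             universe = networkNodes(network), alpha = 0.01,
                             minModuleEdges = 1L) {
  sets <- moduleGenes(modules)
  mir <- list(); tf <- list(); coreg <- logical(length(sets))
  names(coreg) <- names(sets)
  for (id in names(sets)) {
    mi <- assignMirnaRegulators(sets[[id]], demirs, targets, universe, alpha)
    ti <- assignTfRegulators(sets[[id]], tfs, network, minModuleEdges)
    if (nrow(mi))
      mir[[id]] <- cbind(data.frame(module_id = id,
                                    stringsAsFactors = FALSE), mi)
    if (nrow(ti))
      tf[[id]] <- cbind(data.frame(module_id = id,
                                   stringsAsFactors = FALSE), ti)
    coreg[id] <- nrow(mi) > 0L && nrow(ti) > 0L
  }
  empty_mir <- data.frame(module_id = character(), mirna_id = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p_value = numeric())
  empty_tf <- data.frame(module_id = character(), tf_id = character(),
                         module_degree = integer())
  list(mirna = if (length(mir)) do.call(rbind, c(mir, list(make.row.names = FALSE))) else empty_mir,
       tf = if (length(tf)) do.call(rbind, c(tf, list(make.row.names = FALSE))) else empty_tf,
       coregulated = coreg)
}
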