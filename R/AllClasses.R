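#' @import methods
#' @importFrom stats cor median p.adjust pt qt phyper rnorm rbinom runif sd
#' @importFrom utils read.delim write.table head
NULL

#' Weighted gene coexpression network
#'
#' Undirected weighted graph over genes.  An edge links two genes whose
#' expression profiles across the samples used for construction are
#' positively and significantly correlated (Pearson); the edge weight is the
#' correlation coefficient and each edge carries its two-sided p-value.
#' Isolated genes are not part of the node set.
#'
#' @slot graph an \code{igraph} undirected graph with edge attributes
#'   \code{weight} (Pearson r) and \code{p} (two-sided p-value).
#' @slot nSamples integer, number of samples used for the correlation tests.
#' @slot alpha numeric, the edge significance threshold used at construction.
#'
#' @seealso [buildCoexpressionNetwork()]
#' @export
setClass("CoexpressionNetwork",
  representation(graph = "ANY", nSamples = "integer", alpha = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "'graph' must be an igraph object")
  else {
    g <- object@graph
    if (igraph::is_directed(g))
      msg <- c(msg, "graph must be undirected")
    if (igraph::ecount(g) > 0) {
      if (is.null(igraph::E(g)$weight))
        msg <- c(msg, "edges must carry a 'weight' attribute")
      else if (any(igraph::E(g)$weight <= 0))
        msg <- c(msg, "all edge weights must be positive correlations")
      if (any(igraph::which_loop(g)))
        msg <- c(msg, "self-edges are not allowed")
      if (any(igraph::which_multiple(g)))
        msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (length(object@nSamples) != 1L || object@nSamples < 3L)
    msg <- c(msg, "'nSamples' must be a single integer >= 3")
  if (length(msg)) msg else TRUE
})

#' Set of gene modules detected in a coexpression network
#'
#' Holds the gene membership of each module together with per-module summary
#' statistics: size, internal edge count, internal and boundary edge weight,
#' cohesiveness and internal edge density.
#'
#' @slot modules named list of character vectors (gene ids per module); names
#'   are module ids.
#' @slot stats \code{data.frame} with one row per module: \code{module_id},
#'   \code{size}, \code{n_internal_edges}, \code{internal_weight},
#'   \code{boundary_weight}, \code{cohesiveness}, \code{density}.
#' @slot params list of detection parameters used (see [detectionParams()]).
#'
#' @seealso [detectModules()], [mergeModulesByOverlap()]
#' @export
setClass("ModuleSet",
  representation(modules = "list", stats = "data.frame", params = "list"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (nrow(object@stats) != length(object@modules))
    msg <- c(msg, "'stats' must have one row per module")
  if (length(object@modules)) {
    if (is.null(names(object@modules)) || anyDuplicated(names(object@modules)))
      msg <- c(msg, "modules must be uniquely named")
    if (any(vapply(object@modules, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "module gene sets must not contain duplicates")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus miRNA-to-target map
#'
#' Maps each miRNA to the set of target genes retained by the consensus
#' filter: an interaction is kept when it is supported by at least
#' \code{minSources} prediction tools or is experimentally validated.
#'
#' @slot targets named list: miRNA id -> character vector of target gene ids.
#' @slot minSources integer, the prediction-source support threshold used.
#'
#' @seealso [buildConsensusTargets()]
#' @export
setClass("TargetMap",
  representation(targets = "list", minSources = "integer"))

setValidity("TargetMap", function(object) {
  msg <- character()
  if (length(object@targets)) {
    if (is.null(names(object@targets)) || anyDuplicated(names(object@targets)))
      msg <- c(msg, "'targets' must be a uniquely named list")
    if (any(lengths(object@targets) == 0L))
      msg <- c(msg, "every miRNA in the map must retain at least one target")
  }
  if (length(msg)) msg else TRUE
})

#' Tripartite TF-miRNA-gene coregulation network
#'
#' The end product of the pipeline: the modules that are enriched with
#' differentially expressed genes and carry at least one TF regulator and at
#' least one miRNA regulator, assembled into one typed graph.  Node types are
#' \code{"gene"}, \code{"tf"} (a TF that is itself a module gene) and
#' \code{"mirna"}; gene-gene edges are module-internal coexpression edges and
#' mirna-gene edges are consensus target interactions within the module.
#'
#' @slot graph an \code{igraph} graph with vertex attributes \code{type} and
#'   \code{module_id}, and an edge attribute \code{edge_type} in
#'   \code{{"coexpression", "targeting"}}.
#' @slot summary per-module summary \code{data.frame}: \code{module_id},
#'   \code{n_nodes}, \code{n_edges}, \code{mirnas}, \code{tfs}.
#' @slot mirnaAssignments \code{data.frame} of (module_id, mirna_id, p_value).
#' @slot tfAssignments \code{data.frame} of (module_id, tf_id, module_degree).
#' @slot targetEdges \code{data.frame} of (module_id, mirna_id, gene_id)
#'   in-module target interactions.
#'
#' @seealso [buildCoregulationNetwork()]
#' @export
setClass("CoregulationNetwork",
  representation(graph = "ANY", summary = "data.frame",
                 mirnaAssignments = "data.frame", tfAssignments = "data.frame",
                 targetEdges = "data.frame"))

setValidity("CoregulationNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "'graph' must be an igraph object")
  if (nrow(object@summary)) {
    has_mirna <- nzchar(object@summary$mirnas)
    has_tf <- nzchar(object@summary$tfs)
    if (!all(has_mirna & has_tf))
      msg <- c(msg, "every module must have >=1 miRNA and >=1 TF regulator")
  }
  if (length(msg)) msg else TRUE
})
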