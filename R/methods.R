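#' @describeIn CoexpressionNetwork-class the underlying igraph object.
#' @export
setMethod("networkGraph", "CoexpressionNetwork", function(x) x@graph)

#' @describeIn CoexpressionNetwork-class character vector of node (gene) ids.
#' @export
setMethod("networkNodes", "CoexpressionNetwork",
  function(x) igraph::V(x@graph)$name)

#' @describeIn CoexpressionNetwork-class edge table:
#'   \code{gene1, gene2, weight, p}.
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(gene1 = character(), gene2 = character(),
                      weight = numeric(), p = numeric()))
  el <- igraph::as_edgelist(g)
  data.frame(gene1 = el[, 1L], gene2 = el[, 2L],
             weight = igraph::E(g)$weight, p = igraph::E(g)$p)
})

setMethod("show", "CoexpressionNetwork", function(object) {
  g <- object@graph
  cat("CoexpressionNetwork with", igraph::vcount(g), "genes and",
      igraph::ecount(g), "edges\n")
  cat("  built from", object@nSamples, "samples at alpha =", object@alpha, "\n")
  if (igraph::ecount(g) > 0L)
    cat("  edge weight (Pearson r) range: ",
        paste(signif(range(igraph::E(g)$weight), 4), collapse = " .. "), "\n")
})

#' @describeIn ModuleSet-class named list of module gene sets.
#' @export
setMethod("moduleGenes", "ModuleSet", function(x) x@modules)

#' @describeIn ModuleSet-class per-module summary statistics.
#' @export
setMethod("moduleStats", "ModuleSet", function(x) x@stats)

#' @describeIn ModuleSet-class number of modules.
#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

#' @describeIn ModuleSet-class subset to the modules selected by \code{i}.
#' @param i index vector (integer, logical or module-id character).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ModuleSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@modules))
  new("ModuleSet", modules = x@modules[i],
      stats = x@stats[match(names(x@modules[i]), x@stats$module_id), ,
                      drop = FALSE],
      params = x@params)
})

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet with", length(object@modules), "modules\n")
  if (length(object@modules)) {
    cat("  sizes:", paste(range(lengths(object@modules)), collapse = " .. "),
        " cohesiveness:",
        paste(signif(range(object@stats$cohesiveness), 4), collapse = " .. "),
        "\n")
    print(head(object@stats, 5L), row.names = FALSE)
    if (nrow(object@stats) > 5L) cat("  ...\n")
  }
})

#' @describeIn TargetMap-class target genes of one miRNA (character vector,
#'   empty if the miRNA is absent from the map).
#' @param mirna single miRNA id.
#' @param ... ignored.
#' @export
setMethod("targetsOf", "TargetMap", function(x, mirna, ...) {
  stopifnot(length(mirna) == 1L)
  if (!mirna %in% names(x@targets)) return(character())
  x@targets[[mirna]]
})

#' @describeIn TargetMap-class number of miRNAs in the map.
#' @export
setMethod("length", "TargetMap", function(x) length(x@targets))

#' @describeIn TargetMap-class miRNA ids present in the map.
#' @export
setMethod("names", "TargetMap", function(x) names(x@targets))

setMethod("show", "TargetMap", function(object) {
  cat("TargetMap:", length(object@targets), "miRNAs,",
      sum(lengths(object@targets)), "consensus interactions",
      sprintf("(>=%d sources or experimental)\n", object@minSources))
})

#' @describeIn CoregulationNetwork-class the underlying typed igraph object.
#' @export
setMethod("networkGraph", "CoregulationNetwork", function(x) x@graph)

#' @describeIn CoregulationNetwork-class per-module summary table (module id,
#'   node count, edge count, regulator lists).
#' @export
setMethod("moduleSummary", "CoregulationNetwork", function(x) x@summary)

setMethod("show", "CoregulationNetwork", function(object) {
  cat("CoregulationNetwork with", nrow(object@summary), "coregulated modules\n")
  if (nrow(object@summary)) {
    v <- igraph::V(object@graph)$type
    cat("  nodes:", sum(v == "gene"), "genes,", sum(v == "tf"), "TFs,",
        sum(v == "mirna"), "miRNAs\n")
    print(object@summary, row.names = FALSE)
  }
})
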