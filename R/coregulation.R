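#' Assemble the TF-miRNA coregulation network
#'
#' Keeps exactly the modules that received at least one miRNA regulator and
#' at least one TF regulator ("coregulated") and assembles them into one
#' typed graph: module genes (TF members typed \code{"tf"}, others
#' \code{"gene"}) connected by their module-internal coexpression edges, and
#' miRNA regulator nodes connected to the module genes they target in the
#' consensus map.  A per-module summary lists node count, internal edge
#' count and the regulator lists.
#'
#' @param modules the retained (DEG-enriched) [ModuleSet-class].
#' @param assignments result of [assignRegulators()] for these modules.
#' @param targets the consensus [TargetMap-class].
#' @param network the [CoexpressionNetwork-class].
#' @return a [CoregulationNetwork-class]; empty (with a warning) when no
#'   module is coregulated.
#' @export
buildCoregulationNetwork <- function(modules, assignments, targets, network) {
  stopifnot(is(modules, "ModuleSet"), is(targets, "TargetMap"))
  sets <- moduleGenes(modules)
  coreg_ids <- names(which(assignments$coregulated[names(sets)]))
  if (length(coreg_ids) == 0L) {
    warning("no coregulated modules: coregulation network is empty",
            call. = FALSE)
    return(new("CoregulationNetwork",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               summary = .emptyCoregSummary(),
               mirnaAssignments = assignments$mirna[0, , drop = FALSE],
               tfAssignments = assignments$tf[0, , drop = FALSE],
               targetEdges = data.frame(module_id = character(),
                                        mirna_id = character(),
                                        gene_id = character())))
  }
  g <- network@graph
  vattr <- list(name = character(), type = character(),
                module_id = character())
  eattr <- data.frame(from = character(), to = character(),
                      weight = numeric(), edge_type = character(),
                      module_id = character(), stringsAsFactors = FALSE)
  tedges <- list(); summ <- list()
  for (id in coreg_ids) {
    genes <- sets[[id]]
    mi <- assignments$mirna[assignments$mirna$module_id == id, , drop = FALSE]
    ti <- assignments$tf[assignments$tf$module_id == id, , drop = FALSE]
    stopifnot(nrow(mi) > 0L, nrow(ti) > 0L, all(ti$tf_id %in% genes))
    sub <- igraph::induced_subgraph(g, genes)
    el <- igraph::as_edgelist(sub)
    if (nrow(el)) {
      eattr <- rbind(eattr, data.frame(
        from = el[, 1L], to = el[, 2L],
        weight = igraph::E(sub)$weight, edge_type = "coexpression",
        module_id = id, stringsAsFactors = FALSE))
    }
    for (m in mi$mirna_id) {
      tg <- intersect(targetsOf(targets, m), genes)
      if (length(tg))
        tedges[[paste(id, m)]] <- data.frame(
          module_id = id, mirna_id = m, gene_id = tg,
          stringsAsFactors = FALSE)
    }
    new_nodes <- c(genes, setdiff(mi$mirna_id, vattr$name))
    new_nodes <- setdiff(new_nodes, vattr$name)
    types <- ifelse(new_nodes %in% mi$mirna_id, "mirna",
                    ifelse(new_nodes %in% ti$tf_id, "tf", "gene"))
    vattr$name <- c(vattr$name, new_nodes)
    vattr$type <- c(vattr$type, types)
    vattr$module_id <- c(vattr$module_id, rep(id, length(new_nodes)))
    summ[[id]] <- data.frame(
      module_id = id, n_nodes = length(genes),
      n_edges = igraph::ecount(sub),
      mirnas = paste(mi$mirna_id, collapse = ","),
      tfs = paste(ti$tf_id, collapse = ","), stringsAsFactors = FALSE)
  }
  tedges <- if (length(tedges)) do.call(rbind, c(tedges, list(make.row.names = FALSE)))
    else data.frame(module_id = character(), mirna_id = character(),
                    gene_id = character())
  if (nrow(tedges))
    eattr <- rbind(eattr, data.frame(
      from = tedges$mirna_id, to = tedges$gene_id, weight = NA_real_,
      edge_type = "targeting", module_id = tedges$module_id,
      stringsAsFactors = FALSE))
  cg <- igraph::graph_from_data_frame(
    eattr, directed = FALSE,
    vertices = data.frame(name = vattr$name, type = vattr$type,
                          module_id = vattr$module_id,
                          stringsAsFactors = FALSE))
  net <- new("CoregulationNetwork", graph = cg,
             summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
             mirnaAssignments = assignments$mirna[
               assignments$mirna$module_id %in% coreg_ids, , drop = FALSE],
             tfAssignments = assignments$tf[
               assignments$tf$module_id %in% coreg_ids, , drop = FALSE],
             targetEdges = tedges)
  .assertCoregSound(net, targets, sets)
  net
}

.emptyCoregSummary <- function()
  data.frame(module_id = character(), n_nodes = integer(),
             n_edges = integer(), mirnas = character(), tfs = character())

# structural soundness checks run on every build
.assertCoregSound <- function(net, targets, sets) {
  te <- net@targetEdges
  if (nrow(te)) {
    ok <- mapply(function(m, g) g %in% targetsOf(targets, m),
                 te$mirna_id, te$gene_id)
    stopifnot(all(ok))
    stopifnot(all(mapply(function(mod, g) g %in% sets[[mod]],
                         te$module_id, te$gene_id)))
  }
  v <- igraph::V(net@graph)
  stopifnot(all(v$type %in% c("gene", "tf", "mirna")))
  invisible(TRUE)
}

#' miRNA-target expression anticorrelation report
#'
#' For every (module, miRNA regulator) pair of a coregulation network,
#' computes the Pearson correlation between the miRNA's expression profile
#' and each of its in-module target genes' profiles across the samples
#' shared by the two matrices (all matched samples by default, cases only
#' via \code{samples = "case"}).  Repressive regulation predicts negative
#' correlations; a miRNA is labelled \code{"negative"} when its summary
#' (median by default) target correlation is below zero.
#'
#' @param mirnaExpr,geneExpr miRNA and gene expression (SummarizedExperiment
#'   or named numeric matrix).
#' @param coreg a [CoregulationNetwork-class].
#' @param labels named case/control labels; required for
#'   \code{samples = "case"}.
#' @param samples \code{"all"} (default) or \code{"case"}.
#' @param summary \code{"median"} (default) or \code{"mean"}.
#' @return list with \code{pairs} (\code{module_id, mirna_id, gene_id, r})
#'   and \code{summary} (\code{module_id, mirna_id, n_targets, summary_r,
#'   direction}).
#' @export
mirnaTargetAnticorrelation <- function(mirnaExpr, geneExpr, coreg,
                                       labels = NULL,
                                       samples = c("all", "case"),
                                       summary = c("median", "mean")) {
  samples <- match.arg(samples)
  summary <- match.arg(summary)
  mm <- .exprMatrix(mirnaExpr)
  gm <- .exprMatrix(geneExpr)
  shared <- intersect(colnames(mm), colnames(gm))
  if (samples == "case") {
    labels <- .resolveLabels(geneExpr, labels, shared)
    shared <- shared[labels[shared] == "case"]
  }
  if (length(shared) < 3L)
    stop("input error: need at least 3 shared samples between the miRNA ",
         "and gene matrices (got ", length(shared), ")")
  te <- coreg@targetEdges
  pairs <- data.frame(module_id = character(), mirna_id = character(),
                      gene_id = character(), r = numeric())
  if (nrow(te)) {
    keep <- te$mirna_id %in% rownames(mm) & te$gene_id %in% rownames(gm)
    if (any(!keep))
      message(sum(!keep), " target pair(s) without measured expression ",
              "excluded from the anticorrelation report")
    te <- te[keep, , drop = FALSE]
    if (nrow(te)) {
      r <- vapply(seq_len(nrow(te)), function(i) {
        x <- mm[te$mirna_id[i], shared]
        y <- gm[te$gene_id[i], shared]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        stats::cor(x, y)
      }, 0)
      pairs <- data.frame(module_id = te$module_id, mirna_id = te$mirna_id,
                          gene_id = te$gene_id, r = r,
                          stringsAsFactors = FALSE)
    }
  }
  sfun <- if (summary == "median") stats::median else mean
  if (nrow(pairs)) {
    key <- paste(pairs$module_id, pairs$mirna_id, sep = "\r")
    idx <- split(seq_len(nrow(pairs)), factor(key, levels = unique(key)))
    summ <- do.call(rbind, lapply(idx, function(i) {
      r <- pairs$r[i]
      s <- sfun(r[!is.na(r)])
      data.frame(module_id = pairs$module_id[i[1L]],
                 mirna_id = pairs$mirna_id[i[1L]],
                 n_targets = length(i), summary_r = s,
                 direction = if (!is.na(s) && s < 0) "negative"
                             else "non-negative",
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  } else {
    summ <- data.frame(module_id = character(), mirna_id = character(),
                       n_targets = integer(), summary_r = numeric(),
                       direction = character())
  }
  list(pairs = pairs, summary = summ)
}
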