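#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [runPipeline()], with
#' the documented default thresholds (t-test alpha 0.05, network edge alpha
#' 0.05, DEG-enrichment alpha 0.01, miRNA-regulator alpha 0.01) and
#' detection parameters ([detectionParams()]).  Input paths must be filled
#' in by the caller.
#'
#' @param gene_expr,mirna_expr,labels,targets,tfs input file paths (TSV /
#'   list formats of the \code{read*} functions).
#' @param out_dir output directory (created if absent).
#' @param ... named overrides of any default (e.g. \code{alpha_de},
#'   \code{alpha_network}, \code{alpha_enrichment}, \code{alpha_regulator},
#'   \code{detection}, \code{min_sources}, \code{min_module_edges},
#'   \code{network_samples}, \code{anticorrelation_samples},
#'   \code{anticorrelation_summary}, \code{var_equal}, \code{seed}).
#' @return a named configuration list.
#' @export
pipelineConfig <- function(gene_expr, mirna_expr, labels, targets, tfs,
                           out_dir, ...) {
  cfg <- list(gene_expr = gene_expr, mirna_expr = mirna_expr,
              labels = labels, targets = targets, tfs = tfs,
              out_dir = out_dir,
              alpha_de = 0.05, alpha_network = 0.05,
              alpha_enrichment = 0.01, alpha_regulator = 0.01,
              detection = unclass(detectionParams()),
              min_sources = 2L, min_module_edges = 1L,
              network_samples = "case",
              anticorrelation_samples = "all",
              anticorrelation_summary = "median",
              var_equal = TRUE, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full coregulated-module inference pipeline
#'
#' Executes every stage in order: differential calling of genes and miRNAs,
#' coexpression-network construction over case samples, cohesiveness-based
#' module detection, the one-third overlap merge, DEG-enrichment filtering,
#' miRNA/TF regulator assignment, coregulation-network assembly and the
#' miRNA-target anticorrelation report.  Every intermediate table is
#' written to \code{out_dir} as TSV, the networks as GraphML, plus a JSON
#' run report with the stage counts and a log file.  The run is
#' deterministic: identical config (and inputs) reproduce byte-identical
#' tables, GraphML files and report.
#'
#' @param config a configuration list from [pipelineConfig()], or the path
#'   to a JSON file holding one.
#' @return invisibly, a list with all in-memory results (\code{degs},
#'   \code{demirs}, \code{network}, \code{modules}, \code{merged},
#'   \code{enrichment}, \code{assignments}, \code{coregulation},
#'   \code{anticorrelation}, \code{report}) and \code{out_dir}.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("gene_expr", "mirna_expr", "labels", "targets", "tfs", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing field(s): ", paste(miss, collapse = ", "))
  defaults <- pipelineConfig("", "", "", "", "", "")
  for (f in setdiff(names(defaults), names(config)))
    config[[f]] <- defaults[[f]]
  det <- do.call(detectionParams, list(
    penalty = config$detection$penalty,
    minSize = config$detection$minSize %||% config$detection$min_size %||% 3L,
    minDensity = config$detection$minDensity %||%
      config$detection$min_density %||% 0.3,
    mergeOverlapOmega = config$detection$mergeOverlapOmega %||%
      config$detection$merge_overlap_omega %||% 0.8))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  cat("pipeline run\n", file = logfile)
  logln <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    logln("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tsv <- function(df, name) {
    num <- vapply(df, is.numeric, NA)
    out <- df
    for (cn in names(df)[num])
      out[[cn]] <- format(df[[cn]], digits = 15, trim = TRUE,
                          scientific = TRUE)
    write.table(out, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  gene_se <- stage("read_gene_expression",
                   readExpression(config$gene_expr, "gene"))
  mirna_se <- stage("read_mirna_expression",
                    readExpression(config$mirna_expr, "mirna"))
  labels <- stage("read_labels", readSampleLabels(config$labels))
  evidence <- stage("read_targets", readTargetTable(config$targets))
  tfs <- stage("read_tfs", readTFList(config$tfs))
  logln("inputs: ", nrow(gene_se), " genes, ", nrow(mirna_se), " miRNAs, ",
        length(labels), " labelled samples, ", nrow(evidence),
        " target-evidence pairs, ", length(tfs), " TFs")

  degs_tab <- stage("differential_genes",
    callDifferential(gene_se, labels, alpha = config$alpha_de,
                     varEqual = config$var_equal))
  demirs_tab <- stage("differential_mirnas",
    callDifferential(mirna_se, labels, alpha = config$alpha_de,
                     varEqual = config$var_equal))
  degs <- degs_tab$feature_id[degs_tab$significant]
  demirs <- demirs_tab$feature_id[demirs_tab$significant]
  tsv(degs_tab, "degs.tsv"); tsv(demirs_tab, "demirs.tsv")
  logln(length(degs), " DEGs and ", length(demirs),
        " DemiRs at alpha = ", config$alpha_de)

  network <- stage("coexpression_network",
    buildCoexpressionNetwork(gene_se, labels, alpha = config$alpha_network,
                             samples = config$network_samples))
  writeNetwork(network, file.path(config$out_dir, "net.graphml"), "graphml")
  logln("network: ", igraph::vcount(network@graph), " nodes, ",
        igraph::ecount(network@graph), " edges")

  detected <- stage("module_detection", detectModules(network, det))
  .writeModuleSet(detected, config$out_dir, "modules")
  logln(length(detected), " modules detected")

  merged <- stage("module_merge", mergeModulesByOverlap(detected, network))
  .writeModuleSet(merged, config$out_dir, "modules_merged")
  logln(length(merged), " modules after one-third overlap merge")

  universe <- networkNodes(network)
  enr <- stage("deg_enrichment",
    filterModulesByDEG(merged, degs, universe,
                       alpha = config$alpha_enrichment))
  tsv(enr$table, "enrich.tsv")
  logln(length(enr$retained), " modules enriched with DEGs at alpha = ",
        config$alpha_enrichment)

  targets <- stage("consensus_targets",
    buildConsensusTargets(evidence, minSources = config$min_sources))
  logln("consensus target map: ", length(targets), " miRNAs, ",
        sum(lengths(targets@targets)), " interactions")

  if (length(setdiff(tfs, rownames(gene_se))))
    logln(length(setdiff(tfs, rownames(gene_se))),
          " TF(s) not measured in the gene matrix are ignored")
  assignments <- stage("regulator_assignment",
    assignRegulators(enr$retained, demirs, targets, tfs, network,
                     universe = universe, alpha = config$alpha_regulator,
                     minModuleEdges = config$min_module_edges))
  reg_tab <- rbind(
    if (nrow(assignments$mirna))
      data.frame(module_id = assignments$mirna$module_id,
                 regulator_type = "mirna",
                 regulator_id = assignments$mirna$mirna_id,
                 p_value = assignments$mirna$p_value,
                 module_degree = NA_integer_)
    else NULL,
    if (nrow(assignments$tf))
      data.frame(module_id = assignments$tf$module_id,
                 regulator_type = "tf",
                 regulator_id = assignments$tf$tf_id,
                 p_value = NA_real_,
                 module_degree = assignments$tf$module_degree)
    else NULL)
  if (is.null(reg_tab))
    reg_tab <- data.frame(module_id = character(),
                          regulator_type = character(),
                          regulator_id = character(), p_value = numeric(),
                          module_degree = integer())
  tsv(reg_tab, "regulators.tsv")
  logln(sum(assignments$coregulated), " coregulated modules")

  coreg <- stage("coregulation_assembly", withCallingHandlers(
    buildCoregulationNetwork(enr$retained, assignments, targets, network),
    warning = function(w) {
      logln("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  writeNetwork(coreg, file.path(config$out_dir, "coregulation.graphml"),
               "graphml")
  tsv(coreg@targetEdges, "target_edges.tsv")

  anti <- stage("anticorrelation", mirnaTargetAnticorrelation(
    mirna_se, gene_se, coreg, labels = labels,
    samples = config$anticorrelation_samples,
    summary = config$anticorrelation_summary))
  tsv(anti$summary, "anticorrelation.tsv")
  tsv(anti$pairs, "anticorrelation_pairs.tsv")

  report <- list(
    seed = config$seed,
    thresholds = config[c("alpha_de", "alpha_network", "alpha_enrichment",
                          "alpha_regulator")],
    detection = unclass(det),
    counts = list(
      n_genes = nrow(gene_se), n_mirnas = nrow(mirna_se),
      n_samples = length(labels),
      n_case = sum(labels == "case"), n_control = sum(labels == "control"),
      n_degs = length(degs), n_demirs = length(demirs),
      n_network_nodes = igraph::vcount(network@graph),
      n_network_edges = igraph::ecount(network@graph),
      n_modules_detected = length(detected),
      n_modules_after_merge = length(merged),
      n_deg_enriched = length(enr$retained),
      n_coregulated = sum(assignments$coregulated)),
    coregulated_modules = coreg@summary,
    anticorrelation = anti$summary)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logln("done")
  invisible(list(degs = degs_tab, demirs = demirs_tab, network = network,
                 modules = detected, merged = merged, enrichment = enr,
                 targets = targets, assignments = assignments,
                 coregulation = coreg, anticorrelation = anti,
                 report = report, out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeModuleSet <- function(ms, dir, stem) {
  sets <- moduleGenes(ms)
  long <- if (length(sets))
    data.frame(module_id = rep(names(sets), lengths(sets)),
               gene_id = unlist(sets, use.names = FALSE))
  else data.frame(module_id = character(), gene_id = character())
  write.table(long, file.path(dir, paste0(stem, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  st <- moduleStats(ms)
  num <- vapply(st, is.numeric, NA)
  for (cn in names(st)[num])
    st[[cn]] <- format(st[[cn]], digits = 15, trim = TRUE, scientific = TRUE)
  write.table(st, file.path(dir, paste0(stem, "_summary.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
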