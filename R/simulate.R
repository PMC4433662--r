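#' Configuration for the synthetic matched expression dataset
#'
#' Describes the world the generator emulates: a small matched case/control
#' cohort (7 vs 7 by default, the typical size of the microarray studies
#' this pipeline targets) with planted correlated gene modules, planted
#' differential features, planted TF members and planted repressive miRNA
#' regulators, plus a multi-source miRNA-target evidence table with
#' controllable per-source sensitivity and false-positive rate.
#'
#' Module coexpression follows a single-latent-factor model: gene \eqn{g} of
#' module \eqn{m} has profile
#' \eqn{\sigma(\lambda_m F_m + \sqrt{1-\lambda_m^2}\,\epsilon)} with
#' \eqn{F_m, \epsilon \sim N(0,1)} i.i.d. per sample, so any two genes of
#' the module have population correlation \eqn{\lambda_m^2} and genes of
#' different modules are uncorrelated.  Each module's repressor miRNA loads
#' on \eqn{F_m} with the negative coefficient \code{repressor_loading}
#' \eqn{\rho}, giving population miRNA-target correlation
#' \eqn{\lambda_m \rho}; the default \eqn{0.9 \times (-0.89) \approx -0.8}
#' emulates strong repression.  All module genes are planted as
#' down-regulated in cases and each repressor as up-regulated (shift
#' \code{de_effect} noise-sd units), mirroring repressive regulation in the
#' disease state; background features are differential with probability
#' \code{de_fraction_background} and random sign.
#'
#' @param n_case,n_control samples per group (default 7 and 7).
#' @param n_genes,n_mirnas feature counts (defaults 1000 and 60).
#' @param modules list of \code{list(size =, lambda =)} per planted module
#'   (default two modules of sizes 25 and 30 with loading 0.9).
#' @param noise_sd residual standard deviation (default 1).
#' @param de_effect planted case shift in noise-sd units (default 2).
#' @param de_fraction_background probability that a background feature is
#'   differential (default 0.1).
#' @param n_tf_per_module planted TF members per module (default 2).
#' @param regulator_coverage fraction of module genes targeted by the
#'   module's repressor miRNA (default 0.6).
#' @param background_target_rate probability that any other (miRNA, gene)
#'   pair is a true interaction (default 0.05).
#' @param source_sensitivity named per-source detection probability on true
#'   pairs (default 0.7 for four prediction tools).
#' @param source_fpr named per-source false-positive probability on
#'   non-pairs (default 0.01).
#' @param experimental_sensitivity probability that a true pair carries the
#'   experimental-validation flag (default 0.1).
#' @param repressor_loading negative loading of each repressor miRNA on its
#'   module factor (default -0.89).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_case = 7L, n_control = 7L, n_genes = 1000L,
                      n_mirnas = 60L,
                      modules = list(list(size = 25L, lambda = 0.9),
                                     list(size = 30L, lambda = 0.9)),
                      noise_sd = 1, de_effect = 2,
                      de_fraction_background = 0.1, n_tf_per_module = 2L,
                      regulator_coverage = 0.6,
                      background_target_rate = 0.05,
                      source_sensitivity = c(PicTar = 0.7, miRanda = 0.7,
                                             MicroT = 0.7, TargetScan = 0.7),
                      source_fpr = c(PicTar = 0.01, miRanda = 0.01,
                                     MicroT = 0.01, TargetScan = 0.01),
                      experimental_sensitivity = 0.1,
                      repressor_loading = -0.89, seed = 1L) {
  stopifnot(n_case >= 2L, n_control >= 2L, n_genes >= 1L, noise_sd > 0,
            de_fraction_background >= 0, de_fraction_background <= 1,
            regulator_coverage >= 0, regulator_coverage <= 1,
            background_target_rate >= 0, background_target_rate <= 1,
            experimental_sensitivity >= 0, experimental_sensitivity <= 1,
            repressor_loading <= 0, repressor_loading >= -1,
            length(source_sensitivity) == length(source_fpr),
            identical(names(source_sensitivity), names(source_fpr)),
            all(source_sensitivity >= 0 & source_sensitivity <= 1),
            all(source_fpr >= 0 & source_fpr <= 1))
  sizes <- vapply(modules, function(m) as.integer(m$size), 0L)
  lambdas <- vapply(modules, function(m) as.numeric(m$lambda), 0)
  stopifnot(all(lambdas > 0 & lambdas <= 1))
  if (sum(sizes) > n_genes)
    stop("config error: module sizes (", sum(sizes),
         ") exceed n_genes (", n_genes, ")")
  if (length(modules) > n_mirnas)
    stop("config error: need one repressor miRNA per module")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas), modules = modules,
                 noise_sd = noise_sd, de_effect = de_effect,
                 de_fraction_background = de_fraction_background,
                 n_tf_per_module = as.integer(n_tf_per_module),
                 regulator_coverage = regulator_coverage,
                 background_target_rate = background_target_rate,
                 source_sensitivity = source_sensitivity,
                 source_fpr = source_fpr,
                 experimental_sensitivity = experimental_sensitivity,
                 repressor_loading = repressor_loading,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a synthetic matched case/control dataset with ground truth
#'
#' Draws matched gene and miRNA expression matrices, sample labels, a
#' multi-source miRNA-target evidence table and a TF list from a
#' [simConfig()], together with the full ground truth (module memberships,
#' differential flags, planted regulators and true target pairs).  Fully
#' reproducible: the same config (including its seed) yields identical
#' output.
#'
#' @param config a [simConfig()] object.
#' @return a list of class \code{"SimulatedDataset"} with elements
#'   \code{geneExpr} and \code{mirnaExpr} (SummarizedExperiments with
#'   \code{colData(x)$group}), \code{labels} (named factor),
#'   \code{evidence} (merged evidence table as from [readTargetTable()]),
#'   \code{tfs} (character), \code{truth} (list) and \code{config}.
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, .simulate(config))
}

# Per-sample latent factors, one row per module.  Rows are exactly
# decorrelated (Gram-Schmidt) and standardized within the case block and
# within the control block separately: with the tiny cohorts this generator
# emulates (7 vs 7), independently drawn factors are frequently strongly
# correlated in-sample, which would make "distinct" planted modules
# genuinely coexpressed in the realized data; orthogonalization makes the
# planted modules distinct in-sample, as the stated world intends.  Falls
# back to raw standardized draws when a block is too small to orthogonalize
# that many factors.
.drawFactors <- function(nM, nCase, nControl) {
  ortho <- function(n) {
    F <- matrix(rnorm(nM * n), nM, n)
    F <- F - rowMeans(F)
    if (nM > 1L && nM <= n - 1L) {
      for (i in seq_len(nM)) {
        if (i > 1L) for (j in seq_len(i - 1L))
          F[i, ] <- F[i, ] - sum(F[i, ] * F[j, ]) / sum(F[j, ]^2) * F[j, ]
        F[i, ] <- F[i, ] - mean(F[i, ])
      }
    }
    F / apply(F, 1L, sd)
  }
  cbind(ortho(nCase), ortho(nControl))
}

.simulate <- function(cfg) {
  nS <- cfg$n_case + cfg$n_control
  samples <- c(sprintf("case%02d", seq_len(cfg$n_case)),
               sprintf("ctrl%02d", seq_len(cfg$n_control)))
  labels <- stats::setNames(
    factor(rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
           levels = c("case", "control")), samples)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  nM <- length(cfg$modules)
  sizes <- vapply(cfg$modules, function(m) as.integer(m$size), 0L)

  # module membership: consecutive blocks at the head of the gene list
  mod_genes <- list()
  off <- 0L
  for (i in seq_len(nM)) {
    mod_genes[[paste0("T", i)]] <- genes[(off + 1L):(off + sizes[i])]
    off <- off + sizes[i]
  }
  background <- genes[setdiff(seq_len(cfg$n_genes), seq_len(off))]

  factors <- .drawFactors(nM, cfg$n_case, cfg$n_control)
  G <- matrix(rnorm(cfg$n_genes * nS), cfg$n_genes, nS,
              dimnames = list(genes, samples))
  de_gene <- stats::setNames(logical(cfg$n_genes), genes)
  for (i in seq_len(nM)) {
    lam <- cfg$modules[[i]]$lambda
    idx <- match(mod_genes[[i]], genes)
    G[idx, ] <- lam * matrix(factors[i, ], length(idx), nS, byrow = TRUE) +
      sqrt(1 - lam^2) * G[idx, , drop = FALSE]
    de_gene[idx] <- TRUE
  }
  de_bg <- runif(length(background)) < cfg$de_fraction_background
  de_gene[background] <- de_bg
  sign_bg <- stats::setNames(sample(c(-1, 1), length(background),
                                    replace = TRUE), background)
  G <- G * cfg$noise_sd
  shift <- cfg$de_effect * cfg$noise_sd
  case_cols <- seq_len(cfg$n_case)
  for (i in seq_len(nM))   # disease modules down-regulated in cases
    G[match(mod_genes[[i]], genes), case_cols] <-
      G[match(mod_genes[[i]], genes), case_cols] - shift
  bg_de_ids <- background[de_bg]
  if (length(bg_de_ids))
    G[bg_de_ids, case_cols] <- G[bg_de_ids, case_cols] +
      shift * sign_bg[bg_de_ids]

  M <- matrix(rnorm(cfg$n_mirnas * nS), cfg$n_mirnas, nS,
              dimnames = list(mirnas, samples))
  de_mirna <- stats::setNames(logical(cfg$n_mirnas), mirnas)
  repressors <- mirnas[seq_len(nM)]
  rho <- cfg$repressor_loading
  for (i in seq_len(nM)) {
    M[i, ] <- rho * factors[i, ] + sqrt(1 - rho^2) * M[i, ]
    de_mirna[i] <- TRUE
  }
  de_mirna_bg <- runif(cfg$n_mirnas - nM) < cfg$de_fraction_background
  de_mirna[(nM + 1L):cfg$n_mirnas] <- de_mirna_bg
  sign_mbg <- sample(c(-1, 1), cfg$n_mirnas - nM, replace = TRUE)
  M <- M * cfg$noise_sd
  M[seq_len(nM), case_cols] <- M[seq_len(nM), case_cols] + shift  # up in cases
  bg_idx <- (nM + 1L):cfg$n_mirnas
  up <- bg_idx[de_mirna_bg]
  if (length(up))
    M[up, case_cols] <- M[up, case_cols] + shift * sign_mbg[de_mirna_bg]

  # TFs: planted members per module plus as many background decoys
  tf_mod <- unlist(lapply(mod_genes, function(g)
    g[seq_len(min(cfg$n_tf_per_module, length(g)))]), use.names = FALSE)
  n_decoy <- max(2L, length(tf_mod))
  tf_bg <- if (length(background)) sample(background,
                                          min(n_decoy, length(background)))
           else character()
  tfs <- sort(unique(c(tf_mod, tf_bg)), method = "radix")

  # true target pairs: planted module coverage + uniform background rate
  truth_pairs <- matrix(FALSE, cfg$n_mirnas, cfg$n_genes,
                        dimnames = list(mirnas, genes))
  planted_pairs <- list()
  for (i in seq_len(nM)) {
    k <- ceiling(cfg$regulator_coverage * sizes[i])
    tg <- sample(mod_genes[[i]], k)
    truth_pairs[i, match(tg, genes)] <- TRUE
    planted_pairs[[i]] <- data.frame(mirna_id = repressors[i], gene_id = tg,
                                     stringsAsFactors = FALSE)
  }
  bg_draw <- matrix(runif(cfg$n_mirnas * cfg$n_genes) <
                      cfg$background_target_rate,
                    cfg$n_mirnas, cfg$n_genes)
  truth_pairs <- truth_pairs | bg_draw

  # per-source evidence with stated sensitivity / false-positive rate
  srcs <- names(cfg$source_sensitivity)
  np <- length(truth_pairs)
  hit <- matrix(FALSE, np, length(srcs), dimnames = list(NULL, srcs))
  for (s in srcs) {
    pr <- ifelse(truth_pairs, cfg$source_sensitivity[[s]],
                 cfg$source_fpr[[s]])
    hit[, s] <- runif(np) < pr
  }
  expflag <- as.vector(truth_pairs) &
    runif(np) < cfg$experimental_sensitivity
  any_ev <- rowSums(hit) > 0L | expflag
  ii <- which(any_ev)
  mir_of <- rep(mirnas, times = cfg$n_genes)   # column-major layout
  gene_of <- rep(genes, each = cfg$n_mirnas)
  evidence <- data.frame(
    mirna_id = mir_of[ii], gene_id = gene_of[ii],
    sources = apply(hit[ii, , drop = FALSE], 1L, function(h)
      paste(srcs[h], collapse = ";")),
    n_sources = rowSums(hit[ii, , drop = FALSE]),
    experimental = expflag[ii], stringsAsFactors = FALSE)

  mk_se <- function(mat, kind) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat),
      colData = S4Vectors::DataFrame(group = as.character(labels),
                                     row.names = samples))
    S4Vectors::metadata(se)$featureKind <- kind
    se
  }
  truth <- list(
    gene_ids = genes, mirna_ids = mirnas,
    modules = mod_genes,
    de_genes = names(which(de_gene)), de_mirnas = names(which(de_mirna)),
    tfs = tfs, tf_module_members = tf_mod,
    regulators = stats::setNames(names(mod_genes), repressors),
    planted_target_pairs = do.call(rbind, planted_pairs),
    target_matrix = truth_pairs)
  structure(list(geneExpr = mk_se(G, "gene"), mirnaExpr = mk_se(M, "mirna"),
                 labels = labels, evidence = evidence, tfs = tfs,
                 truth = truth, config = cfg),
            class = "SimulatedDataset")
}

#' Write a simulated dataset to a directory in the pipeline input formats
#'
#' Emits \code{gene_expr.tsv}, \code{mirna_expr.tsv}, \code{labels.tsv},
#' \code{targets.tsv} (long 4-column evidence format readable by
#' [readTargetTable()]), \code{tfs.txt} and \code{truth.json}.
#'
#' @param sim a \code{"SimulatedDataset"} from [simulateDataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named list of the written file paths.
#' @export
writeDataset <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    gene_expr = file.path(dir, "gene_expr.tsv"),
    mirna_expr = file.path(dir, "mirna_expr.tsv"),
    labels = file.path(dir, "labels.tsv"),
    targets = file.path(dir, "targets.tsv"),
    tfs = file.path(dir, "tfs.txt"),
    truth = file.path(dir, "truth.json"))
  writeExpression(sim$geneExpr, paths$gene_expr)
  writeExpression(sim$mirnaExpr, paths$mirna_expr)
  writeSampleLabels(sim$labels, paths$labels)
  ev <- sim$evidence
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    s <- strsplit(ev$sources[i], ";", fixed = TRUE)[[1L]]
    s <- s[nzchar(s)]
    out <- if (length(s))
      data.frame(mirna_id = ev$mirna_id[i], gene_id = ev$gene_id[i],
                 source = s, experimental = 0L, stringsAsFactors = FALSE)
    else NULL
    if (ev$experimental[i])
      out <- rbind(out, data.frame(mirna_id = ev$mirna_id[i],
                                   gene_id = ev$gene_id[i], source = "",
                                   experimental = 1L,
                                   stringsAsFactors = FALSE))
    out
  })
  write.table(do.call(rbind, rows), paths$targets, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sim$tfs, paths$tfs)
  tr <- sim$truth
  tr$target_matrix <- NULL   # large and reconstructible from pairs
  jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score recovery of planted structure
#'
#' Compares inferred modules, regulator assignments and differential calls
#' against the generator's ground truth.
#'
#' @param truth the \code{truth} element of a [simulateDataset()] result.
#' @param modules a [ModuleSet-class] or list of gene-id character vectors
#'   (optional).
#' @param regulators \code{data.frame} with columns \code{module_id} (an
#'   inferred module id present in \code{modules}) and \code{mirna_id}
#'   (optional).
#' @param degs,demirs character vectors of called differential genes/miRNAs
#'   (optional).
#' @return list with \code{module_jaccard} (named, per planted module: best
#'   Jaccard over inferred modules), \code{regulator} (precision, recall,
#'   tp, fp, fn; an inferred pair counts as true when its module best
#'   matches the planted module of that miRNA) and \code{de}
#'   (gene/miRNA sensitivity and specificity).
#' @export
scoreRecovery <- function(truth, modules = NULL, regulators = NULL,
                          degs = NULL, demirs = NULL) {
  res <- list()
  inf_sets <- NULL
  if (!is.null(modules)) {
    inf_sets <- if (is(modules, "ModuleSet")) moduleGenes(modules)
                else modules
    allg <- unlist(inf_sets, use.names = FALSE)
    if (length(allg) && !all(allg %in% truth$gene_ids))
      stop("input error: inferred module genes outside the ground-truth ",
           "id namespace")
    jac <- vapply(truth$modules, function(tg) {
      if (!length(inf_sets)) return(0)
      max(vapply(inf_sets, function(s)
        length(intersect(s, tg)) / length(union(s, tg)), 0))
    }, 0)
    res$module_jaccard <- jac
  }
  if (!is.null(regulators)) {
    if (is.null(inf_sets))
      stop("input error: scoring regulators requires 'modules'")
    best_truth <- vapply(names(inf_sets), function(id) {
      j <- vapply(truth$modules, function(tg)
        length(intersect(inf_sets[[id]], tg)) /
          max(1L, length(union(inf_sets[[id]], tg))), 0)
      if (all(j == 0)) NA_character_ else names(truth$modules)[which.max(j)]
    }, "")
    truth_pairs <- paste(truth$regulators, names(truth$regulators))
    inf_pairs <- unique(paste(best_truth[regulators$module_id],
                              regulators$mirna_id))
    tp <- sum(inf_pairs %in% truth_pairs)
    fp <- length(inf_pairs) - tp
    fn <- length(truth_pairs) - tp
    res$regulator <- list(
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      tp = tp, fp = fp, fn = fn)
  }
  de <- list()
  if (!is.null(degs)) {
    pos <- truth$de_genes
    neg <- setdiff(truth$gene_ids, pos)
    de$gene_sensitivity <- mean(pos %in% degs)
    de$gene_specificity <- mean(!neg %in% degs)
  }
  if (!is.null(demirs)) {
    pos <- truth$de_mirnas
    neg <- setdiff(truth$mirna_ids, pos)
    de$mirna_sensitivity <- mean(pos %in% demirs)
    de$mirna_specificity <- mean(!neg %in% demirs)
  }
  if (length(de)) res$de <- de
  res
}
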