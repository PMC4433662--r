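#' Read an expression matrix from TSV
#'
#' Reads a features x samples tab-separated table whose header row holds the
#' sample ids and whose first column holds the feature ids.  Values are
#' assumed already normalized (typically log scale).  Rows containing missing
#' values (\code{NA}, \code{NaN} or empty cells) are dropped with a message;
#' rows sharing a feature id are collapsed to their mean with a warning.  Any
#' other non-numeric cell is a parse error naming the offending row and
#' column.
#'
#' @param path path to the TSV file.
#' @param featureKind either \code{"gene"} or \code{"mirna"}; recorded in the
#'   object metadata.
#' @return a [SummarizedExperiment::SummarizedExperiment] with a single assay
#'   \code{"exprs"} and \code{metadata(x)$featureKind}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' writeExpression(m, tf)
#' se <- readExpression(tf, "gene")
#' dim(se)
#' @export
readExpression <- function(path, featureKind = c("gene", "mirna")) {
  featureKind <- match.arg(featureKind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("format error: empty expression file ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("format error: expression file must have a feature-id column and >=1 sample column")
  fid <- trimws(raw[[1L]])
  sample_ids <- trimws(colnames(raw)[-1L])
  if (anyDuplicated(sample_ids))
    stop("format error: duplicate sample ids in header of ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  missing_mask <- is.na(vals) | trimws(vals) %in% c("", "NA", "NaN")
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "parse error: non-numeric value '%s' at feature '%s', sample '%s'",
      vals[bad[1L, 1L], bad[1L, 2L]], fid[bad[1L, 1L]],
      sample_ids[bad[1L, 2L]]))
  drop_rows <- rowSums(missing_mask) > 0L
  if (any(drop_rows)) {
    message(sum(drop_rows), " feature row(s) with missing values dropped")
    num <- num[!drop_rows, , drop = FALSE]
    fid <- fid[!drop_rows]
  }
  if (anyDuplicated(fid)) {
    dup <- unique(fid[duplicated(fid)])
    warning(length(dup), " duplicated feature id(s) collapsed by mean",
            call. = FALSE)
    num <- rowsum(num, group = fid, reorder = FALSE)
    counts <- as.vector(table(factor(fid, levels = rownames(num))))
    num <- num / counts
    fid <- rownames(num)
  }
  if (nrow(num) == 0L) stop("format error: no usable feature rows in ", path)
  dimnames(num) <- list(fid, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = num))
  S4Vectors::metadata(se)$featureKind <- featureKind
  se
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpression()]: the first column (\code{feature_id}) holds
#' feature ids and the remaining columns are samples.  Values are written
#' with 15 significant digits so a write/read round trip preserves them.
#'
#' @param x a SummarizedExperiment (assay \code{"exprs"} used) or a numeric
#'   matrix with dimnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "exprs") else x
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read case/control sample labels
#'
#' Reads a two-column TSV (\code{sample_id}, \code{group}) where group is
#' \code{"case"} or \code{"control"}.
#'
#' @param path path to the TSV file.
#' @return a named factor with levels \code{c("case", "control")}.
#' @export
readSampleLabels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df)))
    stop("format error: label file must have columns ",
         paste(need, collapse = ", "))
  grp <- tolower(trimws(df$group))
  if (!all(grp %in% c("case", "control")))
    stop("format error: group values must be 'case' or 'control', got: ",
         paste(unique(setdiff(grp, c("case", "control"))), collapse = ", "))
  ids <- trimws(df$sample_id)
  if (anyDuplicated(ids)) stop("format error: duplicate sample ids in labels")
  stats::setNames(factor(grp, levels = c("case", "control")), ids)
}

#' Write sample labels to TSV
#' @param labels named factor/character of \code{"case"}/\code{"control"}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSampleLabels <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels),
                         group = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target evidence table
#'
#' Reads a TSV with columns \code{mirna_id}, \code{gene_id}, \code{source}
#' (prediction tool name, empty for purely experimental rows) and
#' \code{experimental} (0/1).  Rows describing the same (miRNA, gene) pair
#' are merged: prediction sources are unioned and the experimental flag is
#' OR-ed, so each pair appears once in the result.
#'
#' @param path path to the TSV file.
#' @return a \code{data.frame} with columns \code{mirna_id}, \code{gene_id},
#'   \code{sources} (";"-separated source names, possibly empty),
#'   \code{n_sources} and \code{experimental} (logical).
#' @export
readTargetTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("mirna_id", "gene_id", "source", "experimental")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("format error: target table missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      sources = character(), n_sources = integer(),
                      experimental = logical()))
  mirna <- trimws(df$mirna_id); gene <- trimws(df$gene_id)
  src <- trimws(df$source)
  exp_raw <- trimws(df$experimental)
  if (!all(exp_raw %in% c("0", "1", "TRUE", "FALSE")))
    stop("format error: 'experimental' must be 0/1")
  expf <- exp_raw %in% c("1", "TRUE")
  key <- paste(mirna, gene, sep = "\r")
  keys <- unique(key)
  idx <- split(seq_along(key), factor(key, levels = keys))
  srcs <- vapply(idx, function(i) {
    s <- sort(unique(src[i][nzchar(src[i])]))
    paste(s, collapse = ";")
  }, character(1))
  res <- data.frame(
    mirna_id = mirna[match(keys, key)],
    gene_id = gene[match(keys, key)],
    sources = unname(srcs),
    n_sources = unname(vapply(
      strsplit(srcs, ";", fixed = TRUE),
      function(s) sum(nzchar(s)), 0L)),
    experimental = unname(vapply(idx, function(i) any(expf[i]), NA)),
    row.names = NULL)
  empty <- !nzchar(res$sources) & !res$experimental
  if (any(empty))
    stop("format error: pair(s) with neither a prediction source nor an ",
         "experimental flag, e.g. ", res$mirna_id[which(empty)[1L]], " -> ",
         res$gene_id[which(empty)[1L]])
  res
}

#' Read a transcription-factor gene list
#'
#' One gene id per line; blank lines ignored, whitespace stripped.
#'
#' @param path path to the list file.
#' @return character vector of unique TF gene ids.
#' @export
readTFList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) stop("format error: empty TF list ", path)
  x
}

#' Write a network to GraphML or a TSV edge list
#'
#' GraphML preserves all node and edge attributes (node types, module ids,
#' weights); the TSV edge list holds one row per edge with its numeric and
#' character attributes and is convenient for spreadsheets, but does not
#' carry node attributes or isolated nodes.
#'
#' @param x a [CoexpressionNetwork-class], [CoregulationNetwork-class] or a
#'   raw \code{igraph} graph.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return invisibly, \code{path}.
#' @seealso [readNetwork()]
#' @export
writeNetwork <- function(x, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- if (igraph::is_igraph(x)) x else networkGraph(x)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(node1 = el[, 1L], node2 = el[, 2L],
                     stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(g)) {
      v <- igraph::edge_attr(g, a)
      df[[a]] <- if (is.numeric(v))
        format(v, digits = 15, trim = TRUE, scientific = FALSE) else v
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path input path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return an \code{igraph} graph (undirected for TSV edge lists).
#' @export
readNetwork <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::V(g)$id) && is.null(igraph::V(g)$name))
      igraph::V(g)$name <- igraph::V(g)$id
    return(g)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(df, directed = FALSE)
}
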