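#' Pearson correlation and its two-sided significance
#'
#' \code{pearsonCorrelation} is the standard product-moment coefficient;
#' \code{correlationPValue} converts a coefficient observed on \code{n}
#' paired samples into a two-sided p-value via the exact null distribution
#' transform \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} with \eqn{n-2} degrees of
#' freedom; \code{criticalCorrelation} inverts it, returning the smallest
#' coefficient magnitude significant at \code{alpha} (about 0.7545 for
#' \code{n = 7}, \code{alpha = 0.05}).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return \code{pearsonCorrelation}: r in [-1, 1].
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' correlationPValue(0.8, 4)
#' criticalCorrelation(7)                             # ~0.7545
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("input error: unequal lengths")
  if (length(x) < 3L) stop("input error: need at least 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined-correlation error: constant vector")
  stats::cor(x, y)
}

#' @rdname pearsonCorrelation
#' @param r correlation coefficient, |r| <= 1.
#' @param n number of paired samples used to compute \code{r}, >= 3.
#' @return \code{correlationPValue}: two-sided p-value in [0, 1].
#' @export
correlationPValue <- function(r, n) {
  if (any(n < 3L)) stop("input error: n must be >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("input error: |r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  })
  unname(p)
}

#' @rdname pearsonCorrelation
#' @param alpha two-sided significance level (default 0.05).
#' @return \code{criticalCorrelation}: the critical |r| above which the
#'   two-sided p-value drops below \code{alpha}.
#' @export
criticalCorrelation <- function(n, alpha = 0.05) {
  if (any(n < 3L)) stop("input error: n must be >= 3")
  tc <- qt(1 - alpha / 2, df = n - 2)
  unname(tc / sqrt(tc^2 + (n - 2)))
}

#' Build the weighted gene coexpression network
#'
#' Links two genes when their expression profiles over the chosen samples
#' are significantly positively correlated: the edge is kept iff \code{r > 0}
#' and the two-sided Pearson p-value is strictly below \code{alpha}; the edge
#' weight is \code{r} itself.  By default only case samples are used, so the
#' network describes coexpression in the disease state; \code{samples =
#' "all"} uses the full cohort.  All measured genes are candidate nodes
#' (not only differentially expressed ones, so downstream enrichment has a
#' proper universe), but genes left without any significant edge are excluded
#' from the node set.  Genes constant across the used samples have no defined
#' correlation and are skipped with a message.  Setting
#' \code{positiveOnly = FALSE} admits negative correlations with
#' absolute-value weights.
#'
#' @param x a SummarizedExperiment (assay \code{"exprs"}) or numeric matrix,
#'   features x samples.
#' @param labels named case/control labels (see [callDifferential()]);
#'   only needed when \code{samples = "case"}.
#' @param alpha edge significance threshold (default 0.05).
#' @param samples \code{"case"} (default) or \code{"all"}.
#' @param positiveOnly keep only positive correlations (default TRUE).
#' @param maxGenes soft cap; above it a warning about quadratic cost is
#'   emitted (default 20000).
#' @return a [CoexpressionNetwork-class].
#' @export
buildCoexpressionNetwork <- function(x, labels = NULL, alpha = 0.05,
                                     samples = c("case", "all"),
                                     positiveOnly = TRUE, maxGenes = 20000L) {
  samples <- match.arg(samples)
  m <- .exprMatrix(x)
  if (samples == "case") {
    labels <- .resolveLabels(x, labels, colnames(m))
    m <- m[, labels[colnames(m)] == "case", drop = FALSE]
  }
  n <- ncol(m)
  if (n < 3L)
    stop("input error: need at least 3 samples to test correlations (got ",
         n, ")")
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene(s) skipped (undefined correlation)")
    m <- m[sds > 0, , drop = FALSE]
  }
  G <- nrow(m)
  if (G > maxGenes)
    warning("all-pairs correlation over ", G,
            " genes: quadratic cost ahead", call. = FALSE)
  if (G < 2L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(new("CoexpressionNetwork", graph = g, nSamples = as.integer(n),
               alpha = alpha))
  }
  # order genes so edge construction (hence GraphML output) is deterministic
  m <- m[order(rownames(m)), , drop = FALSE]
  R <- stats::cor(t(m))
  ut <- upper.tri(R)
  rvals <- R[ut]
  keep <- if (positiveOnly) rvals > 0 else rvals != 0
  pv <- rep(1, length(rvals))
  pv[keep] <- correlationPValue(rvals[keep], n)
  keep <- keep & pv < alpha
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  edges <- data.frame(
    gene1 = rownames(m)[idx[, 1L]],
    gene2 = rownames(m)[idx[, 2L]],
    weight = if (positiveOnly) rvals[keep] else abs(rvals[keep]),
    p = pv[keep], stringsAsFactors = FALSE)
  g <- if (nrow(edges) == 0L)
    igraph::make_empty_graph(0, directed = FALSE)
  else
    igraph::graph_from_data_frame(edges, directed = FALSE)
  new("CoexpressionNetwork", graph = g, nSamples = as.integer(n),
      alpha = alpha)
}
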