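#' Two-sample Student's t-test
#'
#' Pooled-variance ("Student's") two-sided two-sample t-test, the default
#' test used for differential calling; Welch's unequal-variance variant is
#' available via \code{varEqual = FALSE}.  When both groups are constant the
#' test is degenerate: equal constants give \code{t = 0, p = 1}, unequal
#' constants give an infinite statistic and \code{p = 0}; both are flagged
#' rather than raised so batch runs proceed.
#'
#' @param caseValues,controlValues numeric vectors, each of length >= 2.
#' @param varEqual logical; pooled variance (default) or Welch.
#' @return list with \code{t} (sign follows \code{mean(case) - mean(control)}),
#'   \code{df}, \code{p_value} and \code{degenerate}.
#' @examples
#' tTestTwoSample(c(1, 2, 3), c(4, 5, 6))  # t ~ -3.674, p ~ 0.0213
#' @export
tTestTwoSample <- function(caseValues, controlValues, varEqual = TRUE) {
  if (length(caseValues) < 2L || length(controlValues) < 2L)
    stop("input error: each group needs at least 2 samples")
  r <- .rowTTest(rbind(c(caseValues, controlValues)),
                 case = seq_along(caseValues),
                 control = length(caseValues) + seq_along(controlValues),
                 varEqual = varEqual)
  list(t = r$t[1L], df = r$df[1L], p_value = r$p[1L],
       degenerate = r$degenerate[1L])
}

# vectorized row-wise two-sample t over a features x samples matrix
.rowTTest <- function(X, case, control, varEqual = TRUE) {
  n1 <- length(case); n2 <- length(control)
  X1 <- X[, case, drop = FALSE]; X2 <- X[, control, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, nrow(X))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  degenerate <- se == 0
  t <- ifelse(degenerate, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(is.infinite(t), 0, 2 * pt(abs(t), df, lower.tail = FALSE))
  p[degenerate & diff == 0] <- 1
  df[degenerate & !varEqual] <- n1 + n2 - 2  # Welch df is 0/0 there
  list(t = unname(t), df = unname(df), p = unname(p),
       mean_case = unname(m1), mean_control = unname(m2),
       degenerate = unname(degenerate))
}

#' Call differentially expressed features between cases and controls
#'
#' Applies a two-sided two-sample t-test to every feature of an expression
#' matrix and flags features with raw \code{p < alpha} (strict) as
#' differentially expressed.  No multiple-testing correction is applied by
#' default, matching the raw-threshold convention of small-cohort microarray
#' studies; Benjamini-Hochberg adjustment is available via
#' \code{adjust = "BH"} (the threshold is then applied to the adjusted p).
#'
#' @param x a SummarizedExperiment (assay \code{"exprs"}) or a numeric matrix
#'   (features x samples) with dimnames.
#' @param labels named factor/character assigning \code{"case"}/\code{"control"}
#'   to every sample (column) of \code{x}; defaults to
#'   \code{colData(x)$group} when \code{x} is a SummarizedExperiment.
#' @param alpha significance threshold (default 0.05).
#' @param varEqual pooled (default) vs Welch variance.
#' @param adjust \code{"none"} (default) or any [stats::p.adjust()] method.
#' @return a \code{data.frame} with one row per feature: \code{feature_id},
#'   \code{t_stat}, \code{df}, \code{p_value}, \code{mean_case},
#'   \code{mean_control}, \code{degenerate}, \code{significant} (and
#'   \code{p_adjusted} when \code{adjust != "none"}).
#' @export
callDifferential <- function(x, labels = NULL, alpha = 0.05, varEqual = TRUE,
                             adjust = "none") {
  m <- .exprMatrix(x)
  labels <- .resolveLabels(x, labels, colnames(m))
  case <- which(labels[colnames(m)] == "case")
  control <- which(labels[colnames(m)] == "control")
  if (length(case) < 2L || length(control) < 2L)
    stop("input error: need at least 2 samples per group (got ",
         length(case), " case, ", length(control), " control)")
  r <- .rowTTest(m, case, control, varEqual = varEqual)
  out <- data.frame(feature_id = rownames(m), t_stat = r$t, df = r$df,
                    p_value = r$p, mean_case = r$mean_case,
                    mean_control = r$mean_control, degenerate = r$degenerate,
                    row.names = NULL)
  if (!identical(adjust, "none")) {
    out$p_adjusted <- p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

.exprMatrix <- function(x) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "exprs") else x
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("input error: expression matrix must have feature and sample names")
  m
}

.resolveLabels <- function(x, labels, sample_ids) {
  if (is.null(labels) && methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if ("group" %in% colnames(cd))
      labels <- stats::setNames(as.character(cd$group), colnames(x))
  }
  if (is.null(labels))
    stop("input error: sample labels are required (argument 'labels' or ",
         "colData(x)$group)")
  labels <- stats::setNames(as.character(labels), names(labels))
  miss <- setdiff(sample_ids, names(labels))
  if (length(miss))
    stop("input error: unlabelled sample(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(labels[sample_ids]), c("case", "control"))
  if (length(bad))
    stop("input error: labels must be 'case'/'control', got: ",
         paste(bad, collapse = ", "))
  factor(labels[sample_ids], levels = c("case", "control"))
}
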