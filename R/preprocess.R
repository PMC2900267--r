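# Array-level quantile normalization and the gene-wise [-1, 1]
# normalization applied before clustering.

#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) onto the identical distribution: the mean of
#' the order statistics across arrays. Tied values within a column all
#' receive the mean of the reference values over their shared rank span, so
#' the result is deterministic and within-column rank order is preserved.
#'
#' @param em An [expression_matrix()].
#' @return An `ExpressionMatrix` with normalized values, same ids/design.
#' @export
quantile_normalize <- function(em) {
  x <- em$values
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 arrays",
                         call. = FALSE)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    # tied values share their rank span; all receive the span mean
    if (anyDuplicated(col)) v <- ave(v, match(col, col), FUN = mean)
    v
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, em$design)
}

#' Gene-wise normalization to the interval [-1, 1]
#'
#' Centers each gene at its mean across arrays and scales by the maximum
#' absolute deviation, so every nonconstant gene attains +/-1 at its most
#' extreme array and clustering sees shape rather than magnitude:
#' \deqn{\hat{y}_{nm} = (y_{nm} - \bar{y}_n) / \max_m |y_{nm} - \bar{y}_n|}
#' Constant genes have an undefined direction of change; their rows are set
#' to zero and flagged degenerate (and are excluded from clustering
#' downstream).
#'
#' @param em An [expression_matrix()].
#' @return Object of class `NormalizedMatrix`: list with `values` (genes x
#'   arrays in [-1, 1]), `center` (per-gene mean), `scale` (per-gene max
#'   absolute deviation), `degenerate` (logical per gene), `design`,
#'   `groups`.
#' @export
normalize_gene_wise <- function(em) {
  y <- em$values
  ctr <- rowMeans(y)
  dev <- y - ctr
  scl <- apply(abs(dev), 1, max)
  degenerate <- scl == 0
  scl_safe <- ifelse(degenerate, 1, scl)
  vals <- dev / scl_safe
  vals[degenerate, ] <- 0
  structure(list(values = vals, center = ctr, scale = scl,
                 degenerate = degenerate, design = em$design,
                 groups = em$groups),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d arrays (%d degenerate)\n",
              nrow(x$values), ncol(x$values), sum(x$degenerate)))
  invisible(x)
}
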