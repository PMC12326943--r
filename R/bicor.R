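#' Biweight midcorrelation (bicor)
#'
#' Robust correlation between two numeric vectors based on Tukey biweights.
#' Each vector is median-centered and observations are down-weighted by their
#' distance from the median in units of nine times the (unscaled) median
#' absolute deviation:
#' \deqn{u_i = \frac{x_i - \mathrm{med}(x)}{9\,\mathrm{MAD}(x)}, \qquad
#'       w_i = (1 - u_i^2)^2 \, I(|u_i| < 1),}
#' with \eqn{\mathrm{MAD}(x) = \mathrm{med}(|x - \mathrm{med}(x)|)}. The
#' weighted, centered vectors are normalized to unit Euclidean length and
#' their inner product is the correlation:
#' \deqn{\mathrm{bicor}(x, y) = \sum_i \tilde{x}_i \tilde{y}_i, \qquad
#'       \tilde{x}_i = \frac{(x_i - \mathrm{med}(x))\,w^x_i}
#'       {\sqrt{\sum_j \big[(x_j - \mathrm{med}(x))\,w^x_j\big]^2}}.}
#' Observations beyond nine MADs from the median get zero weight, which makes
#' the statistic resistant to gross outliers while agreeing closely with
#' Pearson correlation on clean Gaussian data.
#'
#' If a vector has zero MAD (more than half its values tied), biweights are
#' undefined; that vector falls back to uniform weights with mean centering
#' (Pearson-style) and the result carries the attribute `fallback = TRUE`. A
#' vector that is entirely constant has no correlation defined and raises an
#' error.
#'
#' @param x,y Numeric vectors of equal length (at least 3), all values finite.
#'
#' @return A numeric scalar in \[-1, 1\] with a logical attribute `fallback`.
#' @seealso [bicor_pvalue()], [correlate_anchor_panel()]
#' @examples
#' bicor(1:5, c(2, 4, 6, 8, 10))           #  1
#' bicor(c(1, 2, 3, 4, 100), 1:5)          # outlier down-weighted
#' @export
bicor <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("at least 3 observations required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  sx <- biweight_standardize(x)
  sy <- biweight_standardize(y)
  r <- sum(sx$z * sy$z)
  r <- min(1, max(-1, r))
  attr(r, "fallback") <- sx$fallback || sy$fallback
  r
}

# Median-center, biweight, and scale to unit norm. Falls back to uniform
# weights (mean centering) when MAD is zero; errors on constant input.
biweight_standardize <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))  # unscaled MAD, no 1.4826 factor
  if (mad0 > 0) {
    u <- (x - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    z <- (x - med) * w
    fallback <- FALSE
  } else {
    z <- x - mean(x)
    fallback <- TRUE
  }
  nrm <- sqrt(sum(z^2))
  if (nrm == 0) {
    stop("correlation undefined: input vector is constant", call. = FALSE)
  }
  list(z = z / nrm, fallback = fallback)
}

#' Two-sided significance of a correlation via the Student-t transform
#'
#' Refers \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} to a Student-t distribution with
#' \eqn{n - 2} degrees of freedom, the conventional test for a sample
#' correlation coefficient, applied here to the biweight midcorrelation.
#'
#' @param r Correlation value in \[-1, 1\].
#' @param n Number of observations used (at least 3).
#'
#' @return Two-sided p-value in (0, 1\]; the smallest positive representable
#'   double when `|r| = 1`.
#' @export
bicor_pvalue <- function(r, n) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  if (any(n < 3)) stop("`n` must be at least 3", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, .Machine$double.xmin, {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  })
  pmin(1, pmax(.Machine$double.xmin, p))
}

#' Correlate an anchor gene against a panel of genes
#'
#' Computes the biweight midcorrelation, sample count, and two-sided p-value
#' of an anchor gene against each available panel gene, on the samples of the
#' requested groups. This reproduces the structure of anchor-vs-panel
#' correlation tables (e.g. ZNF224 against proliferation/survival regulators
#' on tumor samples).
#'
#' @param x An [expression_matrix()].
#' @param anchor Anchor gene symbol; must be present in `x`.
#' @param panel Character vector of panel gene symbols; genes absent from `x`
#'   are reported in a warning and skipped.
#' @param groups Sample groups to use (default `"tumor"`, matching the common
#'   tumor-only correlation scope); `NULL` uses all samples.
#'
#' @return A data frame with one row per available panel gene, columns
#'   `gene_a`, `gene_b`, `bicor`, `n`, `p_value`, `fallback`, sorted by
#'   descending `bicor`.
#' @export
correlate_anchor_panel <- function(x, anchor, panel, groups = "tumor") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!anchor %in% gene_ids(x)) {
    stop("anchor gene '", anchor, "' not present in matrix", call. = FALSE)
  }
  panel <- setdiff(panel, anchor)
  missing <- setdiff(panel, gene_ids(x))
  if (length(missing) == length(panel)) {
    stop("no panel gene present in matrix", call. = FALSE)
  }
  if (length(missing)) {
    warning("panel gene(s) absent from matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  panel <- intersect(panel, gene_ids(x))
  cols <- sample_ids(x)
  if (!is.null(groups)) cols <- cols[x$group[cols] %in% groups]
  if (length(cols) < 3) {
    stop("fewer than 3 samples in requested group(s)", call. = FALSE)
  }
  a <- x$values[anchor, cols]
  res <- lapply(panel, function(g) {
    r <- bicor(a, x$values[g, cols])
    data.frame(gene_a = anchor, gene_b = g, bicor = as.numeric(r),
               n = length(cols), p_value = bicor_pvalue(as.numeric(r), length(cols)),
               fallback = attr(r, "fallback"))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$bicor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
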