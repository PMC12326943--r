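#' Expression matrix with sample group labels
#'
#' Container for a log2-scale gene-by-sample expression matrix together with a
#' per-sample group label (`"nontumor"`, `"tumor"` or `"unknown"`). This is the
#' internal data model every other function in the package consumes: rows are
#' unique gene symbols (or probe identifiers when no annotation was supplied),
#' columns are unique sample identifiers, and all values are finite after
#' validation.
#'
#' @param values Numeric matrix of log2 expression, genes in rows, samples in
#'   columns. Must carry rownames (gene identifiers) and colnames (sample
#'   identifiers).
#' @param group Character vector of per-sample labels, one per column of
#'   `values`, each one of `"nontumor"`, `"tumor"`, `"unknown"`. May be named
#'   by sample id; unnamed vectors are matched positionally.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the numeric matrix) and `group` (named character vector).
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(c("TP53", "CDKN1A", "ZNF224"), paste0("s", 1:4)))
#' x <- expression_matrix(m, c("nontumor", "nontumor", "tumor", "tumor"))
#' x
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  group <- normalize_group(group, colnames(values))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite expression value for gene '%s', sample '%s'",
      rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  structure(list(values = values, group = group), class = "ExpressionMatrix")
}

GROUP_LEVELS <- c("nontumor", "tumor", "unknown")

normalize_group <- function(group, sample_ids) {
  if (is.factor(group)) group <- as.character(group)
  if (!is.null(names(group))) {
    group <- group[sample_ids]
    names(group) <- sample_ids
    group[is.na(group)] <- "unknown"
  } else {
    if (length(group) != length(sample_ids)) {
      stop("`group` must have one label per sample", call. = FALSE)
    }
    names(group) <- sample_ids
  }
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) {
    stop("invalid group label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = "/"),
         call. = FALSE)
  }
  group
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$group, levels = GROUP_LEVELS))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#'
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by genes and/or sample groups
#'
#' Row/column subsetting that preserves the order of the request and carries
#' the sample group labels over. Requesting genes absent from the matrix is an
#' error unless `tolerate_missing = TRUE`, in which case the missing genes are
#' reported in a warning and the remainder returned.
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Character vector of gene identifiers to keep, or `NULL` to
#'   keep all.
#' @param groups Character vector of group labels to keep
#'   (subset of `nontumor`, `tumor`, `unknown`), or `NULL` to keep all.
#' @param samples Character vector of sample identifiers to keep (applied
#'   after `groups`), or `NULL`.
#' @param tolerate_missing If `TRUE`, genes absent from the matrix are dropped
#'   with a warning instead of raising an error.
#'
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, groups = NULL, samples = NULL,
                              tolerate_missing = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep_genes <- gene_ids(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, keep_genes)
    if (length(missing)) {
      if (!tolerate_missing || length(missing) == length(genes)) {
        stop("gene(s) not present in matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      warning("dropping absent gene(s): ", paste(missing, collapse = ", "),
              call. = FALSE)
    }
    keep_genes <- genes[genes %in% keep_genes]
  }
  keep_samples <- sample_ids(x)
  if (!is.null(groups)) {
    bad <- setdiff(groups, GROUP_LEVELS)
    if (length(bad)) {
      stop("invalid group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    keep_samples <- keep_samples[x$group[keep_samples] %in% groups]
  }
  if (!is.null(samples)) keep_samples <- samples[samples %in% keep_samples]
  if (!length(keep_genes) || !length(keep_samples)) {
    stop("subset is empty (no matching genes or samples)", call. = FALSE)
  }
  expression_matrix(x$values[keep_genes, keep_samples, drop = FALSE],
                    x$group[keep_samples])
}

# Per-gene median imputation within the sample's own group; genes missing in
# more than `max_missing` of samples are dropped with a warning. Operates on a
# plain matrix before ExpressionMatrix validation.
impute_missing <- function(values, group, max_missing = 0.2) {
  miss <- !is.finite(values)
  if (!any(miss)) return(values)
  frac <- rowMeans(miss)
  drop <- frac >= max_missing
  if (any(drop)) {
    warning(sprintf("dropping %d gene(s) with >= %.0f%% missing values: %s",
                    sum(drop), 100 * max_missing,
                    paste(utils::head(rownames(values)[drop], 5),
                          collapse = ", ")),
            call. = FALSE)
    values <- values[!drop, , drop = FALSE]
    miss <- miss[!drop, , drop = FALSE]
  }
  for (g in which(rowSums(miss) > 0)) {
    for (grp in unique(group)) {
      cols <- which(group == grp)
      hole <- cols[miss[g, cols]]
      if (!length(hole)) next
      med <- stats::median(values[g, cols][is.finite(values[g, cols])])
      if (!is.finite(med)) {  # whole group missing: fall back to gene median
        med <- stats::median(values[g, ][is.finite(values[g, ])])
      }
      values[g, hole] <- med
    }
  }
  values
}
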