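#' Read an expression matrix from a tab-delimited file
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' row holds sample identifiers. Values are log2-scale expression unless
#' `log2_transform = TRUE`, in which case `log2(x + 1)` is applied to
#' linear-scale input. Duplicate gene rows are collapsed by keeping the row
#' with the highest mean expression (see [collapse_probes()]); empty/NA cells
#' are imputed by the gene's median within the sample's group when the gene is
#' missing in fewer than `max_missing` of samples, otherwise the gene is
#' dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param group_spec Named character vector mapping sample ids to group labels
#'   (`nontumor`/`tumor`); samples absent from the mapping are labeled
#'   `unknown`. `NULL` labels every sample `unknown`.
#' @param log2_transform Apply `log2(x + 1)` to linear-scale input.
#' @param max_missing Per-gene missingness threshold above which the gene is
#'   dropped rather than imputed.
#'
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, group_spec = NULL,
                                log2_transform = FALSE, max_missing = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", "", "null", "NULL"))
  if (ncol(tab) < 2) {
    stop("malformed header in ", path,
         ": expected a gene-id column plus at least one sample column",
         call. = FALSE)
  }
  genes <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(genes, colnames(raw))))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell for gene '%s', sample '%s' (value '%s')",
                 genes[bad[1, 1]], colnames(raw)[bad[1, 2]],
                 raw[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  if (log2_transform) {
    if (any(values < 0, na.rm = TRUE)) {
      stop("negative values are incompatible with log2_transform", call. = FALSE)
    }
    values <- log2(values + 1)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene id(s): ",
            paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    rownames(values) <- NULL
    values <- collapse_probes(values,
                              data.frame(probe_id = as.character(seq_along(genes)),
                                         gene_symbol = genes),
                              probe_ids = as.character(seq_along(genes)))
  }
  group <- rep("unknown", ncol(values))
  names(group) <- colnames(values)
  if (!is.null(group_spec)) {
    hit <- intersect(names(group_spec), names(group))
    group[hit] <- group_spec[hit]
  }
  values <- impute_missing(values, group, max_missing = max_missing)
  expression_matrix(values, group)
}

#' Write an expression matrix to TSV with a companion annotation file
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path (gene rows, sample columns).
#' @param annot_path Optional path for a two-column sample annotation TSV
#'   (`sample_id`, `group`). Defaults to `<path>` with a `.samples.tsv`
#'   suffix; `NA` suppresses it.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, annot_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(annot_path)) {
    annot_path <- sub("\\.tsv$", "", path)
    annot_path <- paste0(annot_path, ".samples.tsv")
  }
  if (!is.na(annot_path)) {
    utils::write.table(
      data.frame(sample_id = sample_ids(x), group = unname(x$group)),
      annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the flat-text series-matrix convention used by the Gene Expression
#' Omnibus: `!`-prefixed metadata lines followed by a tab-delimited expression
#' block between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#' Sample groups are assigned by substring rules applied to a chosen metadata
#' field (GEO vocabularies differ per series, so the mapping is caller
#' supplied). When a probe annotation is given, probes are collapsed to gene
#' symbols via [collapse_probes()]; otherwise probe ids are retained as gene
#' identifiers.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @param group_field Metadata key used for group assignment, e.g. `"title"`
#'   or `"characteristics_ch1"` (matched against `!Sample_<field>` lines,
#'   case-insensitively).
#' @param group_rules Named character vector of substring rules, names are
#'   (case-insensitive, fixed) substrings searched in the metadata field and
#'   values are group labels, e.g. `c(normal = "nontumor", melanoma = "tumor")`.
#'   The first matching rule wins; unmatched samples are labeled `unknown`.
#' @param annotation Optional probe annotation: a data frame (or TSV path)
#'   with columns `probe_id` and `gene_symbol`.
#' @param max_missing Passed to the missing-value imputation step.
#'
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(path, group_field = "title",
                               group_rules = NULL, annotation = NULL,
                               max_missing = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    stop("missing or malformed series_matrix_table markers in ", path,
         call. = FALSE)
  }
  meta_lines <- lines[seq_len(begin - 1)]
  meta_lines <- meta_lines[startsWith(meta_lines, "!")]

  table_lines <- lines[(begin + 1):(end - 1)]
  table_lines <- table_lines[nzchar(table_lines)]
  cells <- strsplit(table_lines, "\t", fixed = TRUE)
  strip <- function(v) gsub('^"|"$', "", v)
  header <- strip(cells[[1]])
  samples <- header[-1]
  probes <- character(length(cells) - 1)
  values <- matrix(NA_real_, length(cells) - 1, length(samples),
                   dimnames = list(NULL, samples))
  for (i in seq_along(probes)) {
    row <- strip(cells[[i + 1]])
    probes[i] <- row[1]
    values[i, ] <- suppressWarnings(as.numeric(row[-1]))
  }
  rownames(values) <- probes

  group <- rep("unknown", length(samples))
  names(group) <- samples
  if (!is.null(group_rules)) {
    field <- series_matrix_field(meta_lines, group_field, length(samples))
    if (is.null(field)) {
      warning("metadata field '", group_field,
              "' not found; all samples labeled unknown", call. = FALSE)
    } else {
      for (i in seq_along(group_rules)) {
        hit <- grepl(tolower(names(group_rules)[i]), tolower(field),
                     fixed = TRUE) & group == "unknown"
        group[hit] <- group_rules[[i]]
      }
      if (all(group == "unknown")) {
        warning("no sample matched any group rule; all samples labeled unknown",
                call. = FALSE)
      }
    }
  }

  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      annotation <- utils::read.delim(annotation, header = TRUE,
                                      colClasses = "character")
    }
    values <- collapse_probes(values, annotation)
  }
  values <- impute_missing(values, group, max_missing = max_missing)
  expression_matrix(values, group)
}

# Locate a !Sample_<field> metadata line and return its per-sample values.
series_matrix_field <- function(meta_lines, field, n_samples) {
  key <- tolower(sub("^!?(sample_)?", "", field))
  keys <- tolower(sub("^!Sample_", "", sub("\t.*$", "", meta_lines),
                      ignore.case = TRUE))
  idx <- which(keys == key & grepl("^!Sample_", meta_lines, ignore.case = TRUE))
  if (!length(idx)) return(NULL)
  vals <- strsplit(meta_lines[idx[1]], "\t", fixed = TRUE)[[1]][-1]
  vals <- gsub('^"|"$', "", vals)
  if (length(vals) != n_samples) return(NULL)
  vals
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene mapped by more than one probe, the probe with the highest
#' mean expression across all samples is retained; ties keep the probe that
#' appears earlier in the input. Probes absent from the map are dropped.
#'
#' @param values Numeric matrix with probe rows (rownames are probe ids unless
#'   `probe_ids` is given) and sample columns.
#' @param probe_map Data frame with columns `probe_id` and `gene_symbol`.
#' @param probe_ids Optional explicit probe ids for the rows of `values`.
#'
#' @return Numeric matrix with unique gene symbols as rownames.
#' @export
collapse_probes <- function(values, probe_map, probe_ids = NULL) {
  stopifnot(is.matrix(values),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  if (is.null(probe_ids)) probe_ids <- rownames(values)
  if (is.null(probe_ids)) stop("probe ids required", call. = FALSE)
  map <- probe_map$gene_symbol[match(probe_ids, probe_map$probe_id)]
  keep <- !is.na(map) & nzchar(map)
  if (!any(keep)) {
    stop("no probe in the matrix is covered by the probe map", call. = FALSE)
  }
  values <- values[keep, , drop = FALSE]
  map <- map[keep]
  means <- rowMeans(values, na.rm = TRUE)
  # stable within-gene order, so which.max ties resolve to file order
  pick <- vapply(split(seq_along(map), map)[unique(map)],
                 function(ix) ix[which.max(means[ix])], integer(1))
  out <- values[pick, , drop = FALSE]
  rownames(out) <- names(pick)
  out
}
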