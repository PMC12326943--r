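#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the input matrix (an
#' [expression_matrix()] or a path plus format), the gene panel, the
#' correlation pairs, classification thresholds, correlation scope, and the
#' output directory. A YAML file with the same field names can be loaded via
#' [load_run_config()].
#'
#' @param input An `ExpressionMatrix`, or a path to an input file.
#' @param format Input format when `input` is a path: `"tsv"` or
#'   `"series-matrix"`.
#' @param group_spec,group_field,group_rules Group assignment, passed to
#'   [read_expression_tsv()] / [read_series_matrix()].
#' @param annotation Optional probe annotation for series-matrix input.
#' @param panel A [gene_panel()]; default [default_p53_panel()].
#' @param pairs Gene pairs for the restoration analysis (list of length-2
#'   character vectors); default ZNF224/CDKN1A and TP53/CDKN1A.
#' @param thresholds Normal-like band `c(lower, upper)`, default
#'   `c(0.9, 1.1)`.
#' @param groups Correlation/classification scope (default `"tumor"`).
#' @param adjust Slope-fit adjustment, see [classify_samples()].
#' @param form Per-gene calibration form, see [fit_target_responses()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(input, format = c("tsv", "series-matrix"),
                       group_spec = NULL, group_field = "title",
                       group_rules = NULL, annotation = NULL,
                       panel = default_p53_panel(),
                       pairs = list(c("ZNF224", "CDKN1A"), c("TP53", "CDKN1A")),
                       thresholds = c(0.9, 1.1), groups = "tumor",
                       adjust = "intercept", form = "linear",
                       out_dir = "p53eff_run", seed = 1L) {
  format <- match.arg(format)
  if (is.character(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    stop("thresholds must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  structure(list(input = input, format = format, group_spec = group_spec,
                 group_field = group_field, group_rules = group_rules,
                 annotation = annotation, panel = panel, pairs = pairs,
                 thresholds = thresholds, groups = groups, adjust = adjust,
                 form = form, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat YAML file whose keys mirror the arguments of [run_config()]
#' (`input`, `format`, `group_rules` as a mapping, `panel_file`, `regulator`,
#' `anchors`, `pairs` as `"A:B"` strings, `thresholds`, `groups`, `adjust`,
#' `form`, `out_dir`, `seed`).
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- default_p53_panel(
    file = y[["panel_file"]],
    regulator = if (is.null(y[["regulator"]])) "TP53" else y[["regulator"]],
    anchors = if (is.null(y[["anchors"]])) c("ZNF224", "CDKN1A") else y[["anchors"]])
  pairs <- if (is.null(y[["pairs"]])) {
    list(c("ZNF224", "CDKN1A"), c("TP53", "CDKN1A"))
  } else {
    lapply(strsplit(unlist(y[["pairs"]]), ":", fixed = TRUE), trimws)
  }
  args <- list(
    input = y[["input"]],
    format = if (is.null(y[["format"]])) "tsv" else y[["format"]],
    group_rules = if (is.null(y[["group_rules"]])) NULL else unlist(y[["group_rules"]]),
    panel = panel, pairs = pairs)
  if (!is.null(y[["group_spec"]])) args$group_spec <- unlist(y[["group_spec"]])
  if (!is.null(y[["group_field"]])) args$group_field <- y[["group_field"]]
  if (!is.null(y[["annotation"]])) args$annotation <- y[["annotation"]]
  if (!is.null(y[["thresholds"]])) args$thresholds <- as.numeric(y[["thresholds"]])
  if (!is.null(y[["groups"]])) args$groups <- y[["groups"]]
  if (!is.null(y[["adjust"]])) args$adjust <- y[["adjust"]]
  if (!is.null(y[["form"]])) args$form <- y[["form"]]
  if (!is.null(y[["out_dir"]])) args$out_dir <- y[["out_dir"]]
  if (!is.null(y[["seed"]])) args$seed <- y[["seed"]]
  do.call(run_config, args)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# Deterministic TSV writer with a provenance header line.
write_stage_tsv <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: log2 | config_hash: %s", config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_hash <- function(config) {
  drop <- c("out_dir")
  slim <- config[setdiff(names(config), drop)]
  slim$input <- if (is.character(slim$input)) slim$input else "in-memory"
  slim$panel <- unclass(slim$panel)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full effectiveness pipeline
#'
#' Orchestrates ingest, per-gene calibration on nontumor samples, per-sample
#' slope classification, removal of impaired samples, anchor correlations
#' before and after filtering, and the restoration report, writing flat TSV
#' outputs plus a log, a human-readable summary, and a JSON manifest with the
#' config echo and content hashes. Identical config and inputs produce
#' byte-identical tables (timestamps live only in `run.log`).
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [load_run_config()]).
#'
#' @return Invisibly, a list with `models`, `slopes`, `correlations_all`,
#'   `correlations_filtered`, `restoration`, `impaired_fraction`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  cat(sprintf("# p53eff run | config_hash: %s\n", hash), file = log_path)

  x <- pipeline_stage("ingest", {
    if (inherits(config$input, "ExpressionMatrix")) {
      config$input
    } else if (config$format == "tsv") {
      read_expression_tsv(config$input, group_spec = config$group_spec)
    } else {
      read_series_matrix(config$input, group_field = config$group_field,
                         group_rules = config$group_rules,
                         annotation = config$annotation)
    }
  })
  logf("ingest: %d genes x %d samples (%d nontumor, %d tumor)",
       nrow(x$values), ncol(x$values),
       sum(x$group == "nontumor"), sum(x$group == "tumor"))

  models <- pipeline_stage("calibrate",
    fit_target_responses(x, config$panel, form = config$form))
  logf("calibrate: %d target models fit on nontumor samples", nrow(models))

  slopes <- pipeline_stage("classify", suppressMessages(
    classify_samples(x, config$panel, models, groups = config$groups,
                     adjust = config$adjust,
                     lower = config$thresholds[1],
                     upper = config$thresholds[2])))
  impaired_fraction <- attr(slopes, "impaired_fraction")
  logf("classify: %d samples scored, impaired fraction %.3f",
       nrow(slopes), impaired_fraction)

  anchors <- intersect(config$panel$anchors, gene_ids(x))
  corr_panel <- unique(c(config$panel$regulator,
                         intersect(config$panel$targets, gene_ids(x)),
                         anchors))
  corr_all <- pipeline_stage("correlate",
    correlate_anchor_panel(x, anchors[1], setdiff(corr_panel, anchors[1]),
                           groups = config$groups))
  x_flt <- pipeline_stage("filter", filter_impaired(x, slopes))
  corr_flt <- pipeline_stage("correlate",
    correlate_anchor_panel(x_flt, anchors[1], setdiff(corr_panel, anchors[1]),
                           groups = config$groups))
  restoration <- pipeline_stage("restore",
    restoration_analysis(x, slopes, config$pairs, groups = config$groups))
  logf("restore: %d pair(s) analyzed", nrow(restoration))

  out <- function(name) file.path(config$out_dir, name)
  write_stage_tsv(models, out("models.tsv"), hash)
  write_stage_tsv(slopes, out("slopes.tsv"), hash)
  write_stage_tsv(corr_all, out("correlations_all.tsv"), hash)
  write_stage_tsv(corr_flt, out("correlations_filtered.tsv"), hash)
  write_stage_tsv(restoration, out("restoration.tsv"), hash)

  summary_lines <- c(
    sprintf("p53 effectiveness run (config_hash %s)", hash),
    sprintf("samples scored: %d | impaired: %d (%.1f%%) | normal_like: %d | above_range: %d",
            nrow(slopes), sum(slopes$class == "impaired"),
            100 * impaired_fraction, sum(slopes$class == "normal_like"),
            sum(slopes$class == "above_range")),
    "pair restoration (bicor all -> filtered):",
    sprintf("  %s/%s: %.3f -> %.3f (n %d -> %d)",
            restoration$anchor, restoration$partner,
            restoration$bicor_all, restoration$bicor_filtered,
            restoration$n_all, restoration$n_filtered))
  writeLines(summary_lines, out("summary.txt"))

  tables <- c("models.tsv", "slopes.tsv", "correlations_all.tsv",
              "correlations_filtered.tsv", "restoration.tsv", "summary.txt")
  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    thresholds = config$thresholds,
    groups = config$groups,
    impaired_fraction = impaired_fraction,
    files = as.list(tools::md5sum(file.path(config$out_dir, tables))))
  names(manifest$files) <- tables
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done")

  invisible(list(models = models, slopes = slopes,
                 correlations_all = corr_all, correlations_filtered = corr_flt,
                 restoration = restoration,
                 impaired_fraction = impaired_fraction,
                 out_dir = config$out_dir))
}
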