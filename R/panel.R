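#' Define a regulator / target-panel / anchor gene set
#'
#' A `gene_panel` names the regulator whose downstream effectiveness is scored
#' (the p53 analog), the panel of its transcriptional target genes used for
#' calibration and per-sample scoring, and the anchor genes used in
#' correlation analyses (e.g. ZNF224 and CDKN1A/p21).
#'
#' @param regulator Regulator gene symbol (default `"TP53"`).
#' @param targets Character vector of target gene symbols; must be non-empty,
#'   unique, and must not contain the regulator.
#' @param anchors Character vector of anchor gene symbols for correlation
#'   tables.
#'
#' @return A `gene_panel` object (list with `regulator`, `targets`,
#'   `anchors`).
#' @seealso [default_p53_panel()]
#' @export
gene_panel <- function(regulator = "TP53", targets, anchors = c("ZNF224", "CDKN1A")) {
  stopifnot(is.character(regulator), length(regulator) == 1L)
  targets <- as.character(targets)
  if (!length(targets)) stop("`targets` must be non-empty", call. = FALSE)
  if (anyDuplicated(targets)) {
    stop("duplicated target gene(s): ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "),
         call. = FALSE)
  }
  if (regulator %in% targets) {
    stop("the regulator must not be contained in the target panel",
         call. = FALSE)
  }
  structure(list(regulator = regulator, targets = targets,
                 anchors = as.character(anchors)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: regulator %s, %d targets, anchors %s\n",
              x$regulator, length(x$targets),
              paste(x$anchors, collapse = "/")))
  invisible(x)
}

#' Default panel of 59 canonical p53 target genes
#'
#' Loads the editable default target list shipped with the package
#' (`inst/extdata/p53_targets_default.txt`): 59 genes with well-established
#' direct transcriptional regulation by p53 (cell-cycle arrest, apoptosis,
#' DNA repair and metabolism branches of the p53 program). Analyses of a
#' specific study should substitute that study's own curated panel via
#' [gene_panel()] or the `file` argument; the biological conclusions of the
#' slope classification depend on the panel genes being genuine p53 targets
#' on the platform at hand.
#'
#' @param file Optional path to a plain-text file with one gene symbol per
#'   line (`#` comments allowed), replacing the shipped default.
#' @param regulator,anchors Passed to [gene_panel()].
#' @return A [gene_panel()].
#' @export
default_p53_panel <- function(file = NULL, regulator = "TP53",
                              anchors = c("ZNF224", "CDKN1A")) {
  if (is.null(file)) {
    file <- system.file("extdata", "p53_targets_default.txt",
                        package = "p53eff", mustWork = TRUE)
  }
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(regulator = regulator, targets = lines, anchors = anchors)
}
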