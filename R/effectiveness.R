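#' Calibrate per-target response functions on nontumor samples
#'
#' Nontumor samples are taken to carry normally functioning p53, so the
#' relationship between the regulator's expression and each target gene's
#' expression can be calibrated on them. By default each target is fit as a
#' straight line in log2 space, `target = a_g + b_g * regulator`, by ordinary
#' least squares; a quadratic form is available behind the same interface for
#' targets with curvature.
#'
#' @param x An [expression_matrix()]; only its nontumor samples are used.
#' @param panel A [gene_panel()]; the regulator must be present in `x`.
#' @param form Functional form of the per-gene fit: `"linear"` (default) or
#'   `"quadratic"`.
#'
#' @return A data frame of class `target_response_models` with one row per
#'   available target: `target`, `intercept`, `slope`, `quad` (0 for linear
#'   fits), `residual_sd`, `r_squared`, `n_fit`. Targets absent from the
#'   matrix are skipped with a warning.
#' @export
fit_target_responses <- function(x, panel, form = c("linear", "quadratic")) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(panel, "gene_panel"))
  form <- match.arg(form)
  if (!panel$regulator %in% gene_ids(x)) {
    stop("regulator gene '", panel$regulator, "' not present in matrix",
         call. = FALSE)
  }
  nt <- sample_ids(x)[x$group == "nontumor"]
  if (length(nt) < 3) {
    stop("at least 3 nontumor samples are required for calibration (found ",
         length(nt), ")", call. = FALSE)
  }
  targets <- intersect(panel$targets, gene_ids(x))
  if (!length(targets)) {
    stop("no panel target present in matrix", call. = FALSE)
  }
  missing <- setdiff(panel$targets, targets)
  if (length(missing)) {
    warning("target gene(s) absent from matrix, skipped: ",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) ", ...", call. = FALSE)
  }
  reg <- x$values[panel$regulator, nt]
  need <- if (form == "quadratic") 4L else 3L
  rows <- lapply(targets, function(g) {
    yv <- x$values[g, nt]
    if (length(yv) < need || stats::sd(reg) == 0) return(NULL)
    fit <- if (form == "quadratic") {
      stats::lm(yv ~ reg + I(reg^2))
    } else {
      stats::lm(yv ~ reg)
    }
    cf <- stats::coef(fit)
    res <- stats::residuals(fit)
    dfree <- fit$df.residual
    tss <- sum((yv - mean(yv))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
    data.frame(target = g,
               intercept = unname(cf[1]),
               slope = unname(cf[2]),
               quad = if (form == "quadratic") unname(cf[3]) else 0,
               residual_sd = if (dfree > 0) sqrt(sum(res^2) / dfree) else 0,
               r_squared = min(1, max(0, r2)),
               n_fit = length(yv))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    stop("no target could be fit", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("target_response_models", "data.frame")
  attr(out, "regulator") <- panel$regulator
  attr(out, "form") <- form
  out
}

#' Expected target expression at a given regulator level
#'
#' Evaluates each calibrated response function at the supplied regulator
#' (p53) expression level: `expected_g = a_g + b_g * level (+ c_g * level^2)`.
#'
#' @param models A `target_response_models` data frame from
#'   [fit_target_responses()].
#' @param p53_level Regulator expression (log2 units), a scalar.
#'
#' @return Named numeric vector of expected log2 expression, ordered as
#'   `models`.
#' @export
predict_expected <- function(models, p53_level) {
  stopifnot(is.data.frame(models), nrow(models) >= 1,
            is.numeric(p53_level), length(p53_level) == 1)
  out <- models$intercept + models$slope * p53_level +
    models$quad * p53_level^2
  names(out) <- models$target
  out
}

#' Classify a slope against the normal-like band
#'
#' Samples whose measured-vs-expected slope lies between 0.9 and 1.1
#' (inclusive) are `normal_like`; slopes below 0.9 indicate an impaired
#' downstream response (`impaired`); slopes above 1.1 are flagged
#' `above_range` but are not treated as impaired.
#'
#' @param slope Numeric vector of slopes.
#' @param lower,upper Band boundaries (defaults 0.9 and 1.1, inclusive).
#' @return Character vector of class labels.
#' @export
classify_slope <- function(slope, lower = 0.9, upper = 1.1) {
  stopifnot(lower < upper)
  ifelse(slope < lower, "impaired",
         ifelse(slope > upper, "above_range", "normal_like"))
}

#' Measured-vs-expected slope of a single sample
#'
#' Fits, by ordinary least squares with a free intercept (or through the
#' origin), the straight line `observed = intercept + slope * expected`
#' across the panel genes of one sample, and classifies the slope.
#'
#' @param observed Measured log2 expression of the panel genes in the sample.
#' @param expected Expected log2 expression from [predict_expected()]; must
#'   not be (near-)constant.
#' @param sample_id Identifier used in the result and in error messages.
#' @param through_origin Force the line through the origin (no intercept).
#' @param lower,upper Classification band, see [classify_slope()].
#'
#' @return One-row data frame: `sample_id`, `slope`, `intercept`,
#'   `n_targets`, `class`.
#' @export
sample_response_slope <- function(observed, expected, sample_id = NA_character_,
                                  through_origin = FALSE,
                                  lower = 0.9, upper = 1.1) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length", call. = FALSE)
  }
  if (length(observed) < 3) {
    stop("at least 3 panel genes required for sample '", sample_id, "'",
         call. = FALSE)
  }
  if (stats::sd(expected) < .Machine$double.eps^0.5 * (1 + mean(abs(expected)))) {
    stop("degenerate expected vector (all values identical) for sample '",
         sample_id, "'", call. = FALSE)
  }
  if (through_origin) {
    slope <- sum(observed * expected) / sum(expected^2)
    intercept <- 0
  } else {
    slope <- stats::cov(observed, expected) / stats::var(expected)
    intercept <- mean(observed) - slope * mean(expected)
  }
  data.frame(sample_id = sample_id, slope = slope, intercept = intercept,
             n_targets = length(observed),
             class = classify_slope(slope, lower, upper))
}

#' Score and classify every sample's p53 effectiveness
#'
#' For each sample in the requested groups, computes the expected expression
#' of every calibrated target at the sample's own regulator level, fits the
#' measured-vs-expected straight line, and classifies the slope against the
#' normal-like band.
#'
#' By default (`adjust = "intercept"`) the fitted per-gene intercepts are
#' subtracted from both the measured and the expected values before the line
#' is fit, so the regression compares the regulator-driven response components
#' directly. Baseline expression differences between panel genes appear
#' identically on both axes and would otherwise pull every slope toward 1,
#' masking attenuation; removing them makes the slope a consistent estimate
#' of the attenuation of the regulator response. `adjust = "none"` fits the
#' raw measured-vs-expected values.
#'
#' @param x An [expression_matrix()].
#' @param panel A [gene_panel()].
#' @param models Calibrated models from [fit_target_responses()]; fit on the
#'   fly from the nontumor samples of `x` when `NULL`.
#' @param groups Sample groups to score (default `"tumor"`).
#' @param adjust `"intercept"` (default) or `"none"`, see Details.
#' @param min_r_squared Optional per-gene quality filter: targets whose
#'   calibration r-squared falls below this value are excluded from scoring
#'   (default 0 = off).
#' @param lower,upper Classification band boundaries.
#' @param through_origin Passed to [sample_response_slope()].
#'
#' @return Data frame with one row per scored sample (`sample_id`, `slope`,
#'   `intercept`, `n_targets`, `class`), with the impaired fraction of the
#'   scored samples in attribute `impaired_fraction`.
#' @export
classify_samples <- function(x, panel, models = NULL, groups = "tumor",
                             adjust = c("intercept", "none"),
                             min_r_squared = 0, lower = 0.9, upper = 1.1,
                             through_origin = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(panel, "gene_panel"))
  adjust <- match.arg(adjust)
  if (is.null(models)) models <- fit_target_responses(x, panel)
  if (min_r_squared > 0) {
    models <- models[models$r_squared >= min_r_squared, , drop = FALSE]
    if (!nrow(models)) stop("no target passes the r_squared filter", call. = FALSE)
  }
  if (!panel$regulator %in% gene_ids(x)) {
    stop("regulator gene '", panel$regulator, "' not present in matrix",
         call. = FALSE)
  }
  cols <- sample_ids(x)
  if (!is.null(groups)) cols <- cols[x$group[cols] %in% groups]
  if (!length(cols)) {
    stop("no sample in requested group(s): ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  targets <- intersect(models$target, gene_ids(x))
  models <- models[match(targets, models$target), , drop = FALSE]
  if (length(targets) < 3) {
    stop("fewer than 3 calibrated targets present in matrix", call. = FALSE)
  }
  obs_mat <- x$values[targets, cols, drop = FALSE]
  rows <- lapply(cols, function(s) {
    expected <- predict_expected(models, x$values[panel$regulator, s])
    observed <- obs_mat[, s]
    if (adjust == "intercept") {
      expected <- expected - models$intercept
      observed <- observed - models$intercept
    }
    sample_response_slope(observed, expected, sample_id = s,
                          through_origin = through_origin,
                          lower = lower, upper = upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "impaired_fraction") <- mean(out$class == "impaired")
  message(sprintf(
    "classified %d sample(s): %d normal_like, %d impaired (%.1f%%), %d above_range",
    nrow(out), sum(out$class == "normal_like"), sum(out$class == "impaired"),
    100 * mean(out$class == "impaired"), sum(out$class == "above_range")))
  out
}

#' Remove p53-impaired samples from an expression matrix
#'
#' Drops the samples classified `impaired`; `normal_like` and `above_range`
#' samples, and any sample not scored, are retained (only low-slope samples
#' are treated as impaired).
#'
#' @param x An [expression_matrix()].
#' @param slopes Classification table from [classify_samples()]; every scored
#'   sample must be present in `x`.
#' @return An `ExpressionMatrix` without the impaired samples.
#' @export
filter_impaired <- function(x, slopes) {
  stopifnot(inherits(x, "ExpressionMatrix"), is.data.frame(slopes))
  absent <- setdiff(slopes$sample_id, sample_ids(x))
  if (length(absent)) {
    stop("scored sample(s) not present in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  bad <- slopes$sample_id[slopes$class == "impaired"]
  keep <- setdiff(sample_ids(x), bad)
  if (!length(keep)) {
    stop("all samples are classified impaired; nothing left to analyze",
         call. = FALSE)
  }
  expression_matrix(x$values[, keep, drop = FALSE], x$group[keep])
}

#' Correlation restoration after removal of impaired samples
#'
#' For each gene pair, computes the biweight midcorrelation and its p-value
#' on all samples of the requested groups and again after removing the
#' samples classified `impaired`, quantifying how much of the pair's
#' correlation is restored once samples with a defective p53 response are set
#' aside.
#'
#' @param x An [expression_matrix()].
#' @param slopes Classification table from [classify_samples()].
#' @param pairs Gene pairs: a list of length-2 character vectors, or a
#'   two-column data frame / matrix.
#' @param groups Sample groups defining the "all" set (default `"tumor"`).
#'
#' @return Data frame with one row per pair: `anchor`, `partner`,
#'   `bicor_all`, `p_all`, `n_all`, `bicor_filtered`, `p_filtered`,
#'   `n_filtered`, `n_removed`.
#' @export
restoration_analysis <- function(x, slopes, pairs, groups = "tumor") {
  stopifnot(inherits(x, "ExpressionMatrix"), is.data.frame(slopes))
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  }
  cols <- sample_ids(x)
  if (!is.null(groups)) cols <- cols[x$group[cols] %in% groups]
  impaired <- slopes$sample_id[slopes$class == "impaired"]
  keep <- setdiff(cols, impaired)
  if (length(keep) < 3) {
    stop("fewer than 3 samples remain after removing impaired samples",
         call. = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    absent <- setdiff(c(a, b), gene_ids(x))
    if (length(absent)) {
      stop("pair gene(s) not present in matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    r_all <- bicor(x$values[a, cols], x$values[b, cols])
    r_flt <- bicor(x$values[a, keep], x$values[b, keep])
    data.frame(anchor = a, partner = b,
               bicor_all = as.numeric(r_all),
               p_all = bicor_pvalue(as.numeric(r_all), length(cols)),
               n_all = length(cols),
               bicor_filtered = as.numeric(r_flt),
               p_filtered = bicor_pvalue(as.numeric(r_flt), length(keep)),
               n_filtered = length(keep),
               n_removed = length(cols) - length(keep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
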