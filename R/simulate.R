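#' Configuration for the synthetic expression simulator
#'
#' Defines the generative model the inference assumes: a regulator (p53
#' analog) whose log2 expression is Normal across samples; a panel of target
#' genes responding linearly to the regulator in functional samples; a fixed
#' fraction of tumor samples whose regulator-coupling terms are attenuated by
#' a factor lambda < 0.9 (impaired samples); and two co-regulated anchor
#' genes — a ZNF224 analog driven by the regulator, and a p21/CDKN1A analog
#' driven by both, whose couplings are attenuated in impaired samples.
#'
#' Defaults emulate a small microarray melanoma cohort: 40 nontumor and 100
#' tumor samples, 59 panel targets, 20% impaired tumor samples with
#' attenuation drawn uniformly from \[0.3, 0.7\], regulator log2 level
#' Normal(8, 1), per-gene intercepts Uniform(2, 6) and response slopes
#' Uniform(0.5, 1.5) in log2-per-log2 units, and residual noise SD 0.3 log2
#' units.
#'
#' @param n_nontumor,n_tumor Sample counts (nontumor must be at least 3).
#' @param n_targets Number of panel target genes (default 59).
#' @param impaired_fraction Fraction of tumor samples with attenuated
#'   responses, in \[0, 1\]. The impaired count is exactly
#'   `round(impaired_fraction * n_tumor)` so tests can assert counts.
#' @param attenuation_range Range `(lambda_lo, lambda_hi)` of the attenuation
#'   factor for impaired samples; requires
#'   `0 <= lambda_lo <= lambda_hi < 0.9`.
#' @param regulator_mean,regulator_sd Regulator log2 expression distribution.
#' @param intercept_range,slope_range Uniform priors for per-target `a_g`
#'   and `b_g`.
#' @param noise_sd Residual noise SD (log2 units), applied to targets and
#'   anchors.
#' @param anchor_coupling Named list with `c0`, `c1` (regulator to anchor1)
#'   and `d0`, `d1`, `d2` (regulator and anchor1 to anchor2); `d1`, `d2` are
#'   multiplied by each sample's lambda.
#' @param seed Integer seed making the simulation deterministic.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_nontumor = 40, n_tumor = 100, n_targets = 59,
                       impaired_fraction = 0.2,
                       attenuation_range = c(0.3, 0.7),
                       regulator_mean = 8, regulator_sd = 1,
                       intercept_range = c(2, 6), slope_range = c(0.5, 1.5),
                       noise_sd = 0.3,
                       anchor_coupling = list(c0 = 2, c1 = 0.6,
                                              d0 = 1, d1 = 0.5, d2 = 0.4),
                       seed = 1L) {
  cfg <- list(n_nontumor = n_nontumor, n_tumor = n_tumor,
              n_targets = n_targets, impaired_fraction = impaired_fraction,
              attenuation_range = attenuation_range,
              regulator_mean = regulator_mean, regulator_sd = regulator_sd,
              intercept_range = intercept_range, slope_range = slope_range,
              noise_sd = noise_sd, anchor_coupling = anchor_coupling,
              seed = as.integer(seed))
  if (cfg$n_nontumor < 3) stop("n_nontumor must be at least 3", call. = FALSE)
  if (cfg$impaired_fraction < 0 || cfg$impaired_fraction > 1) {
    stop("impaired_fraction must lie in [0, 1]", call. = FALSE)
  }
  ar <- cfg$attenuation_range
  if (length(ar) != 2 || ar[1] > ar[2] || ar[1] < 0 || ar[2] >= 0.9) {
    stop("attenuation_range must satisfy 0 <= lo <= hi < 0.9", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  for (rg in list(cfg$intercept_range, cfg$slope_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) {
      stop("priors must be ranges c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

#' Simulate an expression dataset with known impairment ground truth
#'
#' Draws a dataset from the generative model described in [sim_config()].
#' Every nontumor sample is functional (lambda = 1); exactly
#' `round(impaired_fraction * n_tumor)` tumor samples (a seeded random
#' subset) are impaired, with lambda drawn from `attenuation_range`. Each
#' target gene is `a_g + lambda_s * b_g * regulator_s + noise`; the anchors
#' follow `ZNF224 = c0 + c1 * regulator + noise` and
#' `CDKN1A = d0 + lambda_s * (d1 * regulator + d2 * ZNF224) + noise`. The
#' regulator row carries the regulator level itself. Output is deterministic
#' for a fixed config (the seed lives in the config).
#'
#' @param config A [sim_config()].
#'
#' @return List with elements `matrix` (an [expression_matrix()] whose rows
#'   are `TP53`, targets `T01...`, `ZNF224`, `CDKN1A`), `truth` (data frame
#'   `sample_id`, `group`, `is_impaired`, `lambda`), `panel` (the matching
#'   [gene_panel()]), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n_nt <- config$n_nontumor
  n_tu <- config$n_tumor
  n_all <- n_nt + n_tu
  ids <- c(sprintf("NT%03d", seq_len(n_nt)), sprintf("TU%03d", seq_len(n_tu)))
  group <- c(rep("nontumor", n_nt), rep("tumor", n_tu))
  names(group) <- ids

  targets <- sprintf("T%02d", seq_len(config$n_targets))
  a_g <- runif_range(config$n_targets, config$intercept_range)
  b_g <- runif_range(config$n_targets, config$slope_range)

  reg <- stats::rnorm(n_all, config$regulator_mean, config$regulator_sd)

  lambda <- rep(1, n_all)
  n_imp <- round(config$impaired_fraction * n_tu)
  imp_idx <- integer(0)
  if (n_imp > 0) {
    imp_idx <- n_nt + sample(n_tu)[seq_len(n_imp)]
    lambda[imp_idx] <- runif_range(n_imp, config$attenuation_range)
  }

  noise <- function(n) if (config$noise_sd > 0) {
    stats::rnorm(n, 0, config$noise_sd)
  } else rep(0, n)

  # targets: a_g + lambda_s * b_g * reg_s + eps, genes in rows
  tgt <- outer(a_g, rep(1, n_all)) +
    outer(b_g, lambda * reg) +
    matrix(noise(config$n_targets * n_all), config$n_targets, n_all)

  cc <- config$anchor_coupling
  anchor1 <- cc$c0 + cc$c1 * reg + noise(n_all)
  anchor2 <- cc$d0 + lambda * (cc$d1 * reg + cc$d2 * anchor1) + noise(n_all)

  values <- rbind(TP53 = reg, tgt, ZNF224 = anchor1, CDKN1A = anchor2)
  rownames(values) <- c("TP53", targets, "ZNF224", "CDKN1A")
  colnames(values) <- ids

  truth <- data.frame(sample_id = ids, group = group,
                      is_impaired = seq_len(n_all) %in% imp_idx,
                      lambda = lambda, row.names = NULL)
  list(matrix = expression_matrix(values, group),
       truth = truth,
       panel = gene_panel(regulator = "TP53", targets = targets,
                          anchors = c("ZNF224", "CDKN1A")),
       config = config)
}

#' Impairment-recovery metrics against simulation ground truth
#'
#' Compares the classification of tumor samples with the simulator's ground
#' truth, treating `impaired` as the positive class, and measures how closely
#' the recovered slopes track the generating attenuation factors.
#'
#' @param truth Ground-truth data frame from [simulate_dataset()].
#' @param slopes Classification table from [classify_samples()]; its sample
#'   set must match the truth's tumor samples.
#'
#' @return List with `sensitivity`, `specificity`, `accuracy`,
#'   `slope_mae_vs_lambda`, `n`, and the 2x2 `confusion` table.
#' @export
recovery_metrics <- function(truth, slopes) {
  stopifnot(is.data.frame(truth), is.data.frame(slopes))
  tu <- truth[truth$group == "tumor", , drop = FALSE]
  if (!setequal(tu$sample_id, slopes$sample_id)) {
    stop("sample sets of truth (tumor) and slopes do not match", call. = FALSE)
  }
  m <- merge(tu, slopes, by = "sample_id")
  pred <- m$class == "impaired"
  pos <- m$is_impaired
  sens <- if (any(pos)) mean(pred[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred[!pos]) else NA_real_
  list(sensitivity = sens,
       specificity = spec,
       accuracy = mean(pred == pos),
       slope_mae_vs_lambda = mean(abs(m$slope - m$lambda)),
       n = nrow(m),
       confusion = table(truth_impaired = pos, predicted_impaired = pred))
}
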