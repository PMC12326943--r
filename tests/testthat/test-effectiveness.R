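make_calibration_matrix <- function(n_nt = 10, targets = list(), seed = 3,
                                    n_tu = 0) {
  set.seed(seed)
  n <- n_nt + n_tu
  reg <- rnorm(n, 8, 1)
  vals <- rbind(TP53 = reg)
  for (nm in names(targets)) vals <- rbind(vals, targets[[nm]](reg))
  rownames(vals) <- c("TP53", names(targets))
  colnames(vals) <- sprintf("s%02d", seq_len(n))
  expression_matrix(vals, c(rep("nontumor", n_nt), rep("tumor", n_tu)))
}

test_that("noiseless linear targets are recovered exactly", {
  x <- make_calibration_matrix(targets = list(G1 = function(r) 2 + 0.8 * r))
  mod <- fit_target_responses(x, gene_panel(targets = "G1"))
  expect_equal(mod$intercept, 2, tolerance = 1e-9)
  expect_equal(mod$slope, 0.8, tolerance = 1e-9)
  expect_equal(mod$residual_sd, 0, tolerance = 1e-9)
  expect_equal(mod$r_squared, 1, tolerance = 1e-9)
  expect_equal(mod$n_fit, 10)
})

test_that("a target independent of the regulator fits a flat, uninformative model", {
  x <- make_calibration_matrix(
    n_nt = 200,
    targets = list(G1 = function(r) 5 + rnorm(length(r), 0, 0.2)))
  mod <- fit_target_responses(x, gene_panel(targets = "G1"))
  expect_lt(abs(mod$slope), 0.05)
  expect_lt(mod$r_squared, 0.05)
})

test_that("many-target calibration matches the closed-form OLS oracle", {
  set.seed(17)
  n_nt <- 40
  a <- runif(59, 2, 6); b <- runif(59, 0.5, 1.5)
  reg <- rnorm(n_nt, 8, 1)
  vals <- rbind(TP53 = reg,
                t(sapply(1:59, function(g) a[g] + b[g] * reg + rnorm(n_nt, 0, 0.3))))
  rownames(vals) <- c("TP53", sprintf("T%02d", 1:59))
  colnames(vals) <- sprintf("s%02d", 1:n_nt)
  x <- expression_matrix(vals, rep("nontumor", n_nt))
  mod <- fit_target_responses(x, gene_panel(targets = sprintf("T%02d", 1:59)))
  # coefficient-level agreement with an independent closed-form computation
  for (g in c(1, 20, 59)) {
    o <- oracle_ols(reg, vals[g + 1, ])
    expect_equal(mod$intercept[g], unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(mod$slope[g], unname(o["slope"]), tolerance = 1e-10)
  }
  # slope recovery within 3 * (noise_sd / sqrt(n)) / sd(reg)
  expect_lt(mean(abs(mod$slope - b)), 3 * (0.3 / sqrt(n_nt)) / sd(reg))
  # expected vector at any level equals the oracle fitted line
  lvl <- mean(reg)
  exp_vec <- predict_expected(mod, lvl)
  oracle_vec <- sapply(1:59, function(g) {
    o <- oracle_ols(reg, vals[g + 1, ]); o["intercept"] + o["slope"] * lvl
  })
  expect_equal(unname(exp_vec), unname(oracle_vec), tolerance = 1e-10)
})

test_that("calibration preconditions are enforced", {
  x <- make_calibration_matrix(n_nt = 2, n_tu = 3,
                               targets = list(G1 = function(r) r))
  expect_error(fit_target_responses(x, gene_panel(targets = "G1")),
               "at least 3 nontumor")
  x2 <- make_calibration_matrix(targets = list(G1 = function(r) r))
  expect_error(fit_target_responses(x2, gene_panel(regulator = "MDM4",
                                                   targets = "G1")),
               "regulator")
  expect_warning(mod <- fit_target_responses(
    x2, gene_panel(targets = c("G1", "GHOST"))), "GHOST")
  expect_equal(mod$target, "G1")
})

test_that("predict_expected evaluates the response functions", {
  mod <- data.frame(target = c("A", "B"), intercept = c(1, 3),
                    slope = c(1, 0), quad = c(0, 0))
  expect_equal(unname(predict_expected(mod, 4)), c(5, 3))
  expect_equal(unname(predict_expected(mod, -2)), c(-1, 3))
})

test_that("sample_response_slope recovers exact and noisy attenuation", {
  set.seed(23)
  expected <- runif(59, 4, 12)
  s1 <- sample_response_slope(expected, expected, "id1")
  expect_equal(s1$slope, 1, tolerance = 1e-12)
  expect_equal(s1$class, "normal_like")
  s2 <- sample_response_slope(0.5 * expected, expected, "id2")
  expect_equal(s2$slope, 0.5, tolerance = 1e-12)
  expect_equal(s2$class, "impaired")
  obs <- 1 + 0.6 * expected + rnorm(59, 0, 0.05)
  s3 <- sample_response_slope(obs, expected, "id3")
  expect_lt(abs(s3$slope - 0.6), 0.05)
  expect_equal(s3$class, "impaired")
  o <- oracle_ols(expected, obs)
  expect_equal(s3$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(s3$intercept, unname(o["intercept"]), tolerance = 1e-12)
})

test_that("degenerate expected vectors are rejected with the sample named", {
  expect_error(sample_response_slope(1:5, rep(3, 5), "badsample"),
               "badsample")
  expect_error(sample_response_slope(1:4, 1:5), "equal length")
  expect_error(sample_response_slope(1:2, 1:2), "at least 3")
})

test_that("scaling a sample's observed values by k scales its OLS slope by k", {
  set.seed(29)
  for (i in 1:10) {
    expected <- rnorm(30, 8, 2)
    observed <- rnorm(30, 8, 2)
    k <- runif(1, 0.2, 4)
    s1 <- sample_response_slope(observed, expected)
    s2 <- sample_response_slope(k * observed, expected)
    expect_equal(s2$slope, k * s1$slope, tolerance = 1e-12)
  }
})

test_that("slope classification uses an inclusive normal-like band", {
  expect_equal(classify_slope(c(0.89999, 0.9, 1.0, 1.1, 1.10001)),
               c("impaired", "normal_like", "normal_like", "normal_like",
                 "above_range"))
})

test_that("every scored sample receives exactly one class and counts partition", {
  sim <- simulate_dataset(sim_config(n_tumor = 50, seed = 13))
  sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
  expect_equal(nrow(sl), 50L)
  expect_true(all(sl$class %in% c("normal_like", "impaired", "above_range")))
  expect_equal(sum(table(sl$class)), nrow(sl))
  expect_equal(attr(sl, "impaired_fraction"), mean(sl$class == "impaired"))
})

test_that("classify_samples detects a known impaired subset at moderate noise", {
  counts <- vapply(1:5, function(seed) {
    sim <- simulate_dataset(sim_config(n_tumor = 100, impaired_fraction = 0.2,
                                       attenuation_range = c(0.5, 0.5),
                                       noise_sd = 0.2, seed = seed))
    sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
    sum(sl$class == "impaired")
  }, numeric(1))
  expect_true(all(abs(counts - 20) <= 2))
})

test_that("fully functional cohorts yield no impaired calls at low noise", {
  zero <- vapply(1:10, function(seed) {
    sim <- simulate_dataset(sim_config(impaired_fraction = 0, noise_sd = 0.1,
                                       seed = seed))
    sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
    sum(sl$class == "impaired")
  }, numeric(1))
  expect_gte(mean(zero == 0), 0.95)
})

test_that("filter_impaired removes exactly the impaired samples", {
  x <- make_matrix(samples = paste0("s", 1:10),
                   group = rep("tumor", 10))
  slopes <- data.frame(sample_id = paste0("s", 1:10),
                       slope = c(rep(1, 7), rep(0.5, 3)),
                       class = c(rep("normal_like", 7), rep("impaired", 3)))
  y <- filter_impaired(x, slopes)
  expect_equal(dim(y)[2], 7L)
  expect_false(any(paste0("s", 8:10) %in% sample_ids(y)))
  # no impaired: identity
  slopes$class <- "normal_like"
  expect_identical(filter_impaired(x, slopes)$values, x$values)
  # all impaired: error
  slopes$class <- "impaired"
  expect_error(filter_impaired(x, slopes), "all samples")
  # unknown sample id: error
  expect_error(filter_impaired(x, data.frame(sample_id = "zz",
                                             class = "impaired")),
               "not present")
})

test_that("restoration is the identity when nothing is impaired and improves coupling otherwise", {
  sim <- simulate_dataset(sim_config(impaired_fraction = 0, seed = 9))
  sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
  sl$class[] <- "normal_like"   # guard: treat every sample as retained
  rep0 <- restoration_analysis(sim$matrix, sl, list(c("ZNF224", "CDKN1A")))
  expect_identical(rep0$bicor_all, rep0$bicor_filtered)
  expect_equal(rep0$n_removed, 0L)

  deltas <- vapply(1:10, function(seed) {
    sim <- simulate_dataset(sim_config(impaired_fraction = 0.3,
                                       attenuation_range = c(0, 0),
                                       seed = seed))
    sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
    r <- restoration_analysis(sim$matrix, sl, list(c("ZNF224", "CDKN1A")))
    r$bicor_filtered - r$bicor_all
  }, numeric(1))
  expect_gte(mean(deltas > 0), 0.9)
  expect_gt(median(deltas), 0)
})

test_that("restoration_analysis validates its inputs", {
  sim <- simulate_dataset(sim_config(n_tumor = 10, seed = 2))
  sl <- suppressMessages(classify_samples(sim$matrix, sim$panel))
  expect_error(restoration_analysis(sim$matrix, sl, list(c("ZNF224", "GHOST"))),
               "GHOST")
  sl$class[] <- "impaired"
  sl$class[1] <- "normal_like"
  expect_error(restoration_analysis(sim$matrix, sl,
                                    list(c("ZNF224", "CDKN1A"))),
               "fewer than 3")
})
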