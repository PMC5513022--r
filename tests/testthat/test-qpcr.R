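make_cfg <- function(noise_sd, seed, fold = 6, n_null = 2) {
  conditions <- c("leaf", "stem")
  assays <- c("tgt", sprintf("null%d", seq_len(n_null)), "r1", "r2", "r3")
  folds <- matrix(1, length(assays), 2,
                  dimnames = list(assays, conditions))
  folds["tgt", "stem"] <- fold
  eff <- setNames(rep(2, length(assays)), assays)
  make_cq_dataset(conditions, folds, eff, c("r1", "r2", "r3"),
                  noise_sd = noise_sd, seed = seed)
}

test_that("efficiency estimation recovers the textbook series and errors", {
  d <- data.frame(assay = "a", dilution = c(1, 0.1, 0.01),
                  cq = c(20, 23.32, 26.64))
  e <- estimate_efficiency(d)
  expect_equal(unname(e), 2.0, tolerance = 1e-3)
  # slope -3.80 gives E = 10^(1/3.80)
  d2 <- data.frame(assay = "b", dilution = c(1, 0.1, 0.01),
                   cq = 20 + c(0, 3.8, 7.6))
  expect_equal(unname(estimate_efficiency(d2)), 10^(1 / 3.8),
               tolerance = 1e-9)
  expect_error(estimate_efficiency(
    data.frame(assay = "c", dilution = c(1, 0.1), cq = c(20, 23))), ">= 3")
  expect_error(estimate_efficiency(
    data.frame(assay = "d", dilution = c(1, 0.1, 0.01), cq = c(26, 23, 20))),
    "slope")
  expect_warning(estimate_efficiency(
    data.frame(assay = "e", dilution = c(1, 0.1, 0.01),
               cq = c(20, 25, 30))), "outside")
})

test_that("normalization: identical Cq gives NRQ 1, 3 cycles gives ratio 8", {
  cfg <- make_cfg(noise_sd = 0, seed = 1, fold = 1)
  nrq <- normalize_cq(cfg$cq)
  expect_equal(unname(nrq$nrq), matrix(1, nrow(nrq$nrq), ncol(nrq$nrq)),
               tolerance = 1e-12)
  cfg8 <- make_cfg(noise_sd = 0, seed = 1, fold = 8)
  nrq8 <- normalize_cq(cfg8$cq)
  stem <- nrq8$sample_condition == "stem"
  ratio <- mean(nrq8$nrq["tgt", stem]) / mean(nrq8$nrq["tgt", !stem])
  expect_equal(ratio, 8, tolerance = 1e-9)
})

test_that("reference self-normalization: geometric mean of reference NRQ is 1", {
  cfg <- make_cfg(noise_sd = 0.3, seed = 4, fold = 5)
  nrq <- normalize_cq(cfg$cq)
  gm <- exp(colMeans(log(nrq$nrq[c("r1", "r2", "r3"), ])))
  expect_equal(unname(gm), rep(1, ncol(nrq$nrq)), tolerance = 1e-9)
})

test_that("global per-sample Cq shifts leave NRQ invariant (metamorphic)", {
  cfg <- make_cfg(noise_sd = 0.2, seed = 9)
  base <- normalize_cq(cfg$cq)
  shifted <- cfg$cq
  obs <- shifted$observations
  key <- paste(obs$sample, obs$replicate)
  shift <- setNames(runif(length(unique(key)), -2, 2), unique(key))
  obs$cq <- obs$cq + shift[key]
  shifted$observations <- obs
  got <- normalize_cq(shifted)
  expect_equal(got$nrq, base$nrq, tolerance = 1e-9)
})

test_that("noise-free planted fold is recovered exactly; noisy within bound", {
  cfg <- make_cfg(noise_sd = 0, seed = 2, fold = 6)
  nrq <- normalize_cq(cfg$cq)
  cr <- condition_ratios(nrq, data.frame(condition = "stem", control = "leaf"))
  lr <- cr$calls$log2_ratio[cr$calls$assay == "tgt"]
  expect_lt(abs(lr - log2(6)), 1e-9)
  # parameter recovery at noise_sd 0.15 across 50 seeds; per-sample log2
  # noise is noise_sd * sqrt(1 + 1/3) because the normalization factor is
  # the geometric mean of three equally noisy reference assays
  errs <- vapply(1:50, function(s) {
    cfg <- make_cfg(noise_sd = 0.15, seed = 100 + s, fold = 6)
    nrq <- normalize_cq(cfg$cq)
    cr <- condition_ratios(nrq, data.frame(condition = "stem",
                                           control = "leaf"))
    abs(cr$calls$log2_ratio[cr$calls$assay == "tgt"] - log2(6))
  }, numeric(1))
  expect_lt(max(errs), 3 * 0.15 * sqrt(4 / 3) * sqrt(2 / 9))
})

test_that("undetected assays are excluded, not imputed", {
  cfg <- make_cfg(noise_sd = 0, seed = 3)
  obs <- cfg$cq$observations
  obs$cq[obs$assay == "null1" & obs$condition == "stem"] <- NA  # all-ND
  cfg$cq$observations <- obs
  nrq <- normalize_cq(cfg$cq)
  cr <- condition_ratios(nrq, data.frame(condition = "stem", control = "leaf"))
  row <- cr$calls[cr$calls$assay == "null1", ]
  expect_false(row$testable)
  expect_false("null1" %in% rownames(cr$heatmap))
  expect_true("tgt" %in% rownames(cr$heatmap))
})

test_that("missing reference observations are a named error", {
  cfg <- make_cfg(noise_sd = 0, seed = 5)
  obs <- cfg$cq$observations
  drop <- obs$assay == "r1" & obs$sample == "stem1" & obs$replicate == 1
  cfg$cq$observations <- obs[!drop, ]
  expect_error(normalize_cq(cfg$cq), "r1")
})

test_that("technical-replicate averaging reduces units to biological samples", {
  cfg <- make_cfg(noise_sd = 0.1, seed = 6)
  pooled <- normalize_cq(cfg$cq)
  avg <- normalize_cq(cfg$cq, average_technical = TRUE)
  expect_equal(ncol(pooled$nrq), 18)  # 2 conditions x 3 bio x 3 tech
  expect_equal(ncol(avg$nrq), 6)      # 2 conditions x 3 bio
})

test_that("type-I behaviour: planted fold 1 with noise rarely called", {
  res <- vapply(1:100, function(s) {
    cfg <- make_cfg(noise_sd = 0.15, seed = 1000 + s, fold = 1, n_null = 1)
    nrq <- normalize_cq(cfg$cq)
    cr <- condition_ratios(nrq, data.frame(condition = "stem",
                                           control = "leaf"))
    row <- cr$calls[cr$calls$assay == "tgt", ]
    abs(row$log2_ratio) < 0.5 && !row$significant
  }, logical(1))
  expect_gte(mean(res), 0.95)
})
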