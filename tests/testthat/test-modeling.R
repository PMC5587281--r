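test_that("predict_vo2 evaluates the published equations", {
  # intercept identity: all predictors zero, female
  s0 <- tibble::tibble(weight_kg = 0, age_yr = 0, sex = "female", rfsmax = 0)
  expect_equal(predict_vo2(s0, vo2_model("1a"))$vo2peak_pred, 1.587)

  # patient-group means, model 2 — independent hand arithmetic
  cad_means <- tibble::tibble(weight_kg = 93.7, age_yr = 56.6, rfsmax = 4.6)
  by_hand <- 4.624 + 0.00311 * 93.7 + (-0.0516) * 56.6 + 0.123 * 4.6
  out <- predict_vo2(cad_means, vo2_model("2"))
  expect_equal(out$vo2peak_pred, by_hand, tolerance = 1e-12)
  expect_equal(out$vo2peak_pred, 2.5606, tolerance = 1e-4)

  # determinism
  expect_identical(predict_vo2(cad_means, vo2_model("2"))$vo2peak_pred,
                   out$vo2peak_pred)

  # missing predictor named in the error
  err <- expect_error(predict_vo2(tibble::tibble(weight_kg = 80), vo2_model("2")),
                      class = "squatfit_error_schema")
  expect_match(conditionMessage(err), "age_yr")
})

test_that("sex enters model 1b as an exact +0.18 L/min offset", {
  female <- tibble::tibble(weight_kg = 70, age_yr = 30, sex = "female", rfsmax = 15)
  male <- dplyr::mutate(female, sex = "male")
  m1b <- vo2_model("1b")
  expect_equal(predict_vo2(male, m1b)$vo2peak_pred,
               predict_vo2(female, m1b)$vo2peak_pred + 0.18)
})

test_that("fit_vo2 recovers an exact linear structure and matches the normal equations", {
  cohort <- simulate_cohort(n = 40, group = "healthy", noise_sd = 0, seed = 21)
  truth <- vo2_model("1a")$coefficients
  fit <- suppressWarnings(fit_vo2(cohort, c("weight", "age", "sex", "rfsmax")))
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-8)
  expect_equal(fit$r, 1, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)

  # independent normal-equations oracle on a noisy cohort
  noisy <- simulate_cohort(n = 35, group = "healthy", seed = 22)
  fit2 <- fit_vo2(noisy, c("weight", "age", "sex", "rfsmax"))
  X <- design_matrix_manual(noisy, c("weight", "age", "sex", "rfsmax"))
  beta <- ols_normal_equations(X, noisy$vo2peak_lmin)
  expect_equal(unname(fit2$coefficients), unname(beta), tolerance = 1e-9)

  # OLS with intercept: residual mean is zero
  expect_lt(abs(mean(residuals(fit2$lm))), 1e-10)
})

test_that("fit_vo2 surfaces rank deficiency as a singularity error", {
  males <- simulate_cohort(n = 20, group = "cad", p_male = 1, seed = 4)
  expect_error(fit_vo2(males, c("weight", "age", "sex", "rfsmax")),
               class = "squatfit_error_singular")
})

test_that("stepwise_forward admits signal, respects p_enter, and hits both limits", {
  # one strongly predictive candidate among noise: it (alone) should enter
  hits <- 0L
  for (seed in 1:20) {
    coh <- simulate_cohort(
      n = 40, group = "healthy",
      coefficients = c(intercept = 1, weight = 0, age = 0, sex = 0, rfsmax = 0.2),
      noise_sd = 0.3, seed = seed
    )
    sel <- stepwise_forward(coh, p_enter = 0.05)
    if (identical(sel$predictors, "rfsmax")) hits <- hits + 1L
  }
  expect_gte(hits, 14) # majority behaviour over 20 seeds

  # permissive threshold: all candidates enter; final fit is order-independent
  coh <- simulate_cohort(n = 40, group = "healthy", seed = 31)
  all_in <- stepwise_forward(coh, p_enter = 1.0)
  expect_setequal(all_in$predictors, c("weight", "age", "sex", "rfsmax"))
  forced <- fit_vo2(coh, c("weight", "age", "sex", "rfsmax"))
  expect_equal(all_in$coefficients[names(forced$coefficients)],
               forced$coefficients, tolerance = 1e-12)

  # nothing qualifies: intercept-only model
  pure_noise <- simulate_cohort(
    n = 30, group = "healthy",
    coefficients = c(intercept = 2.5, weight = 0, age = 0, sex = 0, rfsmax = 0),
    noise_sd = 0.5, seed = 32
  )
  none <- stepwise_forward(pure_noise, p_enter = 1e-8)
  expect_length(none$predictors, 0)
})

test_that("loocv_vo2 is exact in the noiseless limit", {
  coh <- simulate_cohort(n = 25, group = "cad", noise_sd = 0, seed = 41)
  cv <- loocv_vo2(coh, c("weight", "age", "rfsmax"))
  expect_lt(cv$rmse_cv, 1e-6)
  expect_gt(cv$r_cv, 0.999)
  expect_equal(nrow(cv$predictions), 25)
})

test_that("loocv_vo2 matches a hand-executed fold-by-fold computation at n = 4", {
  data <- tibble::tibble(
    subject_id = paste0("s", 1:4),
    sex = c("female", "male", "male", "female"),
    weight_kg = c(60, 80, 90, 70),
    age_yr = c(30, 40, 50, 35),
    vo2peak_lmin = c(2.1, 3.0, 2.4, 2.6),
    rfsmax = c(15, 20, 5, 12)
  )
  cv <- loocv_vo2(data, predictors = c("weight", "rfsmax"))
  # independent oracle: per-fold normal equations
  X <- design_matrix_manual(data, c("weight", "rfsmax"))
  y <- data$vo2peak_lmin
  held <- vapply(1:4, function(i) {
    beta <- ols_normal_equations(X[-i, , drop = FALSE], y[-i])
    sum(X[i, ] * beta)
  }, numeric(1))
  expect_equal(cv$predictions$predicted, held, tolerance = 1e-9)
  expect_equal(cv$rmse_cv, sqrt(mean((held - y)^2)), tolerance = 1e-9)
  expect_equal(cv$rmse_cv_pct, 100 * cv$rmse_cv / mean(y), tolerance = 1e-12)
  expect_equal(cv$r_cv, cor(held, y), tolerance = 1e-12)
})

test_that("cross-validated error dominates the in-sample error", {
  worse <- 0L
  for (seed in 1:100) {
    coh <- simulate_cohort(n = 30, group = "healthy", seed = seed)
    preds <- c("weight", "age", "sex", "rfsmax")
    if (loocv_vo2(coh, preds)$rmse_cv >= fit_vo2(coh, preds)$rmse) worse <- worse + 1L
  }
  expect_gte(worse, 95)
})

test_that("bland_altman reproduces hand-computed bias and limits", {
  expect_equal(
    as.list(bland_altman(c(1, 2, 3), c(1, 2, 3))[c("bias", "loa_lower", "loa_upper")]),
    list(bias = 0, loa_lower = 0, loa_upper = 0)
  )
  # d = (+0.1, -0.1): sd = sqrt(sum((d - 0)^2) / (n - 1)) = sqrt(0.02)
  ba <- bland_altman(c(2.1, 1.9), c(2, 2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper, 1.96 * sqrt(0.02), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -1.96 * sqrt(0.02), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), class = "squatfit_error_contract")
})

test_that("partial_correlation reduces to Pearson and matches residualization", {
  coh <- simulate_cohort(n = 30, group = "healthy", seed = 51)
  expect_equal(partial_correlation(coh, "rfsmax"),
               cor(coh$rfsmax, coh$vo2peak_lmin), tolerance = 1e-12)

  # brute-force residual-on-residual oracle via normal equations
  controls <- c("weight", "age", "sex")
  Xc <- design_matrix_manual(coh, controls)
  res <- function(v) v - Xc %*% ols_normal_equations(Xc, v)
  oracle <- cor(res(coh$rfsmax), res(coh$vo2peak_lmin))
  expect_equal(partial_correlation(coh, "rfsmax", controls), as.numeric(oracle),
               tolerance = 1e-9)

  # degenerate: constant predictor residuals
  males <- simulate_cohort(n = 20, group = "cad", p_male = 1, seed = 52)
  expect_error(partial_correlation(males, "sex", c("weight", "age")),
               class = "squatfit_error_degenerate")
})

test_that("fitness_category bins relative fitness with lower-inclusive edges", {
  d <- tibble::tibble(
    subject_id = c("a", "b"), weight_kg = c(70, 70), vo2peak_lmin = c(3.0, 2.1)
  )
  out <- fitness_category(d)
  expect_equal(out$rel_fitness, c(1000 * 3 / 70, 30))
  expect_equal(as.character(out$fitness_category), c("[40,50)", "[30,40)"))
  expect_equal(out$normal_to_low, c(FALSE, TRUE))
  expect_equal(out$fitness_flag, c("ok", "ok"))

  # out of range: nearest edge bin plus a warning flag
  expect_warning(
    lo <- fitness_category(tibble::tibble(weight_kg = 100, vo2peak_lmin = 1.0)),
    "edge bins"
  )
  expect_equal(as.character(lo$fitness_category), "[20,30)")
  expect_equal(lo$fitness_flag, "below_range")
})

test_that("rmse_by_category partitions the global error", {
  # all subjects in one bin: that bin's RMSE equals the global rmse_cv
  set.seed(61)
  coh <- simulate_cohort(n = 20, group = "cad", seed = 61)
  coh$vo2peak_lmin <- coh$weight_kg * 25 / 1000 + rnorm(20, 0, 0.1) # all [20,30)
  cv <- loocv_vo2(coh, c("weight", "age", "rfsmax"))
  by_cat <- rmse_by_category(cv, coh)
  expect_equal(nrow(by_cat), 1)
  expect_equal(by_cat$rmse_cv, cv$rmse_cv, tolerance = 1e-12)
  expect_equal(by_cat$n, 20)

  # two-bin toy set against hand-computed per-bin values
  toy <- tibble::tibble(
    subject_id = paste0("t", 1:6),
    sex = rep("male", 6),
    weight_kg = rep(80, 6),
    age_yr = c(30, 35, 40, 45, 50, 55),
    vo2peak_lmin = c(2.0, 2.2, 2.1, 3.0, 3.2, 3.1), # rel: 25,27.5,26.2 | 37.5,40,38.8
    rfsmax = c(5, 6, 4, 15, 16, 14)
  )
  cv2 <- loocv_vo2(toy, c("age", "rfsmax"))
  by2 <- suppressWarnings(rmse_by_category(cv2, toy))
  d <- cv2$predictions$difference
  rel <- 1000 * toy$vo2peak_lmin / toy$weight_kg
  for (bin in split(seq_len(6), findInterval(rel, c(20, 30, 40)))) {
    expect_equal(
      by2$rmse_cv[by2$n == length(bin)][1],
      sqrt(mean(d[bin]^2)), tolerance = 1e-12
    )
  }
})

test_that("subject tables round-trip and validate their schema", {
  coh <- simulate_cohort(n = 12, group = "healthy", seed = 71)
  path <- withr::local_tempfile(fileext = ".csv")
  write_subjects(coh, path)
  back <- read_subjects(path)
  expect_equal(back$vo2peak_lmin, coh$vo2peak_lmin, tolerance = 1e-9)
  expect_equal(back$sex, coh$sex)

  # column mapping for foreign layouts
  foreign <- dplyr::rename(coh, Weight = weight_kg, Age = age_yr)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(foreign, path2)
  mapped <- read_subjects(path2, col_map = c(weight_kg = "Weight", age_yr = "Age"))
  expect_equal(mapped$weight_kg, coh$weight_kg, tolerance = 1e-9)

  err <- expect_error(validate_subjects(coh[, c("subject_id", "sex")]),
                      class = "squatfit_error_schema")
  expect_match(conditionMessage(err), "weight_kg")
  expect_match(conditionMessage(err), "vo2peak_lmin")
})
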