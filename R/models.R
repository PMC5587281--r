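#' Published VO2peak prediction models
#'
#' Three reference regression equations predict absolute VO2peak (L/min) from
#' subject characteristics and the motion-decay feature R_FSmax:
#'
#' * `"1a"` — derived on 30 healthy adults: predictors weight (kg), age (yr),
#'   sex (female = 0, male = 1), R_FSmax.
#' * `"1b"` — derived on the 17 healthy adults with normal-to-low fitness
#'   (relative VO2peak < 40 ml/min/kg): same predictors.
#' * `"2"` — derived on 18 male coronary artery disease patients: weight, age,
#'   R_FSmax (no sex term; the derivation group was all male).
#'
#' @param name `"1a"`, `"1b"` or `"2"`, or `"custom"` with explicit
#'   `predictors` and `coefficients`.
#' @param predictors For `"custom"`: character vector drawn from
#'   `c("weight", "age", "sex", "rfsmax")`.
#' @param coefficients For `"custom"`: named numeric vector with an
#'   `"intercept"` element plus one per predictor (L/min per predictor unit).
#' @return An object of class `vo2_model`.
#' @examples
#' vo2_model("2")
#' @export
vo2_model <- function(name = c("1a", "1b", "2", "custom"),
                      predictors = NULL, coefficients = NULL) {
  name <- match.arg(name)
  published <- list(
    "1a" = list(
      predictors = c("weight", "age", "sex", "rfsmax"),
      coefficients = c(intercept = 1.587, weight = 0.01443, age = -0.01759,
                       sex = 0.674, rfsmax = 0.01712)
    ),
    "1b" = list(
      predictors = c("weight", "age", "sex", "rfsmax"),
      coefficients = c(intercept = 0.145, weight = 0.0299, age = -0.0182,
                       sex = 0.18, rfsmax = 0.0305)
    ),
    "2" = list(
      predictors = c("weight", "age", "rfsmax"),
      coefficients = c(intercept = 4.624, weight = 0.00311, age = -0.0516,
                       rfsmax = 0.123)
    )
  )
  if (name == "custom") {
    if (is.null(predictors) || is.null(coefficients)) {
      stop_squatfit("A custom model needs explicit predictors and coefficients.", "contract")
    }
    predictors <- match_predictors(predictors)
    need <- c("intercept", predictors)
    if (!all(need %in% names(coefficients))) {
      stop_squatfit(
        sprintf("coefficients must be named: %s.", paste(need, collapse = ", ")),
        "contract"
      )
    }
    coefficients <- coefficients[need]
  } else {
    predictors <- published[[name]]$predictors
    coefficients <- published[[name]]$coefficients
  }
  structure(
    list(name = paste0("model_", name), predictors = predictors,
         coefficients = coefficients, sex_coding = c(female = 0, male = 1)),
    class = "vo2_model"
  )
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model> %s: VO2peak [L/min] =\n  %.5f", x$name, x$coefficients[["intercept"]]))
  for (p in x$predictors) {
    cat(sprintf(" %+.5f*%s", x$coefficients[[p]], p))
  }
  cat("\n  (sex coded female = 0, male = 1)\n")
  invisible(x)
}

PREDICTOR_COLUMNS <- c(
  weight = "weight_kg", age = "age_yr", sex = "sex", rfsmax = "rfsmax"
)

match_predictors <- function(predictors) {
  bad <- setdiff(predictors, names(PREDICTOR_COLUMNS))
  if (length(bad)) {
    stop_squatfit(
      sprintf("Unknown predictor(s): %s. Available: %s.",
              paste(bad, collapse = ", "),
              paste(names(PREDICTOR_COLUMNS), collapse = ", ")),
      "contract"
    )
  }
  predictors
}

sex_to01 <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) {
      stop_squatfit("Numeric sex must be coded 0 (female) / 1 (male).", "contract")
    }
    return(as.numeric(sex))
  }
  s <- tolower(as.character(sex))
  out <- dplyr::case_when(
    s %in% c("female", "f", "0") ~ 0,
    s %in% c("male", "m", "1") ~ 1,
    TRUE ~ NA_real_
  )
  if (anyNA(out)) {
    stop_squatfit("sex must be 'female' or 'male' (or 0/1).", "contract")
  }
  out
}

# numeric predictor frame (model-term names) from a subject tibble
design_frame <- function(data, predictors, need_outcome = TRUE) {
  predictors <- match_predictors(predictors)
  cols <- PREDICTOR_COLUMNS[predictors]
  missing_cols <- setdiff(unname(c(if (need_outcome) "vo2peak_lmin", cols)), names(data))
  if (length(missing_cols)) {
    stop_squatfit(
      sprintf("Subject table is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "schema", missing = missing_cols
    )
  }
  out <- tibble(.rows = nrow(data))
  for (i in seq_along(predictors)) {
    v <- data[[cols[[i]]]]
    out[[predictors[[i]]]] <- if (predictors[[i]] == "sex") sex_to01(v) else as.numeric(v)
  }
  if (need_outcome) out$vo2peak <- as.numeric(data$vo2peak_lmin)
  if (anyNA(out)) {
    stop_squatfit("Subject table contains missing values in model columns.", "contract")
  }
  out
}

predict_vector <- function(model, data) {
  df <- design_frame(data, model$predictors, need_outcome = FALSE)
  pred <- rep(model$coefficients[["intercept"]], nrow(df))
  for (p in model$predictors) pred <- pred + model$coefficients[[p]] * df[[p]]
  unname(pred)
}

#' Predict VO2peak for a subject table
#'
#' Applies a fitted or published linear model (`intercept + sum(coef * value)`,
#' sex coded female = 0 / male = 1) to each row of a subject table.
#'
#' @param data A subject tibble with the columns the model's predictors need
#'   (`weight_kg`, `age_yr`, `sex`, `rfsmax`).
#' @param model A [vo2_model()] or a fit from [fit_vo2()].
#' @return `data` with an added `vo2peak_pred` column (L/min).
#' @examples
#' tibble::tibble(weight_kg = 93.7, age_yr = 56.6, rfsmax = 4.6) |>
#'   predict_vo2(vo2_model("2"))
#' @export
predict_vo2 <- function(data, model) {
  model <- as_vo2_model(model)
  dplyr::mutate(as_tibble(data), vo2peak_pred = predict_vector(model, data))
}

as_vo2_model <- function(model) {
  if (inherits(model, "vo2_model")) return(model)
  if (inherits(model, "vo2_fit")) {
    return(vo2_model("custom", predictors = model$predictors,
                     coefficients = model$coefficients))
  }
  stop_squatfit("model must be a vo2_model or vo2_fit.", "contract")
}

#' @export
predict.vo2_model <- function(object, newdata, ...) predict_vector(object, newdata)

#' @export
predict.vo2_fit <- function(object, newdata, ...) {
  predict_vector(as_vo2_model(object), newdata)
}

assert_full_rank <- function(X, context = "design") {
  if (qr(X)$rank < ncol(X)) {
    stop_squatfit(
      sprintf("Rank-deficient %s matrix: a predictor is constant or collinear.", context),
      "singular"
    )
  }
}

#' Fit a VO2peak regression by ordinary least squares
#'
#' Forced-entry OLS of measured VO2peak (L/min) on a chosen predictor subset,
#' via [stats::lm()]. Reports per-coefficient standard errors, t statistics and
#' two-sided p-values, plus the in-sample Pearson correlation r between fitted
#' and measured values, adjusted r^2, and the in-sample RMSE
#' (root mean squared residual, L/min).
#'
#' @param data A subject tibble (columns `vo2peak_lmin` plus the predictor
#'   columns; see [read_subjects()]).
#' @param predictors Character vector from `c("weight", "age", "sex",
#'   "rfsmax")`; may be empty for an intercept-only model.
#' @return An object of class `vo2_fit`; see [tidy()] and [glance()] methods.
#' @examples
#' cohort <- simulate_cohort(n = 40, seed = 1)
#' fit <- fit_vo2(cohort, c("weight", "age", "sex", "rfsmax"))
#' glance(fit)
#' @export
fit_vo2 <- function(data, predictors = c("weight", "age", "sex", "rfsmax")) {
  predictors <- match_predictors(unique(predictors))
  df <- design_frame(data, predictors)
  p <- length(predictors)
  if (nrow(df) <= p + 1L) {
    stop_squatfit(
      sprintf("Need n > %d subjects to fit %d predictors; got %d.", p + 1L, p, nrow(df)),
      "contract"
    )
  }
  form <- if (p == 0) vo2peak ~ 1 else {
    stats::reformulate(predictors, response = "vo2peak")
  }
  assert_full_rank(model.matrix(form, df))
  fit <- lm(form, data = df)
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- c("intercept", predictors)
  coef_table <- tibble(
    term = terms,
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4])
  )
  res <- residuals(fit)
  structure(
    list(
      predictors = predictors,
      coefficients = setNames(unname(coef(fit)), terms),
      coef_table = coef_table,
      r = if (p == 0) NA_real_ else cor(fitted(fit), df$vo2peak),
      adj_r2 = sm$adj.r.squared,
      rmse = sqrt(mean(res^2)),
      n = nrow(df),
      df_residual = fit$df.residual,
      lm = fit
    ),
    class = "vo2_fit"
  )
}

#' @export
print.vo2_fit <- function(x, ...) {
  cat(sprintf("<vo2_fit> n = %d, predictors: %s\n", x$n,
              if (length(x$predictors)) paste(x$predictors, collapse = ", ") else "(intercept only)"))
  print(x$coef_table)
  cat(sprintf("r = %.3f, adj r^2 = %.3f, RMSE = %.3f L/min\n", x$r, x$adj_r2, x$rmse))
  invisible(x)
}

#' Forward stepwise predictor selection with a p-to-enter threshold
#'
#' Starting from an intercept-only model, repeatedly fits one candidate at a
#' time on top of the current predictor set and admits the candidate with the
#' smallest coefficient p-value, as long as that p-value is below `p_enter`.
#' Ties are broken by candidate order. Deterministic; may return an
#' intercept-only fit if no candidate qualifies.
#'
#' @param data A subject tibble.
#' @param candidates Candidate predictor pool (default all four terms).
#' @param p_enter Entry threshold on the candidate's two-sided p-value.
#' @return A `vo2_fit` of the selected model (its `$predictors` records the
#'   entry order).
#' @export
stepwise_forward <- function(data, candidates = c("weight", "age", "sex", "rfsmax"),
                             p_enter = 0.05) {
  candidates <- match_predictors(unique(candidates))
  if (!length(candidates)) {
    stop_squatfit("Candidate pool must be non-empty.", "contract")
  }
  selected <- character(0)
  pool <- candidates
  while (length(pool)) {
    entry_p <- vapply(pool, function(cand) {
      fit <- tryCatch(fit_vo2(data, c(selected, cand)), error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      fit$coef_table$p_value[fit$coef_table$term == cand]
    }, numeric(1))
    best <- which.min(entry_p) # which.min takes the first on ties
    if (!is.finite(entry_p[best]) || entry_p[best] >= p_enter) break
    selected <- c(selected, pool[best])
    pool <- pool[-best]
  }
  fit_vo2(data, if (length(selected)) selected else character(0))
}

#' Leave-one-subject-out cross-validation of a VO2peak model
#'
#' For each subject, refits the fixed predictor set on the remaining n - 1
#' subjects and predicts the held-out one. Summarizes the held-out predictions
#' as RMSE_cv (L/min), RMSE_cv as a percentage of the group's mean measured
#' VO2peak, the Pearson correlation r_cv between held-out predictions and
#' measurements, and Bland-Altman agreement statistics (bias and 1.96 SD
#' limits of agreement of predicted - measured).
#'
#' The predictor set is fixed across folds (no per-fold reselection), so the
#' cross-validation assesses the generalization error of one model.
#'
#' @inheritParams fit_vo2
#' @return An object of class `vo2_cv` with the per-subject held-out
#'   predictions (`$predictions`) and the summary statistics; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' cohort <- simulate_cohort(n = 30, seed = 7)
#' cv <- loocv_vo2(cohort, c("weight", "age", "sex", "rfsmax"))
#' glance(cv)
#' @export
loocv_vo2 <- function(data, predictors = c("weight", "age", "sex", "rfsmax")) {
  predictors <- match_predictors(unique(predictors))
  df <- design_frame(data, predictors)
  n <- nrow(df)
  if (n < 3L) {
    stop_squatfit(sprintf("Leave-one-out cross-validation needs n >= 3 subjects; got %d.", n),
                  "contract")
  }
  form <- stats::reformulate(predictors, response = "vo2peak")
  held_out <- vapply(seq_len(n), function(i) {
    train <- df[-i, , drop = FALSE]
    X <- model.matrix(form, train)
    if (qr(X)$rank < ncol(X)) {
      stop_squatfit(
        sprintf("Rank-deficient design when holding out subject %d.", i),
        "singular", fold = i
      )
    }
    unname(predict(lm(form, data = train), newdata = df[i, , drop = FALSE]))
  }, numeric(1))
  subject_id <- if ("subject_id" %in% names(data)) as.character(data$subject_id) else as.character(seq_len(n))
  preds <- tibble(
    subject_id = subject_id,
    measured = df$vo2peak,
    predicted = held_out,
    difference = held_out - df$vo2peak
  )
  ba <- bland_altman(preds$predicted, preds$measured)
  structure(
    list(
      predictors = predictors,
      predictions = preds,
      rmse_cv = sqrt(mean(preds$difference^2)),
      rmse_cv_pct = 100 * sqrt(mean(preds$difference^2)) / mean(preds$measured),
      r_cv = cor(preds$predicted, preds$measured),
      bias = ba$bias,
      loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper,
      n = n
    ),
    class = "vo2_cv"
  )
}

#' @export
print.vo2_cv <- function(x, ...) {
  cat(sprintf(
    "<vo2_cv> n = %d, predictors: %s\nRMSE_cv = %.3f L/min (%.1f%%), r_cv = %.3f\nbias = %.3f L/min, LoA = [%.3f, %.3f]\n",
    x$n, paste(x$predictors, collapse = ", "), x$rmse_cv, x$rmse_cv_pct, x$r_cv,
    x$bias, x$loa_lower, x$loa_upper
  ))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `predicted - measured`; the bias is their mean and
#' the limits of agreement are bias +/- 1.96 x SD (sample SD, n - 1
#' denominator).
#'
#' @param predicted,measured Numeric vectors of equal length >= 2 (L/min).
#' @return A one-row tibble: `n`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
bland_altman <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop_squatfit("predicted and measured must have equal length.", "contract")
  }
  if (length(predicted) < 2L) {
    stop_squatfit("Bland-Altman needs at least 2 paired values.", "contract")
  }
  d <- predicted - measured
  s <- sd(d)
  tibble(
    n = length(d), bias = mean(d), sd_diff = s,
    loa_lower = mean(d) - 1.96 * s, loa_upper = mean(d) + 1.96 * s
  )
}

#' Partial correlation between VO2peak and one model term
#'
#' The correlation between the outcome and one predictor after removing the
#' linear effects of the control terms from both (residual-on-residual
#' correlation). With no controls this reduces to the plain Pearson
#' correlation.
#'
#' @param data A subject tibble.
#' @param predictor One of `"weight"`, `"age"`, `"sex"`, `"rfsmax"`.
#' @param controls Character vector of control terms (default: none).
#' @return A single correlation in \[-1, 1\].
#' @export
partial_correlation <- function(data, predictor, controls = character(0)) {
  predictor <- match_predictors(predictor)
  controls <- match_predictors(setdiff(controls, predictor))
  df <- design_frame(data, c(predictor, controls))
  if (nrow(df) <= length(controls) + 2L) {
    stop_squatfit("Too few subjects for the requested partial correlation.", "contract")
  }
  if (length(controls) == 0) {
    rx <- df[[predictor]] - mean(df[[predictor]])
    ry <- df$vo2peak - mean(df$vo2peak)
  } else {
    cf <- stats::reformulate(controls)
    rx <- residuals(lm(update(cf, stats::as.formula(paste(predictor, "~ ."))), data = df))
    ry <- residuals(lm(update(cf, vo2peak ~ .), data = df))
  }
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    stop_squatfit("Partial correlation undefined: residuals are (near-)constant.", "degenerate")
  }
  cor(rx, ry)
}

#' @rdname partial_correlation
#' @param predictors Terms to report; each is correlated with the outcome
#'   controlling for the remaining ones.
#' @return `partial_correlations()`: a tibble with columns `term` and
#'   `partial_r`.
#' @export
partial_correlations <- function(data, predictors = c("weight", "age", "sex", "rfsmax")) {
  predictors <- match_predictors(unique(predictors))
  tibble(
    term = predictors,
    partial_r = vapply(predictors, function(p) {
      partial_correlation(data, p, setdiff(predictors, p))
    }, numeric(1))
  )
}

#' Classify subjects into fitness categories
#'
#' Relative fitness is VO2peak normalized by body weight,
#' `1000 * vo2peak_lmin / weight_kg` (ml/min/kg), binned into \[20, 30),
#' \[30, 40) and \[40, 50) ml/min/kg. Values outside \[20, 50) are assigned to
#' the nearest edge bin and flagged. The `normal_to_low` flag (relative
#' fitness < 40 ml/min/kg) selects the derivation subset of model 1b.
#'
#' @param data A subject tibble with `vo2peak_lmin` and `weight_kg`.
#' @return `data` with added columns `rel_fitness` (ml/min/kg),
#'   `fitness_category` (factor `"[20,30)"`, `"[30,40)"`, `"[40,50)"`),
#'   `normal_to_low` (logical) and `fitness_flag` (`"ok"`, `"below_range"`,
#'   `"above_range"`).
#' @export
fitness_category <- function(data) {
  need <- setdiff(c("vo2peak_lmin", "weight_kg"), names(data))
  if (length(need)) {
    stop_squatfit(sprintf("Missing column(s): %s.", paste(need, collapse = ", ")), "schema")
  }
  levels <- c("[20,30)", "[30,40)", "[40,50)")
  out <- as_tibble(data)
  rel <- 1000 * as.numeric(out$vo2peak_lmin) / as.numeric(out$weight_kg)
  idx <- findInterval(rel, c(20, 30, 40, 50))   # 0 below, 4 at/above 50
  flag <- dplyr::case_when(idx == 0 ~ "below_range", idx == 4 ~ "above_range", TRUE ~ "ok")
  if (any(flag != "ok")) {
    warn(sprintf("%d subject(s) outside the 20-50 ml/min/kg range assigned to edge bins.",
                 sum(flag != "ok")))
  }
  idx <- pmin(pmax(idx, 1L), 3L)
  out$rel_fitness <- rel
  out$fitness_category <- factor(levels[idx], levels = levels)
  out$normal_to_low <- rel < 40
  out$fitness_flag <- flag
  out
}

#' Cross-validated error by fitness category
#'
#' Groups the held-out squared errors of a [loocv_vo2()] result by the
#' subjects' fitness categories and reports each category's RMSE_cv, both in
#' L/min and as a percentage of that category's mean measured VO2peak.
#' Categories with no subjects are absent from the output (not reported as
#' zero).
#'
#' @param cv A `vo2_cv` computed on `data`.
#' @param data The subject tibble the cross-validation used.
#' @return A tibble with columns `fitness_category`, `n`, `rmse_cv`,
#'   `rmse_cv_pct`.
#' @export
rmse_by_category <- function(cv, data) {
  stopifnot(inherits(cv, "vo2_cv"))
  if (nrow(data) != cv$n) {
    stop_squatfit("data must be the table the cross-validation was computed on.", "contract")
  }
  cats <- fitness_category(data)
  dplyr::bind_cols(cv$predictions,
                   cats[c("fitness_category")]) |>
    dplyr::group_by(.data$fitness_category) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse_cv = sqrt(mean(.data$difference^2)),
      rmse_cv_pct = 100 * sqrt(mean(.data$difference^2)) / mean(.data$measured),
      .groups = "drop"
    )
}

#' Read and write subject tables
#'
#' A subject table has one row per subject with columns `subject_id`, `group`
#' (`"healthy"` / `"cad"`), `sex` (`"female"` / `"male"`), `weight_kg`,
#' `height_cm`, `age_yr`, `vo2peak_lmin` (measured peak oxygen uptake, L/min)
#' and `rfsmax` (the motion-decay feature; see [compute_rfsmax()]). CSV is read
#' with [readr::read_csv()]; `.xlsx` files (the layout of the original study's
#' supplementary table) are read with readxl when available.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(weight_kg = "Weight", age_yr = "Age")`.
#' @return A validated subject tibble.
#' @export
read_subjects <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop_squatfit(sprintf("Subject table not found: %s", path), "format")
  }
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_squatfit("Reading .xlsx needs the readxl package.", "format")
    }
    data <- readxl::read_excel(path)
  } else {
    data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(data)) {
        names(data)[names(data) == col_map[[canon]]] <- canon
      }
    }
  }
  validate_subjects(data)
}

#' @rdname read_subjects
#' @param data A subject tibble.
#' @export
write_subjects <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_subjects
#' @export
validate_subjects <- function(data) {
  required <- c("subject_id", "sex", "weight_kg", "age_yr", "vo2peak_lmin", "rfsmax")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_squatfit(
      sprintf("Subject table is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "schema", missing = missing_cols
    )
  }
  data <- as_tibble(data)
  data$sex <- c("female", "male")[sex_to01(data$sex) + 1]
  for (col in c("weight_kg", "age_yr", "vo2peak_lmin")) {
    v <- as.numeric(data[[col]])
    if (anyNA(v) || any(v <= 0)) {
      stop_squatfit(sprintf("Column %s must be positive with no missing values.", col), "schema")
    }
    data[[col]] <- v
  }
  data$rfsmax <- as.numeric(data$rfsmax)
  if (anyNA(data$rfsmax)) {
    stop_squatfit("Column rfsmax must have no missing values.", "schema")
  }
  if (any(data$rfsmax < 0)) {
    warn("Negative rfsmax values are not physiological for squat recordings.")
  }
  data
}
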