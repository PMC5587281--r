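#' Regenerate the reference analysis from a subject table
#'
#' Runs the full model battery on a labelled subject table:
#'
#' * **model_1a** — all healthy subjects; predictors weight, age, sex, R_FSmax.
#' * **model_1b** — healthy subjects with relative fitness < 40 ml/min/kg
#'   (the "normal-to-low" subset); same predictors.
#' * **model_2** — male CAD patients; predictors weight, age, R_FSmax.
#'
#' Each section reports the forced-entry OLS fit (coefficients, SE, t, p;
#' r, adjusted r^2, in-sample RMSE), the leave-one-subject-out
#' cross-validation (RMSE_cv absolute and percent, r_cv, bias and limits of
#' agreement of the held-out predictions), partial correlations of each
#' predictor with VO2peak controlling for the others, and RMSE_cv by fitness
#' category.
#'
#' @param table A subject tibble or a path readable by [read_subjects()].
#'   Must carry a `group` column labelling `"healthy"` / `"cad"` subjects.
#' @return An object of class `vo2_report`: a named list of per-model result
#'   lists, plus `$n_total`.
#' @examples
#' cohort <- dplyr::bind_rows(
#'   simulate_cohort(30, "healthy", seed = 1),
#'   simulate_cohort(18, "cad", seed = 2)
#' )
#' rep <- run_reproduction(cohort)
#' rep$model_2$cv$rmse_cv
#' @export
run_reproduction <- function(table) {
  data <- if (is.character(table)) read_subjects(table) else validate_subjects(table)
  if (!"group" %in% names(data)) {
    stop_squatfit("Subject table is missing column(s): group.", "schema")
  }
  data$group <- tolower(as.character(data$group))
  healthy <- dplyr::filter(data, .data$group == "healthy")
  cad <- dplyr::filter(data, .data$group == "cad", .data$sex == "male")
  ntl <- dplyr::filter(suppressWarnings(fitness_category(healthy)), .data$normal_to_low)
  sections <- list(
    model_1a = list(data = healthy, predictors = c("weight", "age", "sex", "rfsmax")),
    model_1b = list(data = ntl[names(healthy)], predictors = c("weight", "age", "sex", "rfsmax")),
    model_2 = list(data = cad, predictors = c("weight", "age", "rfsmax"))
  )
  out <- lapply(names(sections), function(nm) {
    d <- sections[[nm]]$data
    preds <- sections[[nm]]$predictors
    if (nrow(d) < 3L) {
      stop_squatfit(
        sprintf("%s: leave-one-out cross-validation needs n >= 3 subjects; got %d.", nm, nrow(d)),
        "contract"
      )
    }
    fit <- fit_vo2(d, preds)
    cv <- loocv_vo2(d, preds)
    list(
      n = nrow(d),
      predictors = preds,
      fit = list(
        coefficients = tidy(fit),
        r = fit$r, adj_r_squared = fit$adj_r2, rmse = fit$rmse
      ),
      cv = list(
        rmse_cv = cv$rmse_cv, rmse_cv_pct = cv$rmse_cv_pct, r_cv = cv$r_cv,
        bias = cv$bias, loa_lower = cv$loa_lower, loa_upper = cv$loa_upper
      ),
      partial_correlations = partial_correlations(d, preds),
      rmse_by_category = suppressWarnings(rmse_by_category(cv, d))
    )
  })
  names(out) <- names(sections)
  out$n_total <- nrow(data)
  class(out) <- "vo2_report"
  out
}

fmt <- function(x, digits) formatC(x, digits = digits, format = "f")

#' @export
print.vo2_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Serialize a reproduction report
#'
#' `format_report()` renders fixed-precision human-readable text (coefficients
#' at 5 decimals, metrics at 3); `write_report()` writes that text plus a JSON
#' document with sorted keys. Output is byte-identical across repeated runs on
#' identical inputs.
#'
#' @param report A `vo2_report` from [run_reproduction()].
#' @param dir Output directory (created if needed).
#' @return `format_report()`: a character vector of lines. `write_report()`:
#'   the paths written, invisibly.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "vo2_report"))
  lines <- c(sprintf("VO2peak prediction report (n = %d subjects)", report$n_total), "")
  for (nm in c("model_1a", "model_1b", "model_2")) {
    s <- report[[nm]]
    lines <- c(lines,
      sprintf("== %s (n = %d; predictors: %s) ==", nm, s$n, paste(s$predictors, collapse = ", ")),
      "term        coef        SE          t        p",
      sprintf("%-10s %10s %10s %8s %8s",
              s$fit$coefficients$term,
              fmt(s$fit$coefficients$estimate, 5),
              fmt(s$fit$coefficients$std_error, 5),
              fmt(s$fit$coefficients$statistic, 3),
              fmt(s$fit$coefficients$p_value, 4)),
      sprintf("r = %s, adj r^2 = %s, RMSE = %s L/min",
              fmt(s$fit$r, 3), fmt(s$fit$adj_r_squared, 3), fmt(s$fit$rmse, 3)),
      sprintf("LOOCV: RMSE_cv = %s L/min (%s%%), r_cv = %s",
              fmt(s$cv$rmse_cv, 3), fmt(s$cv$rmse_cv_pct, 1), fmt(s$cv$r_cv, 3)),
      sprintf("Bland-Altman: bias = %s, LoA = [%s, %s] L/min",
              fmt(s$cv$bias, 3), fmt(s$cv$loa_lower, 3), fmt(s$cv$loa_upper, 3)),
      sprintf("partial r: %s",
              paste(sprintf("%s = %s", s$partial_correlations$term,
                            fmt(s$partial_correlations$partial_r, 2)), collapse = ", ")),
      "RMSE_cv by fitness category [ml/min/kg]:",
      sprintf("  %s: n = %d, %s L/min (%s%%)",
              as.character(s$rmse_by_category$fitness_category),
              s$rmse_by_category$n,
              fmt(s$rmse_by_category$rmse_cv, 3),
              fmt(s$rmse_by_category$rmse_cv_pct, 1)),
      ""
    )
  }
  lines
}

#' @rdname format_report
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "vo2_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt_path <- file.path(dir, "report.txt")
  json_path <- file.path(dir, "report.json")
  writeLines(format_report(report), txt_path)
  to_json <- report
  class(to_json) <- NULL
  for (nm in c("model_1a", "model_1b", "model_2")) {
    to_json[[nm]]$fit$coefficients <- as.data.frame(to_json[[nm]]$fit$coefficients)
    to_json[[nm]]$partial_correlations <- as.data.frame(to_json[[nm]]$partial_correlations)
    to_json[[nm]]$rmse_by_category <- local({
      d <- as.data.frame(to_json[[nm]]$rmse_by_category)
      d$fitness_category <- as.character(d$fitness_category)
      d
    })
  }
  jsonlite::write_json(to_json, json_path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(c(txt_path, json_path))
}
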