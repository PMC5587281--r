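#' Tidy and glance methods for fitted and cross-validated models
#'
#' `tidy()` on a `vo2_fit` returns the coefficient table (term, estimate,
#' std_error, statistic, p_value); on a `vo2_cv` the per-subject held-out
#' predictions. `glance()` returns the one-row model summary.
#'
#' @param x A `vo2_fit` or `vo2_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @name squatfit-tidiers
NULL

#' @rdname squatfit-tidiers
#' @method tidy vo2_fit
#' @export
tidy.vo2_fit <- function(x, ...) x$coef_table

#' @rdname squatfit-tidiers
#' @method glance vo2_fit
#' @export
glance.vo2_fit <- function(x, ...) {
  tibble(r = x$r, adj_r_squared = x$adj_r2, rmse = x$rmse,
         n = x$n, df_residual = x$df_residual)
}

#' @rdname squatfit-tidiers
#' @method tidy vo2_cv
#' @export
tidy.vo2_cv <- function(x, ...) x$predictions

#' @rdname squatfit-tidiers
#' @method glance vo2_cv
#' @export
glance.vo2_cv <- function(x, ...) {
  tibble(
    rmse_cv = x$rmse_cv, rmse_cv_pct = x$rmse_cv_pct, r_cv = x$r_cv,
    bias = x$bias, loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n
  )
}
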