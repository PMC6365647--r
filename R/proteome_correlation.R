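#' Join protein abundance and environmental profiles
#'
#' Inner join of spectral-count and nutrient tables on `sample_id`.
#' Unmatched samples on either side are reported (attribute
#' `unmatched`, plus a message); duplicated sample ids are an error.
#'
#' @param abundance Tibble with `sample_id`, `spectral_count` and
#'   optionally `station`, `depth`.
#' @param environment Tibble with `sample_id`, `phosphate_uM`.
#' @return Tibble of paired observations with `x = phosphate_uM`,
#'   `y = spectral_count` plus any carried annotation columns; attribute
#'   `unmatched` lists sample ids present on only one side.
#' @export
join_profiles <- function(abundance, environment) {
  abundance <- tibble::as_tibble(abundance)
  environment <- tibble::as_tibble(environment)
  if (!all(c("sample_id", "spectral_count") %in% names(abundance))) {
    stop("abundance needs columns sample_id and spectral_count", call. = FALSE)
  }
  if (!all(c("sample_id", "phosphate_uM") %in% names(environment))) {
    stop("environment needs columns sample_id and phosphate_uM", call. = FALSE)
  }
  dup <- c(abundance$sample_id[duplicated(abundance$sample_id)],
           environment$sample_id[duplicated(environment$sample_id)])
  if (length(dup) > 0) {
    stop("Duplicate sample_id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  pairs <- dplyr::inner_join(abundance, environment, by = "sample_id")
  if (nrow(pairs) == 0) stop("No samples shared between the two profiles", call. = FALSE)
  unmatched <- union(setdiff(abundance$sample_id, environment$sample_id),
                     setdiff(environment$sample_id, abundance$sample_id))
  if (length(unmatched) > 0) {
    message(length(unmatched), " unmatched sample id(s): ",
            paste(unmatched, collapse = ", "))
  }
  pairs$x <- pairs$phosphate_uM
  pairs$y <- pairs$spectral_count
  attr(pairs, "unmatched") <- unmatched
  pairs
}

#' Fit a power law y = a * x^b
#'
#' Ordinary least squares of `log(y)` on `log(x)`: `a = exp(intercept)`,
#' `b` = slope. Pairs with nonpositive x or y are dropped (and counted),
#' not offset. The coefficient of determination is reported in log-log
#' space, where the model is linear; an original-space r-squared is also
#' emitted for sensitivity. No sign constraint is imposed on `b` (an
#' inverse abundance-nutrient relationship simply yields `b < 0`). When
#' `log(y)` has zero variance the fit is flat and the log-space
#' r-squared is 0 by convention.
#'
#' @param pairs Tibble with columns `x` and `y` (e.g. from
#'   [join_profiles()]), or any data frame with those columns.
#' @return A `power_law_fit` object: list with `a`, `b`,
#'   `r_squared_log`, `r_squared_linear`, `n_used`,
#'   `n_dropped_nonpositive`.
#' @export
fit_power_law <- function(pairs) {
  x <- pairs$x
  y <- pairs$y
  keep <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop("Need at least 3 pairs with positive x and y (have ", length(x), ")",
         call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  tss <- sum((ly - mean(ly))^2)
  r2_log <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  yhat <- a * x^b
  tss_lin <- sum((y - mean(y))^2)
  r2_lin <- if (tss_lin == 0) 0 else 1 - sum((y - yhat)^2) / tss_lin
  structure(
    list(a = a, b = b, r_squared_log = r2_log, r_squared_linear = r2_lin,
         n_used = length(x), n_dropped_nonpositive = n_dropped),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g\n", x$a, x$b))
  cat(sprintf("  r^2 (log-log) = %.3f, r^2 (linear) = %.3f, n = %d (%d dropped)\n",
              x$r_squared_log, x$r_squared_linear, x$n_used, x$n_dropped_nonpositive))
  invisible(x)
}

#' Evaluate a power-law fit on paired data
#'
#' @param fit A `power_law_fit`.
#' @param pairs Data frame with `x` and `y`.
#' @return Tibble with `x`, `y`, `predicted` (`a * x^b`) and
#'   `residual_log` (`log(y) - log(predicted)`; `NA` where x or y is
#'   nonpositive).
#' @export
evaluate_fit <- function(fit, pairs) {
  stopifnot(inherits(fit, "power_law_fit"))
  x <- pairs$x
  y <- pairs$y
  predicted <- fit$a * x^fit$b
  residual_log <- ifelse(x > 0 & y > 0, log(y) - log(predicted), NA_real_)
  tibble::tibble(x = x, y = y, predicted = predicted, residual_log = residual_log)
}
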