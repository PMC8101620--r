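#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.accuracy_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.accuracy_calibration <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r^2, n = x$n)
}

#' @export
tidy.calibration_line <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_line <- function(x, ...) {
  tibble::tibble(r = x$r, n_rods = x$n_rods)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf_low = x$ci_low,
                 conf_high = x$ci_high)
}

#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_units = x$n_units, n_replicates = x$n_replicates,
                 model = x$model)
}
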