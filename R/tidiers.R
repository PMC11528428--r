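#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a QPI mixture fit
#'
#' One row per Gaussian component: mean (an exact integer multiple of the
#' unit QPI), width and normalized weight.
#'
#' @param x A `qpi_fit`.
#' @param ... Unused.
#' @return A tibble with `component`, `mean`, `sigma`, `weight`.
#' @export
tidy.qpi_fit <- function(x, ...) {
  tibble(component = seq_len(x$K),
         mean = x$peak_means,
         sigma = x$peak_sigmas,
         weight = x$peak_weights)
}

#' @rdname tidy.qpi_fit
#' @return `glance()` returns a one-row tibble with `unit_qpi_s_inv`, `K`
#'   and the residual sum of squares of the histogram fit.
#' @export
glance.qpi_fit <- function(x, ...) {
  rss <- if (is.null(x$fit)) NA_real_ else sum(x$fit$fvec^2)
  tibble(unit_qpi_s_inv = x$unit_qpi_s_inv, K = x$K, rss = rss)
}

#' Tidy an infinite-dilution extrapolation
#'
#' @param x A `dilution_fit`.
#' @param ... Unused.
#' @return `tidy()`: the coefficient table of the underlying linear fit;
#'   `glance()`: one row with `log_k_limit`, `se`, `slope`, `n`.
#' @export
tidy.dilution_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(cf[, 1L]),
         std.error = unname(cf[, 2L]))
}

#' @rdname tidy.dilution_fit
#' @export
glance.dilution_fit <- function(x, ...) {
  tibble(log_k_limit = x$log_k_limit, se = x$se, slope = x$slope, n = x$n)
}
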