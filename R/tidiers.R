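# broom-style tidiers for the package's fitted/report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectrum report
#'
#' @param x An `fbw_spectrum` from [classify_stability()].
#' @param ... Unused.
#' @return A one-row tibble with the speed, the rightmost absolute-spectrum
#'   points at both ends, the ideal weight, the admissible weight interval
#'   endpoints (`NA` when empty), and the verdict.
#' @method tidy fbw_spectrum
#' @export
tidy.fbw_spectrum <- function(x, ...) {
  tibble::tibble(
    c = x$c, k_plus = x$k_plus, k_minus = x$k_minus,
    ideal_weight = x$ideal_weight,
    weight_lower = if (is.null(x$weight_interval)) NA_real_ else x$weight_interval[1],
    weight_upper = if (is.null(x$weight_interval)) NA_real_ else x$weight_interval[2],
    verdict = x$verdict
  )
}

#' @rdname tidy.fbw_spectrum
#' @method glance fbw_spectrum
#' @export
glance.fbw_spectrum <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, k_plus = x$k_plus)
}

#' Tidy a front-speed fit
#'
#' @param x An `fbw_speed_fit` from [estimate_speed()].
#' @param ... Unused.
#' @return A one-row tibble with `speed`, `intercept`, `rms`, `n` and the
#'   fit window.
#' @method tidy fbw_speed_fit
#' @export
tidy.fbw_speed_fit <- function(x, ...) {
  tibble::tibble(
    speed = x$speed, intercept = x$intercept, rms = x$rms, n = x$n,
    window_start = x$window[1], window_end = x$window[2]
  )
}

#' @rdname tidy.fbw_speed_fit
#' @method glance fbw_speed_fit
#' @export
glance.fbw_speed_fit <- function(x, ...) {
  tibble::tibble(speed = x$speed, rms = x$rms)
}
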