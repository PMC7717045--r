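# ggplot2 quick-look methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_path
#'   geom_hline geom_vline labs
#' @export
ggplot2::autoplot

#' Plot a travelling-wave profile
#'
#' @param object An `fbw_profile` from [assemble_wave()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fbw_profile
#' @export
autoplot.fbw_profile <- function(object, ...) {
  reg <- sign_regime(attr(object, "model", exact = TRUE))
  ggplot(object, aes(x = .data$z, y = .data$u)) +
    geom_hline(yintercept = c(reg$alpha, reg$beta), linetype = "dotted", colour = "grey50") +
    geom_line() +
    labs(x = "z = x - ct", y = "u",
         title = sprintf("Travelling wave, c = %.4g", attr(object, "c", exact = TRUE)))
}

#' Plot a phase-plane orbit
#'
#' @param object An `fbw_orbit` from [shoot_manifold()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fbw_orbit
#' @export
autoplot.fbw_orbit <- function(object, ...) {
  model <- attr(object, "model", exact = TRUE)
  reg <- sign_regime(model)
  ggplot(object, aes(x = .data$u, y = .data$p)) +
    geom_vline(xintercept = c(reg$alpha, reg$beta), linetype = "dashed", colour = "grey50") +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_path() +
    labs(x = "u", y = "p = D(u) du/dz",
         title = sprintf("Orbit %s -> %s, c = %.4g",
                         attr(object, "origin", exact = TRUE),
                         attr(object, "target", exact = TRUE),
                         attr(object, "c", exact = TRUE)))
}

#' Plot a leading-edge track
#'
#' @param object An `fbw_front_track` (`t`, `L`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fbw_front_track
#' @export
autoplot.fbw_front_track <- function(object, ...) {
  ggplot(object, aes(x = .data$t, y = .data$L)) +
    geom_line() +
    labs(x = "t", y = "L(t)", title = "Leading-edge position")
}

#' Plot PDE snapshots
#'
#' @param object An `fbw_sim` from [pde_simulate()].
#' @param times Snapshot times to draw (nearest recorded); default 5 evenly
#'   spaced.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fbw_sim
#' @export
autoplot.fbw_sim <- function(object, times = NULL, ...) {
  snaps <- object$snapshots
  av <- unique(snaps$t)
  if (is.null(times)) times <- av[round(seq(1, length(av), length.out = 5))]
  sel <- snaps[snaps$t %in% vapply(times, function(t) av[which.min(abs(av - t))],
                                   numeric(1)), ]
  ggplot(sel, aes(x = .data$x, y = .data$u, group = .data$t, colour = factor(.data$t))) +
    geom_line() +
    labs(x = "x", y = "U(x, t)", colour = "t")
}

#' Plot dispersion curves and absolute-spectrum bounds
#'
#' @param object An `fbw_spectrum` from [classify_stability()].
#' @param model The model the report was computed from.
#' @param k Spatial frequencies to trace.
#' @param ... Unused.
#' @return A ggplot of the two dispersion parabolas with the rightmost
#'   absolute-spectrum points marked.
#' @method autoplot fbw_spectrum
#' @export
autoplot.fbw_spectrum <- function(object, model, k = seq(-3, 3, length.out = 301), ...) {
  dp <- dispersion_curve(asymptotic_end(model, "plus"), object$c, k)
  dm <- dispersion_curve(asymptotic_end(model, "minus"), object$c, k)
  curves <- dplyr::bind_rows(
    dplyr::mutate(dp[c("re", "im")], end = "+inf"),
    dplyr::mutate(dm[c("re", "im")], end = "-inf")
  )
  pts <- tibble::tibble(re = c(object$k_plus, object$k_minus), im = 0,
                        what = c("K+", "K-"))
  ggplot(curves, aes(x = .data$re, y = .data$im)) +
    geom_path(aes(linetype = .data$end)) +
    geom_vline(xintercept = 0, colour = "grey60") +
    geom_point(data = pts, colour = "red") +
    labs(x = "Re", y = "Im",
         title = sprintf("Essential spectrum boundary, c = %.4g (%s)",
                         object$c, object$verdict))
}
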