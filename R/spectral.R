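# Far-field spectral analysis of the desingularised linearisation.
#
# Linearising about the wave and writing the eigenvalue problem as a first
# order system in (q, s) with s = d(D(u_hat) q)/dz, the essential and
# absolute spectra are fixed by the constant-coefficient asymptotic systems
# at z -> +inf (state 0) and z -> -inf (state 1), where D > 0 at both ends.

#' Asymptotic end data
#'
#' The limiting diffusivity and kinetic slope at one end of the wave:
#' `D(0)`, `R'(0) = lambda` at plus infinity (leading edge), `D(1)`,
#' `R'(1) = -lambda` at minus infinity (invaded bulk).
#'
#' @param model An [fbw_model()].
#' @param end `"plus"` or `"minus"`.
#' @return A list with `end`, `d_value`, `r_prime`.
#' @export
asymptotic_end <- function(model, end = c("plus", "minus")) {
  end <- match.arg(end)
  u0 <- if (end == "plus") 0 else 1
  list(end = end, d_value = diffusivity_at(model, u0),
       r_prime = kinetic_deriv_at(model, u0))
}

#' Spatial eigenvalues of an asymptotic matrix
#'
#' The two spatial roots
#' \eqn{\mu^\pm = (-c \pm \sqrt{c^2 + 4 D (\Lambda - R')})/2}
#' (principal square root) of the constant-coefficient system at one end.
#'
#' @param end An [asymptotic_end()].
#' @param c Wave speed.
#' @param Lambda Complex temporal eigenvalue parameter.
#' @return A complex vector `c(mu_plus, mu_minus)`.
#' @export
spatial_eigenvalues <- function(end, c, Lambda) {
  s <- sqrt(as.complex(c^2 + 4 * end$d_value * (Lambda - end$r_prime)))
  c((-c + s) / 2, (-c - s) / 2)
}

#' Dispersion relation of one end
#'
#' The boundary of the unweighted essential spectrum contributed by one end:
#' the parabola \eqn{\Lambda(k) = -D k^2 + i c k + R'} traced over real
#' spatial frequencies `k`.
#'
#' @inheritParams spatial_eigenvalues
#' @param k Real spatial frequencies.
#' @return A tibble with `k`, `re`, `im` (and complex `Lambda`).
#' @export
dispersion_curve <- function(end, c, k) {
  Lambda <- -end$d_value * k^2 + 1i * c * k + end$r_prime
  tibble::tibble(k = k, re = Re(Lambda), im = Im(Lambda), Lambda = Lambda)
}

#' Rightmost points of the absolute spectrum
#'
#' The absolute spectrum at each end is the real half-line where the two
#' spatial eigenvalues share real part `-c/2`; its rightmost points are
#' \deqn{K_+ = -c^2 / (4 D(0)) + R'(0), \qquad K_- = -c^2 / (4 D(1)) + R'(1).}
#' `K_-` is always negative; `K_+` crosses zero exactly at `c = c*`.
#'
#' @param model An [fbw_model()].
#' @param c Wave speed.
#' @return A list with `k_plus`, `k_minus`.
#' @export
absolute_spectrum_bounds <- function(model, c) {
  ep <- asymptotic_end(model, "plus")
  em <- asymptotic_end(model, "minus")
  if (ep$d_value <= 0 || em$d_value <= 0) {
    abort("absolute spectrum bounds require D > 0 at both end states")
  }
  list(k_plus = -c^2 / (4 * ep$d_value) + ep$r_prime,
       k_minus = -c^2 / (4 * em$d_value) + em$r_prime)
}

#' Weighted essential-spectrum intersections with the real axis
#'
#' In the one-sided exponentially weighted space with rate `nu`, the two
#' dispersion parabolas intersect the real axis at
#' \deqn{K_\pm^\nu = D \nu^2 - c \nu + R'} (evaluated with each end's `D`
#' and `R'`).  At `nu = 0` these reduce to the unweighted intersections
#' `R'(0) = lambda > 0` and `R'(1) = -lambda`.
#'
#' @inheritParams absolute_spectrum_bounds
#' @param nu Weight rate(s).
#' @return A tibble with `nu`, `k_plus_nu`, `k_minus_nu`.
#' @export
weighted_intersections <- function(model, c, nu) {
  ep <- asymptotic_end(model, "plus")
  em <- asymptotic_end(model, "minus")
  tibble::tibble(
    nu = nu,
    k_plus_nu = ep$d_value * nu^2 - c * nu + ep$r_prime,
    k_minus_nu = em$d_value * nu^2 - c * nu + em$r_prime
  )
}

#' Ideal one-sided weight
#'
#' The weight `nu = c / (2 D(0))` minimising `K_+^nu`; the minimum equals
#' `K_+`, the rightmost point of the absolute spectrum at plus infinity, so
#' no weight can do better.
#'
#' @inheritParams absolute_spectrum_bounds
#' @export
ideal_weight <- function(model, c) {
  d0 <- diffusivity_at(model, 0)
  if (d0 <= 0) abort("ideal weight requires D(0) > 0")
  c / (2 * d0)
}

#' Admissible weight interval
#'
#' The open interval of weights `nu` with `K_+^nu < 0`, i.e. the root
#' interval of the quadratic `D(0) nu^2 - c nu + R'(0)`:
#' \deqn{\nu \in \left(\frac{c - \sqrt{c^2 - (c^*)^2}}{2 D(0)},
#'                     \frac{c + \sqrt{c^2 - (c^*)^2}}{2 D(0)}\right)}
#' for `c > c*`; degenerate (empty interior, the single point
#' `c/(2 D(0))`) at `c = c*`; empty for `c < c*`.
#'
#' @inheritParams absolute_spectrum_bounds
#' @return A numeric vector `c(lower, upper)`, or `NULL` when no weight
#'   achieves a negative intersection.
#' @export
admissible_weight_interval <- function(model, c) {
  d0 <- diffusivity_at(model, 0)
  r0 <- kinetic_deriv_at(model, 0)
  disc <- c^2 - 4 * d0 * r0
  # a relative tolerance keeps c computed as 2 sqrt(D(0) R'(0)) on the
  # degenerate (double-root) branch despite rounding
  if (disc < -1e-12 * max(1, c^2)) return(NULL)
  disc <- max(disc, 0)
  c((c - sqrt(disc)) / (2 * d0), (c + sqrt(disc)) / (2 * d0))
}

#' Classify spectral stability at a given speed
#'
#' Assembles the spectrum report: the wave is `absolutely_unstable` when
#' `K_+ > 0` (equivalently `c < c*`): parts of the absolute spectrum lie in
#' the right half plane and no exponential weight can stabilise the
#' essential spectrum.  For `c >= c*` it is `weight_stabilisable`: the
#' absolute spectrum is confined to the closed left half plane and weights
#' in the admissible interval shift the essential spectrum there too.
#'
#' @inheritParams absolute_spectrum_bounds
#' @return An `fbw_spectrum` list: `c`, `k_plus`, `k_minus`, `ideal_weight`,
#'   `weight_interval`, `verdict`.
#' @export
classify_stability <- function(model, c) {
  if (c <= 0) abort("classify_stability requires c > 0")
  b <- absolute_spectrum_bounds(model, c)
  structure(
    list(
      c = c, k_plus = b$k_plus, k_minus = b$k_minus,
      ideal_weight = ideal_weight(model, c),
      weight_interval = admissible_weight_interval(model, c),
      verdict = if (b$k_plus > 1e-12 * max(1, c^2)) "absolutely_unstable"
                else "weight_stabilisable"
    ),
    class = "fbw_spectrum"
  )
}

#' @export
print.fbw_spectrum <- function(x, ...) {
  cat(sprintf("<fbw_spectrum> c = %g: %s\n", x$c, x$verdict))
  cat(sprintf("  K+ = %.6g, K- = %.6g, ideal weight = %.6g\n",
              x$k_plus, x$k_minus, x$ideal_weight))
  if (!is.null(x$weight_interval)) {
    cat(sprintf("  admissible weights: (%.6g, %.6g)\n",
                x$weight_interval[1], x$weight_interval[2]))
  } else {
    cat("  admissible weights: none\n")
  }
  invisible(x)
}

#' Linearised eigenvalue system along the wave
#'
#' `eigenproblem_matrix()` evaluates the coefficient matrix
#' \deqn{A(z; \Lambda) = \begin{pmatrix} -B & 1 \\
#'   c B + D(\hat u)(\Lambda - R'(\hat u)) & -c \end{pmatrix}},
#' with \eqn{B = D'(\hat u)\, d\hat u/dz} evaluated through the orbit's
#' `p`-component (`du/dz = p / D(u)`, finite at the holes).
#' `eigenproblem_rhs()` applies it to a perturbation state `(q, s)`, giving
#' the stretched-variable derivative.  `theta_rate()` is the winding rate of
#' the (q, s) line used in the Sturm count of the point spectrum; at a
#' vertical crossing (`q = 0`) it equals 1 independently of `Lambda`.
#'
#' @param u,dudz Wave value and slope at the evaluation point (rows of an
#'   [assemble_wave()] profile).
#' @param model An [fbw_model()].
#' @param c Wave speed.
#' @param Lambda Complex temporal eigenvalue parameter.
#' @param q,s Perturbation state.
#' @return `eigenproblem_matrix()`: a 2x2 matrix; `eigenproblem_rhs()`: a
#'   length-2 vector; `theta_rate()`: a scalar.
#' @export
eigenproblem_matrix <- function(u, dudz, model, c, Lambda) {
  if (is.na(dudz)) abort("wave slope (dudz) missing at the evaluation point")
  B <- diffusivity_deriv_at(model, u) * dudz
  d <- diffusivity_at(model, u)
  matrix(c(-B, c * B + d * (Lambda - kinetic_deriv_at(model, u)),
           1, -c),
         nrow = 2)
}

#' @rdname eigenproblem_matrix
#' @export
eigenproblem_rhs <- function(q, s, u, dudz, model, c, Lambda) {
  as.vector(eigenproblem_matrix(u, dudz, model, c, Lambda) %*% c(q, s))
}

#' @rdname eigenproblem_matrix
#' @export
theta_rate <- function(q, s, u, dudz, model, c, Lambda) {
  d <- eigenproblem_rhs(q, s, u, dudz, model, c, Lambda)
  Re((s * d[1] - q * d[2]) / (q^2 + s^2))
}
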