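#' Two-rate nonlinear diffusivity
#'
#' The diffusivity arising in the continuum limit of a lattice exclusion
#' process with distinct isolated and grouped agents,
#' \deqn{D(U) = D_i (1 - 4U + 3U^2) + D_g (4U - 3U^2),}
#' so that `D(0) = d_i` (isolated agents set the diffusivity at the leading
#' edge) and `D(1) = d_g` (grouped agents set it in the bulk).  For
#' `d_i > 4 d_g` the quadratic is convex and changes sign twice on (0, 1),
#' making the equation locally backward-parabolic on the inner interval.
#'
#' @param d_i Nonnegative diffusivity of isolated agents (length^2/time).
#' @param d_g Nonnegative diffusivity of grouped agents.
#' @return An object of class `fbw_diffusivity`.
#' @examples
#' D <- two_rate_diffusivity(0.25, 0.05)
#' diffusivity_at(D, c(0, 0.5, 1))
#' @export
two_rate_diffusivity <- function(d_i, d_g) {
  stopifnot(is.numeric(d_i), is.numeric(d_g), length(d_i) == 1L, length(d_g) == 1L)
  if (d_i < 0 || d_g < 0) abort("diffusivities must be nonnegative")
  structure(
    list(coef = c(d_i, 4 * (d_g - d_i), 3 * (d_i - d_g)), d_i = d_i, d_g = d_g),
    class = c("fbw_two_rate", "fbw_diffusivity")
  )
}

#' General polynomial diffusivity
#'
#' A diffusivity given directly by polynomial coefficients, used e.g. for the
#' shock-supporting quadratic \eqn{\hat D(U) = (U - 0.1)(U - 0.3)}.
#'
#' @param coef Polynomial coefficients in ascending order of power of `u`.
#' @return An object of class `fbw_diffusivity`.
#' @examples
#' # (u - 0.1)(u - 0.3) = 0.03 - 0.4 u + u^2
#' Dhat <- polynomial_diffusivity(c(0.03, -0.4, 1))
#' @export
polynomial_diffusivity <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) >= 1L)
  structure(list(coef = as.numeric(coef)), class = c("fbw_poly", "fbw_diffusivity"))
}

#' Logistic kinetics
#'
#' The logistic source term \eqn{R(U) = \lambda U (1 - U)}, the special case
#' of the general kinetics with equal proliferation rates and no death.
#'
#' @param lambda Nonnegative proliferation rate (1/time).
#' @return An object of class `fbw_kinetic`.
#' @export
logistic_kinetic <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (lambda < 0) abort("proliferation rate must be nonnegative")
  structure(
    list(coef = c(0, lambda, -lambda), lambda = lambda),
    class = c("fbw_logistic", "fbw_kinetic")
  )
}

#' General kinetics with distinct isolated/grouped rates
#'
#' The full kinetic term of the continuum limit,
#' \deqn{R(U) = \lambda_g U(1-U) + (\lambda_i - \lambda_g - K_i + K_g) U (1-U)^2 - K_g U,}
#' where `lambda_i`, `lambda_g` are proliferation rates and `k_i`, `k_g` death
#' rates of isolated and grouped agents.  With `lambda_i = lambda_g` and zero
#' death rates it reduces to [logistic_kinetic()].
#'
#' @param lambda_i,lambda_g Proliferation rates (1/time).
#' @param k_i,k_g Death rates (1/time).
#' @return An object of class `fbw_kinetic`.
#' @export
general_kinetic <- function(lambda_i, lambda_g, k_i = 0, k_g = 0) {
  stopifnot(all(vapply(list(lambda_i, lambda_g, k_i, k_g), is.numeric, TRUE)))
  if (any(c(lambda_i, lambda_g, k_i, k_g) < 0)) abort("rates must be nonnegative")
  a <- lambda_i - lambda_g - k_i + k_g
  structure(
    list(
      coef = c(0, lambda_g + a - k_g, -lambda_g - 2 * a, a),
      lambda_i = lambda_i, lambda_g = lambda_g, k_i = k_i, k_g = k_g
    ),
    class = c("fbw_general", "fbw_kinetic")
  )
}

#' Reaction-diffusion model specification
#'
#' Bundles a nonlinear diffusivity and a kinetic term into the model
#' \deqn{U_t = (D(U) U_x)_x + R(U).}
#'
#' @param diffusivity An `fbw_diffusivity`, e.g. [two_rate_diffusivity()].
#' @param kinetic An `fbw_kinetic`, e.g. [logistic_kinetic()].
#' @return An object of class `fbw_model`.
#' @examples
#' m <- fbw_model(two_rate_diffusivity(0.25, 0.05), logistic_kinetic(0.75))
#' min_wave_speed(m)
#' @export
fbw_model <- function(diffusivity, kinetic) {
  stopifnot(inherits(diffusivity, "fbw_diffusivity"), inherits(kinetic, "fbw_kinetic"))
  structure(list(D = diffusivity, R = kinetic), class = "fbw_model")
}

#' @export
print.fbw_model <- function(x, ...) {
  cat("<fbw_model>\n")
  if (inherits(x$D, "fbw_two_rate")) {
    cat(sprintf("  D(u): two-rate, d_i = %g, d_g = %g\n", x$D$d_i, x$D$d_g))
  } else {
    cat("  D(u): polynomial, coef =", paste(signif(x$D$coef, 6), collapse = ", "), "\n")
  }
  if (inherits(x$R, "fbw_logistic")) {
    cat(sprintf("  R(u): logistic, lambda = %g\n", x$R$lambda))
  } else {
    cat("  R(u): general, coef =", paste(signif(x$R$coef, 6), collapse = ", "), "\n")
  }
  reg <- sign_regime(x)
  cat(sprintf("  sign regime: %s", reg$label))
  if (!is.na(reg$alpha)) cat(sprintf(" (alpha = %.6g, beta = %.6g)", reg$alpha, reg$beta))
  cat("\n")
  invisible(x)
}

as_diffusivity <- function(x) {
  if (inherits(x, "fbw_model")) x$D
  else if (inherits(x, "fbw_diffusivity")) x
  else abort("expected an fbw_model or fbw_diffusivity")
}

as_kinetic <- function(x) {
  if (inherits(x, "fbw_model")) x$R
  else if (inherits(x, "fbw_kinetic")) x
  else abort("expected an fbw_model or fbw_kinetic")
}

#' Evaluate model functions
#'
#' Pointwise evaluation of the diffusivity \eqn{D(u)}, the kinetics
#' \eqn{R(u)}, their exact polynomial derivatives, and the flux derivative
#' \eqn{F(u) = d(D R)/du = D'(u) R(u) + D(u) R'(u)}, the quantity entering
#' the phase-plane Jacobian.  Arguments `u` outside \\[0, 1\\] are evaluated
#' as-is (solvers may overshoot); no clamping is performed.
#'
#' @param x An `fbw_model`, or the relevant component for the single-function
#'   evaluators.
#' @param u Density values.
#' @return A numeric vector the length of `u`.
#' @export
diffusivity_at <- function(x, u) poly_eval(as_diffusivity(x)$coef, u)

#' @rdname diffusivity_at
#' @export
diffusivity_deriv_at <- function(x, u) poly_eval(poly_deriv(as_diffusivity(x)$coef), u)

#' @rdname diffusivity_at
#' @export
kinetic_at <- function(x, u) poly_eval(as_kinetic(x)$coef, u)

#' @rdname diffusivity_at
#' @export
kinetic_deriv_at <- function(x, u) poly_eval(poly_deriv(as_kinetic(x)$coef), u)

#' @rdname diffusivity_at
#' @export
flux_deriv_at <- function(x, u) {
  dr <- poly_mult(as_diffusivity(x)$coef, as_kinetic(x)$coef)
  poly_eval(poly_deriv(dr), u)
}

#' Sign regime of the diffusivity
#'
#' Locates the roots of \eqn{D(u)} on \\[0, 1\\] and classifies the model:
#' `"sign_changing"` when D has two distinct roots `alpha < beta` there (the
#' backward-diffusion interval is `(alpha, beta)`), `"degenerate"` when the
#' roots coincide (for the two-rate family exactly at `d_i = 4 d_g`, where
#' `alpha = beta = 2/3`), and `"positive_definite"` otherwise.  For the
#' two-rate family the roots are the closed forms
#' \deqn{\alpha,\beta = \frac{2}{3} \mp \frac{\sqrt{D_i^2 + 4 D_g^2 - 5 D_i D_g}}{3 (D_i - D_g)},}
#' which satisfy `1/3 < alpha < 2/3 < beta < 1`.
#'
#' @param x An `fbw_model` or `fbw_diffusivity`.
#' @return A list with elements `label`, `alpha`, `beta` (roots are `NA` for
#'   the positive-definite case).
#' @examples
#' sign_regime(two_rate_diffusivity(0.25, 0.05)) # alpha = 0.5, beta = 5/6
#' @export
sign_regime <- function(x) {
  D <- as_diffusivity(x)
  out <- function(label, alpha = NA_real_, beta = NA_real_) {
    structure(list(label = label, alpha = alpha, beta = beta), class = "fbw_sign_regime")
  }
  if (inherits(D, "fbw_two_rate")) {
    if (D$d_i > 4 * D$d_g) {
      s <- sqrt(D$d_i^2 + 4 * D$d_g^2 - 5 * D$d_i * D$d_g) / (3 * (D$d_i - D$d_g))
      return(out("sign_changing", 2 / 3 - s, 2 / 3 + s))
    }
    if (D$d_i == 4 * D$d_g && D$d_i > 0) return(out("degenerate", 2 / 3, 2 / 3))
    return(out("positive_definite"))
  }
  r <- poly_real_roots(D$coef, 0, 1)
  if (length(r) >= 2L && diff(range(r[1:2])) > 1e-10) {
    return(out("sign_changing", r[1L], r[2L]))
  }
  if (length(r) >= 1L) return(out("degenerate", r[1L], r[1L]))
  out("positive_definite")
}

#' Minimum wave speed
#'
#' The minimum speed \eqn{c^* = 2\sqrt{D(0) R'(0)}} admitting smooth monotone
#' nonnegative travelling waves; for the two-rate diffusivity with logistic
#' kinetics this is \eqn{2\sqrt{\lambda D_i}}, set by the isolated-agent
#' diffusivity alone.  For general sign-changing diffusivities the value is
#' the linear-spreading (node) threshold at the origin; no minimality claim
#' is made beyond the two-rate family.
#'
#' @param x An `fbw_model`.
#' @return The speed `c*`.
#' @export
min_wave_speed <- function(x) {
  d0 <- diffusivity_at(x, 0)
  r0 <- kinetic_deriv_at(x, 0)
  if (d0 <= 0) abort("min_wave_speed requires D(0) > 0")
  if (r0 <= 0) abort("min_wave_speed requires R'(0) > 0 (monostable kinetics)")
  2 * sqrt(d0 * r0)
}

#' Node-to-spiral threshold at the upper root
#'
#' The speed \eqn{2\sqrt{D'(\beta) R(\beta)}} below which the equilibrium at
#' the upper diffusivity root `beta` turns from a stable node into a stable
#' spiral in the desingularised phase plane, closing the hole in the wall to
#' smooth fronts.  For the two-rate family this threshold always lies below
#' `c*`.
#'
#' @param x An `fbw_model` with a sign-changing (or degenerate) diffusivity.
#' @return The threshold speed.
#' @export
beta_node_threshold <- function(x) {
  reg <- sign_regime(x)
  if (is.na(reg$beta)) abort("diffusivity has no upper root in (0, 1)")
  dbeta <- diffusivity_deriv_at(x, reg$beta)
  if (dbeta <= 0) abort("upper root must have D'(beta) > 0")
  2 * sqrt(dbeta * kinetic_at(x, reg$beta))
}

#' Wave speed bounds for positive diffusivity
#'
#' For strictly positive \eqn{D(u)} on \\[0, 1\\] (two-rate case `d_i < 4 d_g`)
#' the minimum wave speed is only known to lie between
#' \eqn{S_2 = 2\sqrt{D(0) R'(0)}} (node condition at the origin) and
#' \eqn{S_1 = \sup_{u \in (0,1)} 2\sqrt{D(u) R(u) / u}} (invariant-region
#' sufficient condition).  The supremum is located on a dense grid and then
#' polished by golden-section search.
#'
#' @param x An `fbw_model` with positive-definite diffusivity.
#' @param n_grid Number of grid points seeding the supremum search.
#' @return A list with `s2`, `s1` and `u_max`, the maximising density.
#' @export
speed_bounds_positive <- function(x, n_grid = 1e4) {
  reg <- sign_regime(x)
  if (reg$label == "sign_changing") {
    abort("speed bounds require a positive-definite diffusivity (d_i < 4 d_g)")
  }
  s2 <- min_wave_speed(x)
  # g(u) = D(u) R(u) / u, extended continuously to u = 0 by D(0) R'(0)
  g <- function(u) {
    ifelse(u <= 0, diffusivity_at(x, 0) * kinetic_deriv_at(x, 0),
           diffusivity_at(x, u) * kinetic_at(x, u) / u)
  }
  u <- seq(0, 1, length.out = n_grid)
  vals <- g(u)
  i <- which.max(vals)
  lo <- u[max(1L, i - 1L)]
  hi <- u[min(n_grid, i + 1L)]
  if (lo < hi) {
    opt <- optimize(g, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
    if (opt$objective >= vals[i]) {
      u_max <- opt$maximum
      best <- opt$objective
    } else {
      u_max <- u[i]; best <- vals[i]
    }
  } else {
    u_max <- u[i]; best <- vals[i]
  }
  list(s2 = s2, s1 = max(2 * sqrt(best), s2), u_max = u_max)
}

#' Read and write model configurations
#'
#' Plain-text YAML serialisation of a model: either `d_i`/`d_g` or
#' `poly_coef` for the diffusivity, and either `lam` or
#' `lam_i`/`lam_g`/`k_i`/`k_g` for the kinetics.
#'
#' @param x An `fbw_model`.
#' @param path File path.
#' @return `read_model_config()` returns an `fbw_model`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(x, path) {
  stopifnot(inherits(x, "fbw_model"))
  cfg <- list()
  if (inherits(x$D, "fbw_two_rate")) {
    cfg$d_i <- x$D$d_i; cfg$d_g <- x$D$d_g
  } else {
    cfg$poly_coef <- x$D$coef
  }
  if (inherits(x$R, "fbw_logistic")) {
    cfg$lam <- x$R$lambda
  } else {
    cfg$lam_i <- x$R$lambda_i; cfg$lam_g <- x$R$lambda_g
    cfg$k_i <- x$R$k_i; cfg$k_g <- x$R$k_g
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  D <- if (!is.null(cfg$poly_coef)) {
    polynomial_diffusivity(unlist(cfg$poly_coef))
  } else {
    two_rate_diffusivity(cfg$d_i, cfg$d_g)
  }
  R <- if (!is.null(cfg$lam)) {
    logistic_kinetic(cfg$lam)
  } else {
    general_kinetic(cfg$lam_i, cfg$lam_g, cfg$k_i %||% 0, cfg$k_g %||% 0)
  }
  fbw_model(D, R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
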