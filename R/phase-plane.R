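# Phase-plane construction of the travelling wave.
#
# In the wave coordinate z = x - ct, with p = D(u) du/dz, the wave ODE is the
# singular planar system
#     D(u) du/dz = p,   D(u) dp/dz = -c p - D(u) R(u),
# undefined along the walls u = alpha, u = beta where D vanishes.  The
# stretched variable xi with D(u) dxi = dz removes the walls:
#     du/dxi = p,       dp/dxi = -c p - D(u) R(u),
# at the price of reversing orientation wherever D(u) < 0.  The wave is a
# concatenation of three heteroclinic orbits of the desingularised system,
# passing through the holes in the wall (alpha, 0) and (beta, 0).

#' Right-hand sides of the travelling-wave systems
#'
#' `desingularised_rhs()` evaluates the regular (stretched-variable) system
#' `(du/dxi, dp/dxi) = (p, -c p - D(u) R(u))`.  `singular_rhs()` evaluates the
#' original z-parametrised system, which divides by `D(u)` and is therefore
#' only defined away from the walls; it is used for cross-checks.
#'
#' @param u,p Phase-plane coordinates (`p = D(u) du/dz`).
#' @param model An [fbw_model()].
#' @param c Wave speed.
#' @param wall_tol Proximity threshold below which `singular_rhs()` refuses to
#'   divide by `D(u)`.
#' @return A numeric vector `c(du, dp)` (vectorised over `u`, `p` as columns
#'   if inputs have length > 1).
#' @export
desingularised_rhs <- function(u, p, model, c) {
  c(p, -c * p - diffusivity_at(model, u) * kinetic_at(model, u))
}

#' @rdname desingularised_rhs
#' @export
singular_rhs <- function(u, p, model, c, wall_tol = 1e-8) {
  d <- diffusivity_at(model, u)
  if (any(abs(d) < wall_tol)) {
    abort("singular system evaluated on (or too near) a wall of singularities")
  }
  c(p / d, (-c * p - d * kinetic_at(model, u)) / d)
}

#' Equilibria of the desingularised system
#'
#' The four equilibria (0,0), (alpha,0), (beta,0), (1,0) with their Jacobian
#' eigen-data.  The Jacobian is `[[0, 1], [-F(u), -c]]` with
#' `F(u) = (D R)'(u)`, so the eigenvalues are
#' \eqn{\lambda_\pm = (-c \pm \sqrt{c^2 - 4 F(u)})/2} with eigenvectors
#' \eqn{(1, \lambda_\pm)}.  (1,0) and (alpha,0) are saddles; (0,0) is a
#' stable node iff `c >= c*`; (beta,0) is a stable node iff
#' `c >= 2 sqrt(D'(beta) R(beta))`, and a stable spiral otherwise.
#'
#' @inheritParams desingularised_rhs
#' @return A tibble with one row per equilibrium: `name`, `u`, `F` (flux
#'   derivative), complex `lambda_plus`, `lambda_minus`, and
#'   `classification` in `saddle`, `stable_node`, `stable_spiral`.
#' @export
find_equilibria <- function(model, c) {
  reg <- sign_regime(model)
  if (reg$label != "sign_changing") {
    abort("find_equilibria requires a sign-changing diffusivity")
  }
  us <- c(0, reg$alpha, reg$beta, 1)
  nm <- c("origin", "alpha", "beta", "one")
  f <- flux_deriv_at(model, us)
  disc <- c^2 - 4 * f
  # a relative tolerance keeps the threshold cases (disc = 0 up to rounding,
  # e.g. c computed as 2 sqrt(F)) classified as nodes
  is_real <- disc >= -1e-12 * pmax(1, c^2, abs(4 * f))
  sq <- ifelse(is_real, sqrt(pmax(disc, 0)), NA_real_)
  lp <- ifelse(is_real, as.complex((-c + sq) / 2),
               complex(real = -c / 2, imaginary = sqrt(pmax(-disc, 0)) / 2))
  lmn <- ifelse(is_real, as.complex((-c - sq) / 2),
                complex(real = -c / 2, imaginary = -sqrt(pmax(-disc, 0)) / 2))
  cls <- ifelse(f < 0, "saddle", ifelse(is_real, "stable_node", "stable_spiral"))
  tibble::tibble(
    name = nm, u = us, F = f,
    lambda_plus = lp, lambda_minus = lmn,
    classification = cls
  )
}

#' Eigenvector-vs-nullcline slope ordering at an equilibrium
#'
#' At each equilibrium the relevant eigenvector slope must lie below the
#' slope `chi(u) = -F(u)/c` of the nontrivial nullcline
#' `p = -D(u) R(u) / c` for the invariant-region construction to close.
#' Returns `TRUE` when `lambda_+ - chi(u) < 0` at the named point.
#'
#' @inheritParams desingularised_rhs
#' @param point One of `"one"`, `"alpha"`, `"origin"`, `"beta"`.
#' @export
check_slope_ordering <- function(model, c, point = c("one", "alpha", "origin", "beta")) {
  point <- match.arg(point)
  eq <- find_equilibria(model, c)
  row <- eq[eq$name == point, ]
  if (row$classification == "stable_spiral") {
    abort("slope ordering undefined for complex eigenvalues (spiral point)")
  }
  lam <- Re(row$lambda_plus)
  chi <- -row$F / c
  (lam - chi) < 0
}

#' Verify an invariant phase-plane region
#'
#' The existence proof confines trajectories in wedge regions bounded by
#' `p = 0`, a wall, and a line of slope `mu < 0` through an anchor (the
#' origin for region R1; `(beta, 0)` for R2/R3).  The line is non-crossed iff
#' \deqn{\mu(\mu + c) \le -D(u) R(u) / (u - u_0)} on the region's
#' `u`-interval ((0, alpha) for R1, (alpha, 1) for R2/R3).  With the optimal
#' slope `mu = -c/2` this holds exactly when `c >= c*`.
#'
#' @inheritParams desingularised_rhs
#' @param region `"R1"` or `"R2"` (R3 shares the R2 inequality).
#' @param mu Line slope; default `-c/2`, the minimiser of the left side.
#' @param n Number of sample points.
#' @return `TRUE` if the inequality holds at every sampled `u`.
#' @export
verify_invariant_region <- function(model, c, region = c("R1", "R2"), mu = -c / 2,
                                    n = 1000) {
  region <- match.arg(region)
  reg <- sign_regime(model)
  if (is.na(reg$alpha)) abort("invariant regions require a sign-changing diffusivity")
  if (mu >= 0) abort("region boundary slope must be negative")
  if (region == "R1") {
    u <- seq(1e-9, reg$alpha - 1e-9, length.out = n)
    rhs <- -diffusivity_at(model, u) * kinetic_at(model, u) / u
  } else {
    u <- seq(reg$alpha + 1e-9, 1 - 1e-9, length.out = n)
    rhs <- -diffusivity_at(model, u) * kinetic_at(model, u) / (u - reg$beta)
  }
  all(mu * (mu + c) <= rhs + 1e-12)
}

#' Shoot a heteroclinic orbit of the desingularised system
#'
#' Integrates the stretched-variable system from a point displaced by `eps`
#' along the unstable eigenvector of a saddle (the (1,0) and (alpha,0)
#' equilibria), in the direction of increasing or decreasing `u`, until the
#' trajectory enters a small ball around another equilibrium (success) or
#' leaves the strip `u` in \\[-0.1, 1.1\\] (failure).  Node targets use the
#' ball radius `tol_eq`; spiral targets a larger radius since the approach
#' winds.
#'
#' @inheritParams desingularised_rhs
#' @param from `"one"` or `"alpha"`: the saddle to leave.
#' @param direction `-1` to leave with decreasing `u`, `+1` with increasing.
#' @param eps Offset along the unit-normalised unstable eigenvector.
#' @param tol_eq Target-ball radius for node targets.
#' @param tol_spiral Target-ball radius for spiral targets.
#' @param dxi Output sampling interval in the stretched variable.
#' @param xi_max Maximum stretched-variable span before giving up.
#' @param rtol,atol Integrator tolerances (deSolve `lsodar`).
#' @return An `fbw_orbit`: a tibble with columns `xi`, `u`, `p` and
#'   attributes `origin`, `target`, `c`, `model`.
#' @export
shoot_manifold <- function(model, c, from = c("one", "alpha"), direction = -1,
                           eps = 1e-7, tol_eq = 1e-8, tol_spiral = 1e-6,
                           dxi = 0.05, xi_max = 5000, rtol = 1e-10, atol = 1e-12) {
  from <- match.arg(from)
  stopifnot(direction %in% c(-1, 1))
  eq <- find_equilibria(model, c)
  src <- eq[eq$name == from, ]
  if (src$classification != "saddle") abort("shooting must start from a saddle")
  lam <- Re(src$lambda_plus) # the positive (unstable) eigenvalue
  v <- c(1, lam) / sqrt(1 + lam^2)
  y0 <- c(u = src$u + direction * eps * v[1], p = direction * eps * v[2])

  targets <- eq[eq$name != from, ]
  radii <- ifelse(targets$classification == "stable_spiral", tol_spiral, tol_eq)
  rhs <- function(xi, y, parms) {
    list(c(y[2], -c * y[2] - diffusivity_at(model, y[1]) * kinetic_at(model, y[1])))
  }
  rootfun <- function(xi, y, parms) {
    d <- sqrt((y[1] - targets$u)^2 + y[2]^2) - radii
    c(d, y[1] - (-0.1), y[1] - 1.1)
  }
  times <- seq(0, xi_max, by = dxi)
  sol <- deSolve::lsodar(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                         rootfunc = rootfun, maxsteps = 50000)
  iroot <- attr(sol, "iroot")
  if (is.null(iroot) || all(iroot == 0)) {
    abort("orbit did not reach another equilibrium within the xi budget")
  }
  hit <- which(iroot != 0)
  if (any(hit > nrow(targets))) {
    abort("orbit left the phase-plane strip without connecting")
  }
  target <- targets$name[hit[1L]]
  orb <- tibble::tibble(xi = sol[, 1], u = sol[, 2], p = sol[, 3])
  structure(orb, class = c("fbw_orbit", class(orb)),
            origin = from, target = target, c = c, model = model)
}

orbit_attr <- function(orbit, what) attr(orbit, what, exact = TRUE)

#' Count vertical tangents along an orbit
#'
#' The number of interior crossings of `p` through zero, i.e. points where
#' the solution curve in the (u, p) phase portrait has a vertical tangent.
#' This count at `Lambda = 0` versus `Lambda >> 1` bounds the number of real
#' positive point eigenvalues (Sturm-type argument); for the assembled
#' monotone wave it is zero.  Endpoint samples within `endpoint_tol` of an
#' equilibrium are excluded: the holes are orbit endpoints, not interior
#' tangencies.
#'
#' @param orbit An `fbw_orbit` or any tibble with `u` and `p` columns.
#' @param endpoint_tol Radius used to trim equilibrium-adjacent samples.
#' @return Integer count of interior sign changes of `p`.
#' @export
count_vertical_tangents <- function(orbit, endpoint_tol = 1e-3) {
  p <- orbit$p
  n <- length(p)
  if (n < 3L) return(0L)
  # trim leading/trailing stretches where the orbit hugs its endpoints
  amp <- abs(p)
  keep <- which(amp > endpoint_tol * max(amp))
  if (length(keep) < 3L) return(0L)
  p <- p[min(keep):max(keep)]
  s <- sign(p)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Assemble the travelling wave profile from three heteroclinic orbits
#'
#' Shoots the three desingularised heteroclinics (1,0) -> (beta,0),
#' (alpha,0) -> (beta,0) and (alpha,0) -> (0,0), maps each back to the wave
#' coordinate by the quadrature `z = \int D(u) dxi`, reverses the middle
#' segment (where `D < 0` the stretched variable runs against `z`), bridges
#' the truncation gaps at the holes using the exact limiting slope
#' `du/dz -> lambda / D'(u)` there, and concatenates into a single profile
#' `u(z)` translated so that `u(0) = anchor_u`.
#'
#' For `c >= c*` the result is the smooth monotone nonnegative wave; for
#' `2 sqrt(D'(beta) R(beta)) < c < c*` assembly still succeeds but the tail
#' oscillates around zero (the origin is a spiral), reproducing the
#' biologically irrelevant non-monotone waves.
#'
#' @inheritParams desingularised_rhs
#' @param anchor_u Density value pinned to `z = 0`.  Defaults to `1/2`, or to
#'   `alpha/2` when `alpha <= 1/2`, so the anchor always lies strictly inside
#'   the lower (hole-to-origin) segment; the wave itself is
#'   translation-invariant, so the choice is purely presentational.
#' @param eps,tol_eq,tol_spiral,dxi,xi_max,rtol,atol Passed to
#'   [shoot_manifold()].
#' @return An `fbw_profile`: tibble with columns `z`, `u`, `p`, `dudz` and
#'   attributes `c`, `model`, `segments`.
#' @export
assemble_wave <- function(model, c, anchor_u = NULL,
                          eps = 1e-7, tol_eq = 1e-8, tol_spiral = 1e-6,
                          dxi = 0.05, xi_max = 5000, rtol = 1e-10, atol = 1e-12) {
  reg <- sign_regime(model)
  if (reg$label != "sign_changing") {
    abort("wave assembly requires a sign-changing diffusivity")
  }
  shoot <- function(from, direction) {
    shoot_manifold(model, c, from = from, direction = direction, eps = eps,
                   tol_eq = tol_eq, tol_spiral = tol_spiral, dxi = dxi,
                   xi_max = xi_max, rtol = rtol, atol = atol)
  }
  o1 <- shoot("one", -1)    # (1,0) -> (beta,0)
  o2 <- shoot("alpha", +1)  # (alpha,0) -> (beta,0), D < 0 along it
  o3 <- shoot("alpha", -1)  # (alpha,0) -> (0,0)
  if (orbit_attr(o1, "target") != "beta" || orbit_attr(o2, "target") != "beta") {
    abort("upper heteroclinics did not connect to (beta, 0)")
  }
  if (orbit_attr(o3, "target") != "origin") {
    abort("lower heteroclinic did not connect to (0, 0)")
  }

  eq <- find_equilibria(model, c)
  # limiting du/dz at a hole: along the eigendirection with eigenvalue lam,
  # p ~ lam (u - u0) while D ~ D'(u0) (u - u0), so du/dz = p/D -> lam/D'(u0)
  hole_slope <- function(name, lam_name) {
    row <- eq[eq$name == name, ]
    Re(row[[lam_name]]) / diffusivity_deriv_at(model, row$u)
  }
  # departures from (alpha,0) use the unstable eigenvalue; arrivals at
  # (beta,0) the slow stable one (lambda_plus, the least negative)
  s_alpha <- hole_slope("alpha", "lambda_plus")
  s_beta <- hole_slope("beta", "lambda_plus")

  seg_z <- function(orbit) pracma::cumtrapz(orbit$xi, diffusivity_at(model, orbit$u))[, 1]

  # segment A: (1,0) -> (beta,0); z increases with xi (D > 0)
  zA <- seg_z(o1)
  segA <- tibble::tibble(z = zA, u = o1$u, p = o1$p)
  # segment B: middle orbit reversed; D < 0 makes seg_z decreasing, so the
  # reversed sample order gives increasing z from (beta,0) down to (alpha,0)
  zB <- seg_z(o2)
  segB <- tibble::tibble(z = rev(zB), u = rev(o2$u), p = rev(o2$p))
  # segment C: (alpha,0) -> (0,0); D > 0
  zC <- seg_z(o3)
  segC <- tibble::tibble(z = zC, u = o3$u, p = o3$p)

  # stitch: shift each following segment so the small u-gap at the hole is
  # crossed at the exact limiting slope
  segB$z <- segB$z - segB$z[1] + tail(segA$z, 1) + (segB$u[1] - tail(segA$u, 1)) / s_beta
  segC$z <- segC$z - segC$z[1] + tail(segB$z, 1) + (segC$u[1] - tail(segB$u, 1)) / s_alpha

  prof <- dplyr::bind_rows(segA, segB, segC)
  if (any(diff(prof$z) <= 0)) {
    # guard against pathological stitching; keep strictly increasing z
    keep <- c(TRUE, diff(prof$z) > 0)
    prof <- prof[keep, ]
  }
  d <- diffusivity_at(model, prof$u)
  dudz <- ifelse(abs(d) > 1e-9, prof$p / d, NA_real_)
  # fill hole-adjacent points with the limiting slopes
  near_alpha <- abs(prof$u - reg$alpha) < 1e-4 & is.na(dudz)
  near_beta <- abs(prof$u - reg$beta) < 1e-4 & is.na(dudz)
  dudz[near_alpha] <- s_alpha
  dudz[near_beta] <- s_beta
  prof$dudz <- dudz

  if (is.null(anchor_u)) anchor_u <- if (reg$alpha <= 0.5) reg$alpha / 2 else 0.5
  if (anchor_u >= 1 || anchor_u <= 0) abort("anchor_u must lie in (0, 1)")
  # first downward crossing of anchor_u (profile may oscillate for c < c*)
  idx <- which(prof$u[-nrow(prof)] >= anchor_u & prof$u[-1] < anchor_u)[1]
  if (is.na(idx)) abort("anchor level not crossed by the assembled profile")
  z0 <- approx(prof$u[c(idx, idx + 1L)], prof$z[c(idx, idx + 1L)], xout = anchor_u)$y
  prof$z <- prof$z - z0

  structure(prof, class = c("fbw_profile", class(prof)),
            c = c, model = model,
            segments = list(one_beta = o1, alpha_beta = o2, alpha_origin = o3))
}

#' Residual of the wave ODE along a profile
#'
#' Evaluates `d/dz(D(u) du/dz) + c du/dz + R(u)` along an assembled profile
#' by centred finite differences of `p = D(u) du/dz` in `z`.  Used to
#' validate the assembly a posteriori; away from the holes the residual of a
#' correctly assembled wave is at the finite-difference noise level.
#'
#' @param profile An `fbw_profile` from [assemble_wave()].
#' @param exclude_radius Half-width in `u` around each hole to flag.
#' @return A tibble `z`, `u`, `residual`, `near_hole`.
#' @export
wave_residual <- function(profile, exclude_radius = 0.02) {
  model <- attr(profile, "model", exact = TRUE)
  c <- attr(profile, "c", exact = TRUE)
  reg <- sign_regime(model)
  z <- profile$z; u <- profile$u; p <- profile$p
  n <- length(z)
  i <- 2:(n - 1)
  dpdz <- (p[i + 1] - p[i - 1]) / (z[i + 1] - z[i - 1])
  res <- dpdz + c * profile$dudz[i] + kinetic_at(model, u[i])
  near <- abs(u[i] - reg$alpha) < exclude_radius | abs(u[i] - reg$beta) < exclude_radius
  tibble::tibble(z = z[i], u = u[i], residual = res, near_hole = near)
}
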