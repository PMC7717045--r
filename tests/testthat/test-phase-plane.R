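test_that("desingularised and singular right-hand sides are consistent", {
  m <- benchmark_model()
  cc <- 0.866
  # equilibrium at the hole (alpha, 0)
  expect_equal(desingularised_rhs(0.5, 0, m, cc), c(0, 0))
  # on the wall D(alpha) = 0, dp/dxi = -c p
  expect_equal(desingularised_rhs(0.5, -0.1, m, cc), c(-0.1, 0.0866))
  # inside (alpha, beta): D < 0 and the second component is positive on p = 0
  expect_gt(desingularised_rhs(2 / 3, 0, m, cc)[2], 0)

  # orientation: parallel where D > 0, antiparallel where D < 0
  d_out <- desingularised_rhs(0.3, -0.05, m, cc)
  s_out <- singular_rhs(0.3, -0.05, m, cc)
  expect_gt(sum(d_out * s_out), 0)
  d_in <- desingularised_rhs(0.7, 0.05, m, cc)
  s_in <- singular_rhs(0.7, 0.05, m, cc)
  expect_lt(sum(d_in * s_in), 0)
  expect_equal(d_in / diffusivity_at(m, 0.7), s_in)

  expect_error(singular_rhs(0.5, 0.1, m, cc), "wall")
})

test_that("equilibria carry the closed-form eigenvalues and classifications", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)

  eq <- find_equilibria(m, cs)
  expect_setequal(eq$name, c("origin", "alpha", "beta", "one"))
  expect_identical(eq$classification[eq$name == "one"], "saddle")
  expect_identical(eq$classification[eq$name == "alpha"], "saddle")
  expect_identical(eq$classification[eq$name == "origin"], "stable_node")
  expect_identical(eq$classification[eq$name == "beta"], "stable_node")

  # between the two thresholds: origin spirals, beta still a node
  eq4 <- find_equilibria(m, 0.4)
  expect_identical(eq4$classification[eq4$name == "origin"], "stable_spiral")
  expect_identical(eq4$classification[eq4$name == "beta"], "stable_node")
  # below the beta threshold the beta point spirals too
  eq2 <- find_equilibria(m, 0.2)
  expect_identical(eq2$classification[eq2$name == "beta"], "stable_spiral")
  expect_gt(abs(Im(eq2$lambda_plus[eq2$name == "beta"])), 0)

  # closed forms lambda = (-c +- sqrt(c^2 - 4F))/2 for random parameters
  par <- random_sign_changing(20, seed = 3)
  for (i in seq_len(20)) {
    mi <- fbw_model(two_rate_diffusivity(par$d_i[i], par$d_g[i]),
                    logistic_kinetic(par$lam[i]))
    ci <- 1.1 * min_wave_speed(mi)
    eqi <- find_equilibria(mi, ci)
    for (r in seq_len(4)) {
      f <- flux_deriv_at(mi, eqi$u[r])
      lam <- (-ci + sqrt(as.complex(ci^2 - 4 * f))) / 2
      expect_equal(eqi$lambda_plus[r], lam, tolerance = 1e-10)
      # eigenpair residual for the Jacobian [[0,1],[-F,-c]]
      J <- matrix(c(0, -f, 1, -ci), 2)
      v <- c(1, eqi$lambda_plus[r])
      expect_lt(max(Mod(J %*% v - eqi$lambda_plus[r] * v)), 1e-10)
    }
  }
})

test_that("eigenvector slopes lie below the nullcline slope at the connection points", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  expect_true(check_slope_ordering(m, cs, "one"))
  expect_true(check_slope_ordering(m, cs, "alpha"))
  expect_true(check_slope_ordering(m, cs, "origin"))
  expect_true(check_slope_ordering(m, cs, "beta"))
})

test_that("invariant regions close exactly when c is at least c*", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  expect_true(verify_invariant_region(m, cs, "R1"))
  expect_true(verify_invariant_region(m, cs, "R2"))
  expect_true(verify_invariant_region(m, 1.2 * cs, "R1"))
  expect_false(verify_invariant_region(m, 0.5 * cs, "R1"))
})

test_that("heteroclinic shooting reaches the stated targets", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  o1 <- shoot_manifold(m, cs, "one", -1)
  o2 <- shoot_manifold(m, cs, "alpha", +1)
  o3 <- shoot_manifold(m, cs, "alpha", -1)
  expect_identical(attr(o1, "target"), "beta")
  expect_identical(attr(o2, "target"), "beta")
  expect_identical(attr(o3, "target"), "origin")
  # the lower connection stays nonnegative at c >= c* ...
  expect_gte(min(o3$u), 0)
  # ... and dips negative between the two thresholds
  o3_slow <- shoot_manifold(m, 0.4, "alpha", -1)
  expect_identical(attr(o3_slow, "target"), "origin")
  expect_lt(min(o3_slow$u), 0)

  # step-halving: p along the (1,0)->(beta,0) orbit at u = 0.9 is converged
  o1h <- shoot_manifold(m, cs, "one", -1, dxi = 0.025, rtol = 1e-11, atol = 1e-13)
  p_at <- function(o) approx(rev(o$u), rev(o$p), xout = 0.9)$y
  expect_equal(p_at(o1), p_at(o1h), tolerance = 1e-6)
})

test_that("singular-system integration reproduces the desingularised orbit where D > 0", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  o1 <- shoot_manifold(m, cs, "one", -1)
  # start on the orbit at u ~ 0.95 and integrate the singular system in z
  i0 <- which(o1$u <= 0.95)[1]
  rhs_z <- function(z, y, parms) list(singular_rhs(y[1], y[2], m, cs))
  sol <- deSolve::lsoda(c(u = o1$u[i0], p = o1$p[i0]), seq(0, 0.6, by = 0.005),
                        rhs_z, rtol = 1e-10, atol = 1e-12)
  keep <- sol[, "u"] > 0.87 # stay away from the wall at beta
  p_orbit <- approx(rev(o1$u), rev(o1$p), xout = sol[keep, "u"])$y
  expect_lt(max(abs(sol[keep, "p"] - p_orbit)), 1e-5)
})

test_that("the assembled wave is monotone, bounded, and solves the wave ODE", {
  w <- benchmark_wave()
  expect_true(all(diff(w$z) > 0))
  expect_true(all(diff(w$u) <= 1e-9))
  expect_true(all(w$u >= -1e-8 & w$u <= 1 + 1e-8))
  expect_lt(abs(approx(w$z, w$u, xout = 0)$y - 0.25), 1e-6) # anchor u(0) = alpha/2
  # far-field limits
  expect_gt(w$u[1], 1 - 1e-6)
  expect_lt(w$u[nrow(w)], 1e-6)
  res <- wave_residual(w)
  expect_lt(max(abs(res$residual[!res$near_hole])), 1e-4)
})

test_that("wave assembly is invariant under halved integrator tolerances", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  w <- benchmark_wave()
  w2 <- assemble_wave(m, cs, dxi = 0.025, rtol = 1e-11, atol = 1e-13)
  cmp <- compare_profiles(w, w2, shift_range = c(-2, 2))
  expect_lt(cmp$sup_norm, 1e-5)
})

test_that("vertical tangent counts separate monotone waves from spiral tails", {
  m <- benchmark_model()
  cs <- min_wave_speed(m)
  w <- benchmark_wave()
  segs <- attr(w, "segments")
  expect_identical(sum(vapply(segs, count_vertical_tangents, integer(1))), 0L)
  # spiral approach to the origin at c = 0.4 crosses p = 0 repeatedly
  o_spiral <- shoot_manifold(m, 0.4, "alpha", -1)
  expect_gte(count_vertical_tangents(o_spiral), 1L)
  # straight-line synthetic orbit has none
  straight <- tibble::tibble(xi = 0:100, u = seq(1, 0, length.out = 101),
                             p = -seq(1, 0, length.out = 101))
  expect_identical(count_vertical_tangents(straight), 0L)
})
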