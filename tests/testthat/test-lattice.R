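test_that("parameter mapping to the continuum and back is exact", {
  lp <- lattice_params(0.5, 0.1, p_p_i = 0.0075, p_p_g = 0.0075,
                       delta = 0.1, tau = 0.01)
  cp <- continuum_parameters(lp)
  expect_equal(cp$d_i, 0.25)
  expect_equal(cp$d_g, 0.05)
  expect_equal(cp$lambda_g, 0.75)
  lp2 <- lattice_from_continuum(cp$d_i, cp$d_g, cp$lambda_i, cp$lambda_g,
                                cp$k_i, cp$k_g, delta = 0.1, tau = 0.01)
  expect_equal(unclass(lp2), unclass(lp), tolerance = 1e-14)
  expect_error(lattice_params(1.5, 0.1), "\\[0, 1\\]")
  expect_error(lattice_params(0.5, 0.1, delta = 0), "positive")
})

test_that("the two transcriptions of the occupancy recurrence agree", {
  # meanfield_delta is the literal bracket-by-bracket conservation statement;
  # meanfield_step is an independent edge-flux formulation
  lp <- lattice_params(0.5, 0.1, p_p_i = 0.0075, p_p_g = 0.004,
                       p_d_i = 0.002, p_d_g = 0.001, delta = 0.1, tau = 0.01)
  set.seed(8)
  for (rep in 1:5) {
    U <- pmin(pmax(c(rep(1, 20), seq(1, 0, length.out = 30), rep(0, 20)) +
                     runif(70, -0.05, 0.05), 0), 1)
    j <- 3:68
    expect_equal(fbwave:::meanfield_step(U, lp)[j], U[j] + meanfield_delta(U, lp, j),
                 tolerance = 1e-14)
  }
  # no events at all: zero increment everywhere
  lp0 <- lattice_params(0, 0)
  U <- runif(50)
  expect_equal(meanfield_delta(U, lp0, 3:48), rep(0, 46))
  # motility-only uniform state: movement brackets cancel by symmetry
  lpm <- lattice_params(0.37, 0.11)
  expect_equal(meanfield_delta(rep(0.4, 50), lpm, 3:48), rep(0, 46),
               tolerance = 1e-15)
})

test_that("mean-field dynamics conserve occupancy without birth or death", {
  lpm <- lattice_params(0.5, 0.1, delta = 0.1, tau = 0.01)
  U0 <- as.numeric((0:199) * 0.1 < 10)
  mf <- meanfield_simulate(U0, lpm, 1000, record_every = 1000)
  expect_lt(abs(sum(mf$occupancy[nrow(mf$occupancy), ]) - sum(U0)), 1e-12)
  # full occupancy is a fixed point when nothing can die
  lp <- lattice_params(0.5, 0.1, p_p_i = 0.0075, p_p_g = 0.0075)
  mf1 <- meanfield_simulate(rep(1, 50), lp, 10)
  expect_equal(mf1$occupancy[nrow(mf1$occupancy), ], rep(1, 50))
})

test_that("mean-field recurrence converges to the PDE under lattice refinement", {
  # positive-definite diffusivity: the continuum problem is well-posed, so
  # halving the spacing (with tau proportional to delta^2) must shrink the
  # sup-norm gap to a fine-grid reference.  (In the sign-changing case the
  # backward-diffusion interval is grid-regularised and different
  # discretisations need not converge pointwise; see the methods vignette.)
  m <- fbw_model(two_rate_diffusivity(0.25, 0.2), logistic_kinetic(0.75))
  g <- grid1d(0, 40, 0.025)
  ref <- pde_simulate(m, as.numeric(g$x < 20), g, dt = 5e-4, t_final = 4,
                      record_every = 4, scheme = "explicit")
  uref <- ref$snapshots$u[ref$snapshots$t == 4]
  err <- vapply(c(0.2, 0.1), function(delta) {
    tau <- delta^2
    lp <- lattice_from_continuum(0.25, 0.2, 0.75, delta = delta, tau = tau)
    x <- seq(0, 40, by = delta)
    mf <- meanfield_simulate(as.numeric(x < 20), lp, round(4 / tau),
                             record_every = round(4 / tau))
    max(abs(mf$occupancy[nrow(mf$occupancy), ] - approx(g$x, uref, xout = x)$y))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})


test_that("mean-field front speed tracks the PDE front speed", {
  lp <- lattice_from_continuum(0.25, 0.05, 0.75, delta = 0.1, tau = 0.01)
  U0 <- as.numeric((0:999) * 0.1 < 40)
  mf <- meanfield_simulate(U0, lp, 6000, record_every = 50)
  tr <- lattice_front_track(mf$occupancy, mf$x, mf$times)
  sp <- estimate_speed(tr, window = c(30, 60))$speed
  expect_equal(sp, benchmark_speed_fit()$speed, tolerance = 0.02)
})

test_that("stochastic steps respect exclusion, conservation and reproducibility", {
  # no events: lattice unchanged
  lp0 <- lattice_params(0, 0)
  init <- as.integer(c(0, 1, 1, 0, 1, 0, 0, 1))
  s <- stochastic_simulate(init, lp0, 5, record_every = 5)
  expect_equal(s$replicates[[1]][2, ], init)
  # full lattice, no death: exclusion blocks every birth
  lpf <- lattice_params(0.5, 0.5, p_p_i = 1, p_p_g = 1)
  sf <- stochastic_simulate(rep(1L, 30), lpf, 20, record_every = 20)
  expect_equal(sf$replicates[[1]][2, ], rep(1L, 30))
  # motility only conserves agent number per step
  lpm <- lattice_params(0.9, 0.3)
  set.seed(5)
  sm <- stochastic_simulate(as.integer(runif(200) < 0.4), lpm, 50, record_every = 1)
  expect_equal(apply(sm$replicates[[1]], 1, sum),
               rep(sum(sm$replicates[[1]][1, ]), 51))
  # occupancy stays binary
  expect_true(all(sm$replicates[[1]] %in% c(0L, 1L)))
  # seeded runs are bit-reproducible
  lp <- lattice_from_continuum(0.25, 0.05, 0.75)
  init <- as.integer((0:199) * 0.1 < 10)
  set.seed(123); a <- stochastic_simulate(init, lp, 100, record_every = 10, n_rep = 3)
  set.seed(123); b <- stochastic_simulate(init, lp, 100, record_every = 10, n_rep = 3)
  expect_identical(a$replicates, b$replicates)
})

test_that("a single agent's mean-square displacement matches its diffusivity", {
  lp1 <- lattice_params(0.5, 0.1, delta = 0.1, tau = 0.01)
  n <- 401
  init <- integer(n); init[201] <- 1L
  set.seed(17)
  msd <- replicate(3000, {
    occ <- stochastic_simulate(init, lp1, 400, record_every = 400)$replicates[[1]]
    (which(occ[2, ] == 1) - 201)^2
  })
  # MSD (site^2) after n steps is p_m * n = 2 d_i t / delta^2 = 200
  expect_equal(mean(msd), 2 * 0.25 * 4 / 0.1^2,
               tolerance = 4 * sd(msd) / sqrt(3000) / 200)
})

test_that("pure symmetric exclusion reproduces its exact mean-field density", {
  # with equal rates the mean occupancy solves the recurrence exactly
  lpe <- lattice_params(0.5, 0.5, delta = 0.1, tau = 0.01)
  U0 <- as.integer((0:399) * 0.1 < 20)
  set.seed(21)
  ss <- stochastic_simulate(U0, lpe, 500, record_every = 500, n_rep = 200)
  prof <- density_profile(ss)
  m_final <- prof$density[prof$step == 500]
  mf <- meanfield_simulate(as.numeric(U0), lpe, 500, record_every = 500)
  dev <- abs(m_final - mf$occupancy[nrow(mf$occupancy), ])
  expect_lt(max(dev), 5 * sqrt(0.25 / 200)) # within Monte-Carlo error
})

test_that("density profiles average replicates with binomial standard errors", {
  lp0 <- lattice_params(0, 0)
  init <- as.integer(c(1, 0, 1, 0))
  s1 <- stochastic_simulate(init, lp0, 2, record_every = 2, n_rep = 1)
  p1 <- density_profile(s1)
  expect_equal(p1$density[p1$step == 2], as.numeric(init))
  expect_equal(p1$stderr, rep(0, nrow(p1)))
  sz <- stochastic_simulate(integer(4), lp0, 2, record_every = 2, n_rep = 5)
  pz <- density_profile(sz)
  expect_true(all(pz$density == 0))
})
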