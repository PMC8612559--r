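test_that("ball model rests exactly at the leak reversal when passive", {
  m <- ball_model()
  sw <- runSweep(m, list(), passive_cfg(300))
  expect_equal(range(sw@v), c(-50.5, -50.5))
  # active mechanism shifts rest by well under 0.1 mV
  sa <- runSweep(m, list(), SolverConfig(tstop = 1000))
  expect_lt(abs(sa@v[1, ncol(sa@v)] + 50.5), 0.1)
  # sphere surface pi d^2
  expect_equal(m@comp$area[1], pi * 46.6^2 * 1e-8)
})

test_that("passive charging matches the RC closed form and converges with dt", {
  m <- ball_model()
  gl <- m@comp$gpas[1]                      # uS
  tau <- m@comp$cm[1] / gl                  # nF/uS = ms
  err <- vapply(c(0.025, 0.0025), function(dt) {
    sw <- runSweep(m, list(IClamp(0.002, delay = 0, dur = 400)),
                   passive_cfg(400, dt = dt))
    pred <- -50.5 + (0.002 / gl) * (1 - exp(-sw@time / tau))
    max(abs(sw@v[1, ] - pred)) / (0.002 / gl)
  }, 1.0)
  expect_lt(err[1], 1e-3)
  expect_lt(err[2], 1.2e-4)                 # first-order convergence
})

test_that("steady-state dendritic attenuation matches the sealed-end cable solution", {
  bs <- bs_model()
  cfg <- passive_cfg(5000,
                     record = list(c("soma", 0.5), c("dend", 0.25),
                                   c("dend", 0.75), c("dend", 1)))
  sw <- runSweep(bs, list(IClamp(0.001, delay = 0, dur = 5000)), cfg)
  vss <- sw@v[, ncol(sw@v)] + 50.5
  lambda <- sqrt((1e-4 / 4) / (bs@morph@ra * bs@leak@gpas))  # cm
  L <- 0.1 / lambda
  xs <- c(0, 0.2483, 0.7483, 0.99834) * 0.1 / lambda
  pred <- cosh(L - xs) / cosh(L)
  expect_equal(unname(vss / vss[1]), pred, tolerance = 2e-3)
})

test_that("two-compartment passive model matches the matrix-exponential solution", {
  morph <- new("Morphology",
               sections = rbind(
                 egabathr:::.section_row("a", "cyl", 100, 2, 1, naScale = 0),
                 egabathr:::.section_row("b", "cyl", 100, 2, 1,
                                         parent = "a")),
               ra = 150, cm = 1)
  m <- buildModel(morph)
  cfg <- passive_cfg(200, dt = 0.005,
                     record = list(c("a", 0.5), c("b", 0.5)))
  iamp <- 0.005
  sw <- runSweep(m, list(IClamp(iamp, delay = 0, dur = 200,
                                section = "a")), cfg)
  # dense ODE solution: C dv/dt = -G (v - E) + b
  comp <- m@comp
  A <- matrix(0, 2, 2)
  A[1, 1] <- -(comp$gpas[1] + comp$gax[2]) / comp$cm[1]
  A[1, 2] <- comp$gax[2] / comp$cm[1]
  A[2, 2] <- -(comp$gpas[2] + comp$gax[2]) / comp$cm[2]
  A[2, 1] <- comp$gax[2] / comp$cm[2]
  b <- c((comp$gpas[1] * -50.5 + iamp) / comp$cm[1],
         comp$gpas[2] * -50.5 / comp$cm[2])
  vinf <- solve(A, -b)
  eig <- eigen(A)
  c0 <- solve(eig$vectors, c(-50.5, -50.5) - vinf)
  pred <- vapply(sw@time, function(t)
    Re(eig$vectors %*% (c0 * exp(eig$values * t)) + vinf)[1], 1.0)
  expect_equal(sw@v[1, ], pred, tolerance = 1e-3)
})

test_that("spatial refinement of the dendrite barely moves somatic responses", {
  syn <- function(model) gabaSynapse(-40, gmax = 1, section = "dend",
                                     pos = 0.5, onsets = 20)
  m1 <- bs_model()
  m3 <- buildModel(ballAndStickMorphology(nseg = 903))
  s1 <- runSweep(m1, list(syn(m1)), passive_cfg(300))
  s3 <- runSweep(m3, list(syn(m3)), passive_cfg(300))
  a1 <- max(s1@v) + 50.5; a3 <- max(s3@v) + 50.5
  expect_lt(abs(a1 - a3) / a3, 0.01)
})

test_that("sweeps are bit-reproducible and divergence aborts with a flag", {
  m <- ball_model()
  st <- list(IClamp(0.004, delay = 10, dur = 100),
             gabaSynapse(-45, 0.5, onsets = 50))
  s1 <- runSweep(m, st, SolverConfig(tstop = 300))
  s2 <- runSweep(m, st, SolverConfig(tstop = 300))
  expect_identical(s1@v, s2@v)
  bad <- runSweep(m, list(IClamp(100, delay = 1, dur = 200)),
                  SolverConfig(tstop = 300))
  expect_true(bad@diverged)
})

test_that("morphology validity catches cycles and geometry errors", {
  secs <- rbind(egabathr:::.section_row("soma", "sphere", NA, 40, 1),
                egabathr:::.section_row("d1", "cyl", 100, 1, 5,
                                        parent = "d2"),
                egabathr:::.section_row("d2", "cyl", 100, 1, 5,
                                        parent = "d1"))
  expect_error(new("Morphology", sections = secs, ra = 150, cm = 1),
               "root|cycle")
  expect_error(ballMorphology(somaDiam = -1), "diam|positive")
})

test_that("axon variant carries the reduced distal spike mechanism", {
  m <- buildModel(ballStickAxonMorphology())
  s <- m@morph@sections
  expect_equal(sum(grepl("^axon", s$name)) * 10 + 10, 110)  # 10 + 10 x 10 um
  ais <- m@comp[m@comp$section == "ais", ]
  ax <- m@comp[m@comp$section == "axon5", ]
  expect_equal(ax$gna / ax$area, 0.9 * ais$gna / ais$area, tolerance = 1e-12)
  expect_equal(sum(m@comp$gna[m@comp$section %in% c("soma", "dend")]), 0)
  sw <- runSweep(m, list(), SolverConfig(tstop = 500))
  expect_lt(abs(sw@v[1, ncol(sw@v)] + 50.5), 0.1)
})
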