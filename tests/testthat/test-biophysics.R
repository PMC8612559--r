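test_that("sodium rate functions are Boltzmann sigmoids with the right anchors", {
  p <- NaChannelParams()
  r <- naRates(p@Vco, p)
  expect_equal(unname(r[1, "alphaA"]), p@q10 / p@tauAct * p@Gco / 2)
  # saturation limits
  lo <- naRates(-300, p); hi <- naRates(300, p)
  expect_lt(lo[1, "alphaA"], 1e-10)
  expect_equal(unname(hi[1, "alphaA"]), p@q10 / p@tauAct * p@Gco,
               tolerance = 1e-10)
  # monotonicity: alphaA non-decreasing, betaA non-increasing in V
  v <- seq(-100, 60, by = 0.5)
  r <- naRates(v, p)
  expect_true(all(diff(r[, "alphaA"]) >= 0))
  expect_true(all(diff(r[, "betaA"]) <= 0))
  expect_true(all(r >= 0))
  # boundedness: no rate exceeds q10 * max gain / tau
  cap <- p@q10 * max(p@Gco, p@Goc, p@Gic, p@Gci) /
    min(p@tauAct, p@tauIna)
  expect_true(all(r <= cap + 1e-12))
  expect_error(naRates(NaN, p), "finite")
})

test_that("activation/deactivation forms mirror each other at equal gains", {
  p <- NaChannelParams(Gco = 2, Goc = 2)
  x <- seq(-30, 30, by = 0.7)
  a <- naRates(p@Vco + x, p)[, "alphaA"]
  b <- naRates(p@Vco - x, p)[, "betaA"]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("sodium state derivatives honour the kinetic scheme", {
  p <- NaChannelParams()
  # no closed channels left to open
  d <- naDerivatives(-40, o = 0, h = 1, p)
  expect_equal(unname(d["dO"]), 0)
  # at the empty state the open-fraction derivative is alphaA(v)
  d0 <- naDerivatives(-40, 0, 0, p)
  expect_equal(unname(d0["dO"]), unname(naRates(-40, p)[1, "alphaA"]))
  expect_gte(unname(d0["dO"]), 0)
  expect_error(naDerivatives(-40, o = 0.8, h = 0.5, p), "simplex")
  expect_error(naDerivatives(Inf, 0, 0, p), "finite")
})

test_that("cooperativity-free fixed point matches the closed-form rates balance", {
  p <- NaChannelParams(cf = 0)
  v <- -38
  r <- naRates(v, p)
  kH <- r[1, "alphaIC"] + r[1, "betaIC"] + 1 / p@tauRelax
  h <- unname(r[1, "alphaIC"] / kH)
  kO <- r[1, "alphaA"] + r[1, "betaA"] + 1 / p@tauRelax
  o <- unname(r[1, "alphaA"] * (1 - h) / kO)
  d <- naDerivatives(v, o, h, p)
  expect_equal(unname(d["dO"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["dH"]), 0, tolerance = 1e-12)
})

test_that("fine-step Euler integration of the channel ODEs reaches the fixed point", {
  p <- NaChannelParams(cf = 0)
  v <- -36
  o <- 0; h <- 0
  dt <- 1e-4
  for (i in seq_len(200000)) {
    d <- naDerivatives(v, o, h, p)
    o <- o + dt * d["dO"]; h <- h + dt * d["dH"]
  }
  r <- naRates(v, p)
  kH <- r[1, "alphaIC"] + r[1, "betaIC"] + 1 / p@tauRelax
  h_star <- unname(r[1, "alphaIC"] / kH)
  kO <- r[1, "alphaA"] + r[1, "betaA"] + 1 / p@tauRelax
  o_star <- unname(r[1, "alphaA"] * (1 - h_star) / kO)
  expect_equal(unname(o), o_star, tolerance = 0.02)
  expect_equal(unname(h), h_star, tolerance = 0.02)
})

test_that("potassium derivative behaves at the boundaries", {
  p <- KChannelParams()
  expect_equal(kDerivative(-20, 0, p), unname(kRates(-20, p)[1, "alphaA"]))
  expect_lt(kDerivative(-120, 1, p), 0)
  # fixed point with cf = 0
  p0 <- KChannelParams(cf = 0)
  v <- -41
  r <- kRates(v, p0)
  ok <- unname(r[1, "alphaA"] / (r[1, "alphaA"] + r[1, "betaA"] +
                                 1 / p0@tauRelax))
  expect_equal(kDerivative(v, ok, p0), 0, tolerance = 1e-12)
  expect_error(kDerivative(-40, 1.2, p0), "0,1")
})

test_that("membrane currents are Ohmic and vanish at their reversals", {
  na <- NaChannelParams(); k <- KChannelParams(); leak <- LeakParams()
  i <- membraneCurrents(na@erev, o = 0.3, h = 0.1, ok = 0.2, na, k, leak)
  expect_equal(unname(i["iNa"]), 0)
  i2 <- membraneCurrents(leak@epas, o = 0, h = 0, ok = 0, na, k, leak)
  expect_equal(sum(i2), 0)
  # arithmetic identity g * O * (V - E)
  na2 <- NaChannelParams(gmax = 2)
  i3 <- membraneCurrents(na2@erev + 10, 0.5, 0, 0, na2, k, leak)
  expect_equal(unname(i3["iNa"]), 2 * 0.5 * 10)
})

test_that("channel parameter sets load and override from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("na:", "  gmax: 0.001", "leak:", "  gpas: 2.0e-5"), f)
  set <- defaultChannelSet(f)
  expect_equal(set$na@gmax, 0.001)
  expect_equal(set$leak@gpas, 2e-5)
  expect_equal(set$k@erev, defaultChannelSet()$k@erev)
})
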