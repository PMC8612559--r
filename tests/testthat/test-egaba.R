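test_that("GHK chloride conversion reproduces the reference working points", {
  expect_equal(round(ghkClFromEgaba(-50.5), 1), 14.5)
  expect_equal(round(ghkClFromEgaba(-42.8), 1), 21.7)
  expect_equal(round(ghkClFromEgaba(-44.7), 1), 19.7)
  expect_equal(round(ghkClFromEgaba(-47.5), 1), 17.1)
})

test_that("GHK conversion is strictly increasing and exactly invertible", {
  e <- seq(-90, -20, by = 0.5)
  cl <- ghkClFromEgaba(e, warn = FALSE)
  expect_true(all(diff(cl) > 0))
  ok <- cl > 0
  expect_equal(egabaFromCl(cl[ok]), e[ok], tolerance = 1e-9)
  # the zero-chloride root of the closed form
  p <- GhkParams()
  e0 <- p@slope * log10(p@phco3 * p@hco3i / (p@cle + p@phco3 * p@hco3e))
  expect_equal(ghkClFromEgaba(e0, warn = FALSE), 0, tolerance = 1e-12)
  expect_warning(ghkClFromEgaba(e0 - 1), "physiological")
})

test_that("reciprocal estimator recovers an exactly linear reciprocal curve", {
  e0 <- -43.21
  eg <- seq(-43, -40, by = 0.5)
  gthr <- 1 / (0.37 * (eg - e0))
  cur <- new("GThrCurve", egaba = eg, gthr = gthr, meta = list())
  est <- egabaThrReciprocal(cur, nFit = 2)
  expect_equal(est@value, e0, tolerance = 1e-10)
  # n_fit may use more points on an exactly linear curve
  expect_equal(egabaThrReciprocal(cur, nFit = 4)@value, e0,
               tolerance = 1e-10)
  # sentinels ahead of the finite region are tolerated
  cur2 <- new("GThrCurve", egaba = c(-44, -43.5, eg),
              gthr = c(NA, NA, gthr), meta = list())
  expect_equal(egabaThrReciprocal(cur2)@value, e0, tolerance = 1e-10)
  # a flat (non-approaching) curve is rejected
  bad <- new("GThrCurve", egaba = eg, gthr = rep(2, length(eg)),
             meta = list())
  expect_error(egabaThrReciprocal(bad), "slope|extrapolates")
})

test_that("intersection estimator interpolates the sign change", {
  d <- list(egaba = c(-46, -45, -44, -43), delta = c(0.4, 0.2, 0, -0.2))
  expect_equal(egabaThrIntersection(d)@value, -44)
  d2 <- list(egaba = c(-46, -45, -44), delta = c(0.3, 0.1, -0.1))
  expect_equal(egabaThrIntersection(d2)@value, -44.5)
  d3 <- list(egaba = c(-46, -45), delta = c(0.3, 0.1))
  est <- egabaThrIntersection(d3)
  expect_true(is.na(est@value))
  expect_equal(est@method, "out-of-range")
})

test_that("threshold-conductance scan marks the no-threshold region with sentinels", {
  m <- ball_model()
  cur <- scanGGabaThr(m, c(-44, -41.5), cap = 30)
  expect_true(is.na(cur@gthr[1]))       # below threshold E_GABA: capped
  expect_true(is.finite(cur@gthr[2]))
  expect_gt(cur@gthr[2], 0)
})

test_that("synaptic peak time grows with dendritic distance", {
  bs <- bs_model()
  tp <- vapply(c(0.1, 0.5, 0.9), function(p)
    synapticPeakTime(bs, ampaSynapse(gmax = 0.1, section = "dend", pos = p,
                                     onsets = 100)), 1.0)
  expect_true(all(diff(tp) > 0))
})
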