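test_that("AP detection distinguishes resting and suprathreshold sweeps", {
  m <- ball_model()
  rest <- runSweep(m, list(), SolverConfig(tstop = 500))
  expect_false(detectAP(rest)$ap)
  supra <- runSweep(m, list(IClamp(0.02, delay = 50, dur = 400)),
                    SolverConfig(tstop = 500))
  d <- detectAP(supra, window = c(50, 450))
  expect_true(d$ap)
  expect_gt(d$time, 50)
  # verdicts agree between detection levels -10 and 0 mV for full spikes
  expect_equal(detectAP(supra, level = -10)$ap, detectAP(supra, level = 0)$ap)
  expect_equal(detectAP(rest, level = -10)$ap, detectAP(rest, level = 0)$ap)
})

.make_sweep <- function(t, v) {
  new("Sweep", time = t, v = matrix(v, nrow = 1),
      isyn = matrix(numeric(0), 0, length(t)), dt = t[2] - t[1],
      sites = "soma@0.5", diverged = FALSE)
}

test_that("dV/dt threshold interpolates the crossing on constructed traces", {
  t <- seq(0, 100, by = 0.025)
  # ramp at 5 V/s never reaches the criterion
  ramp <- .make_sweep(t, -60 + 5 * t * 1e-3 * 1e3 * 0.005 / 0.005 * 0.001)
  ramp@v[1, ] <- -60 + 0.005 * t   # 5 V/s, stays subthreshold
  expect_error(apThresholdDvdt(ramp), "peak|action")
  # piecewise: slow approach to -40, then a fast 100 V/s rise through 0
  v <- ifelse(t < 50, -60 + 0.4 * t, -40 + 100 * (t - 50) * 1e-3 * 1e3)
  v <- pmin(v, 30)
  sw <- .make_sweep(t, v)
  est <- apThresholdDvdt(sw)
  expect_equal(est$value, -40, tolerance = 0.5)
})

test_that("third-derivative threshold matches an analytic oracle", {
  t <- seq(0, 100, by = 0.025)
  # sigmoidal onset: V = -60 + 90 * pnorm((t - 60)/3); d3V has its first
  # positive maximum where phi''((t-60)/3) peaks: t = 60 - 3*sqrt(3)
  v <- -60 + 90 * pnorm((t - 60) / 3)
  sw <- .make_sweep(t, v)
  est <- apThresholdD3(sw)
  t_star <- 60 - 3 * sqrt(3)
  expect_equal(est$time, t_star, tolerance = 0.05)
  expect_equal(est$value, -60 + 90 * pnorm(-sqrt(3)), tolerance = 0.1)
})

test_that("intersection threshold recovers an exact corner", {
  t <- seq(0, 100, by = 0.025)
  v <- ifelse(t < 60, -55 + 0.05 * t, (-55 + 0.05 * 60) + 120e-3 * 1e3 *
                (t - 60) * 1e-3 * 1e3)
  v <- ifelse(t < 60, -55 + 0.05 * t, -52 + 120 * (t - 60))
  v <- pmin(v, 40)
  sw <- .make_sweep(t, v)
  est <- apThresholdIS(sw, riseRange = c(50, 200))
  expect_equal(est$value, -52, tolerance = 0.2)
})

test_that("alternating search brackets constructed and random oracles", {
  res <- alternatingSearch(function(g) g >= 5.4321, step1 = 1, cap = 100)
  expect_lte(abs(res@gThr - 5.4321), res@finalStep)
  expect_false(res@capped)
  expect_true(all(diff(res@history$g[res@history$ap]) != 0))
  # cap reached -> "no threshold"
  res2 <- alternatingSearch(function(g) FALSE, step1 = 1, cap = 20)
  expect_true(res2@capped)
  expect_true(is.na(res2@gThr))
  # agreement with a brute-force fine grid on random thresholds
  set.seed(42)
  for (i in 1:20) {
    thr <- runif(1, 0.2, 40)
    res <- alternatingSearch(function(g) g >= thr, step1 = 1, cap = 100)
    step <- res@finalStep / 10
    grid <- seq(floor(thr / step - 20) * step, thr + 20 * step, by = step)
    brute <- grid[which(grid >= thr)[1]]
    expect_lte(abs(res@gThr - brute), res@finalStep)
  }
})

test_that("search sweep counts match the reference protocol scale", {
  m <- ball_model()
  gs <- conductanceThresholdSearch(m, gabaSynapse(-40, onsets = 100), "gGABA")
  rampg <- ceiling(gs@gThr / 1)
  expect_gt(gs@sweeps, rampg + 12)
  expect_lt(gs@sweeps, rampg + 60)
  as <- conductanceThresholdSearch(m, ampaSynapse(onsets = 100), "gAMPA")
  # coarse 0.01 nS ramp to the threshold plus ~2-4 sweeps per refinement phase
  ramp <- ceiling(as@gThr / 0.01)
  expect_gt(as@sweeps, ramp + 12)
  expect_lt(as@sweeps, ramp + 60)
  # the threshold is bracketed: spike at gThr, none one final step below
  onset <- 100
  isAP <- function(g) {
    sw <- runSweep(m, list(gabaSynapse(-40, gmax = g, onsets = onset)),
                   SolverConfig(tstop = 950))
    detectAP(sw, c(onset, onset + 800))$ap
  }
  expect_true(isAP(gs@gThr))
  expect_false(isAP(gs@gThr - gs@finalStep))
})

test_that("AMPA analysis window ends at the 63% decay point of the passive response", {
  m <- ball_model()
  syn <- ampaSynapse(onsets = 100)
  w <- ampaAnalysisWindow(m, syn, cfg = SolverConfig(tstop = 800))
  expect_equal(w[1], 100)
  sw <- runSweep(m, list({s <- syn; s@gmax <- 0.1; s}), passive_cfg(800))
  dep <- sw@v[1, ] - sw@v[1, which.min(abs(sw@time - 100))]
  ipk <- which.max(dep)
  expect_gt(w[2], sw@time[ipk])
  i63 <- which.min(abs(sw@time - w[2]))
  expect_equal(dep[i63] / dep[ipk], 0.63, tolerance = 0.01)
})

test_that("AP feature error is the stated weighted sum", {
  f <- c(eThrD3 = -34, vRiseMax = 100, vDecayMax = -30, halfWidth = 2,
         peak = 20)
  expect_equal(apFeatureError(f, f), 0)
  g <- f; g["eThrD3"] <- f["eThrD3"] + 1
  expect_equal(apFeatureError(g, f), 10)
  g <- f; g["vRiseMax"] <- f["vRiseMax"] - 2
  expect_equal(apFeatureError(g, f), 12)
  expect_error(apFeatureError(f[-1], f), "must contain")
  # features from one sweep are bit-reproducible
  m <- ball_model()
  sw <- runSweep(m, list(IClamp(0.008, delay = 100, dur = 1500)),
                 SolverConfig(tstop = 1700))
  expect_identical(apFeatures(sw), apFeatures(sw))
})
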