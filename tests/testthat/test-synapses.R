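test_that("double-exponential conductance is peak-normalized with the exact peak time", {
  spec <- Exp2Synapse(tau1 = 0.1, tau2 = 11, gmax = 2, onsets = 5)
  tp <- exp2PeakTime(0.1, 11)
  expect_equal(tp, 0.1 * 11 / (11 - 0.1) * log(11 / 0.1))
  expect_equal(round(tp, 4), 0.4744)
  expect_equal(exp2Conductance(5 + tp, spec), 2)
  expect_equal(exp2Conductance(5, spec), 0)
  expect_true(all(exp2Conductance(seq(0, 100, by = 0.01), spec) >= 0))
  # single maximum at tp
  tt <- seq(5, 30, by = 1e-3)
  g <- exp2Conductance(tt, spec)
  expect_equal(tt[which.max(g)] - 5, tp, tolerance = 2e-3)
  # onsets sum linearly
  s2 <- Exp2Synapse(tau1 = 0.1, tau2 = 11, gmax = 2, onsets = c(5, 7))
  expect_equal(exp2Conductance(tt, s2),
               g + exp2Conductance(tt - 2, spec), tolerance = 1e-12)
  expect_error(Exp2Synapse(tau1 = 5, tau2 = 2), "tau1")
})

test_that("GABA kinetics default to the slow experimental decay", {
  g <- gabaSynapse(-45)
  expect_equal(g@tau2, 37)
  expect_equal(g@tau1, 0.1)
  a <- ampaSynapse()
  expect_equal(c(a@tau1, a@tau2, a@erev), c(0.1, 11, -12))
})

test_that("passive responses are linear in the synaptic conductance", {
  m <- ball_model()
  one <- list(gabaSynapse(-40, gmax = 0.9, onsets = 50))
  two <- list(gabaSynapse(-40, gmax = 0.4, onsets = 50),
              gabaSynapse(-40, gmax = 0.5, onsets = 50))
  s1 <- runSweep(m, one, passive_cfg(400))
  s2 <- runSweep(m, two, passive_cfg(400))
  expect_equal(s1@v, s2@v, tolerance = 1e-12)
})

test_that("recorded synaptic current equals g(t) times the driving force", {
  m <- ball_model()
  syn <- gabaSynapse(-40, gmax = 1.5, onsets = 30)
  sw <- runSweep(m, list(syn), passive_cfg(300), recordSynCurrent = 1L)
  g <- exp2Conductance(sw@time, syn) * 1e-3     # nS -> uS
  pred <- g * (syn@erev - sw@v[1, ])            # uS * mV = nA
  expect_equal(sw@isyn[1, ], pred, tolerance = 1e-8)
})

test_that("tonic conductance obeys the steady-state conductance divider", {
  m <- ball_model()
  # zero density leaves the model at rest
  s0 <- runSweep(m, list(TonicGaba(0, -40)), passive_cfg(400))
  expect_equal(range(s0@v), c(-50.5, -50.5))
  # reversal at rest leaves the resting potential untouched
  s1 <- runSweep(m, list(TonicGaba(8.75e-7, -50.5)), passive_cfg(400))
  expect_equal(range(s1@v), c(-50.5, -50.5), tolerance = 1e-9)
  # otherwise V_ss = (gL EL + gT ET)/(gL + gT)
  dens <- 8.75e-6
  s2 <- runSweep(m, list(TonicGaba(dens, -40)), passive_cfg(1000))
  gl <- m@leak@gpas
  pred <- (gl * -50.5 + dens * -40) / (gl + dens)
  expect_equal(s2@v[1, ncol(s2@v)], pred, tolerance = 1e-3)
})

test_that("played-back current reproduces the conductance sweep in a passive model", {
  m <- ball_model()
  syn <- gabaSynapse(-42, gmax = 2, onsets = 100)
  cfg <- passive_cfg(600)
  ref <- runSweep(m, list(syn), cfg)
  pb <- recordPlayback(m, syn, cfg)
  rep <- runSweep(m, list(pb), cfg)
  expect_equal(rep@v, ref@v, tolerance = 1e-6)
  # at rest with E_GABA = E_pas the recorded current is identically zero
  pb0 <- recordPlayback(m, gabaSynapse(-50.5, gmax = 2, onsets = 100), cfg)
  expect_equal(max(abs(pb0@wave)), 0, tolerance = 1e-9)
  # dt mismatch is rejected
  expect_error(runSweep(m, list(new("PlaybackCurrent", section = "soma",
                                    pos = 0.5, wave = pb@wave, dt = 0.05)),
                        cfg), "dt")
})
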