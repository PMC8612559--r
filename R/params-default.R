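# Calibrated default channel parameters.
#
# The Na+ activation/inactivation pair and the narrow delayed-rectifier
# activation window were calibrated once, against the reference excitability
# of immature CA3 pyramidal neurons (resting potential -50.5 mV, long-step
# rheobase 4.25 pA in the ball model and 6.55 pA in the ball-and-stick
# model, quasi-stationary spike threshold -42.8 mV, spike overshoot > +50
# mV), by solving the steady-state current-balance conditions for the
# threshold fold and refining against the packaged search protocols. See the
# methods vignette for the calibration rationale.

.default_na <- function() {
  NaChannelParams(gmax = 1.931424e-3, erev = 60,
                  Gco = 1, Goc = 1, Gic = 1, Gci = 1,
                  Vco = -32, Vic = -35, kco = 1.5, kic = 6,
                  tauAct = 0.1, tauIna = 5, tauRelax = 3,
                  cf = 20, q10 = 1)
}

.default_k <- function() {
  KChannelParams(gmax = 2.189386e-6, erev = -90,
                 Gco = 1, Goc = 1,
                 Vco = -43.28, Vic = -43.28, kco = 0.2, kic = 0.2,
                 tauAct = 0.1, tauIna = 0.1, tauRelax = 50,
                 cf = 0, q10 = 1)
}
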