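#' Double-exponential synaptic conductance waveform
#'
#' Evaluates the peak-normalized Exp2 conductance
#' \code{g(t) = gmax * N * (exp(-(t-t0)/tau2) - exp(-(t-t0)/tau1))} summed
#' over all onsets, with N chosen so that each event peaks at exactly
#' \code{gmax} at \code{t0 + tau1*tau2/(tau2-tau1)*log(tau2/tau1)}.
#'
#' @param t times, ms
#' @param spec an \linkS4class{Exp2Synapse}
#' @return conductance, nS (0 before the first onset)
#' @export
exp2Conductance <- function(t, spec) {
  stopifnot(is(spec, "Exp2Synapse"))
  if (any(t < 0)) stop("t must be >= 0")
  tp <- spec@tau1 * spec@tau2 / (spec@tau2 - spec@tau1) *
    log(spec@tau2 / spec@tau1)
  norm <- 1 / (exp(-tp / spec@tau2) - exp(-tp / spec@tau1))
  g <- numeric(length(t))
  for (t0 in spec@onsets) {
    dtq <- t - t0
    on <- dtq >= 0
    g[on] <- g[on] + spec@gmax * norm *
      (exp(-dtq[on] / spec@tau2) - exp(-dtq[on] / spec@tau1))
  }
  pmax(g, 0)
}

#' Peak time of the double-exponential conductance
#' @param tau1,tau2 rise and decay time constants, ms
#' @return time from onset to peak, ms
#' @export
exp2PeakTime <- function(tau1, tau2) {
  if (!(tau1 > 0 && tau1 < tau2)) stop("need 0 < tau1 < tau2")
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' Record a synaptic current for current-clamp playback
#'
#' Runs the model with the given GABA synapse and the spike mechanism
#' disabled, records the synaptic current (depolarizing-positive), and
#' returns it as a \linkS4class{PlaybackCurrent} to be re-injected at the
#' synapse site. Replaying the current isolates the GABAergic depolarization
#' from the GABAergic conductance shunt: in a passive model the playback
#' sweep reproduces the conductance sweep exactly.
#'
#' @param model a \linkS4class{CompartmentalModel}
#' @param gabaSpec the GABA \linkS4class{Exp2Synapse}
#' @param cfg solver configuration (apMechanism is forced off for the
#'   recording sweep)
#' @param otherStimuli additional stimuli present during the recording
#' @return a \linkS4class{PlaybackCurrent}
#' @export
recordPlayback <- function(model, gabaSpec, cfg = SolverConfig(tstop = 1000),
                           otherStimuli = list()) {
  stopifnot(is(gabaSpec, "Exp2Synapse"))
  rcfg <- cfg; rcfg@apMechanism <- FALSE
  sw <- runSweep(model, c(list(gabaSpec), otherStimuli), rcfg,
                 recordSynCurrent = 1L)
  new("PlaybackCurrent", section = gabaSpec@section, pos = gabaSpec@pos,
      wave = as.numeric(sw@isyn[1, ]), dt = cfg@dt)
}
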